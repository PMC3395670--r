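## Same-scale correction: aligning DNA scales across files, equivalent
## S-phase gates, and per-epitope regression onto the common single-colour
## (shared secondary antibody) intensity scale.
##
## Multi-colour fluorescence amplitudes are arbitrary per channel, so the
## cyclin A2 and B1 profiles from one multi-colour assay cannot be compared
## directly.  DNA content, measured with high precision, serves as the
## correlating variable: after stretching each file's DNA axis so its G1
## and G2 modes land on fixed channels, identical S-phase DNA gates select
## equivalent cell sets in every file, and regressing multi-colour against
## single-colour cyclin medians within those gates yields the affine map
## onto the common scale.

#' Detect the G1 and G2 modal channels of a DNA histogram
#'
#' Smoothed-histogram peak detection (512 bins, Gaussian kernel of 3 bins;
#' ties broken toward the lower channel).  The G1 mode is the most
#' prominent peak; the G2 mode is the most prominent peak near twice the G1
#' position.  A G2/G1 ratio outside [1.8, 2.2] triggers a warning.
#'
#' @param x a \linkS4class{CytoFrame} (its \code{dna_integral} channel) or
#'   a numeric vector of DNA intensities.
#' @param bins,bw_bins histogram bin count and smoothing bandwidth (bins).
#' @return named numeric: \code{g1} and \code{g2} modal channel values.
#' @export
findDnaModes <- function(x, bins = 512L, bw_bins = 3) {
  dna <- if (is(x, "CytoFrame")) {
    ch <- channelByRole(x, "dna_integral")
    if (!length(ch)) stop("no dna_integral channel")
    intensities(x)[, ch[1]]
  } else as.numeric(x)
  h <- .smoothed_hist(dna, bins = bins, bw_bins = bw_bins)
  pk <- .hist_peaks(h, min_frac = 0.04)
  if (length(pk$pos) < 2)
    stop("fewer than two DNA histogram peaks; cannot locate G1 and G2")
  g1 <- pk$pos[1]
  ratio <- pk$pos / g1
  cand <- which(ratio > 1.5 & ratio < 2.6)
  if (!length(cand)) {
    ## the tallest peak may itself be G2; look for a peak near half of it
    cand_lo <- which(ratio > 1 / 2.6 & ratio < 1 / 1.5)
    if (!length(cand_lo))
      stop("no second DNA peak near twice (or half) the main mode")
    g2 <- g1
    g1 <- pk$pos[cand_lo[1]]
  } else {
    g2 <- pk$pos[cand[1]]
  }
  if (g2 / g1 < 1.8 || g2 / g1 > 2.2)
    warning(sprintf("G2/G1 mode ratio %.3f outside [1.8, 2.2]", g2 / g1))
  c(g1 = g1, g2 = g2)
}

#' Two-point linear DNA rescaling transform
#'
#' The exact linear map sending the source G1 and G2 modes onto the target
#' channels (two constraints, two parameters).
#'
#' @param g1Mode,g2Mode source modal channels (g2Mode > g1Mode).
#' @param targetG1,targetG2 target modal channels (defaults 350 and 700).
#' @return a \linkS4class{DnaRescale}.
#' @export
dnaRescale <- function(g1Mode, g2Mode, targetG1 = 350, targetG2 = 700) {
  stopifnot(g2Mode > g1Mode)
  a <- (targetG2 - targetG1) / (g2Mode - g1Mode)
  b <- targetG1 - a * g1Mode
  methods::new("DnaRescale", g1Mode = g1Mode, g2Mode = g2Mode,
               targetG1 = targetG1, targetG2 = targetG2, a = a, b = b)
}

#' Apply a DNA rescaling transform to an event table
#'
#' Maps the \code{dna_integral} channel by \code{new = a * old + b}; after
#' the transform the G1 and G2 modes sit on the target channels to within
#' one histogram bin.
#'
#' @param table a \linkS4class{CytoFrame}.
#' @param rescale a \linkS4class{DnaRescale}, or NULL to derive one from
#'   the table's own modes with default targets.
#' @return the rescaled \linkS4class{CytoFrame}.
#' @export
rescaleDna <- function(table, rescale = NULL) {
  stopifnot(is(table, "CytoFrame"))
  if (is.null(rescale)) {
    modes <- findDnaModes(table)
    rescale <- dnaRescale(modes[["g1"]], modes[["g2"]])
  }
  ch <- channelByRole(table, "dna_integral")[1]
  m <- intensities(table)
  m[, ch] <- rescale@a * m[, ch] + rescale@b
  table <- .set_intensities(table, m)
  .log_step(table, "rescaleDna: %s -> a=%.6g b=%.6g", ch, rescale@a,
            rescale@b)
}

#' Equivalent S-phase DNA gates
#'
#' A series of contiguous, equal-width DNA-channel intervals centred on the
#' S-phase midpoint of the rescaled axis, expanding outward from the
#' middle.  Defaults: 7 gates centred at channel 525, total width spanning
#' \code{s_fraction} of the (targetG1, targetG2) span.
#'
#' @param n_gates number of gates (>= 1, default 7).
#' @param width per-gate width in channels; default
#'   \code{s_fraction * (targetG2 - targetG1) / n_gates}.
#' @param center centre channel (default midway between the targets).
#' @param s_fraction fraction of the G1-G2 span covered by the gate union
#'   (used only when \code{width} is NULL; default 0.8).
#' @param targetG1,targetG2 the rescaled modal channels (defaults 350, 700).
#' @return an \linkS4class{EquivalentGates}.
#' @export
buildEquivalentGates <- function(n_gates = 7, width = NULL, center = NULL,
                                 s_fraction = 0.8, targetG1 = 350,
                                 targetG2 = 700) {
  stopifnot(n_gates >= 1)
  if (is.null(center)) center <- (targetG1 + targetG2) / 2
  if (is.null(width)) width <- s_fraction * (targetG2 - targetG1) / n_gates
  lo <- center - n_gates * width / 2 + (seq_len(n_gates) - 1) * width
  iv <- cbind(lo = lo, hi = lo + width)
  if (iv[1, 1] <= targetG1 || iv[n_gates, 2] >= targetG2)
    stop("gate union exceeds the (", targetG1, ", ", targetG2, ") span")
  methods::new("EquivalentGates", intervals = iv, center = center)
}

#' Per-gate epitope medians
#'
#' Median epitope intensity of the events within each equivalent DNA gate,
#' in gate order.  Empty gates yield NA with a warning.
#'
#' @param table a DNA-rescaled \linkS4class{CytoFrame}.
#' @param gates an \linkS4class{EquivalentGates}.
#' @param epitope epitope channel name.
#' @return numeric vector of medians, one per gate.
#' @export
gateMedians <- function(table, gates, epitope) {
  stopifnot(is(table, "CytoFrame"), is(gates, "EquivalentGates"))
  ch <- channelByRole(table, "dna_integral")[1]
  m <- intensities(table)
  dna <- m[, ch]
  out <- apply(gates@intervals, 1, function(iv) {
    sel <- dna >= iv[1] & dna < iv[2]
    if (!any(sel)) return(NA_real_)
    stats::median(m[sel, epitope])
  })
  if (anyNA(out)) warning("empty equivalent gate(s)")
  unname(out)
}

#' Derive the same-scale map from paired gate medians
#'
#' Ordinary least squares of single-colour on multi-colour medians from the
#' same equivalent gate set: \code{single = slope * multi + intercept}.
#' Background subtraction should force the intercept near zero; it is left
#' free so that assumption stays testable.
#'
#' @param multi_medians,single_medians equal-length ordered median vectors.
#' @param marker epitope name recorded on the map.
#' @return a \linkS4class{ScalingMap}.
#' @export
deriveScaling <- function(multi_medians, single_medians, marker = "") {
  ok <- is.finite(multi_medians) & is.finite(single_medians)
  x <- multi_medians[ok]; y <- single_medians[ok]
  if (length(x) < 3) stop("need at least 3 paired medians")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive same-scale slope; assays are not comparable")
  methods::new("ScalingMap", slope = slope,
               intercept = unname(stats::coef(fit)[1]),
               r.squared = suppressWarnings(summary(fit)$r.squared),
               residuals = unname(stats::residuals(fit)), marker = marker)
}

#' @rdname applyScaling
#' @export
setMethod("applyScaling", signature("ExpressionProfile", "ScalingMap"),
          function(profile, map) {
  profile@y <- map@slope * profile@y + map@intercept
  profile@scaleTag <- "samescale"
  methods::validObject(profile)
  profile
})
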