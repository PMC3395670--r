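## Pre-processing: spectral-overlap compensation, G1-anchored background
## subtraction, debris/aggregate exclusion, and the 2C stemline gate.

#' Compensation specification
#'
#' Ordered spillover pairs: each row subtracts \code{coef * from} from
#' channel \code{into}, in listed order.
#'
#' @param from,into character vectors of source and target channel names.
#' @param coef numeric spillover coefficients in [0, 1).
#' @return a data.frame with class \code{"CompensationSpec"}.
#' @export
compensationSpec <- function(from, into, coef) {
  stopifnot(length(from) == length(into), length(from) == length(coef))
  if (any(from == into)) stop("self-spillover pairs are not allowed")
  if (any(coef < 0 | coef >= 1)) stop("coefficients must lie in [0, 1)")
  structure(data.frame(from = from, into = into, coef = coef),
            class = c("CompensationSpec", "data.frame"))
}

#' Correct spectral spillover between channels
#'
#' Applies \code{into = into - coef * from} for each spec row in order.
#' Negative results are permitted (they are clipped later only where an
#' operation requires positivity).
#'
#' @param table a \linkS4class{CytoFrame}.
#' @param spec a \code{\link{compensationSpec}}.
#' @return the compensated \linkS4class{CytoFrame}.
#' @export
compensate <- function(table, spec) {
  stopifnot(is(table, "CytoFrame"))
  m <- intensities(table)
  for (i in seq_len(nrow(spec))) {
    f <- spec$from[i]; g <- spec$into[i]
    if (!all(c(f, g) %in% colnames(m)))
      stop("compensation channel missing: ", f, " or ", g)
    m[, g] <- m[, g] - spec$coef[i] * m[, f]
  }
  table <- .set_intensities(table, m)
  .log_step(table, "compensate: %d pair(s) [%s]", nrow(spec),
            paste(sprintf("%s->%s:%.3g", spec$from, spec$into, spec$coef),
                  collapse = ", "))
}

## Auto G1 gate: DNA within +/- `width` of the G1 mode.  At 2C DNA content
## every cell is in G1 (mitosis sits at 4C), so a DNA window suffices even
## without light scatter.
.auto_g1_mask <- function(table, width = 0.15) {
  dna_ch <- channelByRole(table, "dna_integral")[1]
  dna <- intensities(table)[, dna_ch]
  g1 <- .dens_mode(dna)
  abs(dna - g1) <= width * g1
}

#' Subtract G1-anchored background fluorescence
#'
#' Estimates per-epitope background as the median intensity of G1-gated
#' events (cyclins are not expressed in early G1, so the G1 cluster is pure
#' background staining) and subtracts it, setting negative cells close to
#' zero.  Negative results are retained so background clusters stay
#' symmetric for downstream Gaussian fits.
#'
#' @param table a \linkS4class{CytoFrame}.
#' @param g1_gate logical event mask, a \linkS4class{Region}/
#'   \linkS4class{GateExpr}, or NULL to derive a DNA-window G1 gate
#'   automatically.
#' @param channels epitope channels to correct (default: all channels with
#'   role "epitope").
#' @param min_events minimum number of G1-gated events required.
#' @return list with elements \code{table} (corrected) and \code{anchor}
#'   (named numeric of subtracted offsets plus the gate description).
#' @export
subtractBackground <- function(table, g1_gate = NULL, channels = NULL,
                               min_events = 200) {
  stopifnot(is(table, "CytoFrame"))
  mask <- if (is.null(g1_gate)) .auto_g1_mask(table)
          else if (is.logical(g1_gate)) g1_gate
          else evaluateGate(table, g1_gate)
  if (sum(mask) < min_events)
    stop("G1 gate selects only ", sum(mask), " events (need >= ",
         min_events, ")")
  if (is.null(channels)) channels <- channelByRole(table, "epitope")
  m <- intensities(table)
  offsets <- vapply(channels, function(ch) stats::median(m[mask, ch]),
                    numeric(1))
  for (ch in channels) m[, ch] <- m[, ch] - offsets[[ch]]
  table <- .set_intensities(table, m)
  table <- .log_step(table, "subtractBackground: %s",
                     paste(sprintf("%s-%.4g", channels, offsets),
                           collapse = ", "))
  list(table = table,
       anchor = list(offsets = offsets,
                     gate = if (is.null(g1_gate)) "auto DNA G1 window"
                            else "user gate",
                     n_g1 = sum(mask)))
}

#' Exclude sub-cellular debris and aggregates
#'
#' Removes events below a DNA-integral debris floor and events below the
#' singlet discrimination line in the pulse height-versus-integral plane
#' (aggregates carry more DNA integral per unit pulse height than single
#' cells).  The line is a through-origin boundary height >= m * integral
#' with slope m set from a low quantile of the height/integral ratio over
#' the 2C (G1) cluster.
#'
#' @param table a \linkS4class{CytoFrame} with \code{dna_integral} and
#'   \code{dna_height} channels.
#' @param debris_floor DNA-integral threshold; default 0.75 of the G1 mode.
#' @param ratio_quantile quantile of the 2C-cluster height/integral ratio
#'   anchoring the singlet line (default 0.01).
#' @param ratio_factor safety factor applied below that quantile
#'   (default 0.8).
#' @return the filtered \linkS4class{CytoFrame}.
#' @export
excludeDebrisAggregates <- function(table, debris_floor = NULL,
                                    ratio_quantile = 0.01,
                                    ratio_factor = 0.8) {
  stopifnot(is(table, "CytoFrame"))
  dna_ch <- channelByRole(table, "dna_integral")
  h_ch <- channelByRole(table, "dna_height")
  if (!length(dna_ch) || !length(h_ch))
    stop("dna_integral and dna_height channels are both required")
  m <- intensities(table)
  dna <- m[, dna_ch[1]]
  h <- m[, h_ch[1]]
  g1 <- .dens_mode(dna)
  if (is.null(debris_floor)) debris_floor <- 0.75 * g1
  cl <- abs(dna - g1) <= 0.15 * g1 & dna > 0
  keep_all <- rep(TRUE, length(dna))
  if (sum(cl) >= 50) {
    slope <- ratio_factor *
      stats::quantile(h[cl] / dna[cl], ratio_quantile, names = FALSE)
    keep_all <- h >= slope * dna
  }
  keep <- keep_all & dna >= debris_floor
  table <- .subset_events(table, keep)
  .log_step(table, "excludeDebrisAggregates: kept %d/%d (floor=%.4g)",
            sum(keep), length(keep), debris_floor)
}

#' Gate the 2C stemline
#'
#' Restricts analysis to the main 2C -> 4C proliferating subpopulation on a
#' bivariate plot of cyclin A2 versus DNA content, excluding
#' endoreduplicated/binucleate G1 cells, cyclin-negative outliers and
#' anything outside the 2C-4C DNA span.
#'
#' @param table a \linkS4class{CytoFrame} of interphase events.
#' @param region a \linkS4class{Region} on (dna_integral, epitope); NULL
#'   derives a default rectangle spanning 0.75 x G1 mode to 1.25 x G2 mode
#'   in DNA and the full epitope range.
#' @param epitope epitope channel defining the view (default "cycA").
#' @return the gated \linkS4class{CytoFrame}; empty results raise a
#'   warning.
#' @export
stemlineGate <- function(table, region = NULL, epitope = "cycA") {
  stopifnot(is(table, "CytoFrame"))
  dna_ch <- channelByRole(table, "dna_integral")[1]
  m <- intensities(table)
  if (is.null(region)) {
    modes <- findDnaModes(table)
    y <- m[, epitope]
    pad <- 0.05 * max(abs(y), 1)
    region <- rectangleRegion("stemline", c(dna_ch, epitope),
                              0.75 * modes[["g1"]], 1.25 * modes[["g2"]],
                              min(y) - pad, max(y) + pad)
  }
  keep <- evaluateGate(table, region)
  if (!any(keep)) warning("stemline gate retained no events")
  table <- .subset_events(table, keep)
  .log_step(table, "stemlineGate: kept %d/%d ('%s')", sum(keep),
            length(keep), region@id)
}
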