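## Synthetic asynchronous-population generator with known ground truth.
##
## The generator emulates an exponentially growing culture: cell-cycle ages
## follow the steady-state age density phi(t) = 2 ln2 * 2^(-t) on [0, 1]
## (one mitotic cell yields two newborns, so the density declines from a
## factor of 2 to 1 across the cycle), marker kinetics are piecewise-linear
## functions of age, and the measurement process applies per-assay gains,
## spectral spillover, additive background and multiplicative lognormal
## noise, plus doublet and debris contamination.

#' Steady-state age density and CDF of an exponentially growing population
#'
#' \code{ageDensity} is phi(t) = 2 ln2 * 2^(-t); \code{ageCDF} its integral
#' F(t) = 2 - 2^(1 - t).  Both are defined on t in [0, 1].
#'
#' @param t numeric vector of cell-cycle times in [0, 1].
#' @return numeric vector.
#' @export
ageDensity <- function(t) {
  stopifnot(all(t >= 0 & t <= 1))
  2 * log(2) * 2^(-t)
}

#' @rdname ageDensity
#' @export
ageCDF <- function(t) {
  stopifnot(all(t >= 0 & t <= 1))
  2 - 2^(1 - t)
}

#' Sample cell-cycle ages from the exponential age distribution
#'
#' Draws ages by exact inverse-CDF sampling: t = 1 - log2(2 - u) with
#' u ~ Uniform(0, 1).
#'
#' @param n number of ages to draw (>= 1).
#' @param seed optional integer seed; identical seed gives identical draws.
#' @return numeric vector of n ages in [0, 1].
#' @examples
#' mean(sampleAges(1000, seed = 1) < 0.5)  # about ageCDF(0.5) = 0.586
#' @export
sampleAges <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  .with_seed(seed, {
    u <- stats::runif(as.integer(n))
    1 - log2(2 - u)
  })
}

#' Ground-truth marker kinetics for the synthetic population
#'
#' Builds the default \linkS4class{TruthProfiles}: DNA in C units (2 through
#' G1, linear 2 -> 4 across S, 4 through G2/M); cyclin A2 zero through G1,
#' rising through S and G2 to a peak of 100 at the end of the mitotic pHH3
#' surge, degraded to zero by mid-M; cyclin B1 rising from late G1, peaking
#' with cyclin A2 and held during cyclin A2 degradation, then degraded to
#' zero after cyclin A2; pHH3 basal in G1 doubling linearly to G2, surging
#' sharply at mitotic entry and partially dephosphorylated before division
#' (ending at twice the G1 basal level).
#'
#' @param t_G1S,t_SG2,t_G2M phase boundary times (fractions of the cycle).
#' @param peak cyclin peak level, arbitrary units.
#' @param phh3_basal interphase pHH3 level at t = 0, as a fraction of the
#'   mitotic pHH3 peak (default 0.05).
#' @param surge_width duration of the mitotic pHH3 rise (fraction of the
#'   cycle).
#' @return a \linkS4class{TruthProfiles}.
#' @export
truthProfiles <- function(t_G1S = 0.40, t_SG2 = 0.80, t_G2M = 0.95,
                          peak = 100, phh3_basal = 0.05,
                          surge_width = 0.002) {
  pk <- peak
  b <- phh3_basal * pk
  t_surge <- t_G2M + surge_width      # pHH3 plateau reached
  t_a_zero <- t_G2M + 0.4 * (1 - t_G2M)    # cyclin A2 fully degraded (mid-M)
  t_b_zero <- t_G2M + 0.7 * (1 - t_G2M)    # cyclin B1 fully degraded, later
  t_ret <- t_b_zero                   # pHH3 partial return once B1 is gone
  knots <- list(
    dna = cbind(c(0, t_G1S, t_SG2, 1), c(2, 2, 4, 4)),
    cycA = cbind(c(0, t_G1S, t_SG2, t_surge, t_a_zero, 1),
                 c(0, 0, 0.6 * pk, pk, 0, 0)),
    cycB = cbind(c(0, 0.75 * t_G1S, t_G1S, t_SG2, t_surge, t_a_zero, t_b_zero, 1),
                 c(0, 0, 0.08 * pk, 0.7 * pk, pk, pk, 0, 0)),
    phh3 = cbind(c(0, t_G2M, t_surge, t_ret, 1),
                 c(b, 2 * b, pk, pk, 2 * b))
  )
  methods::new("TruthProfiles", knots = knots,
               phaseTimes = c(t_G1S = t_G1S, t_SG2 = t_SG2, t_G2M = t_G2M))
}

#' Evaluate a ground-truth marker profile
#'
#' @param truth a \linkS4class{TruthProfiles}.
#' @param marker marker name present in the truth set.
#' @param t numeric times in [0, 1].
#' @return numeric truth values.
#' @export
truthValue <- function(truth, marker, t) {
  if (!marker %in% names(truth@knots))
    stop("no truth profile for marker ", marker)
  .pwl_fun(truth@knots[[marker]])(t)
}

#' Phase label of a cell-cycle time
#'
#' @param truth a \linkS4class{TruthProfiles}.
#' @param t numeric times in [0, 1].
#' @return character vector in G1/S/G2/M.
#' @export
truthPhase <- function(truth, t) {
  pt <- truth@phaseTimes
  cut(t, breaks = c(-Inf, pt[["t_G1S"]], pt[["t_SG2"]], pt[["t_G2M"]], Inf),
      labels = c("G1", "S", "G2", "M"), right = FALSE) |> as.character()
}

## phase codes used in the truth_phase column (0 = contamination event)
.PHASE_CODES <- c(G1 = 1, S = 2, G2 = 3, M = 4)

#' Measurement-process model for the synthetic generator
#'
#' @param cv named per-channel lognormal CV (fractions in (0, 0.5)).
#' @param spillover list of \code{list(from=, into=, coef=)} spillover
#'   entries (coefficient in [0, 0.5)).
#' @param offset named per-channel additive background (nonspecific
#'   staining), applied before the multiplicative noise.
#' @param gain named per-channel multiplicative assay gain.
#' @param doubletFrac,debrisFrac contamination fractions in [0, 0.2].
#' @param nEvents number of singlet events.
#' @param seed integer RNG seed.
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(cv = c(dna = 0.03, dna_h = 0.04, cycA = 0.12,
                              cycB = 0.12, phh3 = 0.15),
                       spillover = list(list(from = "phh3", into = "cycA",
                                             coef = 0.08)),
                       offset = c(cycA = 3, cycB = 3),
                       gain = numeric(),
                       doubletFrac = 0.03, debrisFrac = 0.02,
                       nEvents = 20000, seed = 1) {
  methods::new("NoiseModel", cv = cv, spillover = spillover, offset = offset,
               gain = gain, doubletFrac = doubletFrac,
               debrisFrac = debrisFrac, nEvents = nEvents, seed = seed)
}

## look up a named per-channel parameter with a default
.chan_par <- function(vec, channel, default) {
  if (channel %in% names(vec)) unname(vec[[channel]]) else default
}

#' Generate a synthetic asynchronous-population event table
#'
#' Draws ages from the exponential age distribution, evaluates the truth
#' profiles, then applies the measurement process in order: per-channel gain,
#' spectral spillover, additive background offset, multiplicative lognormal
#' noise.  A configured fraction of doublets (summed pairs whose DNA pulse
#' height falls below the singlet discrimination line) and low-DNA debris is
#' appended.  Ground truth is retained in reserved \code{truth_} columns
#' (\code{truth_t}: age, -1 for contamination; \code{truth_phase}: 1 = G1,
#' 2 = S, 3 = G2, 4 = M, 0 = contamination; \code{truth_doublet},
#' \code{truth_debris}: 0/1 flags) so downstream tests can use them as
#' oracles without touching analysis channels.
#'
#' @param truth a \linkS4class{TruthProfiles}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param markers epitope channels to include (subset of the truth markers
#'   other than DNA).
#' @param heightScale DNA pulse-height per unit DNA integral for singlets.
#' @return a \linkS4class{CytoFrame} with channels \code{dna},
#'   \code{dna_h}, the requested markers, and the truth columns.
#' @export
generatePopulation <- function(truth, noise,
                               markers = c("cycA", "cycB", "phh3"),
                               heightScale = 1) {
  stopifnot(is(truth, "TruthProfiles"), is(noise, "NoiseModel"))
  methods::validObject(truth); methods::validObject(noise)
  markers <- match.arg(markers, setdiff(names(truth@knots), "dna"),
                       several.ok = TRUE)
  n <- as.integer(noise@nEvents)
  .with_seed(noise@seed, {
    t <- sampleAges(n)
    nd <- as.integer(round(noise@doubletFrac * n))
    nb <- as.integer(round(noise@debrisFrac * n))
    td1 <- if (nd) sampleAges(nd) else numeric()
    td2 <- if (nd) sampleAges(nd) else numeric()

    chans <- c("dna", markers)
    clean <- vapply(chans, function(ch) truthValue(truth, ch, t),
                    numeric(length(t)))
    clean <- matrix(clean, ncol = length(chans),
                    dimnames = list(NULL, chans))
    if (nd) {
      dval <- vapply(chans, function(ch)
        truthValue(truth, ch, td1) + truthValue(truth, ch, td2),
        numeric(nd))
      clean <- rbind(clean, matrix(dval, ncol = length(chans),
                                   dimnames = list(NULL, chans)))
    }
    if (nb) {
      bval <- matrix(0, nb, length(chans), dimnames = list(NULL, chans))
      bval[, "dna"] <- stats::runif(nb, 0.1, 0.7) * 2
      clean <- rbind(clean, bval)
    }
    ntot <- nrow(clean)
    is_doublet <- c(rep(0, n), rep(1, nd), rep(0, nb))
    is_debris <- c(rep(0, n + nd), rep(1, nb))

    ## pulse height: proportional to integral for singlets and debris;
    ## doublets sit well below the singlet line (two nuclei in one pulse)
    height <- heightScale * clean[, "dna"]
    height[is_doublet == 1] <- 0.55 * height[is_doublet == 1]
    m <- cbind(clean, dna_h = height)

    ## measurement process: gain -> spillover -> offset -> lognormal noise
    for (ch in colnames(m))
      m[, ch] <- m[, ch] * .chan_par(noise@gain, ch, 1)
    if (length(noise@spillover)) {
      spilled <- m
      for (sp in noise@spillover)
        if (all(c(sp$from, sp$into) %in% colnames(m)))
          spilled[, sp$into] <- spilled[, sp$into] + sp$coef * m[, sp$from]
      m <- spilled
    }
    for (ch in names(noise@offset))
      if (ch %in% colnames(m)) m[, ch] <- m[, ch] + noise@offset[[ch]]
    for (ch in colnames(m)) {
      sig <- .sigma_from_cv(.chan_par(noise@cv, ch, 0.05))
      m[, ch] <- m[, ch] * exp(stats::rnorm(ntot, 0, sig))
    }

    phase <- c(.PHASE_CODES[truthPhase(truth, t)], rep(0, nd + nb))
    out <- cbind(m[, c("dna", "dna_h", markers), drop = FALSE],
                 truth_t = c(t, rep(-1, nd + nb)),
                 truth_phase = unname(phase),
                 truth_doublet = is_doublet,
                 truth_debris = is_debris)
    roles <- c(dna = "dna_integral", dna_h = "dna_height",
               stats::setNames(rep("epitope", length(markers)), markers))
    cf <- CytoFrame(out, roles = roles)
    .log_step(cf, "generatePopulation: n=%d doublets=%d debris=%d seed=%s",
              n, nd, nb, format(noise@seed))
  })
}

#' Generate a matched multi-colour / single-colour assay trio
#'
#' Draws three event tables from the same truth kinetics, mimicking one
#' multi-colour direct-stain assay (all markers, independent arbitrary gains
#' per cyclin channel) and two single-colour indirect assays (one cyclin
#' each, detected with the same secondary antibody and therefore sharing one
#' gain).  The shared single-colour gain is what places the two cyclins on a
#' common intensity scale.
#'
#' @param truth a \linkS4class{TruthProfiles}.
#' @param noise_multi noise model for the multi-colour assay.
#' @param noise_single_A,noise_single_B noise models for the single-colour
#'   cyclin A2 and cyclin B1 assays; their gains for their respective
#'   cyclin channels must be equal (same secondary antibody).
#' @return named list of three \linkS4class{CytoFrame}s: \code{multi},
#'   \code{singleA}, \code{singleB}.
#' @export
generateAssayPair <- function(truth, noise_multi, noise_single_A,
                              noise_single_B) {
  gA <- .chan_par(noise_single_A@gain, "cycA", 1)
  gB <- .chan_par(noise_single_B@gain, "cycB", 1)
  if (abs(gA - gB) > 1e-12 * max(gA, gB))
    stop("single-colour assays must share one cyclin gain ",
         "(same secondary antibody); got ", gA, " and ", gB)
  list(
    multi = generatePopulation(truth, noise_multi,
                               markers = c("cycA", "cycB", "phh3")),
    singleA = generatePopulation(truth, noise_single_A, markers = "cycA"),
    singleB = generatePopulation(truth, noise_single_B, markers = "cycB")
  )
}
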