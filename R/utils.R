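## Internal numerical helpers shared across modules.

## Piecewise-linear interpolator from a 2-column (x, y) knot matrix.
## Constant extrapolation beyond the end knots; duplicate x allowed in the
## truth tables (step-like kinetics) and resolved left-continuously.
.pwl_fun <- function(knots) {
  x <- knots[, 1]
  y <- knots[, 2]
  force(x); force(y)
  function(t) {
    stats::approx(x, y, xout = t, method = "linear", rule = 2,
                  ties = list("ordered", min))$y
  }
}

## Run code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}

## Lognormal sigma (of log) from a coefficient of variation.
.sigma_from_cv <- function(cv) sqrt(log1p(cv^2))

## Smoothed histogram of a numeric vector: fixed bin count over the data
## range, Gaussian kernel smoothing with the given bandwidth in bins.
.smoothed_hist <- function(x, bins = 512L, bw_bins = 3) {
  rng <- range(x)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  half <- ceiling(3 * bw_bins)
  kern <- stats::dnorm(seq(-half, half), sd = bw_bins)
  kern <- kern / sum(kern)
  sm <- stats::filter(c(rep(counts[1], half), counts, rep(counts[bins], half)),
                      kern, sides = 2)
  sm <- as.numeric(sm)[(half + 1L):(half + bins)]
  list(mids = mids, counts = counts, smooth = sm, breaks = breaks)
}

## Local maxima of a smoothed histogram, ordered by height (ties toward the
## lower channel).  Returns mid positions and heights.
.hist_peaks <- function(h, min_frac = 0.05) {
  s <- h$smooth
  n <- length(s)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    is_peak[i] <- s[i] == max(s[lo:hi]) && s[i] > 0
  }
  ## collapse plateau runs to their lowest-channel bin
  idx <- which(is_peak)
  keep <- idx[c(TRUE, diff(idx) > 2L)]
  keep <- keep[s[keep] >= min_frac * max(s)]
  ord <- order(-s[keep], h$mids[keep])
  list(pos = h$mids[keep][ord], height = s[keep][ord])
}

## Mode of a numeric vector via the smoothed histogram.
.dens_mode <- function(x, bins = 512L, bw_bins = 3) {
  h <- .smoothed_hist(x, bins = bins, bw_bins = bw_bins)
  h$mids[which.max(h$smooth)]
}

.msg <- function(...) message(sprintf(...))
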