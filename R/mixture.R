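## Boundary-anchored constrained multi-Gaussian deconvolution of phase
## (G1, G2) log-intensity distributions.
##
## The G1 and G2 clusters each collapse a stretch of real expression change
## into one unimodal histogram.  To recover the change without reading
## statistical error as expression, the histogram is modelled as the sum of
## three weighted Gaussians whose outer components are anchored to the
## distributions measured in the thin transition ovals (phase entry and
## exit); the centre component is pinned midway.  Because such fits are
## degenerate (many weight triples fit one unimodal shape), the component
## masses are loosely constrained so that the (cumulative-frequency, mean)
## points continue the expression trajectory extrapolated from S phase;
## the looseness is an explicit quadratic penalty with weight lambda.

## log10 transform with a floor at floor_frac-of-99th-percentile; errors if
## more than max_nonpos of the values sit at or below zero.
.log_values <- function(values, max_nonpos = 0.5, eps_frac = 1e-3) {
  if (!length(values)) stop("no values to fit")
  frac_np <- mean(values <= 0)
  if (frac_np > max_nonpos)
    stop(sprintf("%.0f%% of values are non-positive (limit %.0f%%)",
                 100 * frac_np, 100 * max_nonpos))
  eps <- eps_frac * stats::quantile(values, 0.99, names = FALSE)
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  log10(pmax(values, eps))
}

## default histogram bin count: target ~150 events per bin, clamped to
## [32, 256].  Least-squares histogram fits are limited by the Poisson
## noise floor of the bin counts, so bins scale with event count; the
## 32-bin floor still resolves component SDs (~0.05 log10 over a ~0.6
## log10 range) about three-fold
.fit_bins <- function(n) max(32L, min(256L, as.integer(floor(n / 150))))

## histogram over the log range containing 99.9% of the values
.fit_hist <- function(lv, bins = NULL) {
  if (is.null(bins)) bins <- .fit_bins(length(lv))
  qr <- stats::quantile(lv, c(0.0005, 0.9995), names = FALSE)
  if (diff(qr) <= 0) qr <- qr + c(-0.05, 0.05)
  breaks <- seq(qr[1], qr[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(lv, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  list(breaks = breaks, counts = counts)
}

## expected bin counts of one unit-mass Gaussian (exact bin integrals)
.gauss_bin <- function(breaks, mean, sd) {
  p <- stats::pnorm(breaks, mean, sd)
  diff(p)
}

#' Coefficient of determination between a histogram and a fitted sum
#'
#' R^2 = 1 - SS_res / SS_tot over bin counts.
#'
#' @param counts observed bin counts.
#' @param fitted fitted bin counts on the same bin grid.
#' @return scalar R^2 (at most 1; can be negative for poor fits).
#' @export
rSquared <- function(counts, fitted) {
  if (length(counts) != length(fitted))
    stop("counts and fitted must share one bin grid")
  ss_tot <- sum((counts - mean(counts))^2)
  if (ss_tot == 0) stop("zero-variance histogram")
  1 - sum((counts - fitted)^2) / ss_tot
}

#' Fit a single anchor Gaussian to transition-oval values
#'
#' Maximum-likelihood single-Gaussian fit (sample mean and SD) to the
#' log10 intensities of a transition-oval gate (G1/S, S/G2 or G2/M),
#' providing the mean and deviation that anchor the adjacent phase
#' cluster's deconvolution.
#'
#' @param values positive intensities from the oval gate (>= \code{min_n}).
#' @param min_n minimum number of values (default 50).
#' @param max_nonpos largest tolerated fraction of non-positive values
#'   (floored before the log transform).
#' @param sd_floor smallest admissible SD (log10 units); constant input is
#'   floored here with a warning.
#' @return a \linkS4class{GaussianComponent} (weight = number of values).
#' @export
fitAnchor <- function(values, min_n = 50, max_nonpos = 0.5,
                      sd_floor = 1e-3) {
  if (length(values) < min_n)
    stop("need at least ", min_n, " values, got ", length(values))
  lv <- .log_values(values, max_nonpos)
  s <- stats::sd(lv)
  if (!is.finite(s) || s < sd_floor) {
    warning("degenerate spread; SD floored at ", sd_floor)
    s <- sd_floor
  }
  methods::new("GaussianComponent", mean = mean(lv), sd = s,
               weight = as.numeric(length(values)), constraint = "free")
}

## Core constrained least-squares fitter.
##
## comps: data.frame(mean, sd, sd_free, constraint); weights always free.
## trajectory/fwin: continuity penalty support (see fitG2).
.fit_constrained <- function(lv, comps, lambda = 1, trajectory = NULL,
                             fwin = NULL, bins = NULL) {
  h <- .fit_hist(lv, bins)
  counts <- h$counts
  n <- sum(counts)
  k <- nrow(comps)
  var_c <- stats::var(counts)
  if (!is.finite(var_c) || var_c <= 0) var_c <- 1

  traj_fun <- NULL
  y_scale <- 1
  if (!is.null(trajectory) && lambda > 0 && !is.null(fwin)) {
    tx <- trajectory@x; ty <- trajectory@y
    m <- length(tx)
    slope_hi <- (ty[m] - ty[m - 1]) / (tx[m] - tx[m - 1])
    slope_lo <- (ty[2] - ty[1]) / (tx[2] - tx[1])
    ## linear extrapolation beyond either end of the expression line,
    ## floored at zero (expression cannot be negative)
    traj_fun <- function(x) {
      y <- numeric(length(x))
      lo <- x < tx[1]; hi <- x > tx[m]; mid <- !lo & !hi
      y[lo] <- ty[1] + slope_lo * (x[lo] - tx[1])
      y[hi] <- ty[m] + slope_hi * (x[hi] - tx[m])
      if (any(mid)) y[mid] <- evaluateProfile(trajectory, x[mid])
      pmax(y, 0)
    }
    y_scale <- max(abs(ty), 1e-9)
  }

  shapes <- function(sds) {
    vapply(seq_len(k), function(i)
      .gauss_bin(h$breaks, comps$mean[i], sds[i]), numeric(length(counts)))
  }
  sd_free <- which(comps$sd_free)
  ## component masses live on the simplex scaled to the histogram mass, so
  ## the continuity penalty can only redistribute mass, never destroy it
  to_weights <- function(theta) {
    a <- theta[seq_len(k)]
    n * a / sum(a)
  }
  objective <- function(theta) {
    w <- to_weights(theta)
    sds <- comps$sd
    if (length(sd_free)) sds[sd_free] <- theta[k + seq_along(sd_free)]
    pred <- shapes(sds) %*% w
    obj <- mean((counts - pred)^2) / var_c
    if (!is.null(traj_fun)) {
      xk <- fwin[1] + (cumsum(w) - w / 2) / n * (fwin[2] - fwin[1])
      yk <- 10^comps$mean
      dev <- (traj_fun(xk) - yk) / y_scale
      obj <- obj + lambda * sum(dev^2)
    }
    obj
  }
  starts <- list(rep(1 / k, k),
                 c(0.6, rep(0.4 / (k - 1), k - 1)),
                 c(rep(0.4 / (k - 1), k - 1), 0.6))
  lower <- c(rep(1e-6, k), rep(min(comps$sd) * 0.25, length(sd_free)))
  upper <- c(rep(1, k), rep(max(comps$sd) * 4, length(sd_free)))
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    theta0 <- c(st, comps$sd[sd_free])
    fit <- tryCatch(
      stats::optim(theta0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("constrained mixture optimisation failed")
  w <- to_weights(best$par)
  sds <- comps$sd
  if (length(sd_free)) sds[sd_free] <- best$par[k + seq_along(sd_free)]
  fitted <- as.numeric(shapes(sds) %*% w)
  comp_objs <- lapply(seq_len(k), function(i)
    methods::new("GaussianComponent", mean = comps$mean[i], sd = sds[i],
                 weight = w[i], constraint = comps$constraint[i]))
  methods::new("ComponentFit", components = comp_objs, breaks = h$breaks,
               counts = as.numeric(counts), fitted = fitted,
               r.squared = rSquared(counts, fitted),
               mse = mean((counts - fitted)^2), converged = converged)
}

## Single-Gaussian "fit" packaged as a ComponentFit (degenerate cases).
.fit_single <- function(values, bins = NULL) {
  g <- fitAnchor(values, min_n = 2)
  lv <- .log_values(values)
  h <- .fit_hist(lv, bins)
  fitted <- sum(h$counts) * .gauss_bin(h$breaks, g@mean, g@sd)
  g@weight <- sum(h$counts)
  methods::new("ComponentFit", components = list(g), breaks = h$breaks,
               counts = as.numeric(h$counts), fitted = fitted,
               r.squared = rSquared(h$counts, fitted),
               mse = mean((h$counts - fitted)^2), converged = TRUE)
}

#' Deconvolve a G2 phase cluster between its entry and exit anchors
#'
#' Fits the histogram of log10 G2 intensities as three Gaussian
#' components: the outer two fixed to the S/G2 (entry) and G2/M (exit)
#' anchor fits, the centre pinned midway between them with a free SD.
#' Component masses minimise the histogram mean squared error plus
#' \code{lambda} times the squared deviation of the three
#' (cumulative-frequency, mean) points from the S-phase expression
#' trajectory extrapolated into G2.  Anchors equal within tolerance route
#' to a single-component fit.
#'
#' @param values positive G2 intensities.
#' @param entry,exit \linkS4class{GaussianComponent} anchors from the
#'   transition ovals.
#' @param trajectory optional \linkS4class{ExpressionProfile} of the
#'   S-phase expression line (frequency axis, linear intensity y) used by
#'   the continuity penalty.
#' @param fwin numeric(2): the cumulative-frequency window occupied by the
#'   cluster, needed when \code{trajectory} is given.
#' @param lambda continuity penalty weight in normalised units (default 1).
#' @param bins histogram bin count; default scales as sqrt(n), clamped to
#'   [32, 256].
#' @param anchor_tol anchors closer than this (in units of the larger
#'   anchor SD) are treated as equal (default 0.25).
#' @return a \linkS4class{ComponentFit}.
#' @export
fitG2 <- function(values, entry, exit, trajectory = NULL, fwin = NULL,
                  lambda = 1, bins = NULL, anchor_tol = 0.25) {
  stopifnot(is(entry, "GaussianComponent"), is(exit, "GaussianComponent"))
  if (abs(entry@mean - exit@mean) < anchor_tol * max(entry@sd, exit@sd))
    return(.fit_single(values, bins))
  comps <- data.frame(
    mean = c(entry@mean, (entry@mean + exit@mean) / 2, exit@mean),
    sd = c(entry@sd, max(entry@sd, exit@sd), exit@sd),
    sd_free = c(FALSE, TRUE, FALSE),
    constraint = c("fixed_mean", "midpoint_mean", "fixed_mean"))
  lv <- .log_values(values)
  .fit_constrained(lv, comps, lambda = lambda, trajectory = trajectory,
                   fwin = fwin, bins = bins)
}

#' Deconvolve the G1 cyclin B1 cluster with an exit anchor and a peak anchor
#'
#' Cyclin B1 is already expressed in late G1, so the G1 cluster needs
#' deconvolution but has no entry oval.  The lower (background) component
#' is pinned at the histogram peak position with its SD set from the exit
#' anchor's CV applied at that mean; the centre component sits midway with
#' the same CV; the exit component is fixed.  Masses are optimised as in
#' \code{\link{fitG2}}.
#'
#' @inheritParams fitG2
#' @param exit \linkS4class{GaussianComponent} from the G1/S oval.
#' @return a \linkS4class{ComponentFit}.
#' @export
fitG1CyclinB <- function(values, exit, trajectory = NULL, fwin = NULL,
                         lambda = 1, bins = NULL, anchor_tol = 0.25) {
  stopifnot(is(exit, "GaussianComponent"))
  lv <- .log_values(values)
  h <- .smoothed_hist(lv, bins = 128L, bw_bins = 3)
  peak <- h$mids[which.max(h$smooth)]
  if (abs(exit@mean - peak) < anchor_tol * exit@sd)
    return(.fit_single(values, bins))
  cv <- if (abs(exit@mean) > 1e-9) exit@sd / abs(exit@mean) else NA_real_
  sd_at <- function(m) {
    s <- if (is.finite(cv)) cv * abs(m) else exit@sd
    max(s, 1e-3)
  }
  mid <- (peak + exit@mean) / 2
  comps <- data.frame(
    mean = c(peak, mid, exit@mean),
    sd = c(sd_at(peak), sd_at(mid), exit@sd),
    sd_free = c(FALSE, FALSE, FALSE),
    constraint = c("fixed_mean", "midpoint_mean", "fixed_mean"))
  .fit_constrained(lv, comps, lambda = lambda, trajectory = trajectory,
                   fwin = fwin, bins = bins)
}

#' Unconstrained Gaussian mixture fit of a log-intensity histogram
#'
#' Ordinary histogram least-squares mixture fitting with free means, SDs
#' and weights (no anchors, no continuity penalty): the lambda = 0,
#' unconstrained limit of the boundary-anchored fitter, useful as a
#' cross-check against EM mixture fitting.
#'
#' @param values positive intensities.
#' @param k number of components.
#' @param bins histogram bin count (default sqrt-n rule).
#' @return a \linkS4class{ComponentFit} with components sorted by mean.
#' @export
fitGaussianMixture <- function(values, k = 2, bins = NULL) {
  lv <- .log_values(values)
  h <- .fit_hist(lv, bins)
  counts <- h$counts
  n <- sum(counts)
  var_c <- max(stats::var(counts), 1)
  qs <- stats::quantile(lv, (seq_len(k) - 0.5) / k, names = FALSE)
  s0 <- stats::sd(lv) / k
  objective <- function(theta) {
    mu <- theta[seq_len(k)]
    sds <- theta[k + seq_len(k)]
    w <- theta[2 * k + seq_len(k)]
    pred <- vapply(seq_len(k), function(i)
      .gauss_bin(h$breaks, mu[i], sds[i]), numeric(length(counts))) %*% w
    mean((counts - pred)^2) / var_c
  }
  rng <- range(lv)
  fit <- stats::optim(c(qs, rep(s0, k), rep(n / k, k)), objective,
                      method = "L-BFGS-B",
                      lower = c(rep(rng[1], k), rep(s0 / 20, k), rep(0, k)),
                      upper = c(rep(rng[2], k), rep(diff(rng), k),
                                rep(1.5 * n, k)),
                      control = list(maxit = 1000))
  mu <- fit$par[seq_len(k)]
  sds <- fit$par[k + seq_len(k)]
  w <- fit$par[2 * k + seq_len(k)]
  ord <- order(mu)
  pred <- as.numeric(vapply(seq_len(k), function(i)
    .gauss_bin(h$breaks, mu[i], sds[i]), numeric(length(counts))) %*% w)
  comps <- lapply(ord, function(i)
    methods::new("GaussianComponent", mean = mu[i], sd = sds[i],
                 weight = w[i], constraint = "free"))
  methods::new("ComponentFit", components = comps, breaks = h$breaks,
               counts = as.numeric(counts), fitted = pred,
               r.squared = rSquared(counts, pred),
               mse = mean((counts - pred)^2), converged = fit$convergence == 0)
}

#' Component accessors for ComponentFit
#'
#' @param fit a \linkS4class{ComponentFit}.
#' @return \code{componentMeans}/\code{componentSds}: log10-domain values;
#'   \code{componentWeights}: event-mass weights normalised to fractions.
#' @export
componentMeans <- function(fit) vapply(fit@components, function(g) g@mean,
                                       numeric(1))

#' @rdname componentMeans
#' @export
componentSds <- function(fit) vapply(fit@components, function(g) g@sd,
                                     numeric(1))

#' @rdname componentMeans
#' @export
componentWeights <- function(fit) {
  w <- vapply(fit@components, function(g) g@weight, numeric(1))
  w / sum(w)
}
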