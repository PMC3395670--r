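## Piecewise-linear expression profiles on cumulative-frequency and
## cell-cycle-time axes, with the boundary heuristics.

#' Cumulative-frequency positions of ordered regions/components
#'
#' Places each region or fitted component at the midpoint of its event
#' mass: x_k = sum(f_j, j < k) + f_k / 2.  Fitted G1/G2 sub-components
#' contribute their (ordered) weights as frequencies.  Zero-frequency
#' entries are dropped with a warning.
#'
#' @param frequencies ordered nonnegative frequencies summing to at most 1
#'   (within rounding).
#' @return numeric vector of strictly increasing positions (one per
#'   nonzero frequency, names preserved).
#' @export
cumulativePositions <- function(frequencies) {
  if (any(frequencies < 0)) stop("frequencies must be nonnegative")
  if (sum(frequencies) > 1 + 1e-9)
    stop("frequencies sum to more than 1")
  if (any(frequencies == 0)) {
    warning("dropping zero-frequency step(s)")
    frequencies <- frequencies[frequencies > 0]
  }
  cumsum(frequencies) - frequencies / 2
}

#' Convert cumulative frequency to cell-cycle time (and back)
#'
#' In an exponentially growing population the steady-state age density
#' declines from a factor of 2 to 1 across the cycle, so cumulative event
#' frequency F maps onto cell-cycle time t by t = 1 - log2(2 - F); the
#' inverse is F = 2 - 2^(1 - t).  Both are monotone bijections of [0, 1]
#' onto itself.
#'
#' @param F,t numeric vectors in [0, 1].
#' @return numeric vector.
#' @export
frequencyToTime <- function(F) {
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  1 - log2(2 - F)
}

#' @rdname frequencyToTime
#' @export
timeToFrequency <- function(t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  2 - 2^(1 - t)
}

#' Assemble an expression profile from knots
#'
#' Sorts the knots by x and builds an \linkS4class{ExpressionProfile}
#' evaluated by point-to-point line connections.
#'
#' @param x,y knot coordinates (>= 2 knots, distinct x in [0, 1]).
#' @param axisKind "frequency" or "time".
#' @param marker marker name.
#' @param source per-knot source tag ("region_median", "component_mean" or
#'   "heuristic"); recycled.
#' @param scaleTag scale annotation (default "raw").
#' @return an \linkS4class{ExpressionProfile}.
#' @export
assembleProfile <- function(x, y, axisKind = c("frequency", "time"),
                            marker = "", source = "region_median",
                            scaleTag = "raw") {
  axisKind <- match.arg(axisKind)
  if (anyDuplicated(x)) stop("duplicate x positions")
  ord <- order(x)
  source <- rep_len(source, length(x))
  methods::new("ExpressionProfile", x = x[ord], y = y[ord],
               axisKind = axisKind, marker = marker, scaleTag = scaleTag,
               source = source[ord])
}

#' @rdname evaluateProfile
#' @export
setMethod("evaluateProfile", signature("ExpressionProfile", "numeric"),
          function(profile, x) {
  px <- profile@x; py <- profile@y
  if (any(x < px[1] - 1e-12 | x > px[length(px)] + 1e-12))
    stop("evaluation outside the profile's x range")
  i <- findInterval(x, px, all.inside = TRUE)
  slope <- (py[i + 1] - py[i]) / (px[i + 1] - px[i])
  slope * x + py[i] - slope * px[i]
})

#' Resample a profile on a uniform grid
#'
#' Replaces the knots by a uniform number of interpolated points over the
#' profile's x range; the shape (point-to-point connections) is unchanged.
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param n number of resampled knots (>= 2).
#' @return a resampled \linkS4class{ExpressionProfile}.
#' @export
resampleProfile <- function(profile, n = 100) {
  stopifnot(n >= 2)
  xs <- seq(profile@x[1], profile@x[length(profile@x)], length.out = n)
  assembleProfile(xs, evaluateProfile(profile, xs),
                  axisKind = profile@axisKind, marker = profile@marker,
                  source = "heuristic", scaleTag = profile@scaleTag)
}

#' Convert a profile between frequency and time axes
#'
#' Knot x positions are mapped through the age-distribution transform;
#' y values are untouched.
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @return the converted profile.
#' @export
profileToTime <- function(profile) {
  if (profile@axisKind == "time") return(profile)
  profile@x <- frequencyToTime(profile@x)
  profile@axisKind <- "time"
  methods::validObject(profile)
  profile
}

#' Improve profile boundaries with the transition heuristics
#'
#' Each region/component contributes one central (x, y) value, so phase
#' transitions are sparsely covered; these heuristics add boundary knots:
#' \enumerate{
#'   \item the first G1 value also holds at x = 0, so it is prepended
#'     there;
#'   \item for a marker absent in G1 (cyclin A2), a line through the first
#'     three S knots is extrapolated to its y = 0 crossing and a knot is
#'     inserted there, provided the crossing falls between the last G1
#'     knot and the first S knot (otherwise it is skipped with a warning);
#'   \item the last value is carried to x = 1;
#'   \item with \code{zero_endpoints}, the y values at x = 0 and x = 1 are
#'     set to exactly zero (for cyclins known to be below detection at the
#'     cycle boundaries).
#' }
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param phases character per knot: "G1", "S", "G2" or "M".
#' @param g1s_crossing insert the y = 0 crossing knot at the G1/S boundary.
#' @param zero_endpoints zero the x = 0 and x = 1 values.
#' @return the improved \linkS4class{ExpressionProfile} (heuristic knots
#'   tagged "heuristic").
#' @export
applyBoundaryHeuristics <- function(profile, phases, g1s_crossing = FALSE,
                                    zero_endpoints = FALSE) {
  stopifnot(length(phases) == length(profile@x))
  x <- profile@x; y <- profile@y; src <- profile@source
  if (!length(src)) src <- rep("region_median", length(x))
  ph <- phases

  add_knot <- function(xk, yk, phk, where = c("front", "back", "mid")) {
    where <- match.arg(where)
    if (where == "front") {
      x <<- c(xk, x); y <<- c(yk, y); src <<- c("heuristic", src)
      ph <<- c(phk, ph)
    } else if (where == "back") {
      x <<- c(x, xk); y <<- c(y, yk); src <<- c(src, "heuristic")
      ph <<- c(ph, phk)
    } else {
      i <- findInterval(xk, x)
      x <<- append(x, xk, i); y <<- append(y, yk, i)
      src <<- append(src, "heuristic", i); ph <<- append(ph, phk, i)
    }
  }

  if (x[1] > 1e-12) add_knot(0, y[1], ph[1], "front")
  if (g1s_crossing) {
    s_idx <- which(ph == "S")
    g1_idx <- which(ph == "G1")
    if (length(s_idx) >= 3 && length(g1_idx)) {
      i3 <- s_idx[1:3]
      fit <- stats::lm(y[i3] ~ x[i3])
      a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
      gap <- c(max(x[g1_idx]), x[s_idx[1]])
      if (is.finite(a) && a > 0) {
        x0 <- -b / a
        if (x0 > gap[1] && x0 < gap[2]) add_knot(x0, 0, "S", "mid")
        else warning("G1/S zero crossing outside the admissible gap; ",
                     "transition point left unimproved")
      } else {
        warning("first S knots do not define a rising line; ",
                "transition point left unimproved")
      }
    }
  }
  if (x[length(x)] < 1 - 1e-12)
    add_knot(1, y[length(y)], ph[length(ph)], "back")
  if (zero_endpoints) {
    y[1] <- 0
    y[length(y)] <- 0
    src[1] <- "heuristic"; src[length(src)] <- "heuristic"
  }
  assembleProfile(x, y, axisKind = profile@axisKind,
                  marker = profile@marker, source = src,
                  scaleTag = profile@scaleTag)
}

#' Flatten profiles to a tidy table
#'
#' @param profiles named list of \linkS4class{ExpressionProfile}s on the
#'   frequency axis, optionally paired with same-scale versions.
#' @return data.frame with columns marker, x_frequency, x_time, y,
#'   scale, source.
#' @export
profileTable <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    Fx <- if (p@axisKind == "frequency") p@x else timeToFrequency(p@x)
    data.frame(marker = p@marker, x_frequency = Fx,
               x_time = frequencyToTime(Fx), y = p@y, scale = p@scaleTag,
               source = if (length(p@source)) p@source else NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
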