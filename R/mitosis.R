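## Segmentation of mitosis: an ordered chain crossing three bivariate views.
##
## The trajectory through M is: pHH3 rises sharply at mitotic entry while
## cyclin A2 is at peak; cyclin A2 is degraded after nuclear membrane
## breakdown while cyclin B1 holds; cyclin B1 is degraded next; finally
## pHH3 is partially dephosphorylated and cells divide.  No single bivariate
## view resolves all four stretches, so the chain is segmented per stage in
## the view that exposes it: (pHH3, cyclin A2) for the rise and the cyclin
## A2 degradation, (cyclin A2, cyclin B1) for the cyclin B1 degradation,
## (cyclin B1, pHH3) for completion.  Channels hidden in a step's view are
## read indirectly (median), which assumes the exposed/hidden relationship
## is orthogonal.

## stage codes in traversal order
.M_STAGES <- c("rise", "adeg", "bdeg", "done")

.mitosis_stage <- function(m, ap) {
  a <- m[, ap$chA]; b <- m[, ap$chB]; p <- m[, ap$chP]
  stage <- rep("done", nrow(m))
  stage[b > ap$thrB] <- "bdeg"
  stage[a > ap$thrA] <- "adeg"
  stage[a > ap$thrA & p <= ap$thrP] <- "rise"
  stage
}

## ordering coordinate within each stage (increasing with cell-cycle time)
.mitosis_coord <- function(m, stage, ap) {
  co <- numeric(nrow(m))
  co[stage == "rise"] <- m[stage == "rise", ap$chP]
  co[stage == "adeg"] <- -m[stage == "adeg", ap$chA]
  co[stage == "bdeg"] <- -m[stage == "bdeg", ap$chB]
  co[stage == "done"] <- -m[stage == "done", ap$chP]
  co
}

#' Build the mitotic region chain
#'
#' Segments a mitotic event table into an ordered chain following the
#' mitotic trajectory across three bivariate views: pHH3 rise (default 8
#' steps, cyclin A2 at peak), cyclin A2 degradation (6 steps, pHH3 high),
#' cyclin B1 degradation (3 steps, read in the cyclin A2 x cyclin B1 view),
#' and completion (3 steps, pHH3 partial return, read in the cyclin B1 x
#' pHH3 view).  Stage thresholds are derived from the data (fractions of
#' the upper-quantile marker levels) and stored in the chain, so event
#' assignment is deterministic and reusable.  Consecutive cross-view stages
#' are checked for a consistent hand-off (the ordering statistic must not
#' jump backwards); violations are flagged with a warning.
#'
#' When the cyclin A2/B1 relationship is curved rather than orthogonal
#' (cyclin B1 degradation starting before cyclin A2 is fully lost), set
#' \code{curved = TRUE}: the two degradation stages are then merged and
#' segmented by arc-length projection onto the modal backbone of the
#' (cyclin A2, cyclin B1) view, exactly as for S phase.
#'
#' @param table the mitotic \linkS4class{CytoFrame}.
#' @param n_rise,n_adeg,n_bdeg,n_done steps per stage (defaults 8, 6, 3, 3).
#' @param cycA,cycB,phh3 channel names.
#' @param level_quantile quantile defining the per-marker reference level
#'   (default 0.9).
#' @param frac threshold fraction of the reference level separating
#'   high from low for the cyclins (default 0.25).
#' @param phh3_frac fraction of the pHH3 reference level separating the
#'   rise from the plateau (default 0.5: low enough that plateau events
#'   with downward measurement noise cannot cross it).
#' @param min_step_events smallest event count per step; stages with fewer
#'   events than \code{min_step_events * steps} are split more coarsely
#'   (default 20).
#' @param curved treat the cyclin A2/B1 relationship as curved (see above).
#' @return a \linkS4class{RegionChain} of kind "mitosis" (empty chain for
#'   an empty table).
#' @export
buildMitosisChain <- function(table, n_rise = 8, n_adeg = 6, n_bdeg = 3,
                              n_done = 3, cycA = "cycA", cycB = "cycB",
                              phh3 = "phh3", level_quantile = 0.9,
                              frac = 0.25, phh3_frac = 0.5,
                              min_step_events = 20, curved = FALSE) {
  stopifnot(is(table, "CytoFrame"))
  m <- intensities(table)
  if (nrow(m) == 0)
    return(methods::new("RegionChain", steps = list(), roles = character(),
                        kind = "mitosis",
                        assign_params = list(empty = TRUE)))
  A0 <- stats::quantile(m[, cycA], level_quantile, names = FALSE)
  B0 <- stats::quantile(m[, cycB], level_quantile, names = FALSE)
  P0 <- stats::quantile(m[, phh3], level_quantile, names = FALSE)
  ap <- list(chA = cycA, chB = cycB, chP = phh3,
             thrA = frac * A0, thrB = frac * B0, thrP = phh3_frac * P0,
             curved = curved)
  stage <- .mitosis_stage(m, ap)
  co <- .mitosis_coord(m, stage, ap)

  nseg <- c(rise = n_rise, adeg = n_adeg, bdeg = n_bdeg, done = n_done)
  cuts <- list()
  for (st in .M_STAGES) {
    v <- co[stage == st]
    ## never split a stage thinner than min_step_events per segment
    k <- max(1L, min(nseg[[st]],
                     as.integer(floor(length(v) / min_step_events))))
    cuts[[st]] <- if (k > 1)
      stats::quantile(v, probs = seq_len(k - 1) / k, names = FALSE)
    else numeric()
  }
  if (curved) {
    ## merged degradation stage: backbone in the (cycA, cycB) view
    deg <- stage %in% c("adeg", "bdeg")
    if (sum(deg) >= 40) {
      a <- m[deg, cycA]; b <- m[deg, cycB]
      rngx <- range(-a); rngy <- range(b)
      if (diff(rngx) <= 0) rngx <- rngx + c(-0.5, 0.5)
      if (diff(rngy) <= 0) rngy <- rngy + c(-0.5, 0.5)
      xn <- (-a - rngx[1]) / diff(rngx)
      yn <- (b - rngy[1]) / diff(rngy)
      bb <- .backbone_ridge(xn, yn, stats::quantile(xn, 0.02),
                            stats::quantile(xn, 0.98))
      s <- .project_arclen(xn, yn, bb)
      k <- n_adeg + n_bdeg
      ap$deg_backbone <- bb; ap$deg_rngx <- rngx; ap$deg_rngy <- rngy
      cuts$adeg <- stats::quantile(s, probs = seq_len(k - 1) / k,
                                   names = FALSE)
      cuts$bdeg <- numeric()
    }
  }
  ap$cuts <- cuts
  ap$nseg <- nseg

  ## display regions: rectangles per step in each stage's exposed view.
  ## The cut variable lies on the x axis for the rise stage and on the y
  ## axis elsewhere; cuts in descending stages are sign-flipped back to
  ## channel units.  Assignment itself is threshold/cut based (above).
  rng_pad <- function(v) range(v) + c(-1, 1) * 0.05 * max(1, diff(range(v)))
  pr <- rng_pad(m[, phh3]); ar <- rng_pad(m[, cycA]); br_ <- rng_pad(m[, cycB])
  build_rects <- function(st, ids, view, fixed_lim, cut_axis, cut_sign,
                          cut_lim) {
    br <- sort(c(-Inf, cuts[[st]], Inf))
    lapply(seq_along(ids), function(i) {
      iv <- sort(cut_sign * c(br[i], br[i + 1]))
      iv <- c(max(iv[1], cut_lim[1]), min(iv[2], cut_lim[2]))
      if (iv[1] >= iv[2]) iv <- iv[1] + c(0, 1e-6)
      if (cut_axis == "x")
        rectangleRegion(ids[i], view, iv[1], iv[2], fixed_lim[1],
                        fixed_lim[2])
      else
        rectangleRegion(ids[i], view, fixed_lim[1], fixed_lim[2], iv[1],
                        iv[2])
    })
  }
  n_eff <- vapply(.M_STAGES, function(st) length(cuts[[st]]) + 1L, integer(1))
  if (curved) { n_eff[["adeg"]] <- length(cuts$adeg) + 1L; n_eff[["bdeg"]] <- 0L }
  ids <- function(st, n) sprintf("M_%s%02d", st, seq_len(n))
  steps <- c(
    build_rects("rise", ids("rise", n_eff[["rise"]]), c(phh3, cycA),
                c(ap$thrA, ar[2]), "x", 1, pr),
    build_rects("adeg", ids(if (curved) "deg" else "adeg",
                            n_eff[["adeg"]]), c(phh3, cycA),
                c(ap$thrP, pr[2]), "y", -1, ar),
    if (n_eff[["bdeg"]] > 0)
      build_rects("bdeg", ids("bdeg", n_eff[["bdeg"]]), c(cycA, cycB),
                  c(ar[1], ap$thrA), "y", -1, br_),
    build_rects("done", ids("done", n_eff[["done"]]), c(cycB, phh3),
                c(br_[1], ap$thrB), "y", -1, pr)
  )
  roles <- rep("segment", length(steps))
  ## transition steps: peak (last rise), first of each later stage, final
  marks <- cumsum(n_eff[n_eff > 0])
  roles[n_eff[["rise"]]] <- "transition_oval"
  roles[utils::head(marks, -1) + 1L] <- "transition_oval"
  roles[length(roles)] <- "transition_oval"
  chain <- methods::new("RegionChain", steps = steps, roles = roles,
                        kind = "mitosis", assign_params = ap)

  ## hand-off consistency: the stage ordering statistic must not step back
  idx <- .assign_mitosis(table, chain)
  off <- 0L
  for (si in seq_len(length(.M_STAGES) - 1L)) {
    st <- .M_STAGES[si]; nx <- .M_STAGES[si + 1L]
    if (n_eff[[st]] == 0L || n_eff[[nx]] == 0L) { off <- off + n_eff[[st]]; next }
    last_sel <- idx == off + n_eff[[st]]
    first_sel <- idx == off + n_eff[[st]] + 1L
    if (any(last_sel, na.rm = TRUE) && any(first_sel, na.rm = TRUE)) {
      ch <- switch(nx, adeg = cycA, bdeg = cycB, done = phh3)
      lo <- stats::median(m[which(last_sel), ch])
      hi <- stats::median(m[which(first_sel), ch])
      if (is.finite(lo) && is.finite(hi) && hi > lo * 1.25 + 1e-9)
        warning("inconsistent hand-off between mitotic stages ", st,
                " and ", nx)
    }
    off <- off + n_eff[[st]]
  }
  chain
}

.assign_mitosis <- function(table, chain) {
  ap <- chain@assign_params
  if (isTRUE(ap$empty)) return(rep(NA_integer_, nEvents(table)))
  m <- intensities(table)
  stage <- .mitosis_stage(m, ap)
  co <- .mitosis_coord(m, stage, ap)
  curved <- isTRUE(ap$curved) && !is.null(ap$deg_backbone)
  if (curved) {
    deg <- stage %in% c("adeg", "bdeg")
    if (any(deg)) {
      xn <- (-m[deg, ap$chA] - ap$deg_rngx[1]) / diff(ap$deg_rngx)
      yn <- (m[deg, ap$chB] - ap$deg_rngy[1]) / diff(ap$deg_rngy)
      co[deg] <- .project_arclen(xn, yn, ap$deg_backbone)
      stage[deg] <- "adeg"
    }
  }
  n_eff <- c(rise = length(ap$cuts$rise) + 1L,
             adeg = length(ap$cuts$adeg) + 1L,
             bdeg = if (curved) 0L else length(ap$cuts$bdeg) + 1L,
             done = length(ap$cuts$done) + 1L)
  idx <- rep(NA_integer_, nrow(m))
  off <- 0L
  for (st in .M_STAGES) {
    if (n_eff[[st]] == 0L) next
    sel <- stage == st
    loc <- findInterval(co[sel], sort(c(-Inf, ap$cuts[[st]]))) # 1..n
    idx[sel] <- off + loc
    off <- off + n_eff[[st]]
  }
  idx
}
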