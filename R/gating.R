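## Region geometry, Boolean gate algebra, interphase/mitosis isolation and
## backbone-following segmentation of S phase into an ordered region chain.

#' Construct gate regions
#'
#' \code{rectangleRegion}, \code{polygonRegion} and \code{ellipseRegion}
#' build \linkS4class{Region} objects on a bivariate view.  Membership uses
#' half-open boundaries for rectangles and polygons (lower/left edge
#' inclusive) so abutting regions partition the plane; ellipses are closed.
#'
#' @param id region identifier.
#' @param view character(2): the (x, y) channel names.
#' @param xmin,xmax,ymin,ymax rectangle bounds in channel units.
#' @return a \linkS4class{Region}.
#' @export
rectangleRegion <- function(id, view, xmin, xmax, ymin, ymax) {
  methods::new("Region", id = id, view = view, geometry = "rectangle",
               params = c(xmin, xmax, ymin, ymax))
}

#' @rdname rectangleRegion
#' @param vertices 2-column matrix of polygon vertices (>= 3 rows, simple
#'   polygon, implicitly closed).
#' @export
polygonRegion <- function(id, view, vertices) {
  methods::new("Region", id = id, view = view, geometry = "polygon",
               params = as.matrix(vertices))
}

#' @rdname rectangleRegion
#' @param cx,cy ellipse centre; \code{rx,ry} semi-axes; \code{theta}
#'   rotation of the rx axis from the x axis, radians.
#' @param rx,ry,theta see above.
#' @export
ellipseRegion <- function(id, view, cx, cy, rx, ry, theta = 0) {
  methods::new("Region", id = id, view = view, geometry = "ellipse",
               params = c(cx, cy, rx, ry, theta))
}

#' Boolean gate algebra
#'
#' Combine regions (or sub-expressions) into a \linkS4class{GateExpr} tree.
#'
#' @param x,... Region or GateExpr operands.
#' @return a \linkS4class{GateExpr}.
#' @export
gateAnd <- function(...) .gate_node("and", list(...))

#' @rdname gateAnd
#' @export
gateOr <- function(...) .gate_node("or", list(...))

#' @rdname gateAnd
#' @export
gateNot <- function(x) .gate_node("not", list(x))

.as_gate <- function(x) {
  if (is(x, "GateExpr")) return(x)
  if (is(x, "Region"))
    return(methods::new("GateExpr", op = "region", region = x,
                        children = list()))
  stop("gate operands must be Region or GateExpr objects")
}

.gate_node <- function(op, args) {
  methods::new("GateExpr", op = op, region = NULL,
               children = lapply(args, .as_gate))
}

## point-in-region tests (vectorised over events) -------------------------

.in_rectangle <- function(x, y, p) {
  x >= p[1] & x < p[2] & y >= p[3] & y < p[4]
}

## Crossing-number (even-odd) test.  The half-open ray convention makes
## points on shared edges of abutting polygons fall in exactly one of them.
.in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.in_ellipse <- function(x, y, p) {
  dx <- x - p[1]; dy <- y - p[2]
  u <- dx * cos(p[5]) + dy * sin(p[5])
  w <- -dx * sin(p[5]) + dy * cos(p[5])
  (u / p[3])^2 + (w / p[4])^2 <= 1
}

.region_mask <- function(table, region) {
  miss <- setdiff(region@view, channelNames(table))
  if (length(miss))
    stop("region '", region@id, "' references missing channel(s): ",
         paste(miss, collapse = ", "))
  m <- intensities(table)
  x <- m[, region@view[1]]
  y <- m[, region@view[2]]
  switch(region@geometry,
         rectangle = .in_rectangle(x, y, region@params),
         polygon   = .in_polygon(x, y, region@params),
         ellipse   = .in_ellipse(x, y, region@params))
}

#' @rdname evaluateGate
#' @export
setMethod("evaluateGate", signature("CytoFrame", "Region"),
          function(table, expr) .region_mask(table, expr))

#' @rdname evaluateGate
#' @export
setMethod("evaluateGate", signature("CytoFrame", "GateExpr"),
          function(table, expr) {
  switch(expr@op,
    region = .region_mask(table, expr@region),
    not = !evaluateGate(table, expr@children[[1]]),
    and = Reduce(`&`, lapply(expr@children, evaluateGate, table = table)),
    or  = Reduce(`|`, lapply(expr@children, evaluateGate, table = table)))
})

## region JSON interchange -------------------------------------------------

#' Read and write region files
#'
#' Regions are serialised to a JSON file (schema: list of objects with
#' \code{id}, \code{view}, \code{geometry}, \code{params}; polygon params as
#' a row-major vertex list).  Round-trips are value-exact.
#'
#' @param regions list of \linkS4class{Region} objects.
#' @param path JSON file path.
#' @return \code{readRegions} returns a named list of Regions.
#' @export
writeRegions <- function(regions, path) {
  payload <- lapply(regions, function(r) {
    list(id = r@id, view = r@view, geometry = r@geometry,
         params = if (is.matrix(r@params))
           list(vertices = apply(r@params, 1, as.numeric, simplify = FALSE))
         else as.numeric(r@params))
  })
  ## 17 significant digits round-trips doubles bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(p) {
    params <- if (!is.null(p$params$vertices))
      do.call(rbind, lapply(p$params$vertices, as.numeric))
    else as.numeric(unlist(p$params))
    methods::new("Region", id = p$id,
                 view = as.character(unlist(p$view)),
                 geometry = p$geometry, params = params)
  })
  stats::setNames(out, vapply(out, function(r) r@id, character(1)))
}

## interphase / mitosis isolation ------------------------------------------

#' Split a population into interphase and mitotic subsets
#'
#' Mitotic cells are those with 4C DNA content and pHH3 above the
#' interphase band; interphase cells form the low-pHH3 band from 2C to 4C.
#' The pHH3 threshold is derived from the data: the modal log10 pHH3 of the
#' 4C cluster (dominated by G2 cells) plus \code{k_sigma} robust SDs.
#'
#' @param table a \linkS4class{CytoFrame} with DNA and pHH3 channels.
#' @param phh3 pHH3 channel name.
#' @param k_sigma threshold distance above the interphase 4C pHH3 mode, in
#'   robust log10 SDs (default 4).
#' @param dna_window half-width of the 4C DNA window as a fraction of the
#'   G2 mode (default 0.15).
#' @return list with \code{interphase} and \code{mitotic}
#'   \linkS4class{CytoFrame}s (disjoint), plus the \code{threshold} used
#'   and the detected \code{dna_modes}.
#' @export
splitInterphaseMitosis <- function(table, phh3 = "phh3", k_sigma = 4,
                                   dna_window = 0.15) {
  stopifnot(is(table, "CytoFrame"))
  if (!phh3 %in% channelNames(table)) stop("missing pHH3 channel: ", phh3)
  dna_ch <- channelByRole(table, "dna_integral")[1]
  if (is.na(dna_ch)) stop("missing dna_integral channel")
  m <- intensities(table)
  modes <- findDnaModes(table)
  g1 <- modes[["g1"]]; g2 <- modes[["g2"]]
  at4c <- abs(m[, dna_ch] - g2) <= dna_window * g2
  p <- pmax(m[, phh3], 1e-12)
  lp <- log10(p)
  if (sum(at4c) >= 20) {
    mode4c <- .dens_mode(lp[at4c], bins = 128L)
    near <- at4c & abs(lp - mode4c) <= log10(1.5)
    sig <- stats::mad(lp[near])
    if (!is.finite(sig) || sig <= 0) sig <- stats::sd(lp[near])
    thr <- mode4c + k_sigma * sig
  } else {
    ## too few 4C events to profile: no mitotic cluster resolvable
    thr <- max(lp) + 1
  }
  mito <- at4c & lp > thr
  inter <- !mito & lp <= thr &
    m[, dna_ch] >= (1 - dna_window) * g1 &
    m[, dna_ch] <= (1 + dna_window) * g2
  list(
    interphase = .log_step(.subset_events(table, inter),
                           "splitInterphaseMitosis: interphase %d/%d",
                           sum(inter), nrow(m)),
    mitotic = .log_step(.subset_events(table, mito),
                        "splitInterphaseMitosis: mitotic %d/%d",
                        sum(mito), nrow(m)),
    threshold = 10^thr,
    dna_modes = modes
  )
}

## backbone machinery -------------------------------------------------------

## Modal ridge of the (x, y) point cloud in range-normalised coordinates:
## sliding DNA windows from the G1 cluster to the G2 cluster, modal y per
## window (64-bin smoothed histogram), lightly smoothed along the ridge.
.backbone_ridge <- function(xn, yn, x_lo, x_hi, n_knots = 33L) {
  centers <- seq(x_lo, x_hi, length.out = n_knots)
  half <- 1.25 * (x_hi - x_lo) / n_knots
  ys <- vapply(centers, function(cx) {
    sel <- abs(xn - cx) <= half
    if (sum(sel) < 20) return(NA_real_)
    .dens_mode(yn[sel], bins = 64L, bw_bins = 3)
  }, numeric(1))
  ok <- is.finite(ys)
  centers <- centers[ok]; ys <- ys[ok]
  if (length(ys) >= 5)
    ys <- stats::filter(ys, rep(1 / 3, 3), sides = 2) |>
      (\(v) ifelse(is.na(v), ys, v))() |> as.numeric()
  cbind(x = centers, y = ys)
}

## Project points onto a polyline; returns the arc-length coordinate.
.project_arclen <- function(px, py, bb) {
  nseg <- nrow(bb) - 1L
  seglen <- sqrt(diff(bb[, 1])^2 + diff(bb[, 2])^2)
  arc0 <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, length(px))
  best_s <- rep(0, length(px))
  for (k in seq_len(nseg)) {
    ax <- bb[k, 1]; ay <- bb[k, 2]
    dx <- bb[k + 1L, 1] - ax; dy <- bb[k + 1L, 2] - ay
    L2 <- dx * dx + dy * dy
    tt <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
    qx <- ax + tt * dx; qy <- ay + tt * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- arc0[k] + tt[upd] * seglen[k]
  }
  best_s
}

## Point and unit tangent of a polyline at arc-length s.
.polyline_at <- function(bb, s) {
  seglen <- sqrt(diff(bb[, 1])^2 + diff(bb[, 2])^2)
  arc0 <- c(0, cumsum(seglen))
  s <- min(max(s, 0), arc0[length(arc0)])
  k <- max(1L, min(nrow(bb) - 1L, findInterval(s, arc0)))
  tt <- (s - arc0[k]) / seglen[k]
  p <- c(bb[k, 1] + tt * (bb[k + 1L, 1] - bb[k, 1]),
         bb[k, 2] + tt * (bb[k + 1L, 2] - bb[k, 2]))
  tg <- c(bb[k + 1L, 1] - bb[k, 1], bb[k + 1L, 2] - bb[k, 2]) / seglen[k]
  list(point = p, tangent = tg)
}

#' Automatically segment interphase into an ordered region chain
#'
#' Estimates the modal backbone of the (DNA, cyclin A2) point cloud from
#' the G1 cluster to the G2 cluster, then cuts the S-phase span with
#' boundaries perpendicular to the local backbone direction (in
#' range-normalised coordinates), balanced so every segment holds at least
#' \code{min_events} events.  The chain is: G1 cluster, G1/S transition
#' oval, \code{n_segments} S segments, S/G2 transition oval, G2 cluster.
#' Event assignment is by arc-length projection onto the backbone, stored
#' with the chain so it is exactly reproducible.
#'
#' @param table an interphase, stemline-gated \linkS4class{CytoFrame}.
#' @param n_segments number of S-phase segments (>= 2, default 12).
#' @param min_events minimum events per S segment (default 300).
#' @param epitope y-axis channel of the segmentation view (default "cycA").
#' @param boundary_sigmas distance of the G1/S and S/G2 cuts from the
#'   respective cluster modes, in robust DNA SDs (default 2.5).
#' @return a \linkS4class{RegionChain} of kind "interphase".
#' @export
autoSegmentS <- function(table, n_segments = 12, min_events = 300,
                         epitope = "cycA", boundary_sigmas = 2.5) {
  stopifnot(is(table, "CytoFrame"), n_segments >= 2)
  dna_ch <- channelByRole(table, "dna_integral")[1]
  m <- intensities(table)
  x <- m[, dna_ch]; y <- m[, epitope]
  rngx <- range(x); rngy <- range(y)
  if (diff(rngy) <= 0) rngy <- rngy + c(-0.5, 0.5)
  xn <- (x - rngx[1]) / diff(rngx)
  yn <- (y - rngy[1]) / diff(rngy)
  modes <- findDnaModes(table)
  g1n <- (modes[["g1"]] - rngx[1]) / diff(rngx)
  g2n <- (modes[["g2"]] - rngx[1]) / diff(rngx)

  ## robust cluster widths from the outer (uncontaminated) half of each mode
  s_g1 <- stats::mad(xn[xn < g1n] - g1n, center = 0) * sqrt(2)
  s_g2 <- stats::mad(xn[xn > g2n] - g2n, center = 0) * sqrt(2)
  if (!is.finite(s_g1) || s_g1 <= 0) s_g1 <- 0.02
  if (!is.finite(s_g2) || s_g2 <= 0) s_g2 <- 0.02

  bb <- .backbone_ridge(xn, yn, g1n, g2n)
  if (nrow(bb) < 2) stop("could not estimate a backbone ridge")
  s_ev <- .project_arclen(xn, yn, bb)
  ## phase cuts sit boundary_sigmas beyond each cluster mode, on the backbone
  x_g1s <- g1n + boundary_sigmas * s_g1
  cut_g1s <- .project_arclen(x_g1s, .pwl_fun(bb)(x_g1s), bb)
  x_sg2 <- g2n - boundary_sigmas * s_g2
  cut_sg2 <- .project_arclen(x_sg2, .pwl_fun(bb)(x_sg2), bb)
  if (cut_sg2 <= cut_g1s) stop("S span collapsed; check the input gate")

  in_s <- s_ev > cut_g1s & s_ev <= cut_sg2
  n_s <- sum(in_s)
  if (n_s < n_segments * min_events)
    stop("only ", n_s, " S-phase events for ", n_segments,
         " segments of >= ", min_events)
  ## equal-count (balanced) interior cuts
  qs <- stats::quantile(s_ev[in_s], probs = seq_len(n_segments - 1) /
                          n_segments, names = FALSE)
  cuts <- c(cut_g1s, qs, cut_sg2)

  ## lateral spread about the backbone for region half-widths
  half_L <- 3.5 * max(stats::mad(yn - .pwl_fun(bb)(xn)), 0.02)

  denorm <- function(p) c(p[1] * diff(rngx) + rngx[1],
                          p[2] * diff(rngy) + rngy[1])
  view <- c(dna_ch, epitope)
  seg_region <- function(id, s_lo, s_hi) {
    a <- .polyline_at(bb, s_lo); b <- .polyline_at(bb, s_hi)
    nA <- c(-a$tangent[2], a$tangent[1]); nB <- c(-b$tangent[2], b$tangent[1])
    v <- rbind(denorm(a$point + half_L * nA), denorm(b$point + half_L * nB),
               denorm(b$point - half_L * nB), denorm(a$point - half_L * nA))
    polygonRegion(id, view, v)
  }
  oval_region <- function(id, s0) {
    at <- .polyline_at(bb, s0)
    p <- denorm(at$point)
    tg <- at$tangent
    ## thin along the trajectory, long across it, in normalised space
    rx <- 0.015 * (cut_sg2 - cut_g1s) * diff(rngx)
    ry <- half_L * diff(rngy)
    ellipseRegion(id, view, p[1], p[2], rx, ry, atan2(tg[2], tg[1]))
  }
  g1_at <- .polyline_at(bb, 0); g2_at <- .polyline_at(bb, max(s_ev))
  steps <- c(
    list(ellipseRegion("G1", view, modes[["g1"]],
                       denorm(g1_at$point)[2],
                       3.5 * s_g1 * diff(rngx), half_L * diff(rngy))),
    list(oval_region("G1/S", cut_g1s)),
    lapply(seq_len(n_segments), function(k)
      seg_region(sprintf("S%02d", k), cuts[k], cuts[k + 1])),
    list(oval_region("S/G2", cut_sg2)),
    list(ellipseRegion("G2", view, modes[["g2"]],
                       denorm(g2_at$point)[2],
                       3.5 * s_g2 * diff(rngx), half_L * diff(rngy)))
  )
  roles <- c("phase_cluster", "transition_oval",
             rep("segment", n_segments), "transition_oval", "phase_cluster")
  oval_w <- 0.015 * (cut_sg2 - cut_g1s)
  methods::new("RegionChain", steps = steps, roles = roles,
               kind = "interphase",
               assign_params = list(
                 view = view, rngx = rngx, rngy = rngy, backbone = bb,
                 cuts = cuts, n_segments = n_segments,
                 oval_halfwidth = oval_w,
                 dna_modes = modes))
}

#' @rdname assignChain
#' @export
setMethod("assignChain", signature("CytoFrame", "RegionChain"),
          function(table, chain) {
  if (chain@kind == "mitosis") return(.assign_mitosis(table, chain))
  ap <- chain@assign_params
  m <- intensities(table)
  xn <- (m[, ap$view[1]] - ap$rngx[1]) / diff(ap$rngx)
  yn <- (m[, ap$view[2]] - ap$rngy[1]) / diff(ap$rngy)
  s <- .project_arclen(xn, yn, ap$backbone)
  ## steps: 1 = G1, 2 = G1/S oval, 3..(2+n) = S segments,
  ## (3+n) = S/G2 oval, (4+n) = G2; ovals take no exclusive assignment
  nseg <- ap$n_segments
  idx <- rep(NA_integer_, length(s))
  idx[s <= ap$cuts[1]] <- 1L
  for (k in seq_len(nseg))
    idx[s > ap$cuts[k] & s <= ap$cuts[k + 1]] <- 2L + k
  idx[s > ap$cuts[nseg + 1]] <- 4L + nseg
  idx
})

#' Events inside a transition oval of an interphase chain
#'
#' Returns the logical mask of events within the thin boundary window at
#' the named transition ("G1/S" or "S/G2"), used to fit the anchor
#' Gaussians for phase-cluster deconvolution.
#'
#' @param table a \linkS4class{CytoFrame} of the chain's population.
#' @param chain an interphase \linkS4class{RegionChain}.
#' @param which "G1/S" or "S/G2".
#' @return logical event mask.
#' @export
ovalEvents <- function(table, chain, which = c("G1/S", "S/G2")) {
  which <- match.arg(which)
  stopifnot(chain@kind == "interphase")
  ap <- chain@assign_params
  m <- intensities(table)
  xn <- (m[, ap$view[1]] - ap$rngx[1]) / diff(ap$rngx)
  yn <- (m[, ap$view[2]] - ap$rngy[1]) / diff(ap$rngy)
  s <- .project_arclen(xn, yn, ap$backbone)
  s0 <- if (which == "G1/S") ap$cuts[1] else ap$cuts[length(ap$cuts)]
  abs(s - s0) <= ap$oval_halfwidth
}

#' Per-step statistics of a region chain
#'
#' Event count, frequency (count over the gated-population total),
#' per-channel median, and log10-domain mean and CV for every chain step.
#' Channels not spanning a step's view are still summarised by their median
#' under the orthogonality assumption (indirect reading).  Transition ovals
#' overlap their neighbours, so they report counts but zero frequency (their
#' mass is already carried by the adjacent steps); empty steps yield NA
#' statistics and are flagged.
#'
#' @param table a \linkS4class{CytoFrame} (the chain's gated population).
#' @param chain a \linkS4class{RegionChain}.
#' @param channels channels to summarise (default: all non-truth channels).
#' @return a data.frame with one row per step: id, role, count, frequency,
#'   \code{median.<ch>}, \code{logmean.<ch>}, \code{logcv.<ch>}, empty.
#' @export
chainStats <- function(table, chain, channels = NULL) {
  stopifnot(is(table, "CytoFrame"))
  if (is.null(channels)) {
    cr <- channelRoles(table)
    channels <- names(cr)[cr != "truth"]
  }
  idx <- assignChain(table, chain)
  m <- intensities(table)
  n_tot <- nrow(m)
  rows <- lapply(seq_along(chain@steps), function(k) {
    role <- chain@roles[k]
    if (role == "transition_oval" && chain@kind == "interphase") {
      which_oval <- if (k == 2L) "G1/S" else "S/G2"
      sel <- ovalEvents(table, chain, which_oval)
      freq <- 0
    } else {
      sel <- !is.na(idx) & idx == k
      freq <- if (n_tot > 0) sum(sel) / n_tot else 0
    }
    stats_one <- function(ch) {
      v <- m[sel, ch]
      if (!length(v))
        return(c(median = NA_real_, logmean = NA_real_, logcv = NA_real_))
      lv <- log10(pmax(v, max(v, na.rm = TRUE) * 1e-3, 1e-6))
      lm <- mean(lv)
      c(median = stats::median(v), logmean = lm,
        logcv = if (abs(lm) > 1e-12) stats::sd(lv) / abs(lm) else NA_real_)
    }
    st <- vapply(channels, stats_one, numeric(3))
    out <- data.frame(id = chain@steps[[k]]@id, role = role,
                      count = sum(sel), frequency = freq,
                      empty = sum(sel) == 0L)
    for (ch in channels) {
      out[[paste0("median.", ch)]] <- st["median", ch]
      out[[paste0("logmean.", ch)]] <- st["logmean", ch]
      out[[paste0("logcv.", ch)]] <- st["logcv", ch]
    }
    out
  })
  res <- do.call(rbind, rows)
  if (any(res$empty))
    warning("empty chain step(s): ",
            paste(res$id[res$empty], collapse = ", "))
  res
}
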