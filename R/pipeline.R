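## End-to-end pipeline: preprocess -> gating -> mixture -> samescale ->
## profiles, from a multi-colour table plus two single-colour calibration
## tables to per-marker, time-domain, same-scale expression profiles.

#' Pipeline configuration
#'
#' @param spillover a \code{\link{compensationSpec}} for the multi-colour
#'   table, or NULL for none.
#' @param cycA,cycB,phh3 channel names of the three epitopes.
#' @param n_segments,min_events S-phase segmentation parameters.
#' @param lambda continuity penalty weight for the phase deconvolutions.
#' @param n_gates,gate_width equivalent S-phase gate parameters
#'   (\code{gate_width} NULL uses the default span rule).
#' @param targetG1,targetG2 DNA rescaling target channels.
#' @param zero_endpoints zero the cyclin profiles at x = 0 and x = 1
#'   (they are below detection at the cycle boundaries).
#' @param mitosis_steps integer(4): steps for the pHH3 rise, cyclin A2
#'   degradation, cyclin B1 degradation and completion stages.
#' @return a named list of settings.
#' @export
pipelineConfig <- function(spillover = NULL, cycA = "cycA", cycB = "cycB",
                           phh3 = "phh3", n_segments = 12, min_events = 300,
                           lambda = 1, n_gates = 7, gate_width = NULL,
                           targetG1 = 350, targetG2 = 700,
                           zero_endpoints = TRUE,
                           mitosis_steps = c(8, 6, 3, 3)) {
  list(spillover = spillover, cycA = cycA, cycB = cycB, phh3 = phh3,
       n_segments = n_segments, min_events = min_events, lambda = lambda,
       n_gates = n_gates, gate_width = gate_width, targetG1 = targetG1,
       targetG2 = targetG2, zero_endpoints = zero_endpoints,
       mitosis_steps = mitosis_steps)
}

## preprocessing shared by all three assay tables
.prep_table <- function(table, spillover, epitopes) {
  if (!is.null(spillover)) table <- compensate(table, spillover)
  table <- excludeDebrisAggregates(table)
  bg <- subtractBackground(table, channels = epitopes)
  bg
}

## per-step cumulative layout: global frequencies -> midpoint positions
.layout_positions <- function(freqs) cumsum(freqs) - freqs / 2

#' Run the full expression-profiling pipeline
#'
#' Takes one multi-colour event table (DNA, cyclin A2, cyclin B1, pHH3)
#' and two single-colour calibration tables (DNA plus one indirectly
#' stained cyclin each, shared secondary antibody) and produces per-marker
#' piecewise-linear expression profiles on the cumulative-frequency and
#' cell-cycle-time axes, with the cyclins mapped onto the common
#' single-colour scale, DNA in genome units (G1 mode anchored at 2
#' genomes) and pHH3 relative to its own G1 level.
#'
#' Stages: compensation and background subtraction; debris/aggregate
#' exclusion; interphase/mitosis isolation; 2C stemline gating; automatic
#' S-phase segmentation; boundary-anchored G1/G2 deconvolution; mitotic
#' chain traversal; DNA modal rescaling with equivalent S-phase gates and
#' median regression for the same-scale maps; profile synthesis with the
#' boundary heuristics.
#'
#' @param multi,singleA,singleB \linkS4class{CytoFrame} tables (real or
#'   synthetic).
#' @param config a \code{\link{pipelineConfig}}.
#' @return a list of class \code{"cytocycleResult"}: \code{profiles}
#'   (per marker: frequency/time profiles, and same-scale versions for the
#'   cyclins), \code{scaling} (per-cyclin \linkS4class{ScalingMap}),
#'   \code{fits} (anchor and cluster \linkS4class{ComponentFit}s),
#'   \code{chains}, \code{stats}, \code{diagnostics}.
#' @export
profilePipeline <- function(multi, singleA, singleB,
                            config = pipelineConfig()) {
  cfg <- config
  cyclins <- c(cfg$cycA, cfg$cycB)

  ## ---- preprocess the multi-colour table -------------------------------
  bg <- .prep_table(multi, cfg$spillover, cyclins)
  mt <- bg$table
  offs <- bg$anchor$offsets
  sp <- splitInterphaseMitosis(mt, phh3 = cfg$phh3)
  inter <- stemlineGate(sp$interphase, epitope = cfg$cycA)
  mito <- sp$mitotic
  n_tot <- nEvents(inter) + nEvents(mito)
  w_inter <- nEvents(inter) / n_tot
  w_mito <- nEvents(mito) / n_tot

  ## ---- segment interphase and mitosis ----------------------------------
  chain <- autoSegmentS(inter, n_segments = cfg$n_segments,
                        min_events = cfg$min_events, epitope = cfg$cycA)
  st_i <- chainStats(inter, chain)
  mchain <- buildMitosisChain(mito, n_rise = cfg$mitosis_steps[1],
                              n_adeg = cfg$mitosis_steps[2],
                              n_bdeg = cfg$mitosis_steps[3],
                              n_done = cfg$mitosis_steps[4],
                              cycA = cfg$cycA, cycB = cfg$cycB,
                              phh3 = cfg$phh3)
  has_m <- length(mchain@steps) > 0 && nEvents(mito) > 0
  st_m <- if (has_m) chainStats(mito, mchain) else NULL

  ## ---- frequency layout -------------------------------------------------
  seg_rows <- which(st_i$role == "segment")
  g1_row <- which(st_i$id == "G1")
  g2_row <- which(st_i$id == "G2")
  f_g1 <- st_i$frequency[g1_row] * w_inter
  f_seg <- st_i$frequency[seg_rows] * w_inter
  f_g2 <- st_i$frequency[g2_row] * w_inter
  f_m <- if (has_m) st_m$frequency * w_mito else numeric()
  F_g2_start <- f_g1 + sum(f_seg)
  F_m_start <- F_g2_start + f_g2
  x_seg <- f_g1 + .layout_positions(f_seg)
  x_m <- if (has_m) F_m_start + .layout_positions(f_m) else numeric()

  ## ---- anchors and phase-cluster deconvolution --------------------------
  mi <- intensities(inter)
  g1s_mask <- ovalEvents(inter, chain, "G1/S")
  sg2_mask <- ovalEvents(inter, chain, "S/G2")
  idx_i <- assignChain(inter, chain)
  g1_events <- !is.na(idx_i) & idx_i == 1L
  g2_events <- !is.na(idx_i) & idx_i == max(idx_i, na.rm = TRUE)
  mm <- if (has_m) intensities(mito) else NULL
  idx_m <- if (has_m) assignChain(mito, mchain) else integer()

  fits <- list()
  knots <- list()   # per marker: data.frame(x, y, phase, source)

  for (cy in cyclins) {
    off <- offs[[cy]]
    ## S trajectory in the (positive) pre-subtraction intensity domain
    y_seg <- st_i[seg_rows, paste0("median.", cy)]
    traj <- assembleProfile(x_seg, y_seg + off, axisKind = "frequency",
                            marker = cy)
    entry <- fitAnchor(mi[sg2_mask, cy] + off)
    ## G2/M exit anchor: earliest mitotic steps (pHH3 rise onward), widened
    ## until enough events support a Gaussian fit; cyclin degradation has
    ## barely begun there, so these events sit at the G2 exit level
    exitc <- entry
    if (has_m) {
      for (kmax in seq_len(max(1L, max(idx_m, na.rm = TRUE)))) {
        ev <- mm[!is.na(idx_m) & idx_m <= kmax, cy] + off
        if (length(ev) >= 50) { exitc <- fitAnchor(ev); break }
      }
    }
    fit_g2 <- fitG2(mi[g2_events, cy] + off, entry, exitc,
                    trajectory = traj, fwin = c(F_g2_start, F_m_start),
                    lambda = cfg$lambda)
    w2 <- componentWeights(fit_g2)
    x_g2 <- F_g2_start + (cumsum(w2) - w2 / 2) * f_g2
    y_g2 <- 10^componentMeans(fit_g2) - off
    fits[[paste0("g2_", cy)]] <- fit_g2
    fits[[paste0("anchor_sg2_", cy)]] <- entry
    fits[[paste0("anchor_g2m_", cy)]] <- exitc

    if (cy == cfg$cycB) {
      ## cyclin B1 is expressed in late G1: deconvolve G1 as well
      exit_g1 <- fitAnchor(mi[g1s_mask, cy] + off)
      fit_g1 <- fitG1CyclinB(mi[g1_events, cy] + off, exit_g1,
                             trajectory = traj, fwin = c(0, f_g1),
                             lambda = cfg$lambda)
      w1 <- componentWeights(fit_g1)
      x_g1 <- (cumsum(w1) - w1 / 2) * f_g1
      y_g1 <- 10^componentMeans(fit_g1) - off
      src_g1 <- rep("component_mean", length(x_g1))
      fits[["g1_cycB"]] <- fit_g1
      fits[["anchor_g1s_cycB"]] <- exit_g1
    } else {
      ## cyclin A2 has no G1 expression: one direct region value
      x_g1 <- f_g1 / 2
      y_g1 <- st_i[g1_row, paste0("median.", cy)]
      src_g1 <- "region_median"
    }

    y_m <- if (has_m) st_m[[paste0("median.", cy)]] else numeric()
    kn <- data.frame(
      x = c(x_g1, x_seg, x_g2, x_m),
      y = c(y_g1, y_seg, y_g2, y_m),
      phase = c(rep("G1", length(x_g1)), rep("S", length(x_seg)),
                rep("G2", length(x_g2)), rep("M", length(x_m))),
      source = c(src_g1, rep("region_median", length(x_seg)),
                 rep("component_mean", length(x_g2)),
                 rep("region_median", length(x_m))))
    knots[[cy]] <- kn[is.finite(kn$y), , drop = FALSE]
  }

  ## ---- DNA (genome units) and pHH3 (relative to G1) context profiles ----
  g1_mode <- sp$dna_modes[["g1"]]
  dna_ch <- channelByRole(inter, "dna_integral")[1]
  y_dna <- c(st_i[g1_row, paste0("median.", dna_ch)],
             st_i[seg_rows, paste0("median.", dna_ch)],
             st_i[g2_row, paste0("median.", dna_ch)],
             if (has_m) st_m[[paste0("median.", dna_ch)]])
  x_dna <- c(f_g1 / 2, x_seg, F_g2_start + f_g2 / 2, x_m)
  knots[["dna"]] <- data.frame(
    x = x_dna, y = 2 * y_dna / g1_mode,
    phase = c("G1", rep("S", length(x_seg)), "G2", rep("M", length(x_m))),
    source = "region_median")

  p_g1 <- st_i[g1_row, paste0("median.", cfg$phh3)]
  y_p <- c(st_i[g1_row, paste0("median.", cfg$phh3)],
           st_i[seg_rows, paste0("median.", cfg$phh3)],
           st_i[g2_row, paste0("median.", cfg$phh3)],
           if (has_m) st_m[[paste0("median.", cfg$phh3)]])
  knots[[cfg$phh3]] <- data.frame(
    x = x_dna, y = y_p / p_g1,
    phase = c("G1", rep("S", length(x_seg)), "G2", rep("M", length(x_m))),
    source = "region_median")

  ## ---- same-scale maps from the single-colour calibration pair ----------
  bgA <- .prep_table(singleA, NULL, cfg$cycA)
  bgB <- .prep_table(singleB, NULL, cfg$cycB)
  rs <- function(tb) rescaleDna(tb, {
    md <- findDnaModes(tb)
    dnaRescale(md[["g1"]], md[["g2"]], cfg$targetG1, cfg$targetG2)
  })
  mt_r <- rs(mt); sa_r <- rs(bgA$table); sb_r <- rs(bgB$table)
  gates <- buildEquivalentGates(n_gates = cfg$n_gates,
                                width = cfg$gate_width,
                                targetG1 = cfg$targetG1,
                                targetG2 = cfg$targetG2)
  scaling <- list()
  scaling[[cfg$cycA]] <- deriveScaling(gateMedians(mt_r, gates, cfg$cycA),
                                       gateMedians(sa_r, gates, cfg$cycA),
                                       marker = cfg$cycA)
  scaling[[cfg$cycB]] <- deriveScaling(gateMedians(mt_r, gates, cfg$cycB),
                                       gateMedians(sb_r, gates, cfg$cycB),
                                       marker = cfg$cycB)

  ## ---- assemble, improve, scale ----------------------------------------
  profiles <- list()
  for (mk in names(knots)) {
    kn <- knots[[mk]]
    kn <- kn[order(kn$x), , drop = FALSE]
    kn <- kn[!duplicated(kn$x), , drop = FALSE]
    prof <- assembleProfile(kn$x, kn$y, axisKind = "frequency",
                            marker = mk, source = kn$source)
    is_cyclin <- mk %in% cyclins
    prof <- applyBoundaryHeuristics(
      prof, kn$phase,
      g1s_crossing = identical(mk, cfg$cycA),
      zero_endpoints = is_cyclin && cfg$zero_endpoints)
    entry <- list(frequency = prof, time = profileToTime(prof))
    if (is_cyclin) {
      ss <- applyScaling(prof, scaling[[mk]])
      if (cfg$zero_endpoints) {
        ## the endpoints encode "below detection"; keep them at zero on
        ## the common scale as well
        ss@y[c(1, length(ss@y))] <- 0
      }
      entry$samescale_frequency <- ss
      entry$samescale_time <- profileToTime(ss)
    }
    if (mk == "dna") entry$frequency@scaleTag <- "genomes"
    profiles[[mk]] <- entry
  }

  structure(list(
    profiles = profiles,
    scaling = scaling,
    fits = fits,
    chains = list(interphase = chain, mitosis = mchain),
    stats = list(interphase = st_i, mitosis = st_m),
    diagnostics = list(
      dna_modes = sp$dna_modes,
      mitosis_threshold = sp$threshold,
      background = bg$anchor,
      n_interphase = nEvents(inter), n_mitotic = nEvents(mito),
      gates = gates),
    config = cfg
  ), class = "cytocycleResult")
}

#' @export
print.cytocycleResult <- function(x, ...) {
  cat("cytocycle pipeline result\n")
  cat(sprintf("  events: %d interphase, %d mitotic\n",
              x$diagnostics$n_interphase, x$diagnostics$n_mitotic))
  cat(sprintf("  markers: %s\n", paste(names(x$profiles), collapse = ", ")))
  for (mk in names(x$scaling))
    cat(sprintf("  same-scale %s: slope %.4g intercept %.4g (R^2 %.3f)\n",
                mk, x$scaling[[mk]]@slope, x$scaling[[mk]]@intercept,
                x$scaling[[mk]]@r.squared))
  invisible(x)
}

#' Tidy export of pipeline profiles
#'
#' @param result a \code{profilePipeline} result.
#' @return data.frame with columns marker, x_frequency, x_time, y_raw,
#'   y_samescale (NA for non-cyclin markers), source.
#' @export
resultTable <- function(result) {
  rows <- lapply(names(result$profiles), function(mk) {
    p <- result$profiles[[mk]]$frequency
    ss <- result$profiles[[mk]]$samescale_frequency
    data.frame(marker = mk, x_frequency = p@x,
               x_time = frequencyToTime(p@x), y_raw = p@y,
               y_samescale = if (is.null(ss)) NA_real_ else ss@y,
               source = p@source)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
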