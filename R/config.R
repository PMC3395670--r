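## Run configuration: structured YAML/JSON config for the command-line
## interface and scripted runs.  Anything structural lives in the config;
## command-line flags carry only paths, seeds and verbosity.

#' Default run configuration
#'
#' @return nested named list with the documented defaults for every stage
#'   (synthesis, channels, spillover, segmentation, mixture, samescale,
#'   heuristics).
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    synth = list(
      n_events = 20000,
      n_events_single = 15000,
      multi_gains = list(cycA = 3.0, cycB = 0.2),
      single_gain = 1.0,
      spillover_coef = 0.08,
      phase_times = list(t_G1S = 0.40, t_SG2 = 0.80, t_G2M = 0.95)
    ),
    inputs = list(multi = NULL, singleA = NULL, singleB = NULL),
    channels = list(dna = "dna", dna_h = "dna_h", cycA = "cycA",
                    cycB = "cycB", phh3 = "phh3"),
    spillover = list(list(from = "phh3", into = "cycA", coef = 0.08)),
    segmentation = list(auto = TRUE, region_file = NULL, n_segments = 12,
                        min_events = 300),
    mixture = list(lambda = 1.0),
    samescale = list(target_g1 = 350, target_g2 = 700, n_gates = 7,
                     gate_width = NULL),
    heuristics = list(zero_endpoints = TRUE)
  )
}

#' Read and validate a run configuration
#'
#' Reads YAML (.yml/.yaml) or JSON (.json) and overlays it on the
#' defaults; validation failures are reported together, listing every
#' violated field.
#'
#' @param path config file path, or NULL for pure defaults.
#' @return validated config list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  problems <- validateRunConfig(cfg)
  if (length(problems))
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "))
  cfg
}

#' @rdname readRunConfig
#' @param cfg a config list.
#' @return \code{validateRunConfig}: character vector of violations
#'   (empty when valid).
#' @export
validateRunConfig <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single number")
  chk(cfg$synth$n_events >= 1000, "synth.n_events: >= 1000")
  pt <- cfg$synth$phase_times
  chk(0 < pt$t_G1S && pt$t_G1S < pt$t_SG2 && pt$t_SG2 < pt$t_G2M &&
        pt$t_G2M < 1, "synth.phase_times: 0 < t_G1S < t_SG2 < t_G2M < 1")
  chk(cfg$segmentation$n_segments >= 2, "segmentation.n_segments: >= 2")
  chk(cfg$segmentation$min_events >= 1, "segmentation.min_events: >= 1")
  chk(isTRUE(cfg$segmentation$auto) ||
        !is.null(cfg$segmentation$region_file),
      "segmentation: auto mode off but no region_file given")
  chk(cfg$mixture$lambda >= 0, "mixture.lambda: >= 0")
  chk(cfg$samescale$target_g2 > cfg$samescale$target_g1,
      "samescale: target_g2 must exceed target_g1")
  chk(cfg$samescale$n_gates >= 1, "samescale.n_gates: >= 1")
  for (sp in cfg$spillover)
    chk(sp$coef >= 0 && sp$coef < 1, "spillover.coef: in [0, 1)")
  p
}

#' Serialise a run configuration
#'
#' @param cfg config list.
#' @param path output path (.yaml or .json decided by extension).
#' @export
writeRunConfig <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

## Build generator objects from a config.
.config_truth <- function(cfg) {
  pt <- cfg$synth$phase_times
  truthProfiles(t_G1S = pt$t_G1S, t_SG2 = pt$t_SG2, t_G2M = pt$t_G2M)
}

.config_noise_trio <- function(cfg, seed = cfg$seed) {
  sy <- cfg$synth
  list(
    multi = noiseModel(nEvents = sy$n_events, seed = seed,
                       gain = c(cycA = sy$multi_gains$cycA,
                                cycB = sy$multi_gains$cycB),
                       spillover = list(list(from = "phh3", into = "cycA",
                                             coef = sy$spillover_coef))),
    singleA = noiseModel(nEvents = sy$n_events_single, seed = seed + 1,
                         gain = c(cycA = sy$single_gain),
                         spillover = list()),
    singleB = noiseModel(nEvents = sy$n_events_single, seed = seed + 2,
                         gain = c(cycB = sy$single_gain),
                         spillover = list())
  )
}

#' Generate the synthetic assay trio described by a run config
#'
#' @param cfg a validated run config.
#' @param seed overrides \code{cfg$seed} when given.
#' @return named list of \code{multi}, \code{singleA}, \code{singleB}
#'   \linkS4class{CytoFrame}s.
#' @export
synthFromConfig <- function(cfg, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  tr <- .config_truth(cfg)
  nz <- .config_noise_trio(cfg, seed = seed)
  generateAssayPair(tr, nz$multi, nz$singleA, nz$singleB)
}

#' Load the assay trio named by a run config (or synthesise it)
#'
#' @param cfg a validated run config.
#' @return list of three \linkS4class{CytoFrame}s.
#' @export
loadInputs <- function(cfg) {
  ins <- cfg$inputs
  if (is.null(ins$multi)) return(synthFromConfig(cfg))
  if (is.null(ins$singleA) || is.null(ins$singleB))
    stop("inputs: all of multi, singleA, singleB are required")
  lapply(stats::setNames(ins[c("multi", "singleA", "singleB")],
                         c("multi", "singleA", "singleB")),
         function(p) readEvents(p, format = if (grepl("\\.fcs$", p)) "fcs"
                                else "csv"))
}

#' Translate a run config into a pipeline config
#'
#' @param cfg a validated run config.
#' @return a \code{\link{pipelineConfig}}.
#' @export
asPipelineConfig <- function(cfg) {
  sp <- NULL
  if (length(cfg$spillover))
    sp <- compensationSpec(
      vapply(cfg$spillover, `[[`, character(1), "from"),
      vapply(cfg$spillover, `[[`, character(1), "into"),
      vapply(cfg$spillover, function(s) as.numeric(s$coef), numeric(1)))
  pipelineConfig(
    spillover = sp,
    cycA = cfg$channels$cycA, cycB = cfg$channels$cycB,
    phh3 = cfg$channels$phh3,
    n_segments = cfg$segmentation$n_segments,
    min_events = cfg$segmentation$min_events,
    lambda = cfg$mixture$lambda,
    n_gates = cfg$samescale$n_gates,
    gate_width = cfg$samescale$gate_width,
    targetG1 = cfg$samescale$target_g1,
    targetG2 = cfg$samescale$target_g2,
    zero_endpoints = isTRUE(cfg$heuristics$zero_endpoints))
}
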