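## Shared synthetic fixtures, built in code at test time.

default_truth <- function(...) truthProfiles(...)

## a standard multi-colour population for gating/preprocessing tests
make_pop <- function(seed = 42, n = 20000, ...) {
  generatePopulation(default_truth(), noiseModel(nEvents = n, seed = seed,
                                                 ...))
}

## quiet wrapper: preprocess a raw population up to background subtraction
prep_pop <- function(pop, spill = compensationSpec("phh3", "cycA", 0.08)) {
  pop <- compensate(pop, spill)
  pop <- excludeDebrisAggregates(pop)
  subtractBackground(pop, channels = c("cycA", "cycB"))
}

## the standard calibration trio (multi-colour gains distort the cyclins)
make_trio <- function(seed = 1, n_multi = 20000, n_single = 15000,
                      gains = c(cycA = 3.0, cycB = 0.2),
                      single_gain = 1.0) {
  generateAssayPair(
    default_truth(),
    noiseModel(nEvents = n_multi, seed = seed, gain = gains),
    noiseModel(nEvents = n_single, seed = seed + 1,
               gain = c(cycA = single_gain), spillover = list()),
    noiseModel(nEvents = n_single, seed = seed + 2,
               gain = c(cycB = single_gain), spillover = list()))
}

default_pipeline_config <- function(...) {
  pipelineConfig(spillover = compensationSpec("phh3", "cycA", 0.08), ...)
}

## draw values from a 3-component lognormal mixture (log10 domain)
rmix3 <- function(n, means, sds, weights, seed = 1) {
  set.seed(seed)
  comp <- sample.int(3, n, replace = TRUE, prob = weights)
  10^stats::rnorm(n, means[comp], sds[comp])
}
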