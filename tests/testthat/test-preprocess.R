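test_that("compensation is linear, ordered and identity at zero", {
  cf <- make_pop(seed = 8, n = 2000)
  m0 <- intensities(cf)

  z <- compensate(cf, compensationSpec("phh3", "cycA", 0))
  expect_equal(intensities(z), m0)

  cm <- CytoFrame(cbind(dna = rep(1, 5), src = rep(10, 5),
                        tgt = c(5, 6, 7, 8, 9)),
                  roles = c(dna = "dna_integral"))
  out <- compensate(cm, compensationSpec("src", "tgt", 0.1))
  expect_equal(intensities(out)[, "tgt"], c(4, 5, 6, 7, 8))

  expect_error(compensate(cf, compensationSpec("nope", "cycA", 0.1)),
               "missing")
  expect_error(compensationSpec("a", "a", 0.1), "self")
})

test_that("compensating with the generating coefficient recovers the clean channel", {
  tr <- default_truth()
  base <- noiseModel(nEvents = 8000, seed = 12, spillover = list(),
                     doubletFrac = 0, debrisFrac = 0)
  spilled <- noiseModel(nEvents = 8000, seed = 12,
                        spillover = list(list(from = "phh3",
                                              into = "cycA", coef = 0.1)),
                        doubletFrac = 0, debrisFrac = 0)
  clean <- generatePopulation(tr, base)
  noisy <- generatePopulation(tr, spilled)
  comp <- compensate(noisy, compensationSpec("phh3", "cycA", 0.1))
  d <- intensities(comp)[, "cycA"] - intensities(clean)[, "cycA"]
  ## residual is the noise cross-term only: small relative to the signal
  expect_lt(median(abs(d)), 0.05 * max(intensities(clean)[, "cycA"]))
})

test_that("background subtraction anchors the G1 epitope median at zero", {
  bg <- prep_pop(make_pop(seed = 15))
  tb <- bg$table
  m <- intensities(tb)
  dna <- m[, "dna"]
  g1 <- dna > quantile(dna, 0.05) & dna < median(dna) * 1.1
  for (ch in c("cycA", "cycB")) {
    tol <- 0.02 * quantile(m[, ch], 0.99)
    expect_lt(abs(median(m[g1, ch])), tol)
  }
  ## idempotent: a second application subtracts about nothing
  bg2 <- subtractBackground(tb, channels = c("cycA", "cycB"))
  expect_lt(max(abs(bg2$anchor$offsets)),
            0.02 * quantile(m[, "cycA"], 0.99))
})

test_that("background anchor recovers a generator offset", {
  tr <- default_truth()
  nm <- noiseModel(nEvents = 10000, seed = 16, spillover = list(),
                   offset = c(cycA = 7, cycB = 3))
  cf <- generatePopulation(tr, nm)
  bg <- subtractBackground(cf, channels = c("cycA", "cycB"))
  expect_equal(unname(bg$anchor$offsets["cycA"]), 7, tolerance = 0.05)
  ## cyclin B1 is genuinely expressed in late G1, so its G1-median anchor
  ## slightly exceeds the pure background offset
  expect_equal(unname(bg$anchor$offsets["cycB"]), 3, tolerance = 0.12)

  ## an all-zero channel is unchanged
  z <- CytoFrame(cbind(dna = rnorm(500, 100, 3), zero = rep(0, 500)),
                 roles = c(dna = "dna_integral", zero = "epitope"))
  out <- subtractBackground(z, g1_gate = rep(TRUE, 500),
                            channels = "zero")
  expect_equal(intensities(out$table)[, "zero"], rep(0, 500))

  expect_error(subtractBackground(cf, g1_gate = rep(FALSE, nEvents(cf))),
               "G1 gate")
})

test_that("each preprocessing step appends exactly one provenance record", {
  cf <- make_pop(seed = 17, n = 5000)
  n0 <- length(provenance(cf))
  s1 <- compensate(cf, compensationSpec("phh3", "cycA", 0.08))
  expect_length(provenance(s1), n0 + 1)
  s2 <- excludeDebrisAggregates(s1)
  expect_length(provenance(s2), n0 + 2)
  s3 <- subtractBackground(s2, channels = "cycA")$table
  expect_length(provenance(s3), n0 + 3)
})

test_that("debris and aggregates are excluded; singlets are kept", {
  cf <- generatePopulation(default_truth(),
                           noiseModel(nEvents = 20000, seed = 19,
                                      doubletFrac = 0.05,
                                      debrisFrac = 0.05))
  m <- intensities(cf)
  out <- excludeDebrisAggregates(cf)
  mo <- intensities(out)
  doublet_kept <- sum(mo[, "truth_doublet"] == 1) /
    sum(m[, "truth_doublet"] == 1)
  singlet_kept <- sum(mo[, "truth_doublet"] == 0 & mo[, "truth_debris"] == 0) /
    sum(m[, "truth_doublet"] == 0 & m[, "truth_debris"] == 0)
  debris_kept <- sum(mo[, "truth_debris"] == 1) /
    sum(m[, "truth_debris"] == 1)
  expect_lt(doublet_kept, 0.10)   # >= 90% of doublets removed
  expect_gt(singlet_kept, 0.98)   # <= 2% of singlets removed
  expect_lt(debris_kept, 0.10)

  ## clean input: nearly everything retained
  clean <- generatePopulation(default_truth(),
                              noiseModel(nEvents = 10000, seed = 20,
                                         doubletFrac = 0,
                                         debrisFrac = 0))
  kept <- nEvents(excludeDebrisAggregates(clean)) / nEvents(clean)
  expect_gte(kept, 0.99)

  ## all-debris input with an explicit floor: empty table, no error
  deb <- CytoFrame(cbind(dna = runif(200, 0.2, 1.0),
                         dna_h = runif(200, 0.2, 1.0)),
                   roles = c(dna = "dna_integral", dna_h = "dna_height"))
  out2 <- excludeDebrisAggregates(deb, debris_floor = 1.5)
  expect_equal(nEvents(out2), 0)
})

test_that("the stemline gate keeps the 2C stemline and flags empty results", {
  bg <- prep_pop(make_pop(seed = 22))
  sp <- splitInterphaseMitosis(bg$table)
  inter <- sp$interphase
  kept <- stemlineGate(inter)
  mi <- intensities(inter)
  mk <- intensities(kept)
  frac <- sum(mk[, "truth_phase"] %in% 1:3) / sum(mi[, "truth_phase"] %in% 1:3)
  expect_gte(frac, 0.98)

  full <- rectangleRegion("all", c("dna", "cycA"), -1e6, 1e6, -1e6, 1e6)
  expect_equal(nEvents(stemlineGate(inter, full)), nEvents(inter))

  none <- rectangleRegion("none", c("dna", "cycA"), 1e5, 2e5, 1e5, 2e5)
  expect_warning(out <- stemlineGate(inter, none), "no events")
  expect_equal(nEvents(out), 0)
})
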