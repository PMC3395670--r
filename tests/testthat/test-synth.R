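test_that("age sampling follows the exponential age distribution", {
  t <- sampleAges(200000, seed = 7)
  expect_true(all(t >= 0 & t <= 1))

  ## density declines by a factor of 2 from birth to division
  d0 <- mean(t < 0.05) / 0.05
  d1 <- mean(t > 0.95) / 0.05
  expect_equal(d0 / d1, 2, tolerance = 0.05)

  ## closed-form CDF: F(0.5) = 2 - sqrt(2)
  expect_equal(mean(t <= 0.5), 2 - 2^0.5, tolerance = 0.005)

  ## Kolmogorov-Smirnov distance against the closed form
  t5 <- sampleAges(1e5, seed = 11)
  ks <- max(abs(seq_along(t5) / length(t5) - ageCDF(sort(t5))))
  expect_lt(ks, 0.01)

  expect_length(sampleAges(1, seed = 3), 1)
  expect_error(sampleAges(0), "positive")
  expect_identical(sampleAges(100, seed = 5), sampleAges(100, seed = 5))
})

test_that("truth profiles respect the biological shape constraints", {
  tr <- default_truth()
  pt <- tr@phaseTimes
  expect_equal(truthValue(tr, "dna", 0), 2)
  expect_equal(truthValue(tr, "dna", pt[["t_SG2"]]), 4)
  expect_equal(truthValue(tr, "dna", 1), 4)

  ## cyclin A2 hits zero before cyclin B1 within M
  grid <- seq(pt[["t_G2M"]], 1, by = 1e-4)
  tA <- grid[which(truthValue(tr, "cycA", grid) <= 1e-9)[1]]
  tB <- grid[which(truthValue(tr, "cycB", grid) <= 1e-9)[1]]
  expect_lt(tA, tB)

  ## interphase pHH3 doubles from G1 entry to the G2/M boundary
  expect_equal(truthValue(tr, "phh3", pt[["t_G2M"]]),
               2 * truthValue(tr, "phh3", 0))

  ## all values nonnegative
  g <- seq(0, 1, by = 1e-3)
  for (mk in names(tr@knots))
    expect_true(all(truthValue(tr, mk, g) >= 0))
})

test_that("generated channel values equal the truth in the no-noise limit", {
  tr <- default_truth()
  nm <- noiseModel(cv = c(dna = 1e-6, dna_h = 1e-6, cycA = 1e-6,
                          cycB = 1e-6, phh3 = 1e-6),
                   spillover = list(), offset = numeric(),
                   doubletFrac = 0, debrisFrac = 0, nEvents = 2000,
                   seed = 9)
  cf <- generatePopulation(tr, nm)
  m <- intensities(cf)
  for (ch in c("dna", "cycA", "cycB", "phh3"))
    expect_equal(m[, ch], truthValue(tr, ch, m[, "truth_t"]),
                 tolerance = 1e-4)
})

test_that("phase fractions match the closed-form age CDF", {
  cf <- make_pop(seed = 21)
  m <- intensities(cf)
  real <- m[, "truth_phase"] > 0
  g1_frac <- mean(m[real, "truth_phase"] == 1)
  expect_lt(abs(g1_frac - ageCDF(0.40)), 0.01)
  s_frac <- mean(m[real, "truth_phase"] == 2)
  expect_lt(abs(s_frac - (ageCDF(0.80) - ageCDF(0.40))), 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_pop(seed = 33, n = 5000)
  b <- make_pop(seed = 33, n = 5000)
  expect_identical(intensities(a), intensities(b))
})

test_that("assay trio enforces the shared secondary-antibody gain", {
  tr <- default_truth()
  expect_error(
    generateAssayPair(tr, noiseModel(nEvents = 1000, seed = 1),
                      noiseModel(nEvents = 1000, seed = 2,
                                 gain = c(cycA = 1), spillover = list()),
                      noiseModel(nEvents = 1000, seed = 3,
                                 gain = c(cycB = 2), spillover = list())),
    "secondary")

  ## equal truth and shared gain put the single-colour cyclins on one scale
  trio <- make_trio(seed = 5, n_multi = 5000, n_single = 8000)
  a <- intensities(trio$singleA)
  b <- intensities(trio$singleB)
  sel_a <- a[, "dna"] > 2.8 & a[, "dna"] < 3.2
  sel_b <- b[, "dna"] > 2.8 & b[, "dna"] < 3.2
  mA <- median(a[sel_a, "cycA"])
  mB <- median(b[sel_b, "cycB"])
  tr <- default_truth()
  truthA <- truthValue(tr, "cycA", 0.6) + 3  # mid-S truth + offset
  truthB <- truthValue(tr, "cycB", 0.6) + 3
  expect_equal(mA / mB, truthA / truthB, tolerance = 0.15)

  ## distorting multi-colour gains break the raw peak ratio
  qm <- intensities(trio$multi)
  rawRatio <- quantile(qm[, "cycA"], 0.99) / quantile(qm[, "cycB"], 0.99)
  expect_gt(rawRatio, 5)  # truth ratio is 1; gains are 3.0 vs 0.2
})
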