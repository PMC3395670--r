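test_that("DNA mode detection finds G1 and G2 at a ratio of 2", {
  cf <- make_pop(seed = 101)
  modes <- findDnaModes(cf)
  expect_equal(modes[["g2"]] / modes[["g1"]], 2, tolerance = 0.025)

  ## two-delta histogram: modes at the delta positions (one bin)
  v <- c(rep(100, 3000), rep(200, 2000))
  m2 <- findDnaModes(v)
  binw <- diff(range(v)) / 512
  expect_lt(abs(m2[["g1"]] - 100), binw)
  expect_lt(abs(m2[["g2"]] - 200), binw)

  expect_error(findDnaModes(rnorm(5000, 100, 5)), "peaks|peak")
})

test_that("modal rescaling lands the modes on channels 350 and 700", {
  cf <- make_pop(seed = 105)
  modes <- findDnaModes(cf)
  rs <- dnaRescale(modes[["g1"]], modes[["g2"]])
  out <- rescaleDna(cf, rs)
  new_modes <- findDnaModes(out)
  dna <- intensities(out)[, "dna"]
  binw <- diff(range(dna)) / 512
  expect_lt(abs(new_modes[["g1"]] - 350), binw)
  expect_lt(abs(new_modes[["g2"]] - 700), binw)

  ## exact linearity: the mode midpoint maps to 525
  expect_equal(rs@a * (modes[["g1"]] + modes[["g2"]]) / 2 + rs@b, 525)
  ## exact on the two anchors by construction
  expect_equal(rs@a * modes[["g1"]] + rs@b, 350)
  expect_equal(rs@a * modes[["g2"]] + rs@b, 700)
})

test_that("equivalent gates are seven contiguous intervals about 525", {
  g <- buildEquivalentGates()
  expect_equal(nrow(g@intervals), 7)
  expect_equal(g@center, 525)

  g1 <- buildEquivalentGates(n_gates = 1)
  expect_equal(nrow(g1@intervals), 1)
  expect_equal(mean(g1@intervals[1, ]), 525)

  g7 <- buildEquivalentGates(n_gates = 7, width = 40)
  expect_equal(unname(g7@intervals[, "lo"]), seq(385, 625, by = 40))
  expect_equal(unname(g7@intervals[, "hi"]), seq(425, 665, by = 40))

  expect_error(buildEquivalentGates(n_gates = 7, width = 60), "span")
})

test_that("gate medians rise with DNA for an S-phase-accumulating cyclin", {
  cf <- rescaleDna(make_pop(seed = 109))
  g <- buildEquivalentGates()
  med <- gateMedians(cf, g, "cycA")
  expect_length(med, 7)
  expect_true(all(diff(med) > 0))

  ## constant epitope: all medians equal
  m <- intensities(cf)
  m2 <- cbind(m[, c("dna", "dna_h")], flat = rep(5, nrow(m)))
  cf2 <- CytoFrame(m2, roles = c(dna = "dna_integral",
                                 dna_h = "dna_height"))
  expect_equal(unique(gateMedians(cf2, g, "flat")), 5)
})

test_that("scaling regression recovers exact affine relations", {
  x <- c(1, 2, 3, 5, 8, 13, 21)
  s2 <- deriveScaling(x, 2 * x)
  expect_equal(s2@slope, 2)
  expect_equal(s2@intercept, 0, tolerance = 1e-12)
  s1 <- deriveScaling(x, x)
  expect_equal(s1@slope, 1)
  expect_equal(s1@intercept, 0, tolerance = 1e-12)
  expect_error(deriveScaling(1:2, 1:2), "3")
  expect_error(deriveScaling(x, -2 * x), "slope")
})

test_that("applying a scaling map transforms profile amplitudes", {
  p <- assembleProfile(c(0.1, 0.5, 0.9), c(0, 1, 3), marker = "m")
  idm <- methods::new("ScalingMap", slope = 1, intercept = 0,
                      r.squared = 1, residuals = numeric(), marker = "m")
  expect_equal(applyScaling(p, idm)@y, c(0, 1, 3))
  two <- methods::new("ScalingMap", slope = 2, intercept = 0,
                      r.squared = 1, residuals = numeric(), marker = "m")
  out <- applyScaling(p, two)
  expect_equal(out@y, c(0, 2, 6))
  expect_identical(out@scaleTag, "samescale")
})

test_that("the calibration pair recovers the true cyclin scale relation", {
  trio <- make_trio(seed = 201, n_multi = 15000, n_single = 12000)
  prep1 <- function(tb, ch) {
    tb <- excludeDebrisAggregates(tb)
    subtractBackground(tb, channels = ch)$table
  }
  mt <- rescaleDna(prep1(compensate(trio$multi,
                                    compensationSpec("phh3", "cycA", 0.08)),
                         c("cycA", "cycB")))
  sa <- rescaleDna(prep1(trio$singleA, "cycA"))
  sb <- rescaleDna(prep1(trio$singleB, "cycB"))
  g <- buildEquivalentGates()
  mapA <- deriveScaling(gateMedians(mt, g, "cycA"),
                        gateMedians(sa, g, "cycA"), "cycA")
  mapB <- deriveScaling(gateMedians(mt, g, "cycB"),
                        gateMedians(sb, g, "cycB"), "cycB")
  ## multi-colour gains were 3.0 and 0.2 against a shared single gain of 1
  expect_equal(mapA@slope, 1 / 3, tolerance = 0.1)
  expect_equal(mapB@slope, 1 / 0.2, tolerance = 0.1)

  ## map o medians reproduces the single-colour medians within residuals
  predA <- mapA@slope * gateMedians(mt, g, "cycA") + mapA@intercept
  rmse <- sqrt(mean(mapA@residuals^2))
  expect_lt(max(abs(predA - gateMedians(sa, g, "cycA"))), 3 * rmse + 1e-9)
  expect_lt(rmse, 0.05 * max(gateMedians(sa, g, "cycA")))
})
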