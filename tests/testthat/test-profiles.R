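test_that("cumulative positions use the midpoint-of-mass convention", {
  expect_equal(cumulativePositions(c(0.5, 0.5)), c(0.25, 0.75))
  n <- 8
  expect_equal(cumulativePositions(rep(1 / n, n)),
               (2 * seq_len(n) - 1) / (2 * n))
  expect_warning(x <- cumulativePositions(c(0.3, 0, 0.3)), "zero")
  expect_equal(x, c(0.15, 0.45))
  expect_error(cumulativePositions(c(0.8, 0.4)), "more than 1")
})

test_that("the frequency/time transform is the exact age-distribution map", {
  expect_equal(frequencyToTime(0), 0)
  expect_equal(frequencyToTime(1), 1)
  expect_equal(frequencyToTime(0.5), 1 - log2(1.5))

  g <- seq(0, 1, length.out = 1001)
  expect_lt(max(abs(timeToFrequency(frequencyToTime(g)) - g)), 1e-12)
  expect_lt(max(abs(frequencyToTime(timeToFrequency(g)) - g)), 1e-12)
  expect_true(all(diff(frequencyToTime(g)) > 0))
  expect_error(frequencyToTime(1.2), "0, 1")
})

test_that("profile evaluation follows the two-point line equation", {
  p <- assembleProfile(c(0.2, 0.6), c(1, 3), marker = "m")
  expect_equal(evaluateProfile(p, 0.3), 1.5)
  expect_equal(evaluateProfile(p, c(0.2, 0.6)), c(1, 3))

  ## against the independent interpolation oracle on random profiles
  set.seed(7)
  for (i in 1:10) {
    x <- sort(runif(8))
    y <- rnorm(8)
    pr <- assembleProfile(x, y, marker = "r")
    q <- runif(50, min(x), max(x))
    expect_equal(evaluateProfile(pr, q),
                 stats::approx(x, y, xout = q)$y, tolerance = 1e-12)
  }

  rs <- resampleProfile(p, 41)
  expect_equal(evaluateProfile(rs, c(0.2, 0.35, 0.6)),
               evaluateProfile(p, c(0.2, 0.35, 0.6)), tolerance = 1e-12)

  expect_error(assembleProfile(c(0.1, 0.1, 0.5), c(1, 2, 3)), "duplicate")
  expect_error(evaluateProfile(p, 0.9), "range")
})

test_that("boundary heuristics add the transition knots", {
  ## marker with a nonzero G1 value, no zeroing: G1 value carried to x=0
  p <- assembleProfile(c(0.2, 0.4, 0.6, 0.9), c(5, 6, 8, 9), marker = "m")
  out <- applyBoundaryHeuristics(p, c("G1", "S", "S", "G2"))
  expect_equal(out@x[1], 0)
  expect_equal(out@y[1], 5)
  expect_equal(out@x[length(out@x)], 1)
  expect_identical(out@source[1], "heuristic")

  ## first three S knots collinear through (0.1, 0): knot inserted there
  p2 <- assembleProfile(c(0.05, 0.2, 0.3, 0.4, 0.6),
                        c(0, 1, 2, 3, 4), marker = "cycA")
  out2 <- applyBoundaryHeuristics(p2, c("G1", "S", "S", "S", "G2"),
                                  g1s_crossing = TRUE)
  expect_true(any(abs(out2@x - 0.1) < 1e-9 & abs(out2@y) < 1e-9))

  ## crossing outside the G1-S gap is skipped with a warning
  p3 <- assembleProfile(c(0.05, 0.2, 0.3, 0.4), c(0.5, 5, 6, 7),
                        marker = "cycA")
  expect_warning(
    applyBoundaryHeuristics(p3, c("G1", "S", "S", "S"),
                            g1s_crossing = TRUE), "unimproved")

  ## endpoint zeroing is exact
  out4 <- applyBoundaryHeuristics(p, c("G1", "S", "S", "G2"),
                                  zero_endpoints = TRUE)
  expect_identical(out4@y[1], 0)
  expect_identical(out4@y[length(out4@y)], 0)
})

test_that("profiles flatten to a tidy table", {
  p <- assembleProfile(c(0.1, 0.9), c(1, 2), marker = "m")
  tab <- profileTable(list(p))
  expect_named(tab, c("marker", "x_frequency", "x_time", "y", "scale",
                      "source"))
  expect_equal(tab$x_time, frequencyToTime(c(0.1, 0.9)))
})
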