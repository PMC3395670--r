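test_that("anchor fitting recovers a lognormal component", {
  set.seed(51)
  vals <- 10^rnorm(2000, 2.0, 0.1)
  g <- fitAnchor(vals)
  expect_equal(g@mean, 2.0, tolerance = 0.01)
  expect_equal(g@sd, 0.1, tolerance = 0.01)

  expect_error(fitAnchor(10^rnorm(10, 2, 0.1)), "at least")
  expect_warning(gc <- fitAnchor(rep(100, 60)), "floored")
  expect_equal(gc@sd, 1e-3)
})

test_that("R^2 follows the direct formula", {
  expect_equal(rSquared(c(1, 4, 6, 4, 1), c(1, 4, 6, 4, 1)), 1)
  x <- c(2, 5, 9, 5, 2)
  expect_equal(rSquared(x, rep(mean(x), 5)), 0)
  ## hand-computed: SS_res = 2, SS_tot = 18.8
  expect_equal(rSquared(c(1, 4, 6, 4, 1), c(1, 4, 5, 4, 2)), 1 - 2 / 18.8)
  expect_error(rSquared(rep(3, 4), rep(3, 4)), "zero-variance")
  expect_error(rSquared(1:3, 1:4), "bin grid")
})

test_that("the anchored G2 fit reproduces a generated 3-component mixture", {
  means <- c(2.0, 2.15, 2.3)
  sds <- c(0.05, 0.05, 0.05)
  w_true <- c(0.3, 0.4, 0.3)

  vals <- rmix3(5000, means, sds, w_true, seed = 61)
  set.seed(62)
  entry <- fitAnchor(10^rnorm(2000, means[1], sds[1]))
  exit <- fitAnchor(10^rnorm(2000, means[3], sds[3]))
  fit <- fitG2(vals, entry, exit)
  expect_gte(fit@r.squared, 0.97)
  expect_true(fit@converged)

  ## weight recovery at larger n
  vals2 <- rmix3(20000, means, sds, w_true, seed = 63)
  fit2 <- fitG2(vals2, entry, exit)
  expect_lt(max(abs(componentWeights(fit2) - w_true)), 0.05)

  ## weights carry the histogram mass
  expect_equal(sum(vapply(fit2@components, function(g) g@weight,
                          numeric(1))), sum(fit2@counts),
               tolerance = 1e-6)
})

test_that("equal anchors collapse the G2 fit to a single Gaussian", {
  set.seed(65)
  vals <- 10^rnorm(3000, 2.1, 0.08)
  g <- fitAnchor(vals)
  fit <- fitG2(vals, g, g)
  expect_length(fit@components, 1)
  expect_equal(fit@components[[1]]@mean, g@mean, tolerance = 1e-9)
  expect_equal(fit@components[[1]]@sd, g@sd, tolerance = 1e-9)
})

test_that("weight recovery holds across weight settings", {
  ## parameter-recovery property: many simulated G2 mixtures
  means <- c(1.9, 2.05, 2.2)
  sds <- c(0.05, 0.06, 0.05)
  set.seed(71)
  entry <- fitAnchor(10^rnorm(3000, means[1], sds[1]))
  exit <- fitAnchor(10^rnorm(3000, means[3], sds[3]))
  errs <- vapply(1:40, function(i) {
    w <- as.numeric(stats::rmultinom(1, 20, prob = c(1, 1, 1))) + 1
    w <- w / sum(w)
    vals <- rmix3(8000, means, sds, w, seed = 100 + i)
    fit <- fitG2(vals, entry, exit)
    max(abs(componentWeights(fit) - w))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the G1 cyclin B1 fit recovers the background level", {
  ## lower (background), centre, exit components
  means <- c(0.6, 0.95, 1.3)
  sds <- c(0.08, 0.08, 0.08)
  w_true <- c(0.55, 0.25, 0.20)
  vals <- rmix3(12000, means, sds, w_true, seed = 81)
  set.seed(82)
  exit <- fitAnchor(10^rnorm(2000, means[3], sds[3]))
  fit <- fitG1CyclinB(vals, exit)
  expect_length(fit@components, 3)
  ## lower-component mean within 3% of the generating background level
  expect_equal(fit@components[[1]]@mean, means[1], tolerance = 0.03)
  w <- vapply(fit@components, function(g) g@weight, numeric(1))
  expect_true(all(w >= 0))
  expect_equal(sum(w), sum(fit@counts), tolerance = 1e-6)

  ## exit anchor at the peak position collapses to one component
  uni <- 10^rnorm(3000, 1.0, 0.07)
  g <- fitAnchor(uni)
  fit1 <- fitG1CyclinB(uni, g)
  expect_length(fit1@components, 1)
})

test_that("unconstrained histogram fitting agrees with EM mixtures", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  set.seed(91)
  lv <- c(rnorm(3000, 1.6, 0.07), rnorm(2000, 2.0, 0.07))
  vals <- 10^lv
  fit <- fitGaussianMixture(vals, k = 2)
  em <- Mclust(lv, G = 2, modelNames = "V", verbose = FALSE)
  em_means <- unname(sort(em$parameters$mean))
  expect_equal(componentMeans(fit), em_means, tolerance = 0.02)
})

test_that("raising lambda tightens trajectory continuity", {
  means <- c(2.0, 2.15, 2.3)
  sds <- c(0.05, 0.05, 0.05)
  vals <- rmix3(6000, means, sds, c(0.25, 0.25, 0.5), seed = 95)
  set.seed(96)
  entry <- fitAnchor(10^rnorm(2000, means[1], sds[1]))
  exit <- fitAnchor(10^rnorm(2000, means[3], sds[3]))
  ## a straight trajectory through the component intensity range
  traj <- assembleProfile(c(0.3, 0.6), 10^c(1.95, 2.05), marker = "m")
  fwin <- c(0.6, 0.9)
  dev_term <- function(fit) {
    w <- componentWeights(fit)
    xk <- fwin[1] + (cumsum(w) - w / 2) * diff(fwin)
    slope <- (traj@y[2] - traj@y[1]) / (traj@x[2] - traj@x[1])
    ty <- pmax(traj@y[2] + slope * (xk - traj@x[2]), 0)
    sum((ty - 10^componentMeans(fit))^2)
  }
  devs <- vapply(c(0, 1, 25), function(l)
    dev_term(fitG2(vals, entry, exit, trajectory = traj, fwin = fwin,
                   lambda = l)), numeric(1))
  expect_true(all(diff(devs) <= 1e-9))
})
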