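test_that("rectangle gates and Boolean algebra behave", {
  cf <- CytoFrame(cbind(x = c(5, 15, 5), y = c(5, 5, 15)),
                  roles = c(x = "epitope", y = "epitope"))
  r <- rectangleRegion("r", c("x", "y"), 0, 10, 0, 10)
  expect_identical(evaluateGate(cf, r), c(TRUE, FALSE, FALSE))

  full <- rectangleRegion("full", c("x", "y"), -1e9, 1e9, -1e9, 1e9)
  expect_false(any(evaluateGate(cf, gateNot(full))))
  expect_identical(evaluateGate(cf, gateAnd(full, r)), evaluateGate(cf, r))
  expect_identical(evaluateGate(cf, gateOr(gateNot(full), r)),
                   evaluateGate(cf, r))
  expect_error(evaluateGate(cf, rectangleRegion("m", c("x", "zz"),
                                                0, 1, 0, 1)), "missing")
})

test_that("half-open boundaries assign shared edges to exactly one region", {
  cf <- CytoFrame(cbind(x = c(10, 10), y = c(5, 5)),
                  roles = c(x = "epitope", y = "epitope"))
  left <- rectangleRegion("l", c("x", "y"), 0, 10, 0, 10)
  right <- rectangleRegion("r", c("x", "y"), 10, 20, 0, 10)
  inl <- evaluateGate(cf, left)
  inr <- evaluateGate(cf, right)
  expect_true(all(xor(inl, inr)))
  expect_true(all(inr))  # lower/left edge inclusive
})

test_that("polygon membership matches an independent geometric oracle", {
  skip_if_not_installed("mgcv")
  set.seed(1234)
  for (rep in 1:20) {
    nv <- sample(3:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 0.5, 2)
    v <- cbind(cos(ang) * rad, sin(ang) * rad)  # star-shaped, simple
    pts <- cbind(runif(50, -2.2, 2.2), runif(50, -2.2, 2.2))
    cf <- CytoFrame(cbind(x = pts[, 1], y = pts[, 2]),
                    roles = c(x = "epitope", y = "epitope"))
    got <- evaluateGate(cf, polygonRegion("p", c("x", "y"), v))
    bnd <- rbind(v, v[1, ])
    want <- mgcv::in.out(bnd, pts)
    expect_identical(got, as.logical(want))
  }
})

test_that("region definitions round-trip through the JSON region file", {
  regs <- list(
    rectangleRegion("r1", c("dna", "cycA"), 0.5, 10.25, -3, 7),
    polygonRegion("p1", c("dna", "cycA"),
                  cbind(c(0, 1, 2, 0.5), c(0, 0.1, 2, 3))),
    ellipseRegion("e1", c("cycA", "phh3"), 1.5, 2.5, 0.3, 0.7, pi / 6))
  path <- withr::local_tempfile(fileext = ".json")
  writeRegions(regs, path)
  back <- readRegions(path)
  expect_identical(names(back), c("r1", "p1", "e1"))
  for (i in seq_along(regs)) {
    expect_identical(back[[i]]@view, regs[[i]]@view)
    expect_identical(back[[i]]@geometry, regs[[i]]@geometry)
    expect_identical(unname(back[[i]]@params), unname(regs[[i]]@params))
  }
})

test_that("interphase/mitosis isolation recovers truth-labelled mitosis", {
  cf <- excludeDebrisAggregates(make_pop(seed = 27))
  sp <- splitInterphaseMitosis(cf)
  m <- intensities(cf)
  mm <- intensities(sp$mitotic)
  recall <- sum(mm[, "truth_phase"] == 4) / sum(m[, "truth_phase"] == 4)
  expect_gte(recall, 0.95)

  ## mitotic cells carry 4C DNA: modal DNA in C units is 4
  g1 <- sp$dna_modes[["g1"]]
  mito_mode_c <- 2 * cytocycle:::.dens_mode(mm[, "dna"]) / g1
  expect_equal(mito_mode_c, 4, tolerance = 0.05)

  ## the two subsets are disjoint
  expect_equal(nEvents(sp$interphase) + nEvents(sp$mitotic) <= nEvents(cf),
               TRUE)
})

test_that("a population without mitotic cells yields an empty mitotic set", {
  set.seed(99)
  n <- 6000
  dna <- c(rnorm(n * 0.6, 2, 0.06), rnorm(n * 0.4, 4, 0.12))
  phh3 <- exp(rnorm(length(dna), log(5) + log(dna / 2), 0.15))
  cf <- CytoFrame(cbind(dna = dna, dna_h = dna, phh3 = phh3),
                  roles = c(dna = "dna_integral", dna_h = "dna_height",
                            phh3 = "epitope"))
  sp <- splitInterphaseMitosis(cf)
  expect_equal(nEvents(sp$mitotic), 0)
})

test_that("automatic S segmentation yields a balanced, ordered chain", {
  bg <- prep_pop(make_pop(seed = 31))
  sp <- splitInterphaseMitosis(bg$table)
  inter <- stemlineGate(sp$interphase)
  chain <- autoSegmentS(inter, n_segments = 12, min_events = 300)

  expect_s4_class(chain, "RegionChain")
  expect_length(chain@steps, 16)  # G1 + oval + 12 segments + oval + G2
  expect_equal(sum(chain@roles == "segment"), 12)
  expect_equal(sum(chain@roles == "transition_oval"), 2)
  expect_equal(sum(chain@roles == "phase_cluster"), 2)

  st <- chainStats(inter, chain, channels = c("dna", "cycA", "truth_t"))
  seg <- st[st$role == "segment", ]
  expect_true(all(seg$count >= 300))

  ## traversal order is monotone in truth cell-cycle time
  main <- st[st$role != "transition_oval", ]
  expect_true(all(diff(main$median.truth_t) > 0))

  ## the assignment partitions the gated population
  idx <- assignChain(inter, chain)
  expect_false(anyNA(idx))
  expect_equal(sum(main$frequency), 1, tolerance = 1e-12)

  expect_error(autoSegmentS(inter, n_segments = 12, min_events = 10000),
               "events")
})

test_that("chain medians track the truth kinetics", {
  bg <- prep_pop(make_pop(seed = 35))
  sp <- splitInterphaseMitosis(bg$table)
  inter <- stemlineGate(sp$interphase)
  chain <- autoSegmentS(inter)
  st <- chainStats(inter, chain, channels = c("cycA", "truth_t"))
  seg <- st[st$role == "segment", ]
  tr <- default_truth()
  want <- truthValue(tr, "cycA", seg$median.truth_t)
  rangeA <- diff(range(truthValue(tr, "cycA", seq(0, 1, 0.01))))
  expect_lt(max(abs(seg$median.cycA - want)), 0.05 * rangeA)
})

test_that("the mitotic chain traverses the three views in order", {
  bg <- prep_pop(make_pop(seed = 39))
  sp <- splitInterphaseMitosis(bg$table)
  mch <- buildMitosisChain(sp$mitotic)
  st <- chainStats(sp$mitotic, mch,
                   channels = c("cycA", "cycB", "phh3", "truth_t"))
  expect_true(all(diff(st$median.truth_t) > 0))

  ## at the end of M both cyclins are below the detection level
  last <- st[nrow(st), ]
  detection <- 0.05 * max(st$median.cycA)
  expect_lt(last$median.cycA, detection)
  expect_lt(abs(last$median.cycB), detection)

  ## empty mitotic table: empty chain, no crash
  empty <- sp$mitotic[integer(0), ]
  ech <- buildMitosisChain(empty)
  expect_length(ech@steps, 0)
  expect_true(all(is.na(assignChain(empty, ech))))
})
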