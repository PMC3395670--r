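test_that("CSV round trip preserves values, roles and provenance", {
  cf <- make_pop(seed = 3, n = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEvents(cf, path)
  back <- readEvents(path)
  expect_equal(intensities(back), intensities(cf))
  expect_identical(channelRoles(back), channelRoles(cf))
  expect_identical(unlist(provenance(back)), unlist(provenance(cf)))
})

test_that("a plain CSV with a header reads as an event table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dna,dna_h,cycA,cycB,phh3",
               "100,98,5,3,2", "200,195,50,40,3", "150,149,20,15,2"),
             path)
  cf <- readEvents(path)
  expect_equal(nEvents(cf), 3)
  expect_equal(length(channelNames(cf)), 5)
  expect_identical(channelByRole(cf, "dna_integral"), "dna")
  expect_error(readEvents(path, roles = c(missing_ch = "epitope")),
               "missing_ch")
})

test_that("FCS round trip preserves values within float32 precision", {
  cf <- make_pop(seed = 4, n = 300)
  path <- withr::local_tempfile(fileext = ".fcs")
  writeEvents(cf, path, format = "fcs")
  back <- readEvents(path, format = "fcs")
  expect_identical(colnames(intensities(back)), colnames(intensities(cf)))
  expect_equal(intensities(back), intensities(cf), tolerance = 1e-6)
  expect_identical(channelByRole(back, "dna_integral"), "dna")
})

test_that("missing files and unknown formats are rejected", {
  expect_error(readEvents("no-such-file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(readEvents(path), "dna_integral")
})
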