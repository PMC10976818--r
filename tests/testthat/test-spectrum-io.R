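test_that("delimited spectra parse identically across dialects", {
  mzv <- c(100.0, 100.5, 101.0)
  iv <- c(5, 2, 3)
  spec <- MassSpectrum(mzv, iv)
  for (dialect in c("csv", "tsv", "semicolon")) {
    f <- withr::local_tempfile(fileext = ".txt")
    writeSpectrum(spec, f, dialect = dialect)
    rd <- readSpectrum(f)
    expect_equal(mz(rd), mzv, label = dialect)
    expect_equal(intensity(rd), iv, label = dialect)
  }
})

test_that("header lines and delimiters are inferred", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Instrument: synthetic", "Scan 1", "m/z\tsignal",
               "100.0\t5", "101.0\t3"), f)
  rd <- readSpectrum(f)
  expect_equal(mz(rd), c(100, 101))
  expect_equal(intensity(rd), c(5, 3))
})

test_that("column overrides select the right fields", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("5,100.0,x", "3,101.0,x"), f)
  rd <- readSpectrum(f, mzColumn = 2, signalColumn = 1)
  expect_equal(mz(rd), c(100, 101))
  expect_equal(intensity(rd), c(5, 3))
})

test_that("messy numeric blocks are repaired with warnings", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("101.0,3", "100.0,5", "100.0,2"), f)
  expect_warning(rd <- readSpectrum(f), "non-monotonic")
  expect_equal(mz(rd), c(100, 101))
  expect_equal(intensity(rd), c(7, 3))  # duplicate m/z summed

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("100.0,-5", "101.0,3"), f2)
  expect_warning(rd2 <- readSpectrum(f2), "negative")
  expect_equal(intensity(rd2), c(0, 3))
})

test_that("format errors are reported with the offending line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("just", "text", "only"), f)
  expect_error(readSpectrum(f), "no numeric")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("100.0,5", "101.0,3,9", "102.0,1"), f2)
  expect_error(readSpectrum(f2), "line 2")

  expect_error(readSpectrum(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("realignment recovers constructed offsets within a grid step", {
  d <- exchangeDistribution(14, retention = 0.8)
  pat <- isotopePattern(applyAdduct(parseFormula("C6D14"), "[M+H]+"))
  aligned <- renderSpectrum("C6D14", "[M+H]+", d)
  res0 <- realignSpectrum(aligned, pat)
  expect_lte(abs(res0$offset), 0.005)

  shifted <- renderSpectrum("C6D14", "[M+H]+", d, mzOffset = 0.2)
  res <- realignSpectrum(shifted, pat)
  expect_equal(res$offset, -0.2, tolerance = 0.006)
  expect_equal(mz(res$spectrum), mz(shifted) + res$offset)

  # beyond the cap the best in-range offset aliases onto the ~1.006 Da
  # isotopologue comb; it must match an independent grid-search oracle
  far <- renderSpectrum("C6D14", "[M+H]+", d, mzOffset = 0.7)
  oracleOffset <- local({
    keep <- peakAbundance(pat) >= 1e-3
    pm <- peakMass(pat)[keep]
    pa <- peakAbundance(pat)[keep]
    offs <- seq(-0.5, 0.5, by = 0.005)
    sc <- vapply(offs, function(o) {
      sum(pa * vapply(pm - o, function(centre) {
        sel <- abs(mz(far) - centre) <= 0.05
        if (!any(sel)) 0
        else max(intensity(far)[sel] *
                   (1 - abs(mz(far)[sel] - centre) / 0.05))
      }, numeric(1)))
    }, numeric(1))
    offs[which.max(sc)]
  })
  resFar <- suppressWarnings(realignSpectrum(far, pat))
  expect_equal(resFar$offset, oracleOffset)
  expect_equal(resFar$offset, 1.006277 - 0.7, tolerance = 0.006)
})

test_that("the offset cap is reported when no in-range alignment exists", {
  # single isolated peak: no comb to alias onto, so a +0.52 Da shift can
  # only be chased to the -0.5 Da cap
  single <- DeuteR:::.newPattern(100.5, 1)
  mzv <- seq(100, 102, by = 0.002)
  spec <- MassSpectrum(mzv, exp(-(mzv - 101.02)^2 / (2 * 0.01^2)))
  expect_warning(res <- realignSpectrum(spec, single), "cap")
  expect_equal(res$offset, -0.5)
})

test_that("realignment is idempotent and errors without overlap", {
  d <- exchangeDistribution(14, retention = 0.8)
  pat <- isotopePattern(applyAdduct(parseFormula("C6D14"), "[M+H]+"))
  shifted <- renderSpectrum("C6D14", "[M+H]+", d, mzOffset = 0.13)
  once <- realignSpectrum(shifted, pat)
  twice <- realignSpectrum(once$spectrum, pat)
  expect_lte(abs(twice$offset), 0.005)

  away <- MassSpectrum(seq(500, 510, 0.01), rep(1, 1001))
  expect_error(realignSpectrum(away, pat), "overlap")
})
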