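test_that("single-class exchange is exactly binomial", {
  for (p in c(0.3, 0.6, 0.9)) {
    d <- exchangeDistribution(14, retention = p)
    expect_equal(probabilities(d), stats::dbinom(0:14, 14, p),
                 tolerance = 1e-12)
  }
})

test_that("equal rates degenerate to a single class", {
  one <- exchangeDistribution(14, 1, retention = 0.6)
  two <- exchangeDistribution(c(6, 8), c(1, 1), retention = 0.6)
  expect_equal(probabilities(two), probabilities(one), tolerance = 1e-10)
})

test_that("the exchange mean always equals N x retention", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(1:3, 1)
    n <- sample(1:10, k, replace = TRUE)
    r <- stats::runif(k, 0.2, 5)
    ret <- stats::runif(1, 0.05, 0.95)
    d <- exchangeDistribution(n, r, ret)
    mean_d <- sum((0:sum(n)) * probabilities(d))
    expect_equal(mean_d, sum(n) * ret, tolerance = 1e-9)
  }
})

test_that("the two-class rate-ratio model solves the kinetic root", {
  # independent oracle: direct root solve of 3 p^2.18 + 10 p = 7.8
  f <- function(p) 3 * p^2.18 + 10 * p - 0.6 * 13
  pSlow <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  pFast <- pSlow^2.18
  d <- exchangeDistribution(c(3, 10), c(2.18, 1), retention = 0.6)
  oracle <- stats::convolve(stats::dbinom(0:3, 3, pFast),
                            rev(stats::dbinom(0:10, 10, pSlow)),
                            type = "open")
  expect_equal(probabilities(d), oracle, tolerance = 1e-8)
})

test_that("invalid exchange models are rejected", {
  expect_error(exchangeDistribution(14, retention = 0), "retention")
  expect_error(exchangeDistribution(14, retention = 1.2), "retention")
  expect_error(exchangeDistribution(c(6, 8), c(-1, 1), 0.5), "positive")
  expect_error(exchangeDistribution(integer(0), retention = 0.5), "class")
})

test_that("a delta distribution renders peaks on the predicted pattern", {
  full <- applyAdduct(parseFormula("C6D14"), "[M+H]+")
  pat <- isotopePattern(full)
  delta <- IsotopologueDistribution(c(rep(0, 14), 1), normalised = TRUE)
  spec <- renderSpectrum("C6D14", "[M+H]+", delta)
  mzv <- mz(spec)
  iv <- intensity(spec)
  major <- peakAbundance(pat) > 0.01
  for (m in peakMass(pat)[major]) {
    sel <- abs(mzv - m) < 0.05
    expect_lt(abs(mzv[sel][which.max(iv[sel])] - m), 0.002)
  }
})

test_that("the noiseless round trip recovers the simulated distribution", {
  for (compound in c("C6D14", "C6D13Br")) {
    sim <- studySim(compound)
    res <- quietDeuterate(sim$formula, sim$spectrum, adduct = "[M+H]+")
    expect_lt(max(abs(probabilities(distribution(res)) -
                        probabilities(sim$dist))), 1e-3)
    expect_equal(percentD(res), 60, tolerance = 0.5)
  }
})

test_that("rendering is deterministic for a fixed seed and noise is unbiased", {
  d <- exchangeDistribution(c(6, 8), c(2.18, 1), retention = 0.6)
  a <- renderSpectrum("C6D14", "[M+H]+", d, noiseSd = 0.01, seed = 99L)
  b <- renderSpectrum("C6D14", "[M+H]+", d, noiseSd = 0.01, seed = 99L)
  expect_identical(intensity(a), intensity(b))

  # height extraction for noisy data: window integration would accumulate
  # the (non-negative) baseline across the full +-0.5 Da window
  pds <- vapply(1:20, function(s) {
    spec <- renderSpectrum("C6D14", "[M+H]+", d, noiseSd = 0.01, seed = s)
    percentD(quietDeuterate("C6D14", spec, adduct = "[M+H]+",
                            mode = "height"))
  }, numeric(1))
  expect_lt(abs(mean(pds) - 60), 1)
})

test_that("fixtures round-trip through the delimited reader", {
  d <- exchangeDistribution(3, retention = 0.5)
  spec <- renderSpectrum("C3D3H5", "[M+H]+", d, mzStep = 0.005)
  for (dialect in c("csv", "tsv", "semicolon")) {
    f <- withr::local_tempfile(fileext = ".txt")
    writeFixture(spec, f, dialect = dialect,
                 header = c("synthetic spectrum", "two columns"),
                 manifest = list(formula = "C3D3H5", retention = 0.5))
    rd <- readSpectrum(f)
    expect_equal(mz(rd), mz(spec), label = dialect)
    expect_equal(intensity(rd), intensity(spec), label = dialect)
    expect_true(file.exists(paste0(f, ".manifest.txt")))
  }
})
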