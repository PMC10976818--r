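test_that("single-element patterns reproduce the isotope table", {
  pC <- elementPattern("C", 1)
  expect_equal(peakMass(pC), c(12.0, 13.00335), tolerance = 1e-6)
  expect_equal(peakAbundance(pC), c(0.9893, 0.0107))

  pBr <- elementPattern("Br", 1)
  expect_equal(diff(peakMass(pBr)), 1.99795, tolerance = 1e-4)
  expect_equal(peakAbundance(pBr), c(0.5069, 0.4931))

  p0 <- elementPattern("C", 0)
  expect_equal(peakMass(p0), 0)
  expect_equal(peakAbundance(p0), 1)
})

test_that("convolution has a delta identity and binomial squares", {
  delta <- DeuteR:::.newPattern(0, 1)
  pC <- elementPattern("C", 1)
  expect_equal(peakMass(convolvePatterns(delta, pC)), peakMass(pC))
  expect_equal(peakAbundance(convolvePatterns(delta, pC)), peakAbundance(pC))

  pC2 <- convolvePatterns(pC, pC)
  expect_equal(peakAbundance(pC2),
               c(0.9893^2, 2 * 0.9893 * 0.0107, 0.0107^2),
               tolerance = 1e-9)
})

test_that("abundance is conserved through convolve and merge", {
  set.seed(7)
  symbols <- c("C", "H", "O", "Br", "Cl", "Zr", "S", "Si")
  for (rep in 1:20) {
    syms <- sample(symbols, sample(2:4, 1))
    cts <- setNames(sample(1:25, length(syms), replace = TRUE), syms)
    pat <- isotopePattern(ElementComposition(cts))
    expect_equal(sum(peakAbundance(pat)), 1, tolerance = 1e-9)
    expect_true(!is.unsorted(peakMass(pat), strictly = TRUE))
  }
})

test_that("pattern of a union equals the convolution of the parts", {
  set.seed(11)
  for (rep in 1:10) {
    a <- ElementComposition(setNames(sample(1:8, 2), c("C", "O")))
    b <- ElementComposition(setNames(sample(1:8, 2), c("Br", "H")))
    u <- ElementComposition(DeuteR:::.addCounts(elementCounts(a),
                                                elementCounts(b)))
    direct <- isotopePattern(u)
    split <- convolvePatterns(isotopePattern(a), isotopePattern(b))
    # pruning happens at different stages, so tiny tail peaks may differ;
    # every non-negligible peak must have a partner within the merge width
    # carrying the same abundance
    dm <- peakMass(direct); da <- peakAbundance(direct)
    sm <- peakMass(split); sa <- peakAbundance(split)
    for (j in which(da >= 1e-4)) {
      k <- which.min(abs(sm - dm[j]))
      expect_lt(abs(sm[k] - dm[j]), 1.5e-3)
      expect_lt(abs(sa[k] - da[j]), 1e-4)
    }
    for (j in which(sa >= 1e-4)) {
      k <- which.min(abs(dm - sm[j]))
      expect_lt(abs(dm[k] - sm[j]), 1.5e-3)
    }
  }
})

test_that("patterns match a brute-force enumeration oracle", {
  for (cts in list(c(C = 3L, Br = 1L), c(C = 2L, Cl = 2L),
                   c(C = 4L, O = 2L))) {
    oracle <- bruteForcePattern(as.list(cts))
    pat <- isotopePattern(ElementComposition(cts))
    keep <- oracle$abundance >= 1e-6
    expect_equal(length(peakMass(pat)), length(oracle$mass[keep]))
    expect_lt(max(abs(peakMass(pat) - oracle$mass[keep])), 2e-6)
    expect_lt(max(abs(peakAbundance(pat) -
                        oracle$abundance[keep] / sum(oracle$abundance[keep]))),
              1e-6)
  }
})

test_that("alkane +1 satellite follows the closed-form 13C ratio", {
  for (n in c(5, 10, 20, 30)) {
    cts <- setNames(c(n, 2 * n + 2), c("C", "H"))
    pat <- isotopePattern(ElementComposition(cts))
    ab <- peakAbundance(pat)
    ratio <- ab[2] / ab[1]
    expect_lt(abs(ratio - n * 0.0107 / 0.9893), 0.01)
  }
})

test_that("C6D14 base peak and 13C satellite are positioned correctly", {
  pat <- isotopePattern(parseFormula("C6D14"))
  i0 <- which.max(peakAbundance(pat))
  expect_equal(peakMass(pat)[i0], 100.1974, tolerance = 1e-4)
  sat <- which(abs(peakMass(pat) - (peakMass(pat)[i0] + 1.00336)) < 5e-3)
  expect_length(sat, 1L)
  expect_equal(peakAbundance(pat)[sat] / peakAbundance(pat)[i0],
               6 * 0.0107 / 0.9893, tolerance = 0.02)
})

test_that("bromine splits the C6D13Br pattern into two clusters", {
  pat <- isotopePattern(parseFormula("C6D13Br"))
  m <- peakMass(pat)
  ab <- peakAbundance(pat)
  base <- m[which.max(ab)]
  # 81Br partner ~1.998 Da up, nearly as tall
  partner <- which(abs(m - (base + 1.99795)) < 5e-3)
  expect_length(partner, 1L)
  expect_equal(ab[partner] / max(ab), 0.4931 / 0.5069, tolerance = 0.02)
  # each cluster carries a 13C satellite
  expect_length(which(abs(m - (base + 1.00336)) < 5e-3), 1L)
})

test_that("charged patterns apply the electron mass correction", {
  neutral <- isotopePattern(parseFormula("C6D14"))
  ion <- isotopePattern(ElementComposition(c(C = 6L, D = 14L), charge = 1L))
  expect_equal(peakMass(ion) - peakMass(neutral),
               rep(-0.000548579909, length(peakMass(ion))),
               tolerance = 1e-9)
})
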