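test_that("formula parsing counts D separately from H", {
  cases <- list(
    list(text = "C6D14", counts = c(C = 6L, D = 14L)),
    list(text = "C27HD45O", counts = c(C = 27L, H = 1L, D = 45L, O = 1L)),
    list(text = "C20D28O8Zr", counts = c(C = 20L, D = 28L, O = 8L, Zr = 1L)),
    list(text = "CH3(CD2)2Br", counts = c(C = 3L, H = 3L, D = 4L, Br = 1L))
  )
  for (cs in cases) {
    comp <- parseFormula(cs$text)
    expect_true(comp == ElementComposition(cs$counts), label = cs$text)
  }
  # symbol order in the source string is irrelevant
  expect_true(parseFormula("D14C6") == parseFormula("C6D14"))
})

test_that("formula parse errors name the offending token", {
  expect_error(parseFormula("C6X14"), "X")
  expect_error(parseFormula("C6(D7)0"), "multiplier")
  expect_error(parseFormula(""), "empty")
  expect_error(parseFormula("C6]D14"), "]")
})

test_that("canonical formula strings round-trip through the parser", {
  set.seed(42)
  symbols <- c("C", "H", "D", "O", "N", "Br", "Cl", "Zr", "Na", "S")
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    syms <- sample(symbols, k)
    cts <- setNames(sample(1:40, k, replace = TRUE), syms)
    comp <- ElementComposition(cts)
    expect_true(parseFormula(formulaString(comp)) == comp)
  }
})

test_that("adduct grammar parses canonical ESI forms", {
  a <- parseAdduct("[M+H]+")
  expect_equal(a@multiplier, 1L)
  expect_true(a@gained == ElementComposition(c(H = 1L)))
  expect_equal(ionCharge(a), 1L)

  b <- parseAdduct("[M-H]-")
  expect_true(b@lost == ElementComposition(c(H = 1L)))
  expect_equal(ionCharge(b), -1L)

  c2 <- parseAdduct("[2M+Na]+")
  expect_true(c2 == Adduct(multiplier = 2L, gained = c(Na = 1L), charge = 1L))

  # whitespace-insensitive, condensed gains/losses, multi-charge
  d <- parseAdduct("[M - C5D7O2 + CH3CN]+")
  expect_true(d@gained == parseFormula("CH3CN"))
  expect_true(d@lost == parseFormula("C5D7O2"))
  expect_equal(ionCharge(parseAdduct("[M+2H]2+")), 2L)
  expect_true(parseAdduct("[M+2H]2+")@gained == ElementComposition(c(H = 2L)))
})

test_that("malformed adducts are rejected", {
  expect_error(parseAdduct("M+H+"), "malformed")
  expect_error(parseAdduct("[M+H]0+"), "charge")
  expect_error(parseAdduct("[M*H]+"), "malformed")
})

test_that("adduct labels round-trip and application inverts", {
  labels <- defaultAdducts()
  base <- parseFormula("C6D14")
  for (lab in labels) {
    ad <- parseAdduct(lab)
    expect_true(parseAdduct(adductLabel(ad)) == ad, label = lab)
    ion <- tryCatch(applyAdduct(base, ad), error = function(e) NULL)
    if (is.null(ion)) next  # infeasible for this base (e.g. [M-H]-)
    expect_true(removeAdduct(ion, ad) == base, label = lab)
  }
})

test_that("adduct application follows multiset arithmetic", {
  base <- parseFormula("C6D14")
  ion <- applyAdduct(base, "[M+H]+")
  expect_true(ion == ElementComposition(c(C = 6L, H = 1L, D = 14L), 1L))
  ion2 <- applyAdduct(base, "[M-D]-")
  expect_true(ion2 == ElementComposition(c(C = 6L, D = 13L), -1L))
  expect_error(applyAdduct(base, "[M-Cl]-"), "infeasible")
})

test_that("monoisotopic m/z matches hand-summed isotope masses", {
  expect_equal(monoisotopicMz(parseFormula("C6D14")), 100.1974, tolerance = 1e-5)
  ion <- applyAdduct(parseFormula("C6D14"), "[M+H]+")
  expect_equal(monoisotopicMz(ion), 101.2047, tolerance = 1e-5)
  proton <- ElementComposition(c(H = 1L), charge = 1L)
  expect_equal(monoisotopicMz(proton), 1.00728, tolerance = 1e-5)
})

test_that("isotopologue series enumerates protiated through perdeuterated", {
  s <- isotopologueSeries(parseFormula("C6D14"))
  expect_length(s, 15L)
  expect_true(s[[1]] == parseFormula("C6H14"))
  expect_true(s[[15]] == parseFormula("C6D14"))

  s2 <- isotopologueSeries(parseFormula("C27HD45O"))
  expect_length(s2, 46L)
  # every member keeps the one original H plus the exchanged positions
  hs <- vapply(s2, function(x) elementCounts(x)[["H"]], integer(1))
  expect_equal(hs, 1L + (45:0))

  expect_length(isotopologueSeries(parseFormula("C6D13Br")), 14L)
  expect_error(isotopologueSeries(parseFormula("C6H14")), "no deuterium")
})

test_that("monoisotopic m/z increases strictly along a +1 series", {
  series <- isotopologueSeries(applyAdduct(parseFormula("C6D14"), "[M+H]+"))
  mzs <- vapply(series, monoisotopicMz, numeric(1))
  expect_true(all(diff(mzs) > 0))
  expect_equal(diff(mzs), rep(1.006277, 14), tolerance = 1e-5)
})
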