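# ---------------------------------------------------------------------------
# Molecular formula parsing and composition arithmetic
# ---------------------------------------------------------------------------

# merge two named count vectors by summing shared symbols
.addCounts <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  syms <- union(names(a), names(b))
  out <- setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

# consume an optional run of digits at position `pos` of string `s`
.takeDigits <- function(s, pos) {
  m <- regmatches(substring(s, pos), regexpr("^[0-9]+", substring(s, pos)))
  if (!length(m)) return(list(value = NA_integer_, pos = pos))
  list(value = as.integer(m), pos = pos + nchar(m))
}

#' Parse a condensed molecular formula
#'
#' Parses Hill-style condensed formulas with optional parenthesised groups
#' and integer multipliers, e.g. `"C6D14"`, `"C27HD45O"`,
#' `"Al2(SO4)3"`-style nesting.  `"D"` (deuterium) is the only isotope
#' token and is counted separately from `"H"`; the formula passed to the
#' deuteration pipeline should be that of the *fully* deuterated molecule.
#'
#' @param text A single formula string.
#' @return An [ElementComposition-class] with charge 0.
#' @examples
#' parseFormula("C6D14")
#' parseFormula("C27HD45O")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop("empty formula string")
  stack <- list(setNames(integer(0), character(0)))
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      stack[[length(stack) + 1L]] <- setNames(integer(0), character(0))
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) < 2L)
        stop("unmatched ')' in formula '", text, "'")
      i <- i + 1L
      d <- .takeDigits(s, i)
      i <- d$pos
      mult <- if (is.na(d$value)) 1L else d$value
      if (mult <= 0L)
        stop("zero or negative group multiplier in formula '", text, "'")
      grp <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      stack[[length(stack)]] <- .addCounts(stack[[length(stack)]], grp * mult)
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (i < n && grepl("^[a-z]$", substr(s, i + 1L, i + 1L))) {
        sym <- paste0(sym, substr(s, i + 1L, i + 1L))
        i <- i + 1L
      }
      i <- i + 1L
      if (!sym %in% names(.isotopes))
        stop("unknown element symbol '", sym, "' in formula '", text, "'")
      d <- .takeDigits(s, i)
      i <- d$pos
      cnt <- if (is.na(d$value)) 1L else d$value
      stack[[length(stack)]] <-
        .addCounts(stack[[length(stack)]], setNames(cnt, sym))
    } else {
      stop("unexpected token '", ch, "' in formula '", text, "'")
    }
  }
  if (length(stack) != 1L)
    stop("unmatched '(' in formula '", text, "'")
  ElementComposition(stack[[1L]])
}

#' Canonical formula string of a composition
#'
#' Hill-order condensed formula (C, H, D first, then alphabetical);
#' round-trips through [parseFormula()].
#'
#' @param comp An [ElementComposition-class].
#' @return A single character string, `""` for the empty composition.
#' @export
formulaString <- function(comp) {
  cts <- .hillOrder(elementCounts(comp))
  if (!length(cts)) return("")
  paste0(names(cts), ifelse(cts == 1L, "", cts), collapse = "")
}

#' Monoisotopic m/z of a composition
#'
#' Sum of most-abundant-isotope exact masses (D counts as 2H), corrected
#' for electron mass per unit charge and divided by |charge| for ions.
#'
#' @param comp An [ElementComposition-class].
#' @return Monoisotopic mass (neutral) or m/z (ion), in Da.
#' @examples
#' monoisotopicMz(parseFormula("C6D14"))            # neutral, ~100.1974
#' monoisotopicMz(ElementComposition(c(H = 1), 1))  # a proton, ~1.00728
#' @export
monoisotopicMz <- function(comp) {
  cts <- elementCounts(comp)
  z <- ionCharge(comp)
  m <- sum(vapply(names(cts), .mostAbundantMass, numeric(1)) * cts)
  m <- m - z * .ELECTRON_MASS
  if (z != 0L) m / abs(z) else m
}

#' Enumerate the deuterium isotopologue series
#'
#' For a fully deuterated composition with N deuterium, returns the N+1
#' compositions obtained by replacing N-i of the D with H, i = 0..N.
#' Element `i+1` of the result is the species with `i` deuterium; the last
#' is the input itself.
#'
#' @param full An [ElementComposition-class] with at least one D.
#' @return A list of `ElementComposition`s, protiated first.
#' @examples
#' length(isotopologueSeries(parseFormula("C6D14")))  # 15
#' @export
isotopologueSeries <- function(full) {
  n <- nDeuterium(full)
  if (n < 1L)
    stop("composition contains no deuterium; nothing to deuterate")
  cts <- elementCounts(full)
  h0 <- if ("H" %in% names(cts)) cts[["H"]] else 0L
  z <- ionCharge(full)
  lapply(0:n, function(i) {
    v <- cts
    v[["D"]] <- i
    v <- .addCounts(v[setdiff(names(v), "H")],
                    setNames(h0 + (n - i), "H"))
    ElementComposition(v, z)
  })
}
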