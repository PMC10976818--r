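# ---------------------------------------------------------------------------
# Adduct grammar: "[nM+X1-X2...]z+" / "[nM+X]z-"
# ---------------------------------------------------------------------------

# canonical label reconstruction; gains/losses rendered as single condensed
# formulas so the label always round-trips through parseAdduct()
.adductLabel <- function(ad) {
  g <- formulaString(ad@gained)
  l <- formulaString(ad@lost)
  zm <- abs(ad@charge)
  paste0("[",
         if (ad@multiplier > 1L) ad@multiplier else "",
         "M",
         if (nzchar(g)) paste0("+", g) else "",
         if (nzchar(l)) paste0("-", l) else "",
         "]",
         if (zm > 1L) zm else "",
         if (ad@charge > 0L) "+" else "-")
}

#' Parse an adduct expression
#'
#' Accepts the electrospray adduct grammar `[nM+X1-X2...]z+` (or `z-`):
#' optional molecule multiplier n, one or more gained/lost groups written
#' as condensed formulas with an optional leading integer (so `"+2H"` and
#' `"+H2"` are equivalent), and charge z (magnitude defaults to 1).
#' Whitespace and typographic minus signs are tolerated.  Condensed-formula
#' groups allow fragment adducts such as `"[M-C5D7O2+CH3CN]+"`.
#'
#' @param text Adduct string, e.g. `"[M+H]+"`, `"[M-H]-"`, `"[2M+Na]+"`.
#' @return An [Adduct-class].
#' @examples
#' parseAdduct("[M+H]+")
#' parseAdduct("[2M+Na]+")
#' parseAdduct("[M-D]-")
#' @export
parseAdduct <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("adduct must be a single character string")
  s <- gsub("[[:space:]]+", "", text)
  s <- gsub("−|–|—", "-", s)
  m <- regexec("^\\[([0-9]*)M((?:[+-][0-9A-Za-z()]+)*)\\]([0-9]*)([+-])$", s)
  g <- regmatches(s, m)[[1L]]
  if (!length(g))
    stop("malformed adduct '", text,
         "': expected the form [nM+X]z+ or [nM-X]z-")
  mult <- if (nzchar(g[2L])) as.integer(g[2L]) else 1L
  if (mult < 1L) stop("adduct multiplier must be a positive integer")
  zmag <- if (nzchar(g[4L])) as.integer(g[4L]) else 1L
  if (zmag == 0L) stop("an adduct must be an ion; charge cannot be zero")
  z <- if (g[5L] == "+") zmag else -zmag
  gained <- setNames(integer(0), character(0))
  lost <- setNames(integer(0), character(0))
  if (nzchar(g[3L])) {
    toks <- regmatches(g[3L], gregexpr("[+-][0-9A-Za-z()]+", g[3L]))[[1L]]
    for (tk in toks) {
      sgn <- substr(tk, 1L, 1L)
      body <- substring(tk, 2L)
      gm <- regmatches(body, regexec("^([0-9]*)([A-Z(].*)$", body))[[1L]]
      if (!length(gm))
        stop("malformed adduct group '", tk, "' in '", text, "'")
      k <- if (nzchar(gm[2L])) as.integer(gm[2L]) else 1L
      if (k < 1L)
        stop("zero group multiplier in adduct '", text, "'")
      grp <- elementCounts(parseFormula(gm[3L])) * k
      if (sgn == "+") gained <- .addCounts(gained, grp)
      else lost <- .addCounts(lost, grp)
    }
  }
  Adduct(multiplier = mult, gained = ElementComposition(gained),
         lost = ElementComposition(lost), charge = z)
}

#' Apply an adduct to a neutral composition
#'
#' Returns `multiplier * base + gained - lost`, carrying the adduct charge.
#'
#' @param base Neutral [ElementComposition-class] of the molecule M.
#' @param adduct An [Adduct-class] or adduct string.
#' @return The ionic [ElementComposition-class].
#' @examples
#' applyAdduct(parseFormula("C6D14"), "[M+H]+")
#' @export
applyAdduct <- function(base, adduct) {
  if (is.character(adduct)) adduct <- parseAdduct(adduct)
  cts <- .addCounts(elementCounts(base) * adduct@multiplier,
                    elementCounts(adduct@gained))
  lostc <- elementCounts(adduct@lost)
  for (el in names(lostc)) {
    have <- if (el %in% names(cts)) cts[[el]] else 0L
    if (have < lostc[[el]])
      stop("infeasible adduct ", adductLabel(adduct), ": cannot remove ",
           lostc[[el]], " x ", el, " from ", formulaString(base))
    cts[[el]] <- have - lostc[[el]]
  }
  ElementComposition(cts, adduct@charge)
}

#' Un-apply an adduct, recovering the neutral molecule
#'
#' Inverse of [applyAdduct()]: `(ion - gained + lost) / multiplier` with
#' charge reset to zero.
#'
#' @param ion Ionic [ElementComposition-class] produced by the adduct.
#' @param adduct An [Adduct-class] or adduct string.
#' @return The neutral base [ElementComposition-class].
#' @export
removeAdduct <- function(ion, adduct) {
  if (is.character(adduct)) adduct <- parseAdduct(adduct)
  cts <- .addCounts(elementCounts(ion), elementCounts(adduct@lost))
  gainc <- elementCounts(adduct@gained)
  for (el in names(gainc)) {
    have <- if (el %in% names(cts)) cts[[el]] else 0L
    if (have < gainc[[el]])
      stop("ion is not consistent with adduct ", adductLabel(adduct))
    cts[[el]] <- have - gainc[[el]]
  }
  if (any(cts %% adduct@multiplier != 0L))
    stop("ion is not a multiple of the adduct multiplier")
  ElementComposition(cts %/% adduct@multiplier, 0L)
}

#' Default electrospray adduct candidates
#'
#' The candidate list used by automatic adduct selection: the ion forms
#' most commonly observed in positive- and negative-mode electrospray.
#'
#' @return Character vector of adduct labels.
#' @export
defaultAdducts <- function() {
  c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M]+", "[2M+H]+",
    "[M-H]-", "[M+Cl]-", "[M-D]-", "[M]-")
}
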