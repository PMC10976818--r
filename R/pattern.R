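# ---------------------------------------------------------------------------
# Isotopic pattern computation by convolution of per-element distributions
# ---------------------------------------------------------------------------

# Peaks closer than MERGE_TOL are below any realistic HRMS resolving power
# at the +-0.5 Da windows used downstream; combination states below
# PRUNE_FLOOR relative abundance are under instrument dynamic range.
.MERGE_TOL <- 1e-3
.PRUNE_FLOOR <- 1e-6

.newPattern <- function(mass, abundance, composition = NULL) {
  if (is.null(composition)) composition <- new("ElementComposition")
  o <- order(mass)
  new("IsotopicPattern", mass = mass[o], abundance = abundance[o],
      composition = composition)
}

# merge peaks within `tol` Da (abundance-weighted mean mass), prune states
# below `floor` relative abundance, renormalise to unit sum
.tidyPeaks <- function(mass, ab, tol = .MERGE_TOL, floor = .PRUNE_FLOOR) {
  o <- order(mass)
  mass <- mass[o]
  ab <- ab[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(1, diff(mass) > tol))
    tot <- rowsum(ab, grp)
    mass <- as.numeric(rowsum(ab * mass, grp) / tot)
    ab <- as.numeric(tot)
  }
  ab <- ab / sum(ab)
  keep <- ab >= floor
  mass <- mass[keep]
  ab <- ab[keep]
  list(mass = mass, abundance = ab / sum(ab))
}

#' Isotopic pattern of n atoms of one element
#'
#' The multinomial distribution of isotope combinations for `count` atoms
#' of `symbol`, computed by repeated squaring of the single-atom pattern,
#' merged and pruned.  `count = 0` yields the identity pattern (one peak at
#' mass 0, abundance 1).
#'
#' @param symbol Element symbol present in [isotopeTable()].
#' @param count Number of atoms (`>= 0`).
#' @return An [IsotopicPattern-class].
#' @examples
#' elementPattern("C", 1)
#' elementPattern("Br", 1)
#' @export
elementPattern <- function(symbol, count) {
  entry <- .isotopeEntry(symbol)
  count <- as.integer(count)
  if (count < 0L) stop("atom count must be non-negative")
  comp <- ElementComposition(setNames(count, symbol))
  unit <- .newPattern(0, 1, comp)
  if (count == 0L) return(unit)
  single <- .newPattern(entry$mass, entry$abundance / sum(entry$abundance))
  # binary exponentiation: pattern of 2k atoms = square of pattern of k
  acc <- .newPattern(0, 1)
  base <- single
  k <- count
  while (k > 0L) {
    if (k %% 2L == 1L) acc <- convolvePatterns(acc, base)
    k <- k %/% 2L
    if (k > 0L) base <- convolvePatterns(base, base)
  }
  .newPattern(peakMass(acc), peakAbundance(acc), comp)
}

#' Convolve two isotopic patterns
#'
#' All pairwise mass sums with product abundances, then merging of peaks
#' within the merge width and pruning below the abundance floor.  The
#' result is renormalised, so total abundance is conserved exactly.
#'
#' @param a,b [IsotopicPattern-class] objects.
#' @param tol Peak merge width in Da.
#' @param floor Relative abundance pruning floor.
#' @return An [IsotopicPattern-class] for the combined composition.
#' @export
convolvePatterns <- function(a, b, tol = .MERGE_TOL, floor = .PRUNE_FLOOR) {
  ma <- peakMass(a); aa <- peakAbundance(a)
  mb <- peakMass(b); ab <- peakAbundance(b)
  mass <- as.numeric(outer(ma, mb, `+`))
  w <- as.numeric(outer(aa, ab))
  tp <- .tidyPeaks(mass, w, tol, floor)
  comp <- ElementComposition(.addCounts(elementCounts(a@composition),
                                        elementCounts(b@composition)),
                             ionCharge(a@composition) +
                               ionCharge(b@composition))
  .newPattern(tp$mass, tp$abundance, comp)
}

#' Isotopic pattern of a full composition
#'
#' Convolves the per-element patterns of every element in `comp` (elements
#' processed by ascending atom count).  For a charged composition the
#' electron mass deficit is applied and masses are divided by |charge|, so
#' peak positions are m/z values directly comparable with a spectrum.
#'
#' @param comp An [ElementComposition-class].
#' @param tol,floor Merge width and pruning floor, as in
#'   [convolvePatterns()].
#' @return An [IsotopicPattern-class]; abundances sum to 1.
#' @examples
#' isotopePattern(parseFormula("C6D14"))
#' @export
isotopePattern <- function(comp, tol = .MERGE_TOL, floor = .PRUNE_FLOOR) {
  cts <- elementCounts(comp)
  z <- ionCharge(comp)
  pat <- .newPattern(0, 1)
  for (el in names(cts)[order(cts)])
    pat <- convolvePatterns(pat, elementPattern(el, cts[[el]]), tol, floor)
  mass <- peakMass(pat) - z * .ELECTRON_MASS
  if (z != 0L) mass <- mass / abs(z)
  .newPattern(mass, peakAbundance(pat), comp)
}

#' Export a pattern as two-column delimited text
#'
#' @param pattern An [IsotopicPattern-class].
#' @param path Output file path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writePattern <- function(pattern, path, sep = "\t") {
  utils::write.table(
    data.frame(mz = peakMass(pattern), abundance = peakAbundance(pattern)),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
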