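# Pinned isotope masses (Da) and abundances, CIAAW/NIST recommended values.
# "D" is deuterium as a pseudo-element: pure 2H at the labelled positions.
# Natural hydrogen ("H") keeps its 0.0115% 2H component so that the pattern
# of remaining protium positions is physically complete.
.ELECTRON_MASS <- 0.000548579909

.isotopes <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785),
            abundance = c(0.999885, 0.000115)),
  D  = list(mass = 2.01410177785, abundance = 1),
  C  = list(mass = c(12.0, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088989),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461956, 16.99913175650, 17.99915961286),
            abundance = c(0.99757, 0.00038, 0.00205)),
  F  = list(mass = 18.99840316273, abundance = 1),
  Na = list(mass = 22.9897692809, abundance = 1),
  Si = list(mass = c(27.97692653465, 28.97649466490, 29.973770136),
            abundance = c(0.92223, 0.04685, 0.03092)),
  P  = list(mass = 30.97376163, abundance = 1),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.96885268, 36.96590259),
            abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.96370668, 39.96399848, 40.96182576),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Fe = list(mass = c(53.9396105, 55.9349375, 56.9353940, 57.9332756),
            abundance = c(0.05845, 0.91754, 0.02119, 0.00282)),
  Br = list(mass = c(78.9183371, 80.9162906),
            abundance = c(0.5069, 0.4931)),
  Zr = list(mass = c(89.9047044, 90.9056458, 91.9050408, 93.9063152,
                     95.9082734),
            abundance = c(0.5145, 0.1122, 0.1715, 0.1738, 0.0280)),
  I  = list(mass = 126.904473, abundance = 1)
)

#' Embedded isotope table
#'
#' The static table of isotope exact masses and natural abundances used
#' throughout the package (CIAAW/IUPAC recommended values).  `"D"` is a
#' pseudo-element mapping to pure deuterium (2H).
#'
#' @return A data.frame with columns `element`, `mass` and `abundance`.
#' @examples
#' subset(isotopeTable(), element == "Br")
#' @export
isotopeTable <- function() {
  do.call(rbind, lapply(names(.isotopes), function(el) {
    data.frame(element = el, mass = .isotopes[[el]]$mass,
               abundance = .isotopes[[el]]$abundance)
  }))
}

.isotopeEntry <- function(symbol) {
  entry <- .isotopes[[symbol]]
  if (is.null(entry))
    stop("element '", symbol, "' is not in the isotope table", call. = FALSE)
  entry
}

# mass of the most abundant isotope of an element
.mostAbundantMass <- function(symbol) {
  entry <- .isotopeEntry(symbol)
  entry$mass[which.max(entry$abundance)]
}

# exact D - H mass difference: the isotopologue channel spacing for |z| = 1
.DH_MASS_DIFF <- 2.01410177785 - 1.00782503207
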