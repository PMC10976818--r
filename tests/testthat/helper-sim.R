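# Shared study-condition simulations: first-order two-class back-exchange
# (methyl sites 2.18x faster than methylene) run to 60% overall retention,
# rendered noiselessly as [M+H]+ profile spectra.  Cached per compound so
# several test files can reuse them.
.simCache <- new.env(parent = emptyenv())

studySim <- function(compound = c("C6D14", "C6D13Br")) {
  compound <- match.arg(compound)
  if (!is.null(.simCache[[compound]])) return(.simCache[[compound]])
  cfg <- switch(compound,
    C6D14 = list(formula = "C6D14", classes = c(6L, 8L)),
    C6D13Br = list(formula = "C6D13Br", classes = c(3L, 10L)))
  dist <- exchangeDistribution(cfg$classes, c(2.18, 1), retention = 0.6)
  spec <- renderSpectrum(cfg$formula, "[M+H]+", dist)
  .simCache[[compound]] <- list(formula = cfg$formula, dist = dist,
                                spectrum = spec)
  .simCache[[compound]]
}

# run the pipeline quietly (the C6D13Br grid legitimately warns that the
# +-0.5 Da windows touch at its ~1.0 Da tail spacing)
quietDeuterate <- function(...) suppressWarnings(deuterate(...))

# brute-force isotopic pattern by full enumeration over isotope
# combinations; independent oracle for the convolution-based code
bruteForcePattern <- function(counts, mergeTol = 1e-3) {
  mass <- 0
  ab <- 1
  for (el in names(counts)) {
    entry <- subset(isotopeTable(), element == el)
    for (k in seq_len(counts[[el]])) {
      mass <- as.numeric(outer(mass, entry$mass, `+`))
      ab <- as.numeric(outer(ab, entry$abundance))
    }
  }
  o <- order(mass)
  mass <- mass[o]; ab <- ab[o]
  grp <- cumsum(c(1, diff(mass) > mergeTol))
  tot <- as.numeric(rowsum(ab, grp))
  list(mass = as.numeric(rowsum(ab * mass, grp)) / tot,
       abundance = tot / sum(tot))
}
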