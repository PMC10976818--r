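# ---------------------------------------------------------------------------
# Result report table, delimited export and plot
# ---------------------------------------------------------------------------

#' Isotopologue report table
#'
#' One row per deuteration state: state index, channel m/z, raw extracted
#' signal and normalised probability (zero below the cutoff).
#'
#' @param result A [DeuterationResult-class].
#' @return A data.frame with columns `state`, `mz`, `signal`,
#'   `probability`.
#' @export
reportTable <- function(result) {
  grid <- result@grid
  n <- nStates(grid)
  data.frame(state = 0:n,
             mz = positions(grid)[seq_len(n + 1L)],
             signal = result@signals[seq_len(n + 1L)],
             probability = probabilities(distribution(result)))
}

#' Write a delimited text report
#'
#' Summary lines (percent deuteration, adduct, offset, extraction mode,
#' cutoff) as `#` comments followed by the tab-separated isotopologue
#' table.
#'
#' @param result A [DeuterationResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# formula\t%s", formulaString(result@formula)),
    sprintf("# adduct\t%s%s", adductLabel(result@adduct),
            if (result@autoAdduct) " (auto)" else ""),
    sprintf("# mz offset (Da)\t%.4f", result@offset),
    sprintf("# extraction\t%s", result@mode),
    sprintf("# deconvolved\t%s", result@deconvolved),
    sprintf("# cutoff state\t%d", cutoffIndex(distribution(result))),
    sprintf("# percent deuteration\t%.2f", result@percentD)
  ), con)
  tab <- reportTable(result)
  tab$probability <- round(tab$probability, 6)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a deuteration result
#'
#' The measured spectrum overlaid with the predicted isotopic pattern of
#' the fully deuterated species (scaled to the strongest extracted signal)
#' and stems marking each isotopologue channel's recovered probability.
#'
#' @param result A [DeuterationResult-class].
#' @param path Optional PNG output path; when `NULL`, plots to the active
#'   device.
#' @return `result`, invisibly.
#' @export
plotDeuteration <- function(result, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  spec <- result@spectrum
  grid <- result@grid
  n <- nStates(grid)
  pos <- positions(grid)
  probs <- probabilities(distribution(result))
  ymax <- max(intensity(spec))
  graphics::plot(mz(spec), intensity(spec), type = "l", col = "grey30",
                 xlab = "m/z", ylab = "intensity",
                 main = sprintf("%s %s: %.2f %%D",
                                formulaString(result@formula),
                                adductLabel(result@adduct),
                                result@percentD))
  pat <- isotopePattern(applyAdduct(result@formula, result@adduct))
  sc <- ymax / max(peakAbundance(pat))
  graphics::segments(peakMass(pat), 0, peakMass(pat),
                     peakAbundance(pat) * sc, col = "#d95f02", lwd = 2)
  graphics::segments(pos[seq_len(n + 1L)], 0, pos[seq_len(n + 1L)],
                     probs * ymax, col = "#1b9e77", lwd = 2, lty = 3)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("grey30", "#d95f02", "#1b9e77"),
                   lty = c(1, 1, 3),
                   legend = c("spectrum", "predicted pattern (full D)",
                              "isotopologue probability"))
  invisible(result)
}
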