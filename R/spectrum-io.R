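# ---------------------------------------------------------------------------
# Delimited mass-spectrum reading with dialect inference, and realignment
# ---------------------------------------------------------------------------

.DELIMITERS <- c("\t", ",", ";", " ")

.splitLine <- function(line, delim) {
  f <- if (delim == " ")
    strsplit(trimws(line), "[[:space:]]+")[[1L]]
  else
    trimws(strsplit(line, delim, fixed = TRUE)[[1L]])
  f[nzchar(f)]
}

.numericFields <- function(fields) {
  suppressWarnings(as.numeric(fields))
}

# number of leading lines to drop and the field count, for one delimiter;
# NULL when no block of >= 2 numeric columns is found
.probeDialect <- function(lines, delim) {
  for (i in seq_along(lines)) {
    f <- .splitLine(lines[[i]], delim)
    if (length(f) >= 2L) {
      v <- .numericFields(f)
      if (sum(!is.na(v)) >= 2L)
        return(list(skip = i - 1L, nfields = length(f)))
    }
  }
  NULL
}

#' Read a delimited mass spectrum
#'
#' Reads a text file with at least one m/z and one signal-intensity column.
#' When `delimiter` and `skipRows` are omitted they are inferred: the
#' delimiter is chosen from tab, comma, semicolon and whitespace, and
#' leading non-numeric (header) lines are skipped automatically.  By
#' default the first two numeric columns are taken as (m/z, intensity).
#' Duplicated m/z rows have their intensities summed; non-monotonic m/z is
#' sorted with a warning; negative intensities are clipped to zero with a
#' warning.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter; overrides inference.  Use `" "` for
#'   any-whitespace splitting.
#' @param skipRows Number of leading lines to skip; overrides inference.
#' @param mzColumn,signalColumn 1-based column indices; override the
#'   first-two-numeric-columns default.
#' @param mode Declared spectrum mode, `"profile"` or `"centroid"`.
#' @return A [MassSpectrum-class].
#' @export
readSpectrum <- function(path, delimiter = NULL, skipRows = NULL,
                         mzColumn = NULL, signalColumn = NULL,
                         mode = c("profile", "centroid")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!is.null(skipRows)) {
    if (skipRows >= length(lines)) stop("skipRows leaves no data in ", path)
    lines <- lines[-seq_len(skipRows)]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)

  cands <- if (is.null(delimiter)) .DELIMITERS else delimiter
  delim <- NULL; skip <- NULL; nfields <- NULL
  for (d in cands) {
    pr <- .probeDialect(lines, d)
    # prefer the delimiter whose numeric block starts earliest and splits
    # into the most fields
    if (!is.null(pr) &&
        (is.null(delim) || pr$skip < skip ||
         (pr$skip == skip && pr$nfields > nfields))) {
      delim <- d; skip <- pr$skip; nfields <- pr$nfields
    }
  }
  if (is.null(delim))
    stop("no numeric m/z-intensity block found in ", path)
  if (!is.null(skipRows) && skip > 0L)
    stop("line ", skipRows + 1L, " of ", path,
         " is not numeric after skipping ", skipRows, " rows")

  body <- lines[(skip + 1L):length(lines)]
  fields <- lapply(body, .splitLine, delim = delim)
  nf <- lengths(fields)
  if (any(nf != nfields))
    stop("ragged row in ", path, ": line ",
         skip + which(nf != nfields)[1L],
         " has ", nf[nf != nfields][1L], " fields, expected ", nfields)
  m <- matrix(.numericFields(unlist(fields)), ncol = nfields, byrow = TRUE)
  numericCols <- which(colSums(is.na(m)) == 0L)
  if (is.null(mzColumn) || is.null(signalColumn)) {
    if (length(numericCols) < 2L)
      stop("fewer than two fully numeric columns in ", path)
  }
  mzCol <- if (is.null(mzColumn)) numericCols[1L] else mzColumn
  sigCol <- if (is.null(signalColumn)) numericCols[2L] else signalColumn
  if (mzCol > nfields || sigCol > nfields)
    stop("column index out of range for ", nfields, "-column file ", path)
  mzv <- m[, mzCol]
  iv <- m[, sigCol]
  if (anyNA(mzv) || anyNA(iv))
    stop("non-numeric value in selected columns of ", path, ": line ",
         skip + which(is.na(mzv) | is.na(iv))[1L])
  if (is.unsorted(mzv))
    warning("non-monotonic m/z in ", path, "; sorting")
  if (any(iv < 0)) {
    warning("negative intensities in ", path, "; clipped to zero")
    iv[iv < 0] <- 0
  }
  MassSpectrum(mzv, iv, mode = mode)
}

#' Write a spectrum as delimited text
#'
#' Writes a two-column file readable by [readSpectrum()]; the simulator's
#' fixture writer.
#'
#' @param spectrum A [MassSpectrum-class].
#' @param path Output path.
#' @param dialect `"csv"`, `"tsv"` or `"semicolon"`.
#' @param header Optional character vector of header lines written verbatim
#'   before the data (exercises the reader's inference).
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path,
                          dialect = c("csv", "tsv", "semicolon"),
                          header = NULL) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, csv = ",", tsv = "\t", semicolon = ";")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(format(mz(spectrum), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   format(intensity(spectrum), digits = 15, trim = TRUE,
                          scientific = FALSE), sep = sep), con)
  invisible(path)
}

#' Realign a miscalibrated spectrum against a predicted pattern
#'
#' Grid-searches an m/z offset in `[-maxOffset, +maxOffset]` (0.005 Da
#' steps) maximising the abundance-weighted sum of spectrum heights near
#' each predicted peak, each height down-weighted linearly with its
#' distance from the predicted position (triangular kernel of half-width
#' `tol`) so the objective peaks only at true alignment.  Returns the
#' shifted spectrum.
#'
#' @param spectrum A [MassSpectrum-class].
#' @param pattern Predicted [IsotopicPattern-class] of the target species.
#' @param maxOffset Maximum |offset| in Da (default 0.5, the calibration
#'   error bound the method is designed to absorb).
#' @param step Grid step in Da.
#' @param tol Half-width (Da) of the height-lookup window per peak.
#' @return A list with elements `spectrum` (shifted) and `offset` (Da, the
#'   value added to the input m/z axis).
#' @export
realignSpectrum <- function(spectrum, pattern, maxOffset = 0.5,
                            step = 0.005, tol = 0.05) {
  mzv <- mz(spectrum)
  iv <- intensity(spectrum)
  keep <- peakAbundance(pattern) >= 1e-3
  pm <- peakMass(pattern)[keep]
  pa <- peakAbundance(pattern)[keep]
  if (!length(mzv) || min(pm) > max(mzv) || max(pm) < min(mzv))
    stop("predicted pattern does not overlap the spectrum m/z range; ",
         "cannot realign")
  offs <- seq(-maxOffset, maxOffset, by = step)
  heightNear <- function(centre) {
    lo <- findInterval(centre - tol, mzv) + 1L
    hi <- findInterval(centre + tol, mzv)
    if (hi < lo) return(0)
    idx <- lo:hi
    max(iv[idx] * (1 - abs(mzv[idx] - centre) / tol))
  }
  score <- vapply(offs, function(o) {
    sum(pa * vapply(pm - o, heightNear, numeric(1)))
  }, numeric(1))
  best <- offs[which.max(score)]
  if (abs(best) >= maxOffset - step / 2)
    warning("realignment hit the +/-", maxOffset,
            " Da cap; the true offset may be larger")
  list(spectrum = MassSpectrum(mzv + best, iv, mode = spectrumMode(spectrum)),
       offset = best)
}
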