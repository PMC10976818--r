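# ---------------------------------------------------------------------------
# Adduct auto-selection and the end-to-end deuteration pipeline
# ---------------------------------------------------------------------------

# run `expr`, rethrowing any error tagged with the pipeline stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Automatically select an electrospray adduct
#'
#' For each candidate adduct the expected deuteration window spans the
#' D0..DN base peaks (+-0.5 Da each side).  The most intense spectrum
#' point inside the union of candidate windows is located, and among the
#' candidates whose own window contains it, the one whose fully
#' deuterated monoisotopic m/z lies closest to that peak is chosen; ties
#' are broken by list order.  Automatic selection is a starting point
#' only and should be verified by the user: in particular, partially
#' deuterated samples move the most intense peak several Da below the
#' perdeuterated mass, where a deuterium-loss adduct can explain the
#' spectrum equally well in mass terms.
#'
#' @param base Neutral fully deuterated [ElementComposition-class].
#' @param spectrum A [MassSpectrum-class].
#' @param candidates Character vector (or list of [Adduct-class]) of
#'   candidate adducts; defaults to [defaultAdducts()].
#' @param window Half-width (Da) added around the D0..DN base peaks.
#' @return The selected [Adduct-class].
#' @export
autoSelectAdduct <- function(base, spectrum, candidates = defaultAdducts(),
                             window = 0.5) {
  if (!length(candidates)) stop("no candidate adducts supplied")
  mzv <- mz(spectrum)
  iv <- intensity(spectrum)
  feasible <- list()
  inAny <- rep(FALSE, length(mzv))
  for (cand in candidates) {
    ad <- if (is.character(cand)) parseAdduct(cand) else cand
    full <- tryCatch(applyAdduct(base, ad), error = function(e) NULL)
    if (is.null(full) || nDeuterium(full) < 1L) next
    n <- nDeuterium(full)
    spacing <- .DH_MASS_DIFF / abs(ionCharge(full))
    pN <- monoisotopicMz(full)
    lo <- pN - n * spacing - window
    hi <- pN + window
    sel <- mzv >= lo & mzv <= hi
    if (!any(sel)) next
    inAny <- inAny | sel
    feasible[[length(feasible) + 1L]] <- list(ad = ad, pN = pN,
                                              lo = lo, hi = hi)
  }
  if (!length(feasible))
    stop("no candidate adduct's expected deuteration window overlaps the ",
         "spectrum")
  top <- mzv[inAny][which.max(iv[inAny])]
  best <- NULL
  bestDist <- Inf
  for (f in feasible) {
    if (top < f$lo || top > f$hi) next
    d <- abs(f$pN - top)
    if (d < bestDist) {
      bestDist <- d
      best <- f$ad
    }
  }
  if (is.null(best)) best <- feasible[[1L]]$ad
  best
}

#' Run the full deuteration pipeline
#'
#' Composes the whole calculation: read the spectrum, select or apply the
#' adduct, predict the isotopic pattern of the fully deuterated species,
#' optionally realign the spectrum, build the target grid, extract
#' signals, deconvolve with the response function, apply the probability
#' cutoff and compute percent deuteration.  Errors are tagged with the
#' failing stage.
#'
#' @param formula Formula string (or [ElementComposition-class]) of the
#'   *fully deuterated* molecule, e.g. `"C6D14"`.
#' @param spectrum Path to a delimited spectrum file or a
#'   [MassSpectrum-class].
#' @param adduct Adduct string, [Adduct-class], or `"auto"` for automatic
#'   selection.
#' @param mode Signal extraction mode, `"area"` (default) or `"height"`.
#' @param window Extraction half-width in Da.
#' @param cutoff Optional manual cutoff (deuterium count).
#' @param cutoffMz Optional manual cutoff as an m/z value.
#' @param realign Logical; grid-search an m/z offset (up to
#'   `+-maxOffset`) aligning the data with the predicted pattern.
#' @param maxOffset Realignment cap in Da.
#' @param deconvolve Logical; `FALSE` computes the distribution from raw
#'   extracted signals (diagnostic mode, reproducing what one would obtain
#'   without compensating isotopic interferences).
#' @param method Deconvolution method, `"fourier"` or `"nnls"`.
#' @param candidates Candidate adducts for `adduct = "auto"`.
#' @param delimiter,skipRows,mzColumn,signalColumn Passed to
#'   [readSpectrum()] when `spectrum` is a path.
#' @return A [DeuterationResult-class].
#' @examples
#' d <- exchangeDistribution(nSites = 14, retention = 1)
#' s <- renderSpectrum("C6D14", "[M+H]+", d)
#' res <- deuterate("C6D14", s, adduct = "[M+H]+")
#' percentD(res)  # ~100
#' @export
deuterate <- function(formula, spectrum, adduct = "auto",
                      mode = c("area", "height"), window = 0.5,
                      cutoff = NULL, cutoffMz = NULL, realign = FALSE,
                      maxOffset = 0.5, deconvolve = TRUE,
                      method = c("fourier", "nnls"),
                      candidates = defaultAdducts(),
                      delimiter = NULL, skipRows = NULL, mzColumn = NULL,
                      signalColumn = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  comp <- .stage("formula", {
    cmp <- if (is.character(formula)) parseFormula(formula) else formula
    if (nDeuterium(cmp) < 1L)
      stop("formula contains no deuterium")
    cmp
  })
  spec <- .stage("read", {
    if (is.character(spectrum))
      readSpectrum(spectrum, delimiter = delimiter, skipRows = skipRows,
                   mzColumn = mzColumn, signalColumn = signalColumn)
    else spectrum
  })
  auto <- is.character(adduct) && identical(adduct, "auto")
  ad <- .stage("adduct", {
    if (auto) autoSelectAdduct(comp, spec, candidates, window)
    else if (is.character(adduct)) parseAdduct(adduct)
    else adduct
  })
  full <- .stage("adduct", applyAdduct(comp, ad))
  pat <- .stage("pattern", isotopePattern(full))
  offset <- 0
  if (isTRUE(realign)) {
    re <- .stage("realign", realignSpectrum(spec, pat, maxOffset))
    spec <- re$spectrum
    offset <- re$offset
  }
  grid <- .stage("grid", buildTargetGrid(full, pat, window))
  x <- .stage("extract", extractSignals(spec, grid, mode))
  dist <- .stage("deconvolve", {
    if (deconvolve)
      deconvolveSignals(x, responseVector(grid), nStates(grid), method)
    else
      IsotopologueDistribution(x[seq_len(nStates(grid) + 1L)])
  })
  dist <- .stage("cutoff",
                 applyCutoff(dist, count = cutoff, mzCutoff = cutoffMz,
                             grid = grid))
  pd <- .stage("percentD", percentDeuteration(dist))
  new("DeuterationResult", percentD = pd, distribution = dist, adduct = ad,
      autoAdduct = auto, offset = offset, mode = mode,
      deconvolved = isTRUE(deconvolve), grid = grid, signals = x,
      spectrum = spec, formula = comp)
}
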