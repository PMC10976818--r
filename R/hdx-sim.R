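# ---------------------------------------------------------------------------
# H/D back-exchange simulation and synthetic profile spectrum rendering
# ---------------------------------------------------------------------------

#' Deuterium distribution after first-order back-exchange
#'
#' Models back-exchange from a perdeuterated molecule with site classes
#' (e.g. CD3 vs CD2 positions) exchanging at first-order rates
#' proportional to `rates`.  The common exposure time is solved so the
#' mean retained fraction equals `retention`; each site then keeps its
#' deuterium independently with its class probability
#' `p_c = exp(-rate_c * t)`, making the deuterium count the convolution of
#' per-class binomials.  The distribution is analytic (no Monte Carlo).
#'
#' @param nSites Integer vector of site counts per class; the total is the
#'   molecule's deuterium count N.
#' @param rates Positive relative exchange rates, recycled along
#'   `nSites`.  Only ratios matter.
#' @param retention Overall deuterium retention in `(0, 1]` (e.g. 0.6 for
#'   a final overall deuteration of 60%).
#' @return A normalised [IsotopologueDistribution-class] over states 0..N
#'   whose mean equals `N * retention`.
#' @examples
#' # a single class is exactly Binomial(N, retention)
#' exchangeDistribution(14, retention = 0.6)
#' # hexane-d14 as 6 CD3 + 8 CD2 sites, methyl sites exchanging 2.18x faster
#' exchangeDistribution(c(6, 8), c(2.18, 1), retention = 0.6)
#' @export
exchangeDistribution <- function(nSites, rates = 1, retention) {
  nSites <- as.integer(nSites)
  if (!length(nSites) || any(nSites < 1L))
    stop("each site class must contain at least one site")
  rates <- rep_len(as.numeric(rates), length(nSites))
  if (any(rates <= 0)) stop("relative rates must be positive")
  if (length(retention) != 1L || retention <= 0 || retention > 1)
    stop("overall retention must lie in (0, 1]")
  n <- sum(nSites)
  if (retention == 1) {
    p <- rep(1, length(nSites))
  } else {
    f <- function(t) sum(nSites * exp(-rates * t)) / n - retention
    upper <- 1
    while (f(upper) > 0) upper <- upper * 2
    t <- stats::uniroot(f, c(0, upper), tol = .Machine$double.eps^0.75)$root
    p <- exp(-rates * t)
  }
  y <- 1
  for (cc in seq_along(nSites)) {
    yc <- stats::dbinom(0:nSites[cc], nSites[cc], p[cc])
    y <- stats::convolve(y, rev(yc), type = "open")
  }
  y[y < 0] <- 0  # convolve() via FFT can leave -1e-20 ripples
  IsotopologueDistribution(y / sum(y), cutoffIndex = 0L, normalised = TRUE)
}

#' Render a synthetic profile spectrum for an isotopologue mixture
#'
#' Computes the full mixture pattern
#' `sum_i y_i * isotopePattern(isotopologue_i + adduct)` (every
#' isotopologue with its complete natural isotope structure) and renders
#' it as a sum of Gaussian peaks of width `peakSigma`, sampled every
#' `mzStep`, with peak height proportional to abundance.  Optional
#' Gaussian noise (sd = `noiseSd` x the maximum intensity) and a
#' systematic `mzOffset` emulate measurement imperfections.  Deterministic
#' for a fixed `seed`.
#'
#' @param formula Fully deuterated neutral formula (string or
#'   [ElementComposition-class]).
#' @param adduct Adduct string or [Adduct-class].
#' @param dist [IsotopologueDistribution-class] over states 0..N of the
#'   adducted species.
#' @param peakSigma Gaussian peak sigma in Da.
#' @param mzStep Profile sampling step in Da.
#' @param noiseSd Noise standard deviation relative to the maximum
#'   intensity (0 disables noise).
#' @param mzOffset Simulated calibration error added to the m/z axis (Da).
#' @param seed RNG seed used when `noiseSd > 0`.
#' @param scale Intensity of the most abundant rendered peak.
#' @return A profile-mode [MassSpectrum-class].
#' @export
renderSpectrum <- function(formula, adduct, dist, peakSigma = 0.01,
                           mzStep = 0.002, noiseSd = 0, mzOffset = 0,
                           seed = 1L, scale = 1e4) {
  stopifnot(peakSigma > 0, mzStep > 0, noiseSd >= 0)
  comp <- if (is.character(formula)) parseFormula(formula) else formula
  ad <- if (is.character(adduct)) parseAdduct(adduct) else adduct
  full <- applyAdduct(comp, ad)
  series <- isotopologueSeries(full)
  y <- probabilities(dist)
  if (length(y) != length(series))
    stop("distribution has ", length(y) - 1L, " states but the adducted ",
         "species has ", length(series) - 1L, " deuterium")
  pm <- numeric(0)
  pa <- numeric(0)
  for (i in seq_along(series)) {
    if (y[i] < 1e-9) next
    pat <- isotopePattern(series[[i]])
    pm <- c(pm, peakMass(pat))
    pa <- c(pa, peakAbundance(pat) * y[i])
  }
  mzv <- seq(min(pm) - 1, max(pm) + 1, by = mzStep)
  iv <- numeric(length(mzv))
  halfw <- 8 * peakSigma
  for (j in seq_along(pm)) {
    lo <- findInterval(pm[j] - halfw, mzv) + 1L
    hi <- findInterval(pm[j] + halfw, mzv)
    if (hi < lo) next
    idx <- lo:hi
    iv[idx] <- iv[idx] + pa[j] * exp(-(mzv[idx] - pm[j])^2 / (2 * peakSigma^2))
  }
  iv <- iv * scale / max(iv)
  if (noiseSd > 0) {
    set.seed(seed)
    iv <- iv + stats::rnorm(length(iv), 0, noiseSd * max(iv))
    iv[iv < 0] <- 0
  }
  MassSpectrum(mzv + mzOffset, iv, mode = "profile")
}

#' Write a simulation fixture: spectrum plus manifest
#'
#' Writes the spectrum via [writeSpectrum()] and a plain-text manifest
#' recording the simulation parameters next to it (`<path>.manifest.txt`).
#'
#' @param spectrum A [MassSpectrum-class] from [renderSpectrum()].
#' @param path Spectrum output path.
#' @param dialect Delimited dialect, see [writeSpectrum()].
#' @param header Optional header lines for the spectrum file.
#' @param manifest Named list of parameters to record (formula, adduct,
#'   retention, ...); omitted when `NULL`.
#' @return `path`, invisibly.
#' @export
writeFixture <- function(spectrum, path, dialect = "csv", header = NULL,
                         manifest = NULL) {
  writeSpectrum(spectrum, path, dialect = dialect, header = header)
  if (!is.null(manifest)) {
    writeLines(paste(names(manifest), vapply(manifest, format, character(1)),
                     sep = "\t"),
               paste0(path, ".manifest.txt"))
  }
  invisible(path)
}
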