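# ---------------------------------------------------------------------------
# Target grid construction and signal extraction
# ---------------------------------------------------------------------------

#' Build the deconvolution target grid and response vector
#'
#' Channels 0..N sit at the base-peak m/z of each deuterium isotopologue of
#' the adducted species (spacing (m(D)-m(H))/|z|); tail channels continue
#' above the fully deuterated base peak at the positions of its isotopic
#' pattern clusters, down to `tailFloor` relative abundance, so the full
#' envelope of the fully deuterated species is measured and the Fourier
#' division is well posed.  The response vector h is the pattern binned
#' onto channels by nearest-channel assignment, renormalised to unit sum.
#'
#' @param fullAdduct Ionic [ElementComposition-class] of the fully
#'   deuterated adduct (must contain at least one D).
#' @param pattern Optional precomputed [isotopePattern()] of `fullAdduct`.
#' @param window Extraction half-width in Da (default 0.5).
#' @param tailFloor Smallest response cluster abundance given a tail
#'   channel (default 1e-3).
#' @return A [TargetGrid-class] carrying the channel positions and h.
#' @export
buildTargetGrid <- function(fullAdduct, pattern = NULL, window = 0.5,
                            tailFloor = 1e-3) {
  n <- nDeuterium(fullAdduct)
  if (n < 1L)
    stop("adducted composition contains no deuterium")
  if (is.null(pattern)) pattern <- isotopePattern(fullAdduct)
  z <- ionCharge(fullAdduct)
  spacing <- .DH_MASS_DIFF / max(1L, abs(z))
  pm <- peakMass(pattern)
  pa <- peakAbundance(pattern)
  base <- pm[which.max(pa)]
  # cluster the response pattern by channel offset from its base peak
  k <- as.integer(round((pm - base) / spacing))
  if (any(k < 0L & pa > 1e-4)) {
    warning("response pattern has peaks below its base peak; ",
            "these cannot be represented by the response vector and are ",
            "dropped")
  }
  keep <- k >= 0L
  k <- k[keep]; pm <- pm[keep]; pa <- pa[keep]
  clusterAb <- vapply(0:max(k), function(kk) sum(pa[k == kk]), numeric(1))
  tailMax <- max(c(0L, which(clusterAb[-1L] >= tailFloor)))
  h <- clusterAb[seq_len(tailMax + 1L)]
  h <- h / sum(h)
  tailPos <- vapply(seq_len(tailMax), function(kk) {
    sel <- k == kk
    if (any(sel)) sum(pm[sel] * pa[sel]) / sum(pa[sel])
    else base + kk * spacing
  }, numeric(1))
  pos <- c(base - (n:1) * spacing, base, tailPos)
  if (length(pos) < 2L)
    stop("degenerate grid: the target pattern collapses to one channel")
  if (window > min(diff(pos)) / 2)
    warning("extraction window (+/-", window, " Da) exceeds half the ",
            "minimum channel spacing; adjacent windows overlap")
  new("TargetGrid", positions = pos, window = window, nStates = n,
      response = h)
}

#' Extract per-channel signals from a spectrum
#'
#' Each data point is assigned to its nearest grid channel (ties go to the
#' lower channel) provided it lies within the channel's +-window;
#' `"height"` takes the maximum assigned intensity per channel, `"area"`
#' the trapezoidal integral of the assigned points.  Channels with no data
#' are zero; a warning is raised when more than half are empty.
#'
#' @param spectrum A [MassSpectrum-class].
#' @param grid A [TargetGrid-class].
#' @param mode `"area"` (default; recommended for profile data, robust to
#'   partially resolved fine structure) or `"height"` (maximum data point;
#'   natural for centroided data).
#' @return Numeric vector x of extracted signals, one per grid channel.
#' @export
extractSignals <- function(spectrum, grid, mode = c("area", "height")) {
  mode <- match.arg(mode)
  pos <- positions(grid)
  w <- gridWindow(grid)
  mzv <- mz(spectrum)
  iv <- intensity(spectrum)
  if (!length(mzv) || min(mzv) > max(pos) + w || max(mzv) < min(pos) - w)
    stop("spectrum does not overlap the target grid")
  # nearest channel per point, lower channel on ties
  lo <- findInterval(mzv, pos)
  nearest <- pmax(lo, 1L)
  hasUpper <- lo < length(pos) & lo >= 1L
  dLow <- abs(mzv - pos[nearest])
  dUp <- rep(Inf, length(mzv))
  dUp[hasUpper] <- pos[lo[hasUpper] + 1L] - mzv[hasUpper]
  takeUpper <- (lo == 0L) | (hasUpper & dUp < dLow)
  nearest[takeUpper] <- pmin(lo[takeUpper] + 1L, length(pos))
  dist <- abs(mzv - pos[nearest])
  inWin <- dist <= w
  x <- numeric(length(pos))
  for (ch in unique(nearest[inWin])) {
    sel <- inWin & nearest == ch
    x[ch] <- if (mode == "height") {
      max(iv[sel])
    } else {
      mm <- mzv[sel]
      ii <- iv[sel]
      if (length(mm) < 2L) 0 else sum(diff(mm) * (ii[-1L] + ii[-length(ii)]) / 2)
    }
  }
  if (sum(x > 0) < length(pos) / 2)
    warning("more than half of the target channels contain no signal")
  x
}
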