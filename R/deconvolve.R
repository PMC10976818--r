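# ---------------------------------------------------------------------------
# Deconvolution of extracted signals with the isotopic response function,
# probability cutoff, and the percent-deuteration statistic
# ---------------------------------------------------------------------------

#' Deconvolve extracted signals with the response function
#'
#' Recovers the isotopologue weight vector y from extracted signals x under
#' the model `x = y * h` (discrete convolution), by element-wise division
#' of discrete Fourier transforms: `y = Re(IFFT(FFT(x) / FFT(h)))`.  The
#' response h is zero-padded to `length(x)`; the first `nStates + 1` real
#' components are returned with negative ripples clipped to zero.  The
#' result is *not* normalised (see [applyCutoff()]).
#'
#' An alternative `method = "nnls"` solves the same linear system by
#' non-negative least squares (via [pracma::lsqnonneg()]); it is the
#' recommended fallback when the Fourier division is ill conditioned.
#'
#' @param x Numeric extracted-signal vector (length >= length(h)).
#' @param h Numeric response vector, unit sum.
#' @param nStates Number of deuterium positions N; y covers states 0..N.
#' @param method `"fourier"` (the method's definition) or `"nnls"`.
#' @return A raw (unnormalised) [IsotopologueDistribution-class].
#' @export
deconvolveSignals <- function(x, h, nStates,
                              method = c("fourier", "nnls")) {
  method <- match.arg(method)
  nStates <- as.integer(nStates)
  if (length(x) < length(h))
    stop("x must be at least as long as the response vector")
  if (length(x) < nStates + 1L)
    stop("x has fewer channels than deuteration states")
  if (abs(sum(h) - 1) > 1e-6)
    stop("response vector must be normalised to unit sum")
  if (method == "fourier") {
    hp <- c(h, rep(0, length(x) - length(h)))
    H <- stats::fft(hp)
    if (min(Mod(H)) < 1e-12)
      stop("ill-conditioned response: a Fourier component of h is ",
           "numerically zero; use method = \"nnls\"")
    y <- Re(stats::fft(stats::fft(x) / H, inverse = TRUE)) / length(x)
  } else {
    A <- matrix(0, nrow = length(x), ncol = nStates + 1L)
    for (i in 0:nStates) {
      idx <- seq_along(h) + i
      A[idx, i + 1L] <- h
    }
    y <- rep(0, nStates + 1L)
    fit <- pracma::lsqnonneg(A[, seq_len(nStates + 1L), drop = FALSE], x)
    y <- fit$x
  }
  y <- y[seq_len(nStates + 1L)]
  y[y < 0] <- 0
  IsotopologueDistribution(y, cutoffIndex = 0L, normalised = FALSE)
}

#' Apply the low-state probability cutoff
#'
#' Removes low-deuterium channels that would otherwise be polluted by
#' contaminants or lower-mass adducts.  With no manual override, the
#' cutoff is placed at the lowest deuteration state c such that the two
#' consecutive states immediately below it (c-1 and c-2) each carry less
#' than 1% of the total probability while the retained states c..N carry
#' more than 10%; probabilities for the rule are evaluated on y normalised
#' over all N+1 states.  States below the cutoff are zeroed and the
#' retained states renormalised to unit sum.
#'
#' @param dist A (possibly raw) [IsotopologueDistribution-class].
#' @param count Manual cutoff as a deuterium count (overrides the rule).
#' @param mzCutoff Manual cutoff as an m/z value, mapped to the lowest
#'   channel at or above it; requires `grid`.
#' @param grid The [TargetGrid-class] (only needed for `mzCutoff`).
#' @return A normalised [IsotopologueDistribution-class] with
#'   `cutoffIndex` set.
#' @examples
#' d <- IsotopologueDistribution(c(0.002, 0.003, 0.05, 0.30, 0.40, 0.245))
#' probabilities(applyCutoff(d))   # states 0..1 removed
#' @export
applyCutoff <- function(dist, count = NULL, mzCutoff = NULL, grid = NULL) {
  y <- probabilities(dist)
  n <- length(y) - 1L
  tot <- sum(y)
  if (tot <= 0) stop("all isotopologue weights are zero")
  p <- y / tot
  if (!is.null(mzCutoff)) {
    if (is.null(grid))
      stop("an m/z cutoff requires the target grid")
    count <- which(positions(grid) >= mzCutoff)[1L] - 1L
    if (is.na(count))
      stop("m/z cutoff lies above every channel")
  }
  if (!is.null(count)) {
    cut <- as.integer(count)
    if (cut < 0L) stop("cutoff must be non-negative")
    if (cut > n) stop("manual cutoff excludes all states")
  } else {
    cut <- 0L
    if (n >= 2L) {
      for (cc in 2:n) {
        if (p[cc] < 0.01 && p[cc - 1L] < 0.01 &&
            sum(p[(cc + 1L):(n + 1L)]) > 0.10) {
          cut <- cc
          break
        }
      }
    }
  }
  if (cut > 0L) p[seq_len(cut)] <- 0
  s <- sum(p)
  if (s <= 0) stop("cutoff excludes all states")
  IsotopologueDistribution(p / s, cutoffIndex = cut, normalised = TRUE)
}

#' Percent deuteration
#'
#' The percent of the expected deuterium content,
#' `%D = (100/N) * sum_i i * y_i`, over the normalised retained
#' isotopologue probabilities.  This is relative to the N deuterium of the
#' input formula, not a bulk H/D ratio.
#'
#' @param dist A normalised [IsotopologueDistribution-class] over states
#'   0..N.
#' @return %D in `[0, 100]`.
#' @examples
#' percentDeuteration(IsotopologueDistribution(c(0.25, 0.5, 0.25),
#'                                             normalised = TRUE))  # 50
#' @export
percentDeuteration <- function(dist) {
  y <- probabilities(dist)
  n <- length(y) - 1L
  if (n < 1L) stop("N = 0: the composition has no deuterium positions")
  s <- sum(y)
  if (s <= 0) stop("empty distribution")
  y <- y / s
  100 / n * sum((0:n) * y)
}
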