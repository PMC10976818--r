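#' @import methods
NULL

# ---------------------------------------------------------------------------
# ElementComposition
# ---------------------------------------------------------------------------

#' ElementComposition: an elemental multiset with charge
#'
#' Represents a molecular (or ionic) composition as a named vector of
#' non-negative element counts plus a signed integer charge.  Deuterium is a
#' first-class pseudo-element with symbol `"D"`, counted separately from
#' `"H"`; a formula such as `"C6D14"` therefore describes the fully
#' deuterated molecule, not a bulk H/D ratio.
#'
#' @slot counts Named integer vector of element counts (all `>= 0`).
#' @slot charge Integer charge; `0` for a neutral molecule.
#' @aliases ElementComposition
#' @exportClass ElementComposition
setClass("ElementComposition",
         representation(counts = "integer", charge = "integer"),
         prototype(counts = setNames(integer(0), character(0)), charge = 0L))

setValidity("ElementComposition", function(object) {
  cts <- object@counts
  if (length(cts) && is.null(names(cts)))
    return("counts must be a named integer vector")
  if (any(cts < 0L))
    return("element counts must be non-negative")
  if (anyDuplicated(names(cts)))
    return("duplicate element symbols in counts")
  if (length(object@charge) != 1L || is.na(object@charge))
    return("charge must be a single integer")
  TRUE
})

#' Construct an ElementComposition
#'
#' @param counts Named numeric/integer vector of element counts; zero counts
#'   are dropped.  Element symbols must be present in [isotopeTable()]
#'   (`"D"` included).
#' @param charge Integer charge (default `0`).
#' @return An [ElementComposition-class] object with counts stored in Hill
#'   order (C, H, D, then alphabetical).
#' @seealso [parseFormula()] to build one from a formula string.
#' @export
ElementComposition <- function(counts = integer(0), charge = 0L) {
  counts <- counts[counts != 0]
  cts <- setNames(as.integer(round(counts)), names(counts))
  new("ElementComposition", counts = .hillOrder(cts), charge = as.integer(charge))
}

# Hill convention ordering used for canonical storage and printing
.hillOrder <- function(cts) {
  if (!length(cts)) return(setNames(integer(0), character(0)))
  first <- c("C", "H", "D")
  rest <- sort(setdiff(names(cts), first))
  ord <- c(intersect(first, names(cts)), rest)
  cts[ord]
}

#' @describeIn ElementComposition-class element counts accessor
#' @param object,x An `ElementComposition`.
#' @export
setGeneric("elementCounts", function(object) standardGeneric("elementCounts"))

#' @rdname ElementComposition-class
#' @export
setMethod("elementCounts", "ElementComposition", function(object) object@counts)

#' @rdname ElementComposition-class
#' @export
setGeneric("ionCharge", function(object) standardGeneric("ionCharge"))

#' @rdname ElementComposition-class
#' @export
setMethod("ionCharge", "ElementComposition", function(object) object@charge)

#' @rdname ElementComposition-class
#' @export
setGeneric("nDeuterium", function(object) standardGeneric("nDeuterium"))

#' @rdname ElementComposition-class
#' @export
setMethod("nDeuterium", "ElementComposition", function(object) {
  cts <- object@counts
  if ("D" %in% names(cts)) unname(cts[["D"]]) else 0L
})

setMethod("show", "ElementComposition", function(object) {
  cat("ElementComposition:", formulaString(object))
  z <- object@charge
  if (z != 0L) cat(sprintf(" (charge %+d)", z))
  cat("\n")
  invisible(object)
})

#' @param e1,e2 `ElementComposition` objects.
#' @rdname ElementComposition-class
#' @export
setMethod("==", signature("ElementComposition", "ElementComposition"),
          function(e1, e2) {
  identical(.hillOrder(e1@counts), .hillOrder(e2@counts)) &&
    e1@charge == e2@charge
})

# ---------------------------------------------------------------------------
# Adduct
# ---------------------------------------------------------------------------

#' Adduct: an electrospray ion form `[nM+X]z`
#'
#' An adduct transforms a neutral composition M into the observed ion:
#' `multiplier * M + gained - lost`, carrying `charge`.
#'
#' @slot multiplier Positive integer, the n in `[nM+X]`.
#' @slot gained,lost [ElementComposition-class] multisets added to / removed
#'   from the molecule.
#' @slot charge Non-zero integer ion charge.
#' @slot label Canonical text form, e.g. `"[M+H]+"`.
#' @aliases Adduct
#' @exportClass Adduct
setClass("Adduct",
         representation(multiplier = "integer",
                        gained = "ElementComposition",
                        lost = "ElementComposition",
                        charge = "integer",
                        label = "character"))

setValidity("Adduct", function(object) {
  if (object@multiplier < 1L) return("adduct multiplier must be >= 1")
  if (object@charge == 0L) return("an adduct must be an ion (charge != 0)")
  TRUE
})

#' Construct an Adduct
#'
#' @param multiplier Positive integer molecule multiplier.
#' @param gained,lost [ElementComposition-class] (or named count vectors)
#'   gained/lost during ionisation.
#' @param charge Non-zero integer charge.
#' @return An [Adduct-class]; its `label` is rebuilt in canonical form.
#' @seealso [parseAdduct()]
#' @export
Adduct <- function(multiplier = 1L, gained = ElementComposition(),
                   lost = ElementComposition(), charge = 1L) {
  if (!is(gained, "ElementComposition")) gained <- ElementComposition(gained)
  if (!is(lost, "ElementComposition")) lost <- ElementComposition(lost)
  ad <- new("Adduct", multiplier = as.integer(multiplier), gained = gained,
            lost = lost, charge = as.integer(charge), label = "")
  ad@label <- .adductLabel(ad)
  ad
}

#' @rdname Adduct-class
#' @param object An `Adduct`.
#' @export
setGeneric("adductLabel", function(object) standardGeneric("adductLabel"))

#' @rdname Adduct-class
#' @export
setMethod("adductLabel", "Adduct", function(object) object@label)

#' @rdname Adduct-class
#' @export
setMethod("ionCharge", "Adduct", function(object) object@charge)

setMethod("show", "Adduct", function(object) {
  cat("Adduct:", object@label, "\n")
  invisible(object)
})

#' @rdname Adduct-class
#' @export
setMethod("==", signature("Adduct", "Adduct"), function(e1, e2) {
  e1@multiplier == e2@multiplier && e1@charge == e2@charge &&
    e1@gained == e2@gained && e1@lost == e2@lost
})

# ---------------------------------------------------------------------------
# IsotopicPattern
# ---------------------------------------------------------------------------

#' IsotopicPattern: exact masses and relative abundances
#'
#' The isotopic spectrum of a composition: peaks at exact masses (m/z for
#' ions) with abundances normalised to unit sum.  The pattern of the fully
#' deuterated adduct serves as the response function *h* during
#' deconvolution.
#'
#' @slot mass Ascending numeric vector of exact masses (Da, or m/z for a
#'   charged provenance composition).
#' @slot abundance Relative abundances, summing to 1.
#' @slot composition The [ElementComposition-class] described (may be empty
#'   for derived patterns).
#' @aliases IsotopicPattern
#' @exportClass IsotopicPattern
setClass("IsotopicPattern",
         representation(mass = "numeric", abundance = "numeric",
                        composition = "ElementComposition"),
         prototype(mass = numeric(0), abundance = numeric(0),
                   composition = new("ElementComposition")))

setValidity("IsotopicPattern", function(object) {
  if (length(object@mass) != length(object@abundance))
    return("mass and abundance lengths differ")
  if (is.unsorted(object@mass, strictly = TRUE) && length(object@mass) > 1L)
    return("masses must be strictly increasing")
  if (any(object@abundance < 0))
    return("abundances must be non-negative")
  if (length(object@abundance) &&
      abs(sum(object@abundance) - 1) > 1e-9)
    return("abundances must sum to 1 within 1e-9")
  TRUE
})

#' @rdname IsotopicPattern-class
#' @param object An `IsotopicPattern`.
#' @export
setGeneric("peakMass", function(object) standardGeneric("peakMass"))

#' @rdname IsotopicPattern-class
#' @export
setMethod("peakMass", "IsotopicPattern", function(object) object@mass)

#' @rdname IsotopicPattern-class
#' @export
setGeneric("peakAbundance", function(object) standardGeneric("peakAbundance"))

#' @rdname IsotopicPattern-class
#' @export
setMethod("peakAbundance", "IsotopicPattern", function(object) object@abundance)

setMethod("show", "IsotopicPattern", function(object) {
  cat("IsotopicPattern with", length(object@mass), "peaks\n")
  n <- min(length(object@mass), 8L)
  if (n) {
    o <- order(object@abundance, decreasing = TRUE)[seq_len(n)]
    o <- sort(o)
    df <- data.frame(mass = round(object@mass[o], 5),
                     abundance = signif(object@abundance[o], 4))
    print(df, row.names = FALSE)
    if (length(object@mass) > n) cat("  ...\n")
  }
  invisible(object)
})

# ---------------------------------------------------------------------------
# MassSpectrum
# ---------------------------------------------------------------------------

#' MassSpectrum: paired m/z and intensity arrays
#'
#' @slot mz Strictly increasing numeric vector of m/z values (Da).
#' @slot intensity Non-negative numeric vector, same length as `mz`.
#' @slot mode `"profile"` (continuously sampled peak shapes) or
#'   `"centroid"` (one point per detected peak).
#' @aliases MassSpectrum
#' @exportClass MassSpectrum
setClass("MassSpectrum",
         representation(mz = "numeric", intensity = "numeric",
                        mode = "character"),
         prototype(mz = numeric(0), intensity = numeric(0), mode = "profile"))

setValidity("MassSpectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (length(object@mz) > 1L && is.unsorted(object@mz, strictly = TRUE))
    return("mz must be strictly increasing")
  if (any(object@intensity < 0))
    return("intensities must be non-negative")
  if (!object@mode %in% c("profile", "centroid"))
    return("mode must be 'profile' or 'centroid'")
  TRUE
})

#' Construct a MassSpectrum
#'
#' Duplicated m/z values have their intensities summed; unsorted input is
#' sorted.
#'
#' @param mz,intensity Equal-length numeric vectors.
#' @param mode `"profile"` or `"centroid"`.
#' @return A [MassSpectrum-class].
#' @export
MassSpectrum <- function(mz, intensity, mode = "profile") {
  stopifnot(length(mz) == length(intensity))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    s <- rowsum(intensity, group = mz)
    mz <- as.numeric(rownames(s))
    intensity <- as.numeric(s)
  }
  new("MassSpectrum", mz = mz, intensity = intensity, mode = mode)
}

#' @rdname MassSpectrum-class
#' @param object A `MassSpectrum`.
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname MassSpectrum-class
#' @export
setMethod("mz", "MassSpectrum", function(object) object@mz)

#' @rdname MassSpectrum-class
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname MassSpectrum-class
#' @export
setMethod("intensity", "MassSpectrum", function(object) object@intensity)

#' @rdname MassSpectrum-class
#' @export
setGeneric("spectrumMode", function(object) standardGeneric("spectrumMode"))

#' @rdname MassSpectrum-class
#' @export
setMethod("spectrumMode", "MassSpectrum", function(object) object@mode)

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum (%s): %d points", object@mode,
              length(object@mz)))
  if (length(object@mz))
    cat(sprintf(", m/z %.4f-%.4f", min(object@mz), max(object@mz)))
  cat("\n")
  invisible(object)
})

# ---------------------------------------------------------------------------
# TargetGrid
# ---------------------------------------------------------------------------

#' TargetGrid: deconvolution channels and the response vector
#'
#' Channel positions span the base peak of the fully protiated isotopologue
#' (channel 0) through the tail of the fully deuterated species' isotopic
#' pattern.  The response vector `h` is that pattern binned onto the
#' channels, starting at its base-peak channel.
#'
#' @slot positions Strictly increasing channel m/z positions.
#' @slot window Half-width (Da) of each extraction window.
#' @slot nStates Number of deuterium positions N; channels `0..N` are the
#'   isotopologue base peaks, later channels are response tail.
#' @slot response Numeric response vector `h`, unit sum.
#' @aliases TargetGrid
#' @exportClass TargetGrid
setClass("TargetGrid",
         representation(positions = "numeric", window = "numeric",
                        nStates = "integer", response = "numeric"))

setValidity("TargetGrid", function(object) {
  if (length(object@positions) > 1L &&
      is.unsorted(object@positions, strictly = TRUE))
    return("channel positions must be strictly increasing")
  if (object@window <= 0) return("window must be positive")
  if (length(object@positions) != object@nStates + length(object@response))
    return("positions length must equal nStates + length(response)")
  if (length(object@response) &&
      abs(sum(object@response) - 1) > 1e-6)
    return("response vector must sum to 1 within 1e-6")
  TRUE
})

#' @rdname TargetGrid-class
#' @param object A `TargetGrid`.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname TargetGrid-class
#' @export
setMethod("positions", "TargetGrid", function(object) object@positions)

#' @rdname TargetGrid-class
#' @export
setGeneric("gridWindow", function(object) standardGeneric("gridWindow"))

#' @rdname TargetGrid-class
#' @export
setMethod("gridWindow", "TargetGrid", function(object) object@window)

#' @rdname TargetGrid-class
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname TargetGrid-class
#' @export
setMethod("nStates", "TargetGrid", function(object) object@nStates)

#' @rdname TargetGrid-class
#' @export
setGeneric("responseVector", function(object) standardGeneric("responseVector"))

#' @rdname TargetGrid-class
#' @export
setMethod("responseVector", "TargetGrid", function(object) object@response)

setMethod("show", "TargetGrid", function(object) {
  cat(sprintf(
    "TargetGrid: %d channels (states 0..%d + %d tail), window +/-%.3g Da\n",
    length(object@positions), object@nStates,
    length(object@response) - 1L, object@window))
  invisible(object)
})

# ---------------------------------------------------------------------------
# IsotopologueDistribution
# ---------------------------------------------------------------------------

#' IsotopologueDistribution: probabilities of deuteration states 0..N
#'
#' @slot probability Numeric vector of length N+1; entry `i+1` is the
#'   probability (or raw deconvolved weight) of the state with `i`
#'   deuterium.
#' @slot cutoffIndex Lowest retained deuteration state (0 = none removed).
#' @slot normalised Logical; `TRUE` once retained states sum to 1.
#' @aliases IsotopologueDistribution
#' @exportClass IsotopologueDistribution
setClass("IsotopologueDistribution",
         representation(probability = "numeric", cutoffIndex = "integer",
                        normalised = "logical"),
         prototype(probability = numeric(0), cutoffIndex = 0L,
                   normalised = FALSE))

setValidity("IsotopologueDistribution", function(object) {
  p <- object@probability
  if (any(p < 0)) return("probabilities must be non-negative")
  if (object@cutoffIndex < 0L ||
      (length(p) && object@cutoffIndex > length(p) - 1L))
    return("cutoffIndex out of range")
  if (isTRUE(object@normalised) && length(p) &&
      abs(sum(p) - 1) > 1e-6)
    return("normalised distribution must sum to 1")
  TRUE
})

#' Construct an IsotopologueDistribution
#'
#' @param probability Non-negative numeric vector over states `0..N`.
#' @param cutoffIndex Lowest retained state (states below are zero).
#' @param normalised Whether `probability` sums to 1 over retained states.
#' @return An [IsotopologueDistribution-class].
#' @export
IsotopologueDistribution <- function(probability, cutoffIndex = 0L,
                                     normalised = FALSE) {
  new("IsotopologueDistribution", probability = as.numeric(probability),
      cutoffIndex = as.integer(cutoffIndex), normalised = normalised)
}

#' @rdname IsotopologueDistribution-class
#' @param object An `IsotopologueDistribution`.
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

#' @rdname IsotopologueDistribution-class
#' @export
setMethod("probabilities", "IsotopologueDistribution",
          function(object) object@probability)

#' @rdname IsotopologueDistribution-class
#' @export
setGeneric("cutoffIndex", function(object) standardGeneric("cutoffIndex"))

#' @rdname IsotopologueDistribution-class
#' @export
setMethod("cutoffIndex", "IsotopologueDistribution",
          function(object) object@cutoffIndex)

setMethod("show", "IsotopologueDistribution", function(object) {
  n <- length(object@probability) - 1L
  cat(sprintf("IsotopologueDistribution over D0..D%d (%s)", n,
              if (object@normalised) "normalised" else "raw"))
  if (object@cutoffIndex > 0L)
    cat(sprintf(", cutoff at D%d", object@cutoffIndex))
  cat("\n")
  invisible(object)
})

# ---------------------------------------------------------------------------
# DeuterationResult
# ---------------------------------------------------------------------------

#' DeuterationResult: the outcome of the deuteration pipeline
#'
#' @slot percentD Percent of the expected deuterium content, in `[0, 100]`.
#' @slot distribution The retained, normalised
#'   [IsotopologueDistribution-class].
#' @slot adduct The [Adduct-class] used.
#' @slot autoAdduct `TRUE` when the adduct was auto-selected (verify it!).
#' @slot offset m/z offset (Da) applied during realignment (0 if none).
#' @slot mode Extraction mode used, `"area"` or `"height"`.
#' @slot deconvolved `FALSE` when raw extracted signals were used.
#' @slot grid The [TargetGrid-class] used for extraction.
#' @slot signals Extracted signal vector x (one per grid channel).
#' @slot spectrum The (possibly realigned) [MassSpectrum-class].
#' @slot formula The fully deuterated neutral [ElementComposition-class].
#' @aliases DeuterationResult
#' @exportClass DeuterationResult
setClass("DeuterationResult",
         representation(percentD = "numeric",
                        distribution = "IsotopologueDistribution",
                        adduct = "Adduct",
                        autoAdduct = "logical",
                        offset = "numeric",
                        mode = "character",
                        deconvolved = "logical",
                        grid = "TargetGrid",
                        signals = "numeric",
                        spectrum = "MassSpectrum",
                        formula = "ElementComposition"))

setValidity("DeuterationResult", function(object) {
  if (object@percentD < 0 || object@percentD > 100)
    return("percentD must lie in [0, 100]")
  TRUE
})

#' @rdname DeuterationResult-class
#' @param object A `DeuterationResult`.
#' @export
setGeneric("percentD", function(object) standardGeneric("percentD"))

#' @rdname DeuterationResult-class
#' @export
setMethod("percentD", "DeuterationResult", function(object) object@percentD)

#' @rdname DeuterationResult-class
#' @export
setGeneric("distribution", function(object) standardGeneric("distribution"))

#' @rdname DeuterationResult-class
#' @export
setMethod("distribution", "DeuterationResult",
          function(object) object@distribution)

#' @rdname DeuterationResult-class
#' @export
setGeneric("resultAdduct", function(object) standardGeneric("resultAdduct"))

#' @rdname DeuterationResult-class
#' @export
setMethod("resultAdduct", "DeuterationResult", function(object) object@adduct)

#' @rdname DeuterationResult-class
#' @export
setGeneric("appliedOffset", function(object) standardGeneric("appliedOffset"))

#' @rdname DeuterationResult-class
#' @export
setMethod("appliedOffset", "DeuterationResult", function(object) object@offset)

setMethod("show", "DeuterationResult", function(object) {
  cat("DeuterationResult\n")
  cat(sprintf("  Formula     : %s (N = %d D)\n",
              formulaString(object@formula), nDeuterium(object@formula)))
  cat(sprintf("  Adduct      : %s%s\n", adductLabel(object@adduct),
              if (object@autoAdduct) " (auto-selected, verify)" else ""))
  cat(sprintf("  m/z offset  : %+.3f Da\n", object@offset))
  cat(sprintf("  Extraction  : %s%s\n", object@mode,
              if (object@deconvolved) ", deconvolved" else ", raw signals"))
  co <- cutoffIndex(object@distribution)
  if (co > 0L) cat(sprintf("  Cutoff      : D%d\n", co))
  cat(sprintf("  Deuteration : %.2f %%\n", object@percentD))
  invisible(object)
})
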