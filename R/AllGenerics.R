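#' @include AllClasses.R
NULL

#' Accessors for acquisition profiles and cohorts
#'
#' Small generic accessors so user code never touches slots directly:
#' \code{nTransients}, \code{trS}, \code{nPoints}, \code{larmorMhz} on a
#' profile or cohort; \code{ppm}, \code{conditions}, \code{acqProfile},
#' \code{subjectIds}, \code{nSubjects}, \code{tissueFractions},
#' \code{groundTruth} and \code{spectra} on a cohort.
#'
#' @param x an [AcquisitionProfile-class] or [MegaCohort-class].
#' @param subject subject id (for \code{spectra}).
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTransients", function(x) standardGeneric("nTransients"))
#' @rdname accessors
#' @export
setGeneric("trS", function(x) standardGeneric("trS"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("larmorMhz", function(x) standardGeneric("larmorMhz"))
#' @rdname accessors
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("acqProfile", function(x) standardGeneric("acqProfile"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("tissueFractions", function(x) standardGeneric("tissueFractions"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("spectra", function(x, subject) standardGeneric("spectra"))

#' @rdname accessors
setMethod("nTransients", "AcquisitionProfile", function(x) x@nTransients)
#' @rdname accessors
setMethod("trS", "AcquisitionProfile", function(x) x@trS)
#' @rdname accessors
setMethod("nPoints", "AcquisitionProfile", function(x) x@nPoints)
#' @rdname accessors
setMethod("larmorMhz", "AcquisitionProfile", function(x) x@larmorMhz)

#' @rdname accessors
setMethod("nTransients", "MegaCohort", function(x) x@profile@nTransients)
#' @rdname accessors
setMethod("trS", "MegaCohort", function(x) x@profile@trS)
#' @rdname accessors
setMethod("nPoints", "MegaCohort", function(x) x@profile@nPoints)
#' @rdname accessors
setMethod("larmorMhz", "MegaCohort", function(x) x@profile@larmorMhz)
#' @rdname accessors
setMethod("ppm", "MegaCohort", function(x) x@ppm)
#' @rdname accessors
setMethod("conditions", "MegaCohort", function(x) x@conditions)
#' @rdname accessors
setMethod("acqProfile", "MegaCohort", function(x) x@profile)
#' @rdname accessors
setMethod("subjectIds", "MegaCohort", function(x) names(x@spectra))
#' @rdname accessors
setMethod("nSubjects", "MegaCohort", function(x) length(x@spectra))
#' @rdname accessors
setMethod("tissueFractions", "MegaCohort", function(x) x@tissue)
#' @rdname accessors
setMethod("groundTruth", "MegaCohort", function(x) x@truth)
#' @rdname accessors
setMethod("spectra", "MegaCohort", function(x, subject) {
  if (!subject %in% names(x@spectra))
    stop("unknown subject: ", subject)
  x@spectra[[subject]]
})

setMethod("show", "AcquisitionProfile", function(object) {
  cat(sprintf(
    "AcquisitionProfile '%s': %d transients, TR %.1f s, %d points, %g Hz sweep, %.1f MHz%s\n",
    object@name, object@nTransients, object@trS, object@nPoints,
    object@sweepHz, object@larmorMhz,
    if (object@residualWater) ", residual water" else ""))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  cat(sprintf("  baseline ratios (tCr): GABA+ %.3f, Glx %.3f, tNAA %.3f\n",
              object@baselineRatio[["gaba"]], object@baselineRatio[["glx"]],
              object@baselineRatio[["tnaa"]]))
  cat(sprintf("  drift totals: GABA+ %+.3f, Glx %+.3f, tNAA %+.3f\n",
              object@driftTotal[["gaba"]], object@driftTotal[["glx"]],
              object@driftTotal[["tnaa"]]))
  cat(sprintf("  latent: SD %.3f, AR %.2f; coupling kappa %.2f at %d bins; innovation SD %.3f\n",
              object@latentSd, object@latentAr, object@couplingKappa,
              object@couplingDelayBins, object@innovationSd))
  cat(sprintf("  instrument: noise SD %.3f, jitter %.4f ppm / %.1f deg, drift %.4f ppm, edit eff %.2f\n",
              object@noiseSd, object@freqJitterPpm, object@phaseJitterDeg,
              object@scannerDriftPpm, object@editEfficiency))
})

setMethod("show", "MegaCohort", function(object) {
  cat(sprintf("MegaCohort: %d subjects x %d transients x %d points ('%s' profile)\n",
              length(object@spectra), object@profile@nTransients,
              object@profile@nPoints, object@profile@name))
  cat(sprintf("  ppm %.2f .. %.2f; %s; %s\n",
              max(object@ppm), min(object@ppm),
              if (is.null(object@truth)) "no ground truth" else "synthetic (ground truth attached)",
              if (isTRUE(object@processing$corrected)) "preprocessed" else "raw"))
})

setMethod("show", "PeakFit", function(object) {
  cat(sprintf("PeakFit [%s]%s: area %.5g, FWHM %.2f Hz, fit error %.2f%%\n",
              object@model, if (object@ok) "" else " (FLAGGED)",
              object@area, object@fwhmHz, object@fitErrorPct))
})

setMethod("show", "GroupTrace", function(object) {
  cat(sprintf("GroupTrace [%s:%s]: %d bins of %d transients (%.0f s each), normalization '%s'\n",
              object@metabolite, object@reference, object@nBins,
              object@binSizeTransients,
              if (object@nBins > 1) object@timesS[2] - object@timesS[1] else NA,
              object@normalized))
})

setMethod("show", "ClusterTestResult", function(object) {
  ns <- sum(object@clusters$significant)
  cat(sprintf("ClusterTestResult: %d windows, %d cluster(s), %d significant (nPerm %d, alpha %.2f)\n",
              length(object@tMap), nrow(object@clusters), ns,
              object@nPerm, object@alpha))
  if (nrow(object@clusters)) print(object@clusters)
})

setMethod("show", "CrossCorrResult", function(object) {
  cat(sprintf("CrossCorrResult: %d lags (%+.0f .. %+.0f s, >= %d overlapping bins)\n",
              length(object@lagsS), min(object@lagsS), max(object@lagsS),
              object@minOverlap))
  if (nrow(object@clusters)) {
    cat(sprintf("  %d significant cluster(s):\n",
                sum(object@clusters$significant)))
    print(object@clusters)
  }
})
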