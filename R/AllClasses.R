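#' @import methods
NULL

#' Acquisition profile for a MEGA-PRESS time series
#'
#' Describes one edited-MRS acquisition: the number of ON/OFF transients, the
#' repetition time, the digitisation (points and sweep width) and the field
#' strength (proton frequency, which fixes the Hz-per-ppm conversion).
#'
#' @slot name profile label, e.g. \code{"vc"} or \code{"pcc"}.
#' @slot nTransients total number of transients (even; conditions alternate).
#' @slot trS repetition time in seconds.
#' @slot nPoints spectral points per transient.
#' @slot sweepHz spectral width in Hz.
#' @slot larmorMhz proton frequency in MHz (Hz per ppm).
#' @slot residualWater logical; include a broad residual-water component at
#'   4.7 ppm in simulated spectra.
#'
#' @seealso [vcProfile()], [pccProfile()]
#' @export
setClass("AcquisitionProfile",
  representation(
    name = "character",
    nTransients = "integer",
    trS = "numeric",
    nPoints = "integer",
    sweepHz = "numeric",
    larmorMhz = "numeric",
    residualWater = "logical"
  )
)

setValidity("AcquisitionProfile", function(object) {
  msg <- character()
  if (object@nTransients < 2L || object@nTransients %% 2L != 0L)
    msg <- c(msg, "nTransients must be even and >= 2 (alternating ON/OFF)")
  if (object@nPoints < 512L)
    msg <- c(msg, "nPoints must be >= 512")
  if (object@trS <= 0) msg <- c(msg, "trS must be > 0")
  if (object@sweepHz <= 0) msg <- c(msg, "sweepHz must be > 0")
  if (object@larmorMhz <= 0) msg <- c(msg, "larmorMhz must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic MEGA-PRESS cohort
#'
#' Holds every parameter of the generative model: per-metabolite baseline
#' ratios (to tCr) and their across-subject spread, fractional linear
#' concentration drifts over the acquisition, the cohort-shared latent
#' fluctuation process with its delayed GABA-to-Glx anti-coupling, and the
#' instrument model (noise, frequency/phase jitter, scanner drift, editing
#' efficiency).
#'
#' @slot baselineRatio named numeric; mean GABA+:tCr, Glx:tCr, tNAA:tCr.
#' @slot baselineSd named numeric; across-subject SD of the same ratios.
#' @slot driftTotal named numeric; fractional endpoint-to-endpoint linear
#'   change per metabolite (|value| < 1).
#' @slot latentSd stationary SD of the cohort-shared AR(1) GABA fluctuation,
#'   in fractional (relative concentration) units per high-resolution bin.
#' @slot latentAr AR(1) coefficient of the GABA latent.
#' @slot couplingKappa strength of the delayed GABA-to-Glx anti-coupling.
#' @slot couplingDelayBins delay of the anti-coupling in high-resolution bins.
#' @slot innovationSd SD of the independent Glx latent innovation.
#' @slot noiseSd complex noise SD per spectral point per transient.
#' @slot freqJitterPpm per-transient frequency jitter SD (ppm).
#' @slot scannerDriftPpm total linear frequency drift over the acquisition.
#' @slot phaseJitterDeg per-transient zero-order phase SD (degrees).
#' @slot editEfficiency scale applied to the edited difference signature.
#' @slot naaEditRatio edited (negative) tNAA area as a fraction of tCr area.
#' @slot tissueMean named numeric; mean GM/WM/CSF voxel fractions.
#' @slot tissueConcentration Dirichlet concentration for tissue draws.
#'
#' @seealso [defaultGroundTruth()], [nullGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    baselineRatio = "numeric",
    baselineSd = "numeric",
    driftTotal = "numeric",
    latentSd = "numeric",
    latentAr = "numeric",
    couplingKappa = "numeric",
    couplingDelayBins = "integer",
    innovationSd = "numeric",
    noiseSd = "numeric",
    freqJitterPpm = "numeric",
    scannerDriftPpm = "numeric",
    phaseJitterDeg = "numeric",
    editEfficiency = "numeric",
    naaEditRatio = "numeric",
    tissueMean = "numeric",
    tissueConcentration = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  mets <- c("gaba", "glx", "tnaa")
  for (s in c("baselineRatio", "baselineSd", "driftTotal")) {
    v <- slot(object, s)
    if (!all(mets %in% names(v)))
      msg <- c(msg, sprintf("%s must be named with %s", s,
                            paste(mets, collapse = ", ")))
  }
  if (any(object@baselineSd < 0) || object@latentSd < 0 ||
      object@innovationSd < 0 || object@noiseSd < 0 ||
      object@freqJitterPpm < 0 || object@phaseJitterDeg < 0)
    msg <- c(msg, "all SDs must be >= 0")
  if (any(abs(object@driftTotal) >= 1))
    msg <- c(msg, "|driftTotal| must be < 1")
  if (object@couplingDelayBins < 0L)
    msg <- c(msg, "couplingDelayBins must be >= 0")
  if (abs(object@latentAr) >= 1)
    msg <- c(msg, "|latentAr| must be < 1 (stationary AR(1))")
  tm <- object@tissueMean
  if (!all(c("gm", "wm", "csf") %in% names(tm)) ||
      abs(sum(tm) - 1) > 1e-8 || any(tm < 0) || tm[["csf"]] >= 1)
    msg <- c(msg, "tissueMean must be gm/wm/csf proportions summing to 1")
  if (length(msg)) msg else TRUE
})

#' Cohort of MEGA-PRESS transients
#'
#' The central data container: one complex frequency-domain spectrum per
#' transient per subject, the shared decreasing ppm axis, the acquisition
#' profile, per-subject tissue fractions and (for synthetic cohorts) the
#' generative ground truth.  Preprocessing (\code{\link{preprocessCohort}})
#' returns a cohort whose spectra are frequency/phase corrected and whose
#' \code{processing} slot carries the per-transient reference fits and
#' retention masks.
#'
#' @slot spectra named list of complex matrices, \code{nPoints x nTransients},
#'   one per subject (columns in acquisition order).
#' @slot conditions character vector \code{"OFF"}/\code{"ON"}, length
#'   \code{nTransients}, alternating OFF-first.
#' @slot ppm numeric axis in ppm, strictly decreasing, length \code{nPoints}.
#' @slot profile the [AcquisitionProfile-class].
#' @slot tissue data.frame with columns subject, gm, wm, csf.
#' @slot truth the generating [GroundTruth-class], or NULL for real data.
#' @slot processing list; populated by [preprocessCohort()] with elements
#'   \code{refFits} (per-subject data.frame) and \code{retained}
#'   (per-subject logical vector), plus \code{corrected = TRUE}.
#'
#' @export
setClass("MegaCohort",
  representation(
    spectra = "list",
    conditions = "character",
    ppm = "numeric",
    profile = "AcquisitionProfile",
    tissue = "data.frame",
    truth = "ANY",
    processing = "list"
  )
)

setValidity("MegaCohort", function(object) {
  msg <- character()
  np <- object@profile@nPoints
  nt <- object@profile@nTransients
  if (length(object@ppm) != np)
    msg <- c(msg, "ppm axis length must equal nPoints")
  if (any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing")
  if (length(object@conditions) != nt)
    msg <- c(msg, "conditions length must equal nTransients")
  if (!all(object@conditions %in% c("OFF", "ON")))
    msg <- c(msg, "conditions must be 'OFF' or 'ON'")
  if (length(object@conditions) >= 2 &&
      !all(object@conditions == rep(c("OFF", "ON"), length.out = nt)))
    msg <- c(msg, "conditions must alternate OFF, ON, OFF, ON, ...")
  bad <- vapply(object@spectra, function(m) {
    !is.complex(m) || nrow(m) != np || ncol(m) != nt
  }, logical(1))
  if (any(bad))
    msg <- c(msg, "each subject's spectra must be a complex nPoints x nTransients matrix")
  if (is.null(names(object@spectra)) || anyDuplicated(names(object@spectra)))
    msg <- c(msg, "spectra must be a named list with unique subject ids")
  if (nrow(object@tissue) &&
      !all(c("subject", "gm", "wm", "csf") %in% names(object@tissue)))
    msg <- c(msg, "tissue must have columns subject, gm, wm, csf")
  if (length(msg)) msg else TRUE
})

#' Single peak-model fit
#'
#' Result of fitting one line-shape model (plus linear baseline) to a spectral
#' window: the fitted parameters, the analytic area under the model peak(s),
#' the model FWHM in Hz and the normalised fit error.
#'
#' @slot model one of \code{"lorentzian"}, \code{"gaussian"},
#'   \code{"double_gaussian"}, \code{"inverse_lorentzian"}.
#' @slot params named numeric vector of fitted parameters (amplitudes,
#'   centers in ppm, width in ppm, baseline slope/intercept).
#' @slot area analytic area under the fitted peak(s); for the inverse
#'   Lorentzian this is the positive magnitude of the negative lobe.
#' @slot fwhmHz model FWHM converted to Hz.
#' @slot fitErrorPct residual SD divided by fitted amplitude, in percent.
#' @slot ok logical convergence/sanity flag.
#'
#' @export
setClass("PeakFit",
  representation(
    model = "character",
    params = "numeric",
    area = "numeric",
    fwhmHz = "numeric",
    fitErrorPct = "numeric",
    ok = "logical"
  )
)

setValidity("PeakFit", function(object) {
  msg <- character()
  if (!object@model %in% c("lorentzian", "gaussian", "double_gaussian",
                           "inverse_lorentzian"))
    msg <- c(msg, "unknown model")
  if (object@ok && (!is.finite(object@area) || object@fwhmHz <= 0))
    msg <- c(msg, "retained fits need finite area and positive FWHM")
  if (is.finite(object@fitErrorPct) && object@fitErrorPct < 0)
    msg <- c(msg, "fitErrorPct must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cluster-based permutation test result
#'
#' Per-window (or per-lag) t statistics, the maximal same-sign suprathreshold
#' clusters scored by their summed t values, the permutation-null critical
#' masses for positive and negative clusters (the 1 - alpha/2 percentile of
#' each side's maximal-mass null), and per-cluster permutation p-values.
#'
#' @slot tMap numeric t statistic per window.
#' @slot timesS window-centre times in seconds.
#' @slot clusters data.frame with columns start, end, sign, mass, p,
#'   significant (start/end are 1-based inclusive window indices).
#' @slot nullPos,nullNeg permutation critical values (1 - alpha/2 percentile)
#'   of the maximal positive and |negative| cluster masses.
#' @slot significantMask logical per window, TRUE inside significant clusters.
#' @slot nPerm,alpha test configuration.
#'
#' @export
setClass("ClusterTestResult",
  representation(
    tMap = "numeric",
    timesS = "numeric",
    clusters = "data.frame",
    nullPos = "numeric",
    nullNeg = "numeric",
    significantMask = "logical",
    nPerm = "integer",
    alpha = "numeric"
  )
)

#' High-resolution group metabolite trace
#'
#' One metabolite ratio per across-subject bin: transients from all retained
#' subjects falling in the same acquisition-time bin are pooled, averaged per
#' condition, and quantified, yielding a single cohort-level trace at the
#' bin resolution (12 s at the default bin sizes).
#'
#' @slot metabolite quantified metabolite.
#' @slot reference internal reference metabolite.
#' @slot timesS bin-centre times in seconds, strictly increasing.
#' @slot values ratio (or normalized percent) per bin.
#' @slot nBins number of full bins.
#' @slot binSizeTransients transients per bin.
#' @slot normalized \code{"none"}, \code{"percent_of_mean"} or
#'   \code{"change_from_first"}.
#'
#' @export
setClass("GroupTrace",
  representation(
    metabolite = "character",
    reference = "character",
    timesS = "numeric",
    values = "numeric",
    nBins = "integer",
    binSizeTransients = "integer",
    normalized = "character"
  )
)

setValidity("GroupTrace", function(object) {
  msg <- character()
  if (length(object@values) != object@nBins)
    msg <- c(msg, "values length must equal nBins")
  if (length(object@timesS) != object@nBins || any(diff(object@timesS) <= 0))
    msg <- c(msg, "timesS must be strictly increasing, one per bin")
  if (length(msg)) msg else TRUE
})

#' Lag-constrained cross-correlation result
#'
#' Pearson correlations between two high-resolution metabolite traces at
#' every signed lag retaining at least \code{minOverlap} overlapping bins.
#' The sign convention follows the acquisition-time difference: negative lags
#' mean the first trace (GABA+) was acquired earlier and predicts the second
#' (Glx).
#'
#' @slot lagsS signed lags in seconds (negative: trace A precedes trace B).
#' @slot r Pearson correlation per lag.
#' @slot n overlapping bins per lag.
#' @slot ciLo,ciHi Fisher-z 95\% confidence limits per lag.
#' @slot t t statistic per lag, \code{r * sqrt((n-2)/(1-r^2))}.
#' @slot minOverlap minimum overlap rule used.
#' @slot dtS bin resolution in seconds.
#' @slot clusters data.frame of same-sign suprathreshold lag clusters
#'   (populated by [crossCorrClusterTest()]).
#' @slot significantMask logical per lag (populated by the cluster test).
#' @slot traceA,traceB the input traces (kept for the permutation test).
#'
#' @export
setClass("CrossCorrResult",
  representation(
    lagsS = "numeric",
    r = "numeric",
    n = "integer",
    ciLo = "numeric",
    ciHi = "numeric",
    t = "numeric",
    minOverlap = "integer",
    dtS = "numeric",
    clusters = "data.frame",
    significantMask = "logical",
    traceA = "numeric",
    traceB = "numeric"
  )
)

setValidity("CrossCorrResult", function(object) {
  msg <- character()
  if (any(abs(object@r) > 1 + 1e-12)) msg <- c(msg, "r must lie in [-1, 1]")
  if (any(object@n < object@minOverlap))
    msg <- c(msg, "all lags must retain at least minOverlap points")
  if (length(msg)) msg else TRUE
})
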