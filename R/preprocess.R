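#' @include AllClasses.R utils.R
NULL

# Batch creatine reference fit over the columns of a complex spectrum matrix.
# Returns a data.frame with one row per column.
.fitReferenceBatch <- function(specMat, ppmAxis, larmorMhz,
                               windowPpm = c(2.4, 3.6)) {
  idx <- .ppmWindowIdx(ppmAxis, windowPpm)
  x <- ppmAxis[idx]
  RE <- t(Re(specMat[idx, , drop = FALSE]))
  IM <- t(Im(specMat[idx, , drop = FALSE]))
  raw <- .cpp_fit_ref(RE, IM, x, 0.033)
  gamma <- raw[, 3]
  halfwin <- (max(windowPpm) - min(windowPpm)) / 2
  ok <- raw[, 6] > 0 & raw[, 1] > 0 & gamma > 1e-4 & gamma < halfwin &
    raw[, 2] > min(windowPpm) & raw[, 2] < max(windowPpm)
  data.frame(freqPpm = raw[, 2],
             phaseDeg = raw[, 4] * 180 / pi,
             area = lorentzianArea(raw[, 1], gamma),
             fwhmHz = lorentzianFwhm(gamma) * larmorMhz,
             residSd = raw[, 5],
             ok = ok)
}

#' Fit the creatine reference peak of one transient
#'
#' Fits a complex Lorentzian (absorption + dispersion, free zero-order phase)
#' plus a complex linear baseline to the 2.4-3.6 ppm window of a single
#' transient.  The fitted frequency, phase, area and FWHM of the Cr peak at
#' 3.0 ppm drive transient-level outlier rejection and frequency/phase
#' correction.  Non-convergent or degenerate fits are returned with
#' \code{ok = FALSE} rather than an error, and are excluded downstream.
#'
#' @param spec complex spectrum (one transient).
#' @param ppm the decreasing ppm axis.
#' @param larmorMhz proton frequency in MHz (Hz-per-ppm conversion).
#' @param windowPpm fit window, default 2.4-3.6 ppm.
#' @return one-row data.frame: freqPpm, phaseDeg, area, fwhmHz, residSd, ok.
#' @examples
#' prof <- vcProfile()
#' areas <- c(tcr = 0.33, tnaa = 0.46, gaba = 0.04, glx = 0.05, naaedit = 0.15)
#' sp <- synthesizeTransient(prof, areas, "OFF")
#' fitReferencePeak(sp, ppmAxis(prof), larmorMhz(prof))
#' @export
fitReferencePeak <- function(spec, ppm, larmorMhz, windowPpm = c(2.4, 3.6)) {
  if (min(ppm) > min(windowPpm) || max(ppm) < max(windowPpm))
    stop("spectrum does not cover the ", min(windowPpm), "-", max(windowPpm),
         " ppm reference window")
  .fitReferenceBatch(matrix(spec, ncol = 1), ppm, larmorMhz, windowPpm)
}

#' Reject outlier transients from reference-fit parameters
#'
#' A transient is dropped when the z-score of any of its four reference-fit
#' parameters (frequency, phase, area, FWHM) exceeds \code{k} in magnitude,
#' where mean and SD are computed over that subject's own converged fits.  A
#' parameter with zero spread is excluded from the criterion.  Fits flagged
#' \code{ok = FALSE} are always dropped.
#'
#' @param fits data.frame from the reference fit (one subject), with columns
#'   freqPpm, phaseDeg, area, fwhmHz, ok.
#' @param k z-score threshold (default 3, the usual 3 SD rule).
#' @return logical retention mask, one element per transient.
#' @export
rejectOutlierTransients <- function(fits, k = 3) {
  if (nrow(fits) < 3) stop("need at least 3 reference fits")
  keep <- fits$ok
  for (p in c("freqPpm", "phaseDeg", "area", "fwhmHz")) {
    v <- fits[[p]]
    m <- mean(v[fits$ok])
    s <- stats::sd(v[fits$ok])
    if (!is.finite(s) || s == 0) next  # degenerate parameter: skip criterion
    keep <- keep & abs(v - m) <= k * s
  }
  keep
}

#' Frequency- and phase-correct a transient
#'
#' Shifts the spectrum so the fitted Cr frequency lands exactly on 3.0 ppm
#' (implemented as a time-domain phase ramp, exact for band-limited spectra)
#' and removes the fitted zero-order phase by complex rotation.  Refitting
#' the reference peak on the output yields a centre of 3.0 ppm and zero phase
#' to within fit tolerance.
#'
#' @param spec complex spectrum or matrix of spectra (columns = transients).
#' @param ppm the decreasing ppm axis.
#' @param fit reference fit(s): data.frame with freqPpm and phaseDeg (one row
#'   per column of \code{spec}).
#' @param targetPpm alignment target (3.0 ppm, the Cr resonance).
#' @return corrected spectrum (same shape as \code{spec}).
#' @export
applyFreqPhaseCorrection <- function(spec, ppm, fit, targetPpm = 3.0) {
  vec <- is.null(dim(spec))
  S <- if (vec) matrix(spec, ncol = 1) else spec
  if (nrow(fit) != ncol(S))
    stop("need one reference fit per transient")
  shift <- targetPpm - fit$freqPpm
  span <- max(ppm) - min(ppm)
  if (any(abs(shift) > span / 2))
    stop("fitted frequency offset exceeds half the spectral width; ",
         "degenerate reference fit")
  out <- .shiftSpectra(S, ppm, shift)
  out <- sweep(out, 2, exp(-1i * fit$phaseDeg * pi / 180), `*`)
  if (vec) out[, 1] else out
}

#' Frequency drift of an acquisition
#'
#' The SD of the fitted Cr peak position across retained OFF transients,
#' before alignment, in ppm.
#'
#' @param fits reference-fit data.frame for one subject with a
#'   \code{condition} column (\code{"OFF"}/\code{"ON"}).
#' @param retained logical retention mask (defaults to \code{fits$ok}).
#' @return ppm SD (scalar).
#' @export
frequencyDrift <- function(fits, retained = fits$ok) {
  sel <- retained & fits$condition == "OFF"
  if (sum(sel) < 2) stop("need at least 2 retained OFF reference fits")
  stats::sd(fits$freqPpm[sel])
}

#' Condition-wise averages and the edited difference spectrum
#'
#' Arithmetic means of the retained ON and OFF transients inside an index
#' selection, and their difference DIFF = mean(ON) - mean(OFF), the edited
#' spectrum.
#'
#' @param spectra complex matrix, nPoints x nTransients.
#' @param conditions character vector "OFF"/"ON" per transient.
#' @param retained logical retention mask per transient.
#' @param selection integer vector of transient indices (1-based); defaults
#'   to all transients.
#' @return list with complex vectors \code{meanOn}, \code{meanOff},
#'   \code{diff} and the retained counts \code{nOn}, \code{nOff}.
#' @export
averageAndDifference <- function(spectra, conditions, retained = NULL,
                                 selection = seq_len(ncol(spectra))) {
  if (is.null(retained)) retained <- rep(TRUE, ncol(spectra))
  selOn <- selection[retained[selection] & conditions[selection] == "ON"]
  selOff <- selection[retained[selection] & conditions[selection] == "OFF"]
  if (!length(selOn) || !length(selOff))
    stop("selection [", min(selection), ", ", max(selection),
         "] has no retained ", if (length(selOn)) "OFF" else "ON",
         " transients")
  meanOn <- rowMeans(spectra[, selOn, drop = FALSE])
  meanOff <- rowMeans(spectra[, selOff, drop = FALSE])
  list(meanOn = meanOn, meanOff = meanOff, diff = meanOn - meanOff,
       nOn = length(selOn), nOff = length(selOff))
}

#' Preprocess a cohort: reference fits, rejection, alignment
#'
#' For every subject, fits the Cr reference to every transient (ON and OFF
#' alike; Cr is present in both), drops transients whose reference
#' parameters are more than \code{k} SDs from that subject's mean
#' ([rejectOutlierTransients()]), and frequency/phase-corrects all transients
#' so the Cr peak is aligned at 3.0 ppm with zero phase.  The per-transient
#' fits (with pre-alignment frequencies, used by [frequencyDrift()]) and the
#' retention masks are stored in the cohort's \code{processing} slot.
#'
#' @param cohort a [MegaCohort-class].
#' @param k outlier threshold in SDs (default 3).
#' @return the corrected [MegaCohort-class].
#' @export
preprocessCohort <- function(cohort, k = 3) {
  stopifnot(is(cohort, "MegaCohort"))
  lar <- cohort@profile@larmorMhz
  refFits <- list()
  retained <- list()
  spectra <- cohort@spectra
  for (id in names(spectra)) {
    fits <- .fitReferenceBatch(spectra[[id]], cohort@ppm, lar)
    fits$condition <- cohort@conditions
    fits$index <- seq_len(nrow(fits)) - 1L
    keep <- rejectOutlierTransients(fits, k = k)
    spectra[[id]] <- applyFreqPhaseCorrection(spectra[[id]], cohort@ppm, fits)
    refFits[[id]] <- fits
    retained[[id]] <- keep
  }
  cohort@spectra <- spectra
  cohort@processing <- list(refFits = refFits, retained = retained,
                            corrected = TRUE, k = k)
  cohort
}

#' Retention masks and reference fits of a preprocessed cohort
#'
#' @param cohort a preprocessed [MegaCohort-class].
#' @return \code{retainedTransients}: named list of logical masks;
#'   \code{referenceFits}: named list of per-transient fit data.frames.
#' @rdname processingAccessors
#' @export
retainedTransients <- function(cohort) {
  if (!isTRUE(cohort@processing$corrected))
    stop("cohort has not been preprocessed; run preprocessCohort()")
  cohort@processing$retained
}

#' @rdname processingAccessors
#' @export
referenceFits <- function(cohort) {
  if (!isTRUE(cohort@processing$corrected))
    stop("cohort has not been preprocessed; run preprocessCohort()")
  cohort@processing$refFits
}
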