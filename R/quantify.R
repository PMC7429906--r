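#' @include AllClasses.R utils.R lineshapes.R preprocess.R
NULL

.modelIds <- c(lorentzian = 1L, gaussian = 2L, double_gaussian = 3L,
               inverse_lorentzian = 4L)

# Peak-model configuration: windows are package conventions (the study names
# only the peak centres); widths are initial values in ppm.
.peakConfig <- function() {
  list(
    tcr = list(model = "lorentzian", window = c(2.6, 3.4),
               centers = 3.0, widthInit = 0.0333, source = "off"),
    tnaa = list(model = "lorentzian", window = c(1.8, 2.2),
                centers = 2.0, widthInit = 0.0329, source = "off"),
    gaba = list(model = "gaussian", window = c(2.8, 3.3),
                centers = 3.0, widthInit = 0.0831, source = "diff"),
    glx = list(model = "double_gaussian", window = c(3.45, 4.10),
               centers = c(3.71, 3.79), widthInit = 0.0466, source = "diff"),
    naaedit = list(model = "inverse_lorentzian", window = c(1.8, 2.2),
                   centers = 2.0, widthInit = 0.0329, source = "diff")
  )
}

# Fit one peak model to each row of Y (real spectra restricted internally to
# the config window).  Returns a data.frame with a row per spectrum.
.fitPeaksMatrix <- function(Y, ppm, cfg, larmorMhz) {
  idx <- .ppmWindowIdx(ppm, cfg$window)
  x <- ppm[idx]
  Yw <- Y[, idx, drop = FALSE]
  mid <- .modelIds[[cfg$model]]
  raw <- .cpp_fit_peaks(Yw, x, mid, cfg$centers, cfg$widthInit)
  lo <- min(cfg$window); hi <- max(cfg$window)
  halfwin <- (hi - lo) / 2
  if (mid == 3L) {
    A1 <- raw[, 1]; A2 <- raw[, 2]; s <- raw[, 5]
    amp <- pmax(A1, A2)
    out <- data.frame(
      area = gaussianArea(A1 + A2, s),
      fwhmHz = gaussianFwhm(s) * larmorMhz,
      amplitude = amp,
      centerPpm = (raw[, 3] + raw[, 4]) / 2,
      widthPpm = s,
      residSd = raw[, 8],
      conv = raw[, 9] > 0)
    out$ok <- out$conv & A1 > 0 & A2 > 0 & s > 1e-4 & s < halfwin &
      raw[, 3] > lo & raw[, 3] < hi & raw[, 4] > lo & raw[, 4] < hi
  } else {
    A <- raw[, 1]; w <- raw[, 3]
    area <- if (mid == 2L) gaussianArea(A, w) else lorentzianArea(A, w)
    fw <- if (mid == 2L) gaussianFwhm(w) else lorentzianFwhm(w)
    out <- data.frame(
      area = area,
      fwhmHz = fw * larmorMhz,
      amplitude = A,
      centerPpm = raw[, 2],
      widthPpm = w,
      residSd = raw[, 4 + 2],
      conv = raw[, 7] > 0)
    out$ok <- out$conv & A > 0 & w > 1e-4 & w < halfwin &
      out$centerPpm > lo & out$centerPpm < hi
  }
  out$fitErrorPct <- 100 * out$residSd / out$amplitude
  out
}

#' Fit a single peak model to a spectral window
#'
#' Nonlinear least squares of a Lorentzian, Gaussian, double Gaussian
#' (shared width) or inverse (negative-lobe) Lorentzian plus a linear
#' baseline.  The area is the analytic area under the fitted model:
#' \code{pi*A*gamma} for a Lorentzian, \code{A*sigma*sqrt(2*pi)} for a
#' Gaussian (summed over both components of a double Gaussian); the inverse
#' Lorentzian reports the positive magnitude of the negative lobe.  FWHM is
#' \code{2*gamma} or \code{2*sigma*sqrt(2*log(2))}, converted to Hz.  The
#' fit error is the residual SD divided by the fitted amplitude, in percent.
#'
#' @param y real spectrum (e.g. the real part of an averaged spectrum).
#' @param ppm decreasing ppm axis matching \code{y}.
#' @param model one of \code{"lorentzian"}, \code{"gaussian"},
#'   \code{"double_gaussian"}, \code{"inverse_lorentzian"}.
#' @param centerPpm initial peak centre(s); two values for the double
#'   Gaussian.
#' @param windowPpm fit interval in ppm (must contain the centre(s)).
#' @param larmorMhz proton frequency in MHz for the Hz conversion.
#' @param widthInitPpm initial width (gamma or sigma) in ppm.
#' @return a [PeakFit-class]; non-convergent or degenerate fits carry
#'   \code{ok = FALSE}.
#' @examples
#' prof <- vcProfile()
#' x <- ppmAxis(prof)
#' y <- exp(-0.5 * ((x - 3.0) / 0.04)^2)
#' fitPeak(y, x, "gaussian", 3.0, c(2.8, 3.3), larmorMhz(prof))
#' @export
fitPeak <- function(y, ppm, model, centerPpm, windowPpm, larmorMhz,
                    widthInitPpm = 0.04) {
  model <- match.arg(model, names(.modelIds))
  if (any(centerPpm <= min(windowPpm)) || any(centerPpm >= max(windowPpm)))
    stop("window must contain the peak centre(s)")
  if (min(windowPpm) < min(ppm) || max(windowPpm) > max(ppm))
    stop("fit window must lie within the ppm axis")
  cfg <- list(model = model, window = windowPpm, centers = centerPpm,
              widthInit = widthInitPpm)
  df <- .fitPeaksMatrix(matrix(y, nrow = 1), ppm, cfg, larmorMhz)
  params <- c(amplitude = df$amplitude, center = df$centerPpm,
              width = df$widthPpm)
  new("PeakFit", model = model, params = params, area = df$area,
      fwhmHz = df$fwhmHz, fitErrorPct = df$fitErrorPct, ok = df$ok)
}

#' Quantify all metabolites from an averaged OFF and difference spectrum
#'
#' tCr and tNAA are fitted as single Lorentzians on the mean OFF spectrum
#' (windows 2.6-3.4 and 1.8-2.2 ppm); GABA+ as a single Gaussian
#' (2.8-3.3 ppm) and Glx as a double Gaussian (3.45-4.10 ppm) on the
#' difference spectrum; the co-edited negative tNAA lobe as an inverse
#' Lorentzian on the difference spectrum.  Ratios are taken to the chosen
#' internal reference.
#'
#' @param meanOff averaged OFF spectrum (complex allowed; the real part is
#'   fitted).
#' @param diff edited difference spectrum (same axis).
#' @param ppm decreasing ppm axis.
#' @param larmorMhz proton frequency in MHz.
#' @param reference internal reference metabolite, \code{"tcr"} (default) or
#'   \code{"tnaa"}.
#' @return one-row data.frame with per-metabolite areas, FWHMs (Hz), fit
#'   errors (percent), the reference used, the ratios \code{gaba_ratio},
#'   \code{glx_ratio}, \code{tnaa_ratio} (tNAA is always referenced to tCr)
#'   and an overall \code{ok} flag (all component fits converged and sane).
#' @export
quantifySelection <- function(meanOff, diff, ppm, larmorMhz,
                              reference = c("tcr", "tnaa")) {
  reference <- match.arg(reference)
  cfgs <- .peakConfig()
  offRe <- matrix(Re(meanOff), nrow = 1)
  diffRe <- matrix(Re(diff), nrow = 1)
  fits <- lapply(cfgs, function(cfg) {
    Y <- if (cfg$source == "off") offRe else diffRe
    .fitPeaksMatrix(Y, ppm, cfg, larmorMhz)
  })
  refArea <- fits[[reference]]$area
  out <- data.frame(reference = reference)
  for (m in names(fits)) {
    out[[paste0(m, "_area")]] <- fits[[m]]$area
    out[[paste0(m, "_fwhm_hz")]] <- fits[[m]]$fwhmHz
    out[[paste0(m, "_fiterr")]] <- fits[[m]]$fitErrorPct
    out[[paste0(m, "_ok")]] <- fits[[m]]$ok
  }
  out$gaba_ratio <- fits$gaba$area / refArea
  out$glx_ratio <- fits$glx$area / refArea
  out$tnaa_ratio <- fits$tnaa$area / fits$tcr$area
  out$ok <- all(vapply(fits[c("tcr", "tnaa", "gaba", "glx")],
                       function(f) f$ok, logical(1))) && refArea > 0
  out
}

#' CSF partial-volume correction
#'
#' Metabolites are absent from cerebrospinal fluid, so a measured ratio is
#' divided by the metabolite-visible voxel fraction:
#' \code{corrected = measured / (1 - fCsf)}.  The correction is the identity
#' at zero CSF and strictly increases with the CSF fraction.
#'
#' @param cMeas measured concentration ratio(s).
#' @param fCsf CSF voxel fraction(s) in [0, 1).
#' @return corrected ratio(s).
#' @examples
#' csfCorrect(1.2, 0.25)  # 1.6
#' @export
csfCorrect <- function(cMeas, fCsf) {
  if (any(fCsf < 0) || any(fCsf >= 1))
    stop("fCsf must lie in [0, 1)")
  cMeas / (1 - fCsf)
}

#' Exclude participants with outlying linewidths
#'
#' A participant is dropped when the cohort-wise z-score of any quantified
#' metabolite's FWHM (tCr, tNAA, GABA+, Glx) exceeds \code{k} in magnitude.
#' A metabolite with zero FWHM spread is skipped.
#'
#' @param fwhm data.frame or matrix of per-participant FWHMs with columns
#'   \code{tcr}, \code{tnaa}, \code{gaba}, \code{glx} (>= 3 rows).
#' @param k z-score threshold (default 3).
#' @return logical retention mask per participant.
#' @export
excludeParticipantsByFwhm <- function(fwhm, k = 3) {
  fwhm <- as.data.frame(fwhm)
  need <- c("tcr", "tnaa", "gaba", "glx")
  stopifnot(all(need %in% names(fwhm)))
  if (nrow(fwhm) < 3) stop("need at least 3 participants")
  keep <- rep(TRUE, nrow(fwhm))
  for (m in need) {
    v <- fwhm[[m]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    keep <- keep & abs(v - mean(v)) <= k * s
  }
  keep
}

#' Static per-subject metabolite estimates
#'
#' The classic static analysis: for each subject all retained transients are
#' averaged, the averages quantified ([quantifySelection()]), the ratios
#' CSF-corrected ([csfCorrect()]) with the subject's tissue fractions, and
#' participants with outlying linewidths excluded
#' ([excludeParticipantsByFwhm()]).
#'
#' @param cohort a preprocessed [MegaCohort-class].
#' @param reference internal reference, \code{"tcr"} or \code{"tnaa"}.
#' @param k FWHM exclusion threshold in SDs.
#' @return data.frame with one row per subject: tissue fractions, raw and
#'   CSF-corrected ratios, FWHMs, fit errors, and the \code{included} flag.
#' @export
staticEstimates <- function(cohort, reference = "tcr", k = 3) {
  retained <- retainedTransients(cohort)
  rows <- lapply(subjectIds(cohort), function(id) {
    avg <- averageAndDifference(spectra(cohort, id), conditions(cohort),
                                retained[[id]])
    q <- quantifySelection(avg$meanOff, avg$diff, ppm(cohort),
                           larmorMhz(cohort), reference)
    cbind(data.frame(subject = id), q)
  })
  est <- do.call(rbind, rows)
  est <- merge(tissueFractions(cohort), est, by = "subject", sort = TRUE)
  fw <- data.frame(tcr = est$tcr_fwhm_hz, tnaa = est$tnaa_fwhm_hz,
                   gaba = est$gaba_fwhm_hz, glx = est$glx_fwhm_hz)
  est$included <- excludeParticipantsByFwhm(fw, k = k) & est$ok
  for (m in c("gaba", "glx", "tnaa")) {
    est[[paste0(m, "_ratio_corr")]] <-
      csfCorrect(est[[paste0(m, "_ratio")]], est$csf)
  }
  est
}

#' Pearson partial correlation
#'
#' First-order partial correlation of \code{x} and \code{y} controlling for
#' \code{z}:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' with a two-sided p-value from the t distribution on \code{n - 3} degrees
#' of freedom.
#'
#' @param x,y variables of interest.
#' @param z control variable.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
partialCorrelation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("inputs must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("zero variance in an input")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den < 1e-12)
    stop("control variable is collinear with an input; partial correlation undefined")
  r <- (rxy - rxz * ryz) / den
  tt <- r * sqrt((n - 3) / max(1 - r^2, 1e-300))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 3), n = n)
}

#' Compare two groups with a normality-gated test
#'
#' Shapiro-Wilk normality is assessed in each group at alpha 0.05; when both
#' groups are consistent with normality an independent two-sided pooled t
#' test is used, otherwise the Wilcoxon rank-sum test (normal approximation
#' with tie correction).
#'
#' @param a,b numeric samples (each >= 3 values).
#' @return data.frame with \code{test} ("t" or "rank-sum"),
#'   \code{statistic}, \code{p} and the two Shapiro p-values.
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("each group needs >= 3 values")
  shapiroP <- function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  pa <- shapiroP(a); pb <- shapiroP(b)
  if (pa > 0.05 && pb > 0.05) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(test = "t", statistic = unname(ht$statistic),
               p = ht$p.value, shapiroA = pa, shapiroB = pb)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    data.frame(test = "rank-sum", statistic = unname(ht$statistic),
               p = ht$p.value, shapiroA = pa, shapiroB = pb)
  }
}
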