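#' @include AllClasses.R utils.R quantify.R dynamics-low.R
NULL

#' Bin transients across subjects into high-resolution group traces
#'
#' All retained transients (from every retained subject) whose acquisition
#' index falls in the same bin of \code{binSize} transients are pooled,
#' averaged per condition, differenced, and quantified — trading the
#' across-subject dimension for temporal resolution.  Transients beyond the
#' last full bin are discarded.
#'
#' @param cohort a preprocessed [MegaCohort-class].
#' @param binSize transients per bin (4 for the VC profile, 6 for PCC:
#'   12 s bins).
#' @param metabolites metabolites to quantify.
#' @param reference internal reference (\code{"tcr"} or \code{"tnaa"}).
#' @param subjects subject ids to pool (default: all).
#' @return named list of [GroupTrace-class], one per metabolite; bins whose
#'   component fit is flagged are \code{NA}.
#' @examples
#' \donttest{
#' coh <- preprocessCohort(simulateCohort(vcProfile(), nSubjects = 6, seed = 1))
#' tr <- binAcrossSubjects(coh, 4)
#' tr$gaba
#' }
#' @export
binAcrossSubjects <- function(cohort, binSize,
                              metabolites = c("gaba", "glx", "tnaa"),
                              reference = "tcr",
                              subjects = subjectIds(cohort)) {
  nT <- nTransients(cohort)
  nBins <- nT %/% binSize
  if (nBins < 1) stop("binSize exceeds the number of transients")
  retained <- retainedTransients(cohort)
  conds <- conditions(cohort)
  npts <- nPoints(cohort)

  sumOn <- matrix(0, nBins, npts)
  sumOff <- matrix(0, nBins, npts)
  nOn <- integer(nBins)
  nOff <- integer(nBins)
  binOf <- (seq_len(nT) - 1L) %/% binSize + 1L  # > nBins for leftovers
  for (id in subjects) {
    S <- Re(spectra(cohort, id))
    keep <- retained[[id]]
    for (b in seq_len(nBins)) {
      sel <- which(binOf == b & keep)
      on <- sel[conds[sel] == "ON"]
      off <- sel[conds[sel] == "OFF"]
      if (length(on)) {
        sumOn[b, ] <- sumOn[b, ] + rowSums(S[, on, drop = FALSE])
        nOn[b] <- nOn[b] + length(on)
      }
      if (length(off)) {
        sumOff[b, ] <- sumOff[b, ] + rowSums(S[, off, drop = FALSE])
        nOff[b] <- nOff[b] + length(off)
      }
    }
  }
  if (any(nOn == 0) || any(nOff == 0)) {
    b <- which(nOn == 0 | nOff == 0)[1]
    stop("bin ", b, " has no retained ",
         if (nOn[b] == 0) "ON" else "OFF", " transients")
  }
  mOff <- sumOff / nOff
  mDiff <- sumOn / nOn - mOff

  peaks <- unique(c(metabolites, reference))
  cfgs <- .peakConfig()[peaks]
  lar <- larmorMhz(cohort)
  fits <- lapply(cfgs, function(cfg) {
    Y <- if (cfg$source == "off") mOff else mDiff
    .fitPeaksMatrix(Y, ppm(cohort), cfg, lar)
  })
  timesS <- (((seq_len(nBins) - 1) * binSize) + (binSize - 1) / 2) *
    trS(cohort)
  out <- lapply(metabolites, function(m) {
    v <- fits[[m]]$area / fits[[reference]]$area
    v[!(fits[[m]]$ok & fits[[reference]]$ok)] <- NA
    new("GroupTrace", metabolite = m, reference = reference,
        timesS = timesS, values = v, nBins = as.integer(nBins),
        binSizeTransients = as.integer(binSize), normalized = "none")
  })
  names(out) <- metabolites
  out
}

#' Temporal resolution of a binned trace
#'
#' @param profile an [AcquisitionProfile-class].
#' @param binSize transients per bin.
#' @return seconds per bin (\code{binSize * trS}).
#' @examples
#' traceResolution(vcProfile(), 4)   # 12
#' traceResolution(pccProfile(), 6)  # 12
#' @export
traceResolution <- function(profile, binSize) {
  stopifnot(is(profile, "AcquisitionProfile"))
  binSize * profile@trS
}

#' Normalize a metabolite trace
#'
#' \code{percent_of_mean}: \code{100 * (v - mean(v)) / mean(v)} (output mean
#' zero); \code{change_from_first}: \code{100 * (v - v[1]) / v[1]} (first
#' value zero).  Downstream correlations are invariant to the choice.
#'
#' @param x numeric vector or [GroupTrace-class].
#' @param mode \code{"percent_of_mean"} or \code{"change_from_first"}.
#' @return same type as \code{x}.
#' @export
normalizeTrace <- function(x, mode = c("percent_of_mean",
                                       "change_from_first")) {
  mode <- match.arg(mode)
  if (is(x, "GroupTrace")) {
    x@values <- normalizeTrace(x@values, mode)
    x@normalized <- mode
    return(x)
  }
  ref <- if (mode == "percent_of_mean") mean(x, na.rm = TRUE) else x[1]
  if (!is.finite(ref) || ref == 0)
    stop("normalization denominator is zero or undefined")
  100 * (x - ref) / ref
}

#' Centred moving average of a trace
#'
#' Smoothing for presentation and for the low/high cross-validation; the
#' window shrinks at the edges.  Never applied before cross-correlation.
#'
#' @param x numeric vector or [GroupTrace-class].
#' @param window window length in bins (1 = identity).
#' @return same type as \code{x}.
#' @export
smoothTrace <- function(x, window) {
  if (is(x, "GroupTrace")) {
    x@values <- smoothTrace(x@values, window)
    return(x)
  }
  n <- length(x)
  if (window > n) stop("window exceeds trace length")
  if (window == 1) return(x)
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - lo):min(n, i + hi)], na.rm = TRUE)
  }, numeric(1))
}

#' Lag-constrained cross-correlation of two metabolite traces
#'
#' Pearson correlation at every lag retaining at least \code{minOverlap}
#' overlapping bins.  For lag index \code{k >= 0} the correlation between
#' \code{a[1:n]} and \code{b[(k+1):(k+n)]} (\code{n = nBins - k}) is
#' reported at the signed lag \code{-k * dtS} — trace A (GABA+) acquired
#' earlier, predicting trace B (Glx) — and the mirrored computation at
#' \code{+k * dtS}.  Each direction therefore contributes
#' \code{nBins - minOverlap + 1} lags (lag 0 appears once in the combined
#' result).  Confidence intervals are Fisher-z 95\% using each lag's own
#' sample size.
#'
#' @param a,b numeric traces or [GroupTrace-class] objects of equal length
#'   (A = GABA+, B = Glx for the standard analysis).
#' @param minOverlap minimum overlapping bins per lag (default 25).
#' @param dtS seconds per bin (taken from \code{a} when it is a GroupTrace).
#' @return a [CrossCorrResult-class] (cluster fields empty until
#'   [crossCorrClusterTest()]).
#' @export
crossCorrelation <- function(a, b, minOverlap = 25, dtS = NULL) {
  if (is(a, "GroupTrace")) {
    dtS <- dtS %||% (a@timesS[2] - a@timesS[1])
    a <- a@values
  }
  if (is(b, "GroupTrace")) b <- b@values
  dtS <- dtS %||% 1
  if (minOverlap < 4) stop("minOverlap must be >= 4")
  n <- length(a)
  if (length(b) != n) stop("traces must have equal length")
  if (n < minOverlap)
    stop("trace length (", n, ") below the minimum overlap (", minOverlap, ")")
  if (anyNA(a) || anyNA(b))
    stop("traces contain missing bins; interpolate or drop them first")
  K <- n - as.integer(minOverlap)
  maps <- .cpp_lag_maps(a, b, K)
  kAbs <- c(rev(seq_len(K)), 0, seq_len(K))
  r <- c(rev(maps$ab[-1]), maps$ab[1], maps$ba[-1])
  nPer <- as.integer(n - kAbs)
  capped <- abs(r) >= 1 - 1e-12
  if (any(capped))
    warning("correlation magnitude ~1 at ", sum(capped),
            " lag(s); t statistic capped")
  tt <- ifelse(capped, sign(r) * 1e6,
               r * sqrt((nPer - 2) / (1 - r^2)))
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(pmax(nPer - 3, 1))
  new("CrossCorrResult",
      lagsS = (seq_along(r) - K - 1) * dtS,
      r = r, n = nPer,
      ciLo = tanh(z - stats::qnorm(0.975) * se),
      ciHi = tanh(z + stats::qnorm(0.975) * se),
      t = tt, minOverlap = as.integer(minOverlap), dtS = dtS,
      clusters = data.frame(), significantMask = rep(FALSE, length(r)),
      traceA = a, traceB = b)
}

#' Cluster-corrected significance of a cross-correlation
#'
#' Each lag's correlation is converted to a t statistic
#' (\code{r * sqrt((n-2)/(1-r^2))}) and thresholded at its own two-sided
#' point-wise critical value (p < \code{clusterAlpha}).  Contiguous
#' same-sign suprathreshold lags within a predictive direction form
#' clusters scored by their summed t values.  The null is built by fully
#' permuting the time order of trace B \code{nPerm} times, recomputing the
#' whole lag map, and recording the maximal positive and |negative| cluster
#' mass per direction; observed clusters above the 95th percentile of the
#' matching null are significant.
#'
#' @param ccres a [CrossCorrResult-class] from [crossCorrelation()].
#' @param nPerm number of permutations (study default 5000).
#' @param alpha cluster-level level (0.05: the 95th-percentile rule).
#' @param clusterAlpha point-wise two-sided cluster-forming level.
#' @param seed integer seed.
#' @return the [CrossCorrResult-class] with \code{clusters} and
#'   \code{significantMask} populated.
#' @export
crossCorrClusterTest <- function(ccres, nPerm = 5000, alpha = 0.05,
                                 clusterAlpha = 0.05, seed = 1) {
  stopifnot(is(ccres, "CrossCorrResult"))
  K <- (length(ccres@lagsS) - 1L) %/% 2L
  N <- length(ccres@traceA)
  nPer <- N - (0:K)
  tcrit <- stats::qt(1 - clusterAlpha / 2, df = pmax(nPer - 2, 1))
  i0 <- K + 1L
  dirIdx <- list(ab = seq.int(i0, 1L), ba = seq.int(i0, 2L * K + 1L))
  null <- .withSeed(seed, .cpp_xcorr_perm_null(ccres@traceA, ccres@traceB,
                                               K, tcrit, as.integer(nPerm)))
  nullCols <- list(ab = c(pos = 1L, neg = 2L), ba = c(pos = 3L, neg = 4L))
  clusters <- NULL
  mask <- rep(FALSE, length(ccres@lagsS))
  for (d in c("ab", "ba")) {
    idx <- dirIdx[[d]]
    tmap <- ccres@t[idx]
    tmap[abs(tmap) <= tcrit] <- 0
    runs <- .clusterRuns(tmap, 0)
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      col <- if (runs$sign[i] > 0) nullCols[[d]][["pos"]]
             else nullCols[[d]][["neg"]]
      nullm <- null[, col]
      # alpha/2 per sign keeps each direction's family-wise level at alpha
      qcrit <- stats::quantile(nullm, 1 - alpha / 2, names = FALSE)
      sig <- abs(runs$mass[i]) > qcrit
      lagIdx <- idx[runs$start[i]:runs$end[i]]
      if (sig) mask[lagIdx] <- TRUE
      clusters <- rbind(clusters, data.frame(
        direction = if (d == "ab") "A_precedes_B" else "B_precedes_A",
        lagStartS = min(ccres@lagsS[lagIdx]),
        lagEndS = max(ccres@lagsS[lagIdx]),
        sign = runs$sign[i], mass = runs$mass[i],
        p = (1 + sum(nullm >= abs(runs$mass[i]))) / (nPerm + 1),
        significant = sig))
    }
  }
  ccres@clusters <- if (is.null(clusters)) data.frame() else clusters
  ccres@significantMask <- mask
  ccres
}

#' Cross-validate the low- and high-resolution analyses
#'
#' Applies a sliding window of \code{plan$width} transients (i.e.
#' \code{plan$width / binSize} bins, advancing one bin at a time) to the
#' high-resolution group trace and correlates the result with the
#' low-resolution group-mean trace at the matching window starts.
#'
#' @param low numeric low-resolution group-mean change trace (one value per
#'   sliding window of \code{plan}).
#' @param high [GroupTrace-class] or numeric high-resolution trace.
#' @param plan the [slidingWindows()] plan that produced \code{low}.
#' @param binSize transients per high-resolution bin.
#' @return list with Pearson \code{r}, \code{p}, \code{n}, the matched
#'   low-resolution indices and the smoothed high-resolution values.
#' @export
validateLowHigh <- function(low, high, plan, binSize) {
  if (is(high, "GroupTrace")) high <- high@values
  if (plan$width %% binSize != 0)
    stop("window width (", plan$width,
         " transients) is not a whole number of bins of ", binSize)
  widthBins <- plan$width %/% binSize
  nBins <- length(high)
  if (widthBins > nBins) stop("window exceeds the high-resolution trace")
  starts <- 0:(nBins - widthBins)           # in bins
  startT <- starts * binSize                # in transients
  if (any(startT %% plan$step != 0))
    stop("grid mismatch: high-resolution windows start every ", binSize,
         " transients but low-resolution windows every ", plan$step)
  lowIdx <- startT %/% plan$step + 1L
  if (max(lowIdx) > length(low))
    stop("grid mismatch: low-resolution trace has ", length(low),
         " windows but index ", max(lowIdx), " is required")
  highWin <- vapply(starts, function(j)
    mean(high[(j + 1):(j + widthBins)]), numeric(1))
  ok <- !is.na(highWin) & !is.na(low[lowIdx])
  ct <- stats::cor.test(low[lowIdx][ok], highWin[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       lowIndex = lowIdx, highSmoothed = highWin)
}
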