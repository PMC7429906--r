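#' @include AllClasses.R utils.R quantify.R
NULL

#' Sliding-window plan
#'
#' Half-open index intervals \code{[i*step, i*step + width)} over
#' \code{nTransients} acquisitions; the number of windows is
#' \code{floor((N - width)/step) + 1} and window-centre times are
#' \code{(start + (width - 1)/2) * trS}.
#'
#' @param nTransients total transients N.
#' @param width window width in transients (0 < width <= N).
#' @param step transients between window starts (>= 1).
#' @param trS repetition time in seconds (for window times).
#' @return an object of class \code{windowPlan}: list with \code{width},
#'   \code{step}, \code{starts} (0-based), \code{ends} (exclusive),
#'   \code{timesS} and \code{n}.
#' @examples
#' slidingWindows(256, 128, 2)$n  # 65
#' @export
slidingWindows <- function(nTransients, width, step = 2, trS = 1) {
  if (width <= 0 || width > nTransients)
    stop("width must satisfy 0 < width <= nTransients")
  if (step < 1) stop("step must be >= 1")
  starts <- seq.int(0L, nTransients - width, by = step)
  plan <- list(width = as.integer(width), step = as.integer(step),
               nTransients = as.integer(nTransients),
               starts = as.integer(starts),
               ends = as.integer(starts + width),
               timesS = (starts + (width - 1) / 2) * trS,
               n = length(starts))
  class(plan) <- "windowPlan"
  plan
}

#' @export
print.windowPlan <- function(x, ...) {
  cat(sprintf("windowPlan: %d windows of width %d, step %d over %d transients\n",
              x$n, x$width, x$step, x$nTransients))
  invisible(x)
}

# Per-window condition-wise mean spectra (real part) for one subject,
# computed as S %*% indicator via BLAS; errors if a window has no retained
# transients of a condition.  Returns nWindows x nPoints matrices (rows may
# be restricted via rowIdx) for OFF and DIFF.
.windowMeans <- function(specMat, conds, retained, plan, rowIdx = NULL) {
  S <- Re(specMat)
  if (!is.null(rowIdx)) S <- S[rowIdx, , drop = FALSE]
  onMask <- retained & conds == "ON"
  offMask <- retained & conds == "OFF"
  nT <- ncol(S)
  inWin <- matrix(0, nT, plan$n)
  for (w in seq_len(plan$n))
    inWin[(plan$starts[w] + 1L):plan$ends[w], w] <- 1
  nOn <- as.vector(crossprod(inWin, onMask))
  nOff <- as.vector(crossprod(inWin, offMask))
  if (any(nOn == 0) || any(nOff == 0)) {
    w <- which(nOn == 0 | nOff == 0)[1]
    stop("window ", w, " [", plan$starts[w], ", ", plan$ends[w],
         ") has no retained ", if (nOn[w] == 0) "ON" else "OFF",
         " transients")
  }
  mOn <- t(S %*% (inWin * onMask)) / nOn
  mOff <- t(S %*% (inWin * offMask)) / nOff
  list(off = mOff, diff = mOn - mOff)
}

# Fit the requested peaks in every window of one subject.
# Returns a named list of per-window fit data.frames.
.windowQuantify <- function(cohort, subject, plan,
                            peaks = c("gaba", "tcr")) {
  retained <- retainedTransients(cohort)[[subject]]
  cfgs <- .peakConfig()[peaks]
  px <- ppm(cohort)
  rowIdx <- sort(unique(unlist(lapply(cfgs, function(cfg)
    .ppmWindowIdx(px, cfg$window)))))
  wm <- .windowMeans(spectra(cohort, subject), conditions(cohort),
                     retained, plan, rowIdx)
  lar <- larmorMhz(cohort)
  lapply(cfgs, function(cfg) {
    Y <- if (cfg$source == "off") wm$off else wm$diff
    .fitPeaksMatrix(Y, px[rowIdx], cfg, lar)
  })
}

#' Per-subject sliding-window change trace
#'
#' For every window, the retained transients are averaged per condition, the
#' metabolite and reference quantified, and the ratio expressed as percent
#' change from the first window (which is therefore identically zero).
#' Windows with a flagged component fit are returned as \code{NA}.
#'
#' @param cohort a preprocessed [MegaCohort-class].
#' @param subject subject id.
#' @param plan a [slidingWindows()] plan.
#' @param metabolite \code{"gaba"}, \code{"glx"} or \code{"tnaa"}.
#' @param reference \code{"tcr"} or \code{"tnaa"}.
#' @return numeric vector of percent changes, one per window.
#' @export
subjectChangeTrace <- function(cohort, subject, plan, metabolite = "gaba",
                               reference = "tcr") {
  metabolite <- match.arg(metabolite, c("gaba", "glx", "tnaa"))
  reference <- match.arg(reference, c("tcr", "tnaa"))
  if (metabolite == reference)
    stop("metabolite and reference must differ")
  peaks <- unique(c(metabolite, reference))
  fits <- .windowQuantify(cohort, subject, plan, peaks)
  ratio <- fits[[metabolite]]$area / fits[[reference]]$area
  ratio[!(fits[[metabolite]]$ok & fits[[reference]]$ok)] <- NA
  if (is.na(ratio[1]))
    return(rep(NA_real_, plan$n))
  100 * (ratio - ratio[1]) / ratio[1]
}

#' Sliding-window change traces for all subjects
#'
#' @inheritParams subjectChangeTrace
#' @param subjects subject ids to include (default: all).
#' @return numeric matrix, subjects x windows, of percent changes.
#' @export
changeTraces <- function(cohort, plan, metabolite = "gaba",
                         reference = "tcr", subjects = subjectIds(cohort)) {
  tr <- vapply(subjects,
               function(id) subjectChangeTrace(cohort, id, plan,
                                               metabolite, reference),
               numeric(plan$n))
  t(tr)
}

# maximal same-sign suprathreshold runs of a t map
.clusterRuns <- function(tmap, tcrit) {
  sign <- ifelse(tmap > tcrit, 1L, ifelse(tmap < -tcrit, -1L, 0L))
  out <- data.frame(start = integer(), end = integer(), sign = integer(),
                    mass = numeric())
  w <- 1
  while (w <= length(tmap)) {
    if (sign[w] != 0) {
      e <- w
      while (e < length(tmap) && sign[e + 1] == sign[w]) e <- e + 1
      out <- rbind(out, data.frame(start = w, end = e, sign = sign[w],
                                   mass = sum(tmap[w:e])))
      w <- e + 1
    } else w <- w + 1
  }
  out
}

# one-sample t per window; a window with zero spread but nonzero mean is a
# perfect deviation from zero -> capped t of +-1e6 (the all-zero first
# window of a change trace stays 0)
.colT <- function(X) {
  apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    s <- stats::sd(v)
    if (s == 0) return(if (mean(v) == 0) 0 else sign(mean(v)) * 1e6)
    mean(v) / (s / sqrt(length(v)))
  })
}

#' Cluster-based permutation test of sliding-window traces
#'
#' At every window a one-sample two-sided t test of the per-subject changes
#' against zero is computed.  Windows whose |t| exceeds the two-sided
#' cluster-forming critical value are grouped into maximal same-sign runs
#' ("clusters") scored by the sum of their t values.  The null distribution
#' of the maximal positive and |negative| cluster mass is built from
#' \code{nPerm} resamples of the subject traces; observed clusters whose
#' mass exceeds the 95th percentile of the matching null are significant.
#' Positive and negative clusters are treated separately.  Missing values
#' are excluded pairwise from the t map.
#'
#' Two exchange schemes are available.  The default, \code{"signflip"},
#' flips the sign of each subject's whole trace with probability one half:
#' it preserves the strong window-to-window autocorrelation that the
#' overlapping sliding windows induce and is exact under a
#' symmetric-about-zero null.  \code{"shuffle"} permutes each subject's
#' window labels independently; because it destroys that autocorrelation it
#' is anticonservative for heavily overlapping windows (family-wise error
#' roughly doubles in null simulations) and is provided for comparison.
#'
#' @param traces numeric matrix, subjects x windows, of percent changes.
#' @param nPerm number of permutations (>= 100; study default 5000).
#' @param alpha cluster-level significance level (0.05: the 95th-percentile
#'   rule).
#' @param clusterAlpha point-wise two-sided cluster-forming level.
#' @param seed integer seed for the permutation draws.
#' @param timesS optional window-centre times stored with the result.
#' @param nullScheme \code{"signflip"} (default) or \code{"shuffle"}.
#' @return a [ClusterTestResult-class].
#' @export
clusterPermutationTest <- function(traces, nPerm = 5000, alpha = 0.05,
                                   clusterAlpha = 0.05, seed = 1,
                                   timesS = numeric(),
                                   nullScheme = c("signflip", "shuffle")) {
  nullScheme <- match.arg(nullScheme)
  traces <- as.matrix(traces)
  S <- nrow(traces); W <- ncol(traces)
  if (nPerm < 100) stop("nPerm must be >= 100")
  nPerWin <- colSums(!is.na(traces))
  if (any(nPerWin == 0))
    stop("window ", which(nPerWin == 0)[1], " has no non-missing values")
  if (S < 3) stop("need at least 3 subjects")
  tcrit <- stats::qt(1 - clusterAlpha / 2, df = S - 1)
  tmap <- .colT(traces)
  clusters <- .clusterRuns(tmap, tcrit)
  null <- .withSeed(seed, .cpp_cluster_perm_null(
    traces, tcrit, as.integer(nPerm),
    if (nullScheme == "shuffle") 1L else 0L))
  # positive and negative clusters are tested separately; alpha/2 per side
  # keeps the two-sided family-wise level at alpha
  qPos <- stats::quantile(null[, 1], 1 - alpha / 2, names = FALSE)
  qNeg <- stats::quantile(null[, 2], 1 - alpha / 2, names = FALSE)
  if (nrow(clusters)) {
    clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
      m <- clusters$mass[i]
      nullm <- if (clusters$sign[i] > 0) null[, 1] else null[, 2]
      (1 + sum(nullm >= abs(m))) / (nPerm + 1)
    }, numeric(1))
    clusters$significant <- ifelse(clusters$sign > 0,
                                   clusters$mass > qPos,
                                   abs(clusters$mass) > qNeg)
  } else {
    clusters$p <- numeric()
    clusters$significant <- logical()
  }
  mask <- rep(FALSE, W)
  for (i in seq_len(nrow(clusters)))
    if (clusters$significant[i])
      mask[clusters$start[i]:clusters$end[i]] <- TRUE
  new("ClusterTestResult", tMap = tmap,
      timesS = if (length(timesS)) timesS else as.numeric(seq_len(W)),
      clusters = clusters, nullPos = qPos, nullNeg = qNeg,
      significantMask = mask, nPerm = as.integer(nPerm), alpha = alpha)
}

#' Fit-error and edited-tNAA control traces
#'
#' Applies the sliding-window machinery to quantities that should stay flat
#' if quantification quality and editing efficiency are stable: the
#' per-window fit error of each metabolite peak (as change from the first
#' window, in percentage points) and the co-edited negative tNAA area in the
#' difference spectrum (as percent change), each with the same
#' cluster-permutation correction.
#'
#' @param cohort a preprocessed [MegaCohort-class].
#' @param plan a [slidingWindows()] plan.
#' @param subjects subject ids to include.
#' @param nPerm,alpha,seed passed to [clusterPermutationTest()].
#' @return list with \code{fitErrorTraces} (named list of subject x window
#'   matrices), \code{naaEditTrace} (matrix), \code{tests} (named list of
#'   [ClusterTestResult-class]).
#' @export
controlTraces <- function(cohort, plan, subjects = subjectIds(cohort),
                          nPerm = 5000, alpha = 0.05, seed = 1) {
  peaks <- c("gaba", "glx", "tnaa", "tcr", "naaedit")
  perSubject <- lapply(subjects, function(id)
    .windowQuantify(cohort, id, plan, peaks))
  names(perSubject) <- subjects
  feTraces <- lapply(c(gaba = "gaba", glx = "glx", tnaa = "tnaa",
                       tcr = "tcr"), function(m) {
    t(vapply(subjects, function(id) {
      fe <- perSubject[[id]][[m]]$fitErrorPct
      fe[!perSubject[[id]][[m]]$ok] <- NA
      fe - fe[1]
    }, numeric(plan$n)))
  })
  naaTrace <- t(vapply(subjects, function(id) {
    a <- perSubject[[id]]$naaedit$area
    a[!perSubject[[id]]$naaedit$ok] <- NA
    100 * (a - a[1]) / a[1]
  }, numeric(plan$n)))
  tests <- lapply(feTraces, clusterPermutationTest, nPerm = nPerm,
                  alpha = alpha, seed = seed, timesS = plan$timesS)
  tests$naaEdit <- clusterPermutationTest(naaTrace, nPerm = nPerm,
                                          alpha = alpha, seed = seed,
                                          timesS = plan$timesS)
  list(fitErrorTraces = feTraces, naaEditTrace = naaTrace, tests = tests)
}

#' Interindividual correlations between per-subject scalars
#'
#' Pearson correlations (two-sided p) between per-subject summary scalars,
#' e.g. last-minus-first-window concentration changes versus fit-error
#' changes or versus frequency drift.
#'
#' @param scalars data.frame of per-subject scalars (>= 4 rows).
#' @param pairs optional two-column character matrix of column pairs; by
#'   default every unordered pair of numeric columns.
#' @return data.frame with columns x, y, r, p, n.
#' @export
interindividualCorrelations <- function(scalars, pairs = NULL) {
  num <- names(scalars)[vapply(scalars, is.numeric, logical(1))]
  if (nrow(scalars) < 4) stop("need at least 4 subjects")
  if (is.null(pairs)) {
    if (length(num) < 2) stop("need at least two numeric columns")
    pairs <- t(utils::combn(num, 2))
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- scalars[[pairs[i, 1]]]; y <- scalars[[pairs[i, 2]]]
    ok <- !is.na(x) & !is.na(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("zero variance in ", pairs[i, 1], " or ", pairs[i, 2])
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(x = pairs[i, 1], y = pairs[i, 2],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  do.call(rbind, out)
}
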