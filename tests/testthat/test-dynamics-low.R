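test_that("window plans satisfy the count law", {
  expect_equal(slidingWindows(256, 128, 2)$n, 65)
  expect_equal(slidingWindows(10, 4, 2)$n, 4)
  expect_equal(slidingWindows(320, 192, 2)$n, 65)
  # exhaustive over all feasible (N, w, s) up to N = 64
  for (N in 4:64) for (w in seq(2, N, 7)) for (s in c(1, 2, 3)) {
    p <- slidingWindows(N, w, s)
    expect_equal(p$n, floor((N - w) / s) + 1)
    expect_true(all(p$starts >= 0 & p$ends <= N))
  }
  expect_error(slidingWindows(100, 128, 2), "width")
  # window-centre times
  p <- slidingWindows(256, 128, 2, trS = 3)
  expect_equal(p$timesS[1], (0 + 127 / 2) * 3)
})

test_that("change traces are zero for constant cohorts and scale-free", {
  coh <- tinyCohort(seed = 31)
  plan <- slidingWindows(64, 32, 4, 3)
  tr <- subjectChangeTrace(coh, "S001", plan, "gaba", "tcr")
  expect_identical(tr[1], 0)
  expect_lt(max(abs(tr)), 0.5)

  # multiplying a subject's spectra by a constant leaves the trace unchanged
  coh2 <- coh
  coh2@spectra[["S001"]] <- coh@spectra[["S001"]] * 5
  tr2 <- subjectChangeTrace(coh2, "S001", plan, "gaba", "tcr")
  expect_equal(tr2, tr, tolerance = 1e-4)

  expect_error(subjectChangeTrace(coh, "S001", plan, "tnaa", "tnaa"),
               "must differ")
})

test_that("a linear ramp yields the closed-form windowed maximum change", {
  d <- -0.10
  tr <- quietTruth(driftTotal = c(gaba = d, glx = 0, tnaa = 0),
                   noiseSd = 1e-4)
  coh <- preprocessCohort(simulateCohort(tinyProfile(128L), tr, 2, seed = 32))
  plan <- slidingWindows(128, 64, 2, 3)
  g <- subjectChangeTrace(coh, "S001", plan, "gaba", "tcr")
  N <- 128; w <- 64
  closed <- 100 * d * (N - w) / (N - 1) / (1 + d * (w - 1) / (2 * (N - 1)))
  expect_equal(g[plan$n], closed, tolerance = 0.03)
  # monotonicity: larger drift, larger maximum |change|
  tr2 <- quietTruth(driftTotal = c(gaba = -0.2, glx = 0, tnaa = 0),
                    noiseSd = 1e-4)
  coh2 <- preprocessCohort(simulateCohort(tinyProfile(128L), tr2, 2, seed = 32))
  g2 <- subjectChangeTrace(coh2, "S001", plan, "gaba", "tcr")
  expect_gt(max(abs(g2)), max(abs(g)))
})

test_that("maximal saturated signal forms one significant full-span cluster", {
  S <- 8; W <- 65
  traces <- matrix(1, S, W)
  traces[, 1] <- 0  # change from first window is identically zero there
  res <- clusterPermutationTest(traces, nPerm = 500, seed = 1)
  expect_s4_class(res, "ClusterTestResult")
  pos <- res@clusters[res@clusters$sign > 0, ]
  expect_equal(nrow(pos), 1)
  expect_equal(c(pos$start, pos$end), c(2, 65))
  expect_true(pos$significant)
  expect_lt(pos$p, 0.05)
})

test_that("cluster masses are exact sums and permutations reproducible", {
  set.seed(40)
  traces <- matrix(rnorm(12 * 20), 12, 20)
  traces[, 8:11] <- traces[, 8:11] + 1.5
  res <- clusterPermutationTest(traces, nPerm = 300, seed = 9)
  tmap <- res@tMap
  tcrit <- qt(0.975, df = 11)
  for (i in seq_len(nrow(res@clusters))) {
    cl <- res@clusters[i, ]
    expect_equal(cl$mass, sum(tmap[cl$start:cl$end]), tolerance = 1e-12)
    expect_true(all(abs(tmap[cl$start:cl$end]) > tcrit))
  }
  res2 <- clusterPermutationTest(traces, nPerm = 300, seed = 9)
  expect_identical(res@clusters, res2@clusters)
  res3 <- clusterPermutationTest(traces, nPerm = 300, seed = 10)
  expect_false(identical(res@nullPos, res3@nullPos))
})

test_that("permutation null matches a brute-force resampling oracle", {
  set.seed(41)
  traces <- matrix(rnorm(4 * 6), 4, 6)
  tcrit <- qt(0.975, df = 3)
  set.seed(2)
  null <- megadyn:::.cpp_cluster_perm_null(traces, tcrit, 5000L, 1L)
  # independent plain-R implementation of the label-shuffle scheme
  oracleMax <- replicate(20000, {
    perm <- t(apply(traces, 1, sample))
    tm <- apply(perm, 2, function(v) mean(v) / (sd(v) / sqrt(length(v))))
    sup <- ifelse(tm > tcrit, tm, 0)
    runs <- rle(sup > 0)
    if (!any(runs$values)) 0 else {
      ends <- cumsum(runs$lengths)
      max(vapply(which(runs$values), function(j)
        sum(sup[(ends[j] - runs$lengths[j] + 1):ends[j]]), numeric(1)))
    }
  })
  # the max-mass distribution is discrete at this tiny size, so compare
  # tail probabilities at common reference points rather than quantiles
  for (q in quantile(oracleMax, c(0.5, 0.8, 0.95), names = FALSE))
    expect_lt(abs(mean(null[, 1] >= q) - mean(oracleMax >= q)), 0.03)
})

test_that("missing windows are excluded pairwise; all-missing errors", {
  set.seed(42)
  traces <- matrix(rnorm(6 * 10), 6, 10)
  traces[1:3, 4] <- NA
  res <- clusterPermutationTest(traces, nPerm = 200, seed = 1)
  expect_length(res@tMap, 10)
  traces[, 4] <- NA
  expect_error(clusterPermutationTest(traces, nPerm = 200, seed = 1),
               "window 4")
})

test_that("control traces stay flat for a stable cohort", {
  tr <- quietTruth(noiseSd = 0.01)
  coh <- preprocessCohort(simulateCohort(tinyProfile(), tr, 5, seed = 44))
  plan <- slidingWindows(64, 32, 8, 3)
  ctl <- controlTraces(coh, plan, nPerm = 300, seed = 3)
  expect_named(ctl$tests, c("gaba", "glx", "tnaa", "tcr", "naaEdit"))
  # constant editing efficiency: negative-tNAA trace centred on zero
  expect_lt(abs(mean(ctl$naaEditTrace[, plan$n], na.rm = TRUE)), 3)
  nSig <- sum(vapply(ctl$tests, function(t)
    sum(t@clusters$significant), integer(1)))
  expect_lte(nSig, 1)
})

test_that("interindividual correlations behave at the edges", {
  df <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  out <- interindividualCorrelations(df)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_error(interindividualCorrelations(df[1:3, ]), "at least 4")
  expect_error(interindividualCorrelations(
    data.frame(a = rep(1, 5), b = rnorm(5))), "zero variance")
})
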