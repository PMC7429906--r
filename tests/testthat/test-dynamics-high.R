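test_that("binning counts, resolution and leftover discard", {
  expect_equal(256 %/% 4, 64)
  expect_equal(traceResolution(vcProfile(), 4), 12)
  expect_equal(traceResolution(pccProfile(), 6), 12)
  expect_equal(traceResolution(acquisitionProfile("x", 10, 1, 1024), 1), 1)

  coh <- tinyCohort(seed = 50, nSubjects = 3)
  g <- binAcrossSubjects(coh, 4)$gaba
  expect_equal(g@nBins, 16L)
  g2 <- binAcrossSubjects(coh, 6)$gaba   # 64 = 10*6 + 4 leftovers
  expect_equal(g2@nBins, 10L)
  expect_equal(diff(g2@timesS), rep(6 * 3, 9))
  # values recover the injected flat ratio
  expect_equal(unname(g@values), rep(0.12, 16), tolerance = 0.02)
})

test_that("normalization modes and their affine equivalence", {
  expect_equal(normalizeTrace(c(1.0, 1.1), "percent_of_mean"),
               c(-100 / 21, 100 / 21), tolerance = 1e-10)
  expect_equal(normalizeTrace(c(1.0, 1.1), "change_from_first"),
               c(0, 10), tolerance = 1e-10)
  cst <- rep(2, 5)
  expect_equal(normalizeTrace(cst, "percent_of_mean"), rep(0, 5))
  expect_equal(normalizeTrace(cst, "change_from_first"), rep(0, 5))
  expect_error(normalizeTrace(rep(0, 4)), "zero")

  set.seed(51)
  a <- rnorm(40, 10); b <- rnorm(40, 10)
  r1 <- crossCorrelation(normalizeTrace(a, "percent_of_mean"),
                         normalizeTrace(b, "percent_of_mean"), 25)
  r2 <- crossCorrelation(normalizeTrace(a, "change_from_first"),
                         normalizeTrace(b, "change_from_first"), 25)
  expect_equal(r1@r, r2@r, tolerance = 1e-12)
})

test_that("smoothing is a shrinking centred moving average", {
  xv <- c(1, 2, 3, 4, 5)
  expect_identical(smoothTrace(xv, 1), xv)
  expect_equal(smoothTrace(rep(3, 10), 8), rep(3, 10))
  expect_equal(smoothTrace(xv, 3)[2], 2)
  # variance reduction ~ 1/w in the interior for white noise
  set.seed(52)
  v <- replicate(150, {
    z <- rnorm(100)
    var(smoothTrace(z, 8)[20:80])
  })
  expect_equal(mean(v), 1 / 8, tolerance = 0.15)
})

test_that("cross-correlation lag bookkeeping matches the study counts", {
  set.seed(53)
  a64 <- rnorm(64); b64 <- rnorm(64)
  cc <- crossCorrelation(a64, b64, 25, dtS = 12)
  expect_equal(sum(cc@lagsS <= 0), 40)   # lags per direction, incl 0
  expect_equal(sum(cc@lagsS >= 0), 40)
  expect_equal(cc@n[cc@lagsS == -9 * 12], 55L)
  expect_equal(length(cc@lagsS), 2 * 40 - 1)

  cc53 <- crossCorrelation(rnorm(53), rnorm(53), 25, dtS = 12)
  expect_equal(sum(cc53@lagsS <= 0), 29)

  # self-correlation at lag zero is exactly 1 (t capped, with a warning)
  expect_warning(ccs <- crossCorrelation(a64, a64, 25, dtS = 12), "capped")
  expect_equal(unname(ccs@r[ccs@lagsS == 0]), 1, tolerance = 1e-12)

  expect_error(crossCorrelation(rnorm(20), rnorm(20), 25), "below the minimum")
  expect_error(crossCorrelation(a64, rnorm(63), 25), "equal length")
})

test_that("antisymmetry and the lag-count law hold exhaustively", {
  set.seed(54)
  for (n in seq(25, 100, 11)) {
    a <- rnorm(n); b <- rnorm(n)
    ab <- crossCorrelation(a, b, 25, dtS = 1)
    ba <- crossCorrelation(b, a, 25, dtS = 1)
    expect_equal(ab@r, rev(ba@r), tolerance = 1e-12)
    expect_equal(sum(ab@lagsS <= 0), n - 25 + 1)
  }
})

test_that("per-lag t statistics and Fisher intervals are correct", {
  # closed form: r = -0.36, n = 55 -> t ~ -2.81, pointwise p < 0.05
  tval <- -0.36 * sqrt((55 - 2) / (1 - 0.36^2))
  expect_equal(tval, -2.81, tolerance = 0.01)
  expect_lt(2 * pt(tval, 53), 0.05)

  set.seed(55)
  a <- rnorm(64); b <- rnorm(64)
  cc <- crossCorrelation(a, b, 25, dtS = 12)
  i <- which(cc@lagsS == 0)
  expect_equal(cc@t[i],
               cc@r[i] * sqrt((cc@n[i] - 2) / (1 - cc@r[i]^2)),
               tolerance = 1e-12)
  z <- atanh(cc@r[i]); se <- 1 / sqrt(cc@n[i] - 3)
  expect_equal(cc@ciLo[i], tanh(z - qnorm(0.975) * se), tolerance = 1e-12)
})

test_that("cross-correlation cluster test controls false positives", {
  set.seed(56)
  hits <- replicate(200, {
    cc <- crossCorrelation(rnorm(64), rnorm(64), 25, dtS = 12)
    cc <- crossCorrClusterTest(cc, nPerm = 400, seed = sample.int(1e6, 1))
    cl <- cc@clusters
    c(ab = any(cl$significant[cl$direction == "A_precedes_B"]),
      ba = any(cl$significant[cl$direction == "B_precedes_A"]))
  })
  expect_lte(mean(hits["ab", ]), 0.07)
  expect_lte(mean(hits["ba", ]), 0.07)
})

test_that("an injected lagged anti-coupling is localised correctly", {
  set.seed(57)
  found <- replicate(20, {
    g <- as.numeric(arima.sim(list(ar = 0.5), 74, sd = 1))
    glx <- -0.8 * g[1:64] + rnorm(64, 0, 0.6)
    gaba <- g[11:74]
    cc <- crossCorrClusterTest(crossCorrelation(gaba, glx, 25, dtS = 12),
                               nPerm = 500, seed = sample.int(1e6, 1))
    rs <- cc@r; rs[!cc@significantMask | rs > 0] <- NA
    if (all(is.na(rs))) NA_real_ else cc@lagsS[which.min(rs)]
  })
  expect_gte(mean(!is.na(found)), 0.8)
  expect_gte(mean(abs(found[!is.na(found)] + 120) <= 12), 0.8)
})

test_that("low/high cross-validation recovers a shared ramp", {
  d <- -0.15
  tr <- quietTruth(driftTotal = c(gaba = d, glx = 0, tnaa = 0),
                   noiseSd = 1e-4)
  coh <- preprocessCohort(simulateCohort(tinyProfile(128L), tr, 3, seed = 58))
  plan <- slidingWindows(128, 64, 4, 3)
  low <- colMeans(changeTraces(coh, plan, "gaba", "tcr"), na.rm = TRUE)
  high <- binAcrossSubjects(coh, 4)$gaba
  v <- validateLowHigh(low, high, plan, 4)
  expect_gt(v$r, 0.999)
  expect_equal(v$n, 128 / 4 - 64 / 4 + 1)

  badPlan <- slidingWindows(128, 64, 3, 3)
  expect_error(validateLowHigh(low, high, badPlan, 4), "grid mismatch")
  oddPlan <- slidingWindows(128, 62, 2, 3)
  expect_error(validateLowHigh(low, high, oddPlan, 4), "whole number")
})
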