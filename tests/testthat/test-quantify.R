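prof <- tinyProfile()
x <- ppmAxis(prof)
lar <- larmorMhz(prof)

test_that("fitted areas and FWHMs match closed forms on noiseless peaks", {
  # Gaussian: A = 1, sigma = 0.04 ppm
  y <- exp(-0.5 * ((x - 3.0) / 0.04)^2)
  f <- fitPeak(y, x, "gaussian", 3.0, c(2.8, 3.3), lar, 0.05)
  expect_true(f@ok)
  expect_equal(f@area, 1 * 0.04 * sqrt(2 * pi), tolerance = 1e-3)
  expect_equal(f@fwhmHz, 2 * 0.04 * sqrt(2 * log(2)) * lar, tolerance = 1e-3)

  # Lorentzian with gamma = 4.25 Hz -> FWHM 8.5 Hz
  g <- 4.25 / lar
  y2 <- 0.7 / (1 + ((x - 3.0) / g)^2)
  f2 <- fitPeak(y2, x, "lorentzian", 3.0, c(2.6, 3.4), lar, 0.03)
  expect_equal(f2@fwhmHz, 8.5, tolerance = 1e-3)
  expect_equal(f2@area, pi * 0.7 * g, tolerance = 1e-3)

  # inverse Lorentzian returns the magnitude of the negative lobe
  f3 <- fitPeak(-y2, x, "inverse_lorentzian", 3.0, c(2.6, 3.4), lar, 0.03)
  expect_true(f3@ok)
  expect_equal(f3@area, pi * 0.7 * g, tolerance = 1e-3)

  # double Gaussian area is the sum of both components
  y4 <- 0.5 * exp(-0.5 * ((x - 3.71) / 0.045)^2) +
        0.4 * exp(-0.5 * ((x - 3.79) / 0.045)^2)
  f4 <- fitPeak(y4, x, "double_gaussian", c(3.71, 3.79), c(3.45, 4.10),
                lar, 0.05)
  expect_true(f4@ok)
  expect_equal(f4@area, (0.5 + 0.4) * 0.045 * sqrt(2 * pi), tolerance = 1e-3)
})

test_that("line-shape closed forms agree with numerical quadrature", {
  A <- 0.7; g <- 0.0333
  num <- integrate(function(f) A / (1 + ((f - 3) / g)^2), -Inf, Inf)$value
  expect_equal(lorentzianArea(A, g), num, tolerance = 1e-6)
  s <- 0.083
  num2 <- integrate(function(f) A * exp(-0.5 * ((f - 3) / s)^2),
                    -Inf, Inf)$value
  expect_equal(gaussianArea(A, s), num2, tolerance = 1e-6)
})

test_that("peak fitting agrees with an independent NLS implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(3)
  y <- 0.5 * exp(-0.5 * ((x - 3.02) / 0.07)^2) + 0.01 +
    rnorm(length(x), 0, 0.004)
  win <- x >= 2.8 & x <= 3.3
  f <- fitPeak(y, x, "gaussian", 3.0, c(2.8, 3.3), lar, 0.08)
  d <- data.frame(x = x[win], y = y[win])
  m <- minpack.lm::nlsLM(
    y ~ A * exp(-0.5 * ((x - f0) / s)^2) + b0 + b1 * (x - 3.05),
    data = d, start = list(A = 0.4, f0 = 3.0, s = 0.08, b0 = 0, b1 = 0))
  cf <- coef(m)
  expect_equal(unname(f@params["amplitude"]), unname(cf["A"]),
               tolerance = 1e-4)
  expect_equal(unname(f@params["center"]), unname(cf["f0"]),
               tolerance = 1e-5)
  expect_equal(unname(abs(f@params["width"])), unname(abs(cf["s"])),
               tolerance = 1e-4)
})

test_that("area recovery is unbiased and fit error grows with noise", {
  set.seed(11)
  trueArea <- 0.06 * 0.083 * sqrt(2 * pi)
  res <- sapply(c(0.002, 0.008), function(ns) {
    runs <- replicate(60, {
      y <- 0.06 * exp(-0.5 * ((x - 3.0) / 0.083)^2) + rnorm(length(x), 0, ns)
      f <- fitPeak(y, x, "gaussian", 3.0, c(2.8, 3.3), lar, 0.08)
      c(f@area, f@fitErrorPct)
    })
    c(medArea = median(runs[1, ]), medErr = median(runs[2, ]))
  })
  expect_lt(abs(res["medArea", 1] - trueArea) / trueArea, 0.02)
  expect_lt(abs(res["medArea", 2] - trueArea) / trueArea, 0.1)
  expect_gt(res["medErr", 2], res["medErr", 1])  # monotone in noise
})

test_that("quantifySelection recovers injected ratios and is scale-free", {
  areas <- vcAreas()
  off <- synthesizeTransient(prof, areas, "OFF")
  on <- synthesizeTransient(prof, areas, "ON")
  q <- quantifySelection(off, on - off, x, lar)
  expect_true(q$ok)
  expect_equal(q$gaba_ratio, 0.12, tolerance = 0.02)
  expect_equal(q$glx_ratio, 0.15, tolerance = 0.02)
  expect_equal(q$tnaa_ratio, 1.40, tolerance = 0.02)

  q3 <- quantifySelection(3 * off, 3 * (on - off), x, lar)
  expect_equal(q3$gaba_ratio, q$gaba_ratio, tolerance = 1e-6)
  expect_equal(q3$glx_ratio, q$glx_ratio, tolerance = 1e-6)

  # algebraic identity when the reference switches to tNAA
  qn <- quantifySelection(off, on - off, x, lar, reference = "tnaa")
  expect_equal(qn$gaba_ratio, q$gaba_ratio * q$tcr_area / q$tnaa_area,
               tolerance = 1e-10)
})

test_that("CSF correction implements division by (1 - fcsf)", {
  expect_equal(csfCorrect(1.0, 0), 1.0)
  expect_equal(csfCorrect(1.2, 0.25), 1.6)
  xv <- c(0.3, 1.7, 2.2)
  expect_equal(csfCorrect(xv, 0.5), 2 * xv)
  # strictly increasing in fcsf
  fr <- seq(0, 0.9, 0.1)
  expect_true(all(diff(csfCorrect(1, fr)) > 0))
  expect_error(csfCorrect(1, 1), "\\[0, 1\\)")
  expect_error(csfCorrect(1, -0.1), "\\[0, 1\\)")
})

test_that("FWHM-based participant exclusion flags only gross outliers", {
  fw <- data.frame(tcr = rep(8.5, 10), tnaa = rep(8.4, 10),
                   gaba = rep(25, 10), glx = rep(17.8, 10))
  expect_true(all(excludeParticipantsByFwhm(fw)))  # homogeneous

  set.seed(21)
  # inliers drawn within +-2 SD so only the planted outlier can trip the rule
  fw58 <- data.frame(tcr = 8.5 + 0.2 * runif(58, -2, 2),
                     tnaa = 8.4 + 0.2 * runif(58, -2, 2),
                     gaba = 25 + 0.8 * runif(58, -2, 2),
                     glx = 17.8 + 0.5 * runif(58, -2, 2))
  fw58$tcr[13] <- mean(fw58$tcr) + 6 * sd(fw58$tcr)  # ~6 SD high
  keep <- excludeParticipantsByFwhm(fw58)
  expect_false(keep[13])
  expect_equal(sum(keep), 57)

  # fixed point: re-applying to the retained set flags no one else
  expect_true(all(excludeParticipantsByFwhm(fw58[keep, ])))
})

test_that("a broadened-linewidth subject is excluded end to end", {
  tr <- quietTruth(noiseSd = 0.005, baselineSd = c(gaba = 0.005, glx = 0.005,
                                                   tnaa = 0.02))
  # n must be large enough that one outlier cannot hide by inflating the
  # cohort SD (max attainable |z| is (n-1)/sqrt(n))
  coh <- preprocessCohort(simulateCohort(tinyProfile(), tr, nSubjects = 14,
                                         seed = 12, nBroad = 1))
  st <- staticEstimates(coh)
  expect_equal(sum(st$included), 13)
  expect_false(st$included[st$subject == "S014"])
})

test_that("static estimates recover baselines, ramp means and CSF identity", {
  # null cohort: static ratio ~ injected baseline
  coh <- tinyCohort(seed = 14, nSubjects = 3)
  st <- staticEstimates(coh)
  expect_equal(st$gaba_ratio, rep(0.12, 3), tolerance = 0.02)
  # corrected > raw unless csf = 0
  expect_true(all(st$gaba_ratio_corr >= st$gaba_ratio))
  expect_equal(st$gaba_ratio_corr, st$gaba_ratio / (1 - st$csf),
               tolerance = 1e-12)

  # drifting cohort: static estimate ~ baseline * (1 + drift/2)
  trd <- quietTruth(driftTotal = c(gaba = -0.2, glx = 0, tnaa = 0),
                    noiseSd = 1e-4)
  cohd <- preprocessCohort(simulateCohort(tinyProfile(), trd, 3, seed = 15))
  std <- staticEstimates(cohd)
  expect_equal(mean(std$gaba_ratio), 0.12 * (1 - 0.2 / 2), tolerance = 0.01)
})

test_that("partial correlation matches formula and regression residuals", {
  # exact sample correlations via orthonormal construction
  n <- 12
  set.seed(5)
  Z <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  S <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3)
  Xm <- Q %*% chol(S)
  pc <- partialCorrelation(Xm[, 1], Xm[, 2], Xm[, 3])
  expect_equal(pc$r, (0.5 - 0.25) / 0.75, tolerance = 1e-10)  # = 1/3

  # regression-residual oracle on random data
  set.seed(6)
  xr <- rnorm(30); zr <- rnorm(30); yr <- 0.4 * xr + 0.3 * zr + rnorm(30)
  pc2 <- partialCorrelation(xr, yr, zr)
  rres <- cor(resid(lm(xr ~ zr)), resid(lm(yr ~ zr)))
  expect_equal(pc2$r, rres, tolerance = 1e-10)

  # z uncorrelated (exactly orthogonal) with x and y: reduces to plain r
  zo <- Q[, 3]
  pc3 <- partialCorrelation(Xm[, 1], Xm[, 2] - sum(Xm[, 2] * zo) * zo, zo)
  expect_equal(pc3$r,
               cor(Xm[, 1], Xm[, 2] - sum(Xm[, 2] * zo) * zo),
               tolerance = 1e-10)

  expect_error(partialCorrelation(xr, yr, xr), "collinear")
  expect_error(partialCorrelation(rep(1, 10), rnorm(10), rnorm(10)),
               "zero variance")
})

test_that("group comparison gates on normality and has power", {
  set.seed(7)
  a <- rnorm(40)
  r0 <- compareGroups(a, a)
  expect_equal(r0$p, 1, tolerance = 1e-6)
  expect_lt(abs(r0$statistic), 1e-10)

  runs <- replicate(60, {
    g1 <- rnorm(100, 0); g2 <- rnorm(100, 1)
    r <- compareGroups(g1, g2)
    c(sig = r$p < 0.001, t = r$test == "t")
  })
  expect_gte(mean(runs["sig", ]), 0.95)
  # the Shapiro gate itself rejects ~10% of truly normal pairs
  expect_gt(mean(runs["t", ]), 0.7)

  heavy <- replicate(40, {
    g1 <- rcauchy(50); g2 <- rcauchy(50)
    compareGroups(g1, g2)$test
  })
  expect_gt(mean(heavy == "rank-sum"), 0.5)
})
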