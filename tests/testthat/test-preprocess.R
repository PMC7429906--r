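prof <- tinyProfile()
x <- ppmAxis(prof)
lar <- larmorMhz(prof)
crOnly <- c(tcr = 0.1046, tnaa = 0, gaba = 0, glx = 0, naaedit = 0)

test_that("reference fit recovers injected Cr parameters", {
  sp <- synthesizeTransient(prof, crOnly, "OFF")
  f <- fitReferencePeak(sp, x, lar)
  expect_true(f$ok)
  expect_equal(f$freqPpm, 3.0, tolerance = 1e-3)
  expect_lt(abs(f$fwhmHz - 8.5), 0.05)
  expect_equal(f$area, 0.1046, tolerance = 1e-3)

  sh <- synthesizeTransient(prof, crOnly, "OFF", freqOffsetPpm = 0.02)
  expect_lt(abs(fitReferencePeak(sh, x, lar)$freqPpm - 3.02), 1e-3)

  ph <- synthesizeTransient(prof, crOnly, "OFF", phaseOffsetDeg = 30)
  expect_lt(abs(fitReferencePeak(ph, x, lar)$phaseDeg - 30), 1)
})

test_that("reference fit is scale-equivariant in area only", {
  sp <- synthesizeTransient(prof, vcAreas(), "OFF", noiseSd = 0)
  f1 <- fitReferencePeak(sp, x, lar)
  f2 <- fitReferencePeak(3 * sp, x, lar)
  expect_equal(f2$area / f1$area, 3, tolerance = 1e-6)
  expect_equal(f2$freqPpm, f1$freqPpm, tolerance = 1e-9)
  expect_equal(f2$fwhmHz, f1$fwhmHz, tolerance = 1e-6)
  expect_equal(f2$phaseDeg, f1$phaseDeg, tolerance = 1e-6)
})

test_that("outlier rejection drops exactly the deviant transients", {
  base <- data.frame(freqPpm = rep(3, 100), phaseDeg = rep(0, 100),
                     area = rep(1, 100), fwhmHz = rep(8.5, 100), ok = TRUE)
  expect_true(all(rejectOutlierTransients(base)))  # identical -> all retained

  set.seed(4)
  fits <- data.frame(freqPpm = rnorm(100, 3, 0.005),
                     phaseDeg = rnorm(100, 0, 3),
                     area = rnorm(100, 1, 0.02),
                     fwhmHz = rnorm(100, 8.5, 0.2), ok = TRUE)
  fits$freqPpm[37] <- 3 + 10 * 0.005 * 4   # far outlier
  keep <- rejectOutlierTransients(fits, k = 3)
  expect_false(keep[37])

  expect_error(rejectOutlierTransients(fits[1:2, ]), "at least 3")
})

test_that("retention fraction matches a brute-force z-rule oracle", {
  set.seed(9)
  n <- 10000
  fits <- data.frame(freqPpm = rnorm(n), phaseDeg = rnorm(n),
                     area = rnorm(n, 10), fwhmHz = rnorm(n, 8.5), ok = TRUE)
  keep <- rejectOutlierTransients(fits, k = 3)
  oracle <- rep(TRUE, n)  # independent plain-R implementation
  for (p in c("freqPpm", "phaseDeg", "area", "fwhmHz")) {
    z <- (fits[[p]] - mean(fits[[p]])) / sd(fits[[p]])
    oracle <- oracle & abs(z) <= 3
  }
  expect_identical(keep, oracle)
  # close to the independence approximation P(|z|<=3)^4
  expect_lt(abs(mean(keep) - (1 - 2 * pnorm(-3))^4), 0.01)
})

test_that("mask monotonicity: smaller k never retains more", {
  set.seed(2)
  fits <- data.frame(freqPpm = rnorm(50, 3, 0.01), phaseDeg = rnorm(50, 0, 4),
                     area = rnorm(50, 1, 0.05), fwhmHz = rnorm(50, 8.5, 0.3),
                     ok = TRUE)
  k4 <- rejectOutlierTransients(fits, k = 4)
  k3 <- rejectOutlierTransients(fits, k = 3)
  k2 <- rejectOutlierTransients(fits, k = 2)
  expect_true(all(k3 <= k4))
  expect_true(all(k2 <= k3))
})

test_that("frequency/phase correction inverts the applied offsets", {
  sp <- synthesizeTransient(prof, crOnly, "OFF", freqOffsetPpm = 0.01,
                            phaseOffsetDeg = 25)
  f <- fitReferencePeak(sp, x, lar)
  corr <- applyFreqPhaseCorrection(sp, x, f)
  f2 <- fitReferencePeak(corr, x, lar)
  expect_equal(f2$freqPpm, 3.0, tolerance = 1e-4)
  expect_lt(abs(f2$phaseDeg), 0.5)
  # residual phase ~ 0: the dispersion (imaginary) component is odd about
  # the centre, so its symmetric integral vanishes for a dephased peak
  win <- abs(x - 3.0) < 0.2
  expect_lt(abs(Arg(sum(corr[win]))) * 180 / pi, 2)

  # identity when no offset is present
  clean <- synthesizeTransient(prof, crOnly, "OFF")
  id <- applyFreqPhaseCorrection(clean, x,
                                 data.frame(freqPpm = 3, phaseDeg = 0))
  expect_lt(max(Mod(id - clean)), 1e-10)

  # idempotence: a second correction changes (almost) nothing
  f3 <- fitReferencePeak(corr, x, lar)
  corr2 <- applyFreqPhaseCorrection(corr, x, f3)
  expect_lt(max(Mod(corr2 - corr)) / max(Mod(corr)), 1e-3)

  # degenerate fit -> error
  expect_error(
    applyFreqPhaseCorrection(sp, x, data.frame(freqPpm = 3 + 20, phaseDeg = 0)),
    "half the spectral width")
})

test_that("frequency drift is the SD of pre-alignment OFF Cr positions", {
  f <- data.frame(freqPpm = c(3.00, 3.01, 3.00, 3.01),
                  condition = c("OFF", "OFF", "ON", "ON"), ok = TRUE)
  expect_equal(frequencyDrift(f, rep(TRUE, 4)), sd(c(3, 3.01)),
               tolerance = 1e-12)
  fc <- data.frame(freqPpm = rep(3, 4), condition = rep("OFF", 4), ok = TRUE)
  expect_equal(frequencyDrift(fc), 0)
  expect_error(frequencyDrift(f[3:4, ]), "at least 2")
})

test_that("generator frequency jitter is recovered by the drift metric", {
  tr <- quietTruth(freqJitterPpm = 0.0088, noiseSd = 0.01)
  coh <- simulateCohort(tinyProfile(128L), tr, nSubjects = 4, seed = 6)
  coh <- preprocessCohort(coh)
  rf <- referenceFits(coh)
  ret <- retainedTransients(coh)
  drifts <- vapply(names(rf), function(id)
    frequencyDrift(rf[[id]], ret[[id]]), numeric(1))
  expect_lt(abs(mean(drifts) - 0.0088) / 0.0088, 0.2)
})

test_that("averaging and differencing obey the ON/OFF contract", {
  coh <- tinyCohort(seed = 5)
  S <- spectra(coh, "S001")
  conds <- conditions(coh)
  avg <- averageAndDifference(S, conds)
  expect_equal(avg$diff, avg$meanOn - avg$meanOff)
  expect_equal(avg$nOn + avg$nOff, nTransients(coh))
  # identical ON and OFF -> zero difference
  S2 <- S; S2[, conds == "ON"] <- S[, conds == "OFF"]
  expect_equal(max(Mod(averageAndDifference(S2, conds)$diff)), 0)
  # a selection devoid of one condition errors, naming the window
  expect_error(averageAndDifference(S, conds, selection = 1),
               "no retained ON")
})

test_that("difference-spectrum noise follows sqrt(2/n) error propagation", {
  set.seed(8)
  s <- 0.05; n <- 32
  sds <- replicate(200, {
    spectra <- matrix(complex(real = rnorm(64 * 2 * n, 0, s),
                              imaginary = rnorm(64 * 2 * n, 0, s)),
                      nrow = 64)
    conds <- rep(c("OFF", "ON"), n)
    sd(Re(averageAndDifference(spectra, conds)$diff))
  })
  expect_equal(mean(sds), s * sqrt(2 / n), tolerance = 0.03)
})

test_that("preprocessing aligns a jittered cohort and stores masks", {
  tr <- quietTruth(freqJitterPpm = 0.005, phaseJitterDeg = 4, noiseSd = 0.01)
  coh <- preprocessCohort(simulateCohort(tinyProfile(), tr, 3, seed = 2))
  rf <- referenceFits(coh)
  expect_named(rf, subjectIds(coh))
  # corrected spectra refit at 3.0 ppm with ~zero phase
  post <- fitReferencePeak(spectra(coh, "S001")[, 1], ppm(coh), lar)
  expect_equal(post$freqPpm, 3.0, tolerance = 2e-3)
  expect_lt(abs(post$phaseDeg), 2)
  expect_true(all(lengths(retainedTransients(coh)) == nTransients(coh)))
  expect_error(retainedTransients(tinyCohort(preprocess = FALSE)),
               "preprocessCohort")
})
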