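# shared fixtures, built in code and memoized per test run

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small acquisition for fast unit tests: same spectral geometry, fewer
# transients and points
tinyProfile <- function(nTransients = 64L) {
  acquisitionProfile("tiny", nTransients, trS = 3, nPoints = 1024L)
}

# quiet truth: no dynamics, mild noise, no jitter (overrides win)
quietTruth <- function(...) {
  args <- utils::modifyList(
    list(noiseSd = 1e-4, freqJitterPpm = 0, phaseJitterDeg = 0,
         baselineSd = c(gaba = 0, glx = 0, tnaa = 0)),
    list(...))
  do.call(nullGroundTruth, args)
}

tinyCohort <- function(seed = 1, truth = quietTruth(), nSubjects = 3,
                       nTransients = 64L, preprocess = TRUE) {
  coh <- simulateCohort(tinyProfile(nTransients), truth, nSubjects,
                        seed = seed)
  if (preprocess) preprocessCohort(coh) else coh
}

# canonical VC-like areas for single-transient fixtures (ratios to tCr area)
vcAreas <- function(tcr = 1) {
  base <- pi * 1 * (8.5 / 2) / 127.7 * tcr
  c(tcr = base, tnaa = 1.4 * base, gaba = 0.12 * base, glx = 0.15 * base,
    naaedit = 0.45 * base)
}

# full-size preprocessed VC cohort with default dynamics, shared across
# acceptance-level tests (expensive: built once)
vcBundle <- function(seed) {
  memo(paste0("vc", seed), {
    coh <- preprocessCohort(simulateCohort(vcProfile(), defaultGroundTruth(),
                                           nSubjects = 57, seed = seed))
    plan <- slidingWindows(256, 128, 2, 3)
    trG <- changeTraces(coh, plan, "gaba", "tcr")
    trX <- changeTraces(coh, plan, "glx", "tcr")
    high <- binAcrossSubjects(coh, 4)
    list(cohort = coh, plan = plan, gaba = trG, glx = trX, high = high)
  })
}
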