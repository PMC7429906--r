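#' @include AllClasses.R utils.R synthetic.R preprocess.R quantify.R
#' @include dynamics-low.R dynamics-high.R
NULL

#' Default pipeline configuration
#'
#' Every parameter defaults to the study value: sliding window width 128
#' transients (VC) or 192 (PCC) with step 2; high-resolution bins of 4 (VC)
#' or 6 (PCC) transients, i.e. 12 s; minimum cross-correlation overlap 25
#' bins; 5000 permutations at alpha 0.05; 3 SD outlier thresholds; tCr
#' reference.
#'
#' @param profile \code{"vc"}, \code{"pcc"}, or an
#'   [AcquisitionProfile-class].
#' @param ... overrides of any configuration element.
#' @return named list of configuration values.
#' @export
defaultConfig <- function(profile = "vc", ...) {
  prof <- if (is(profile, "AcquisitionProfile")) profile
          else switch(profile, vc = vcProfile(), pcc = pccProfile(),
                      stop("unknown profile '", profile, "'"))
  cfg <- list(
    profile = prof,
    nSubjects = 58L,
    nBroad = 0L,
    seed = 1L,
    truth = if (prof@name == "pcc") nullGroundTruth() else defaultGroundTruth(),
    width = if (prof@name == "pcc") 192L else 128L,
    step = 2L,
    binSize = binSizeForProfile(prof),
    minOverlap = 25L,
    nPerm = 5000L,
    alpha = 0.05,
    clusterAlpha = 0.05,
    k = 3,
    reference = "tcr",
    normalization = "percent_of_mean",
    metabolites = c("gaba", "glx", "tnaa"),
    runControls = FALSE,
    cohortPath = NULL,
    outDir = NULL
  )
  utils::modifyList(cfg, list(...))
}

.validateConfig <- function(cfg) {
  nT <- cfg$profile@nTransients
  if (cfg$width > nT)
    stop("config error: window width (", cfg$width,
         ") exceeds nTransients (", nT, ")")
  if (cfg$step < 1) stop("config error: step must be >= 1")
  if (nT %/% cfg$binSize < cfg$minOverlap)
    stop("config error: fewer bins than the minimum overlap")
  if (!cfg$reference %in% c("tcr", "tnaa"))
    stop("config error: reference must be 'tcr' or 'tnaa'")
  invisible(cfg)
}

#' Run the full dynamics pipeline
#'
#' Simulates (or loads) a cohort, preprocesses it, computes static
#' estimates with CSF correction and FWHM-based participant exclusion, runs
#' the low-resolution sliding-window analysis with cluster-permutation
#' inference for each metabolite, the high-resolution across-subject
#' binning with cluster-corrected GABA+/Glx cross-correlation, and the
#' low/high cross-validation.  When \code{config$outDir} is set, CSV result
#' tables and a YAML run manifest are written there.
#'
#' @param config a [defaultConfig()] list.
#' @return list with elements \code{cohort}, \code{static}, \code{plan},
#'   \code{traces}, \code{clusterTests}, \code{groupTraces},
#'   \code{crossCorr}, \code{validation}, \code{drift}, \code{controls}
#'   (when requested) and \code{counts}.
#' @export
runPipeline <- function(config = defaultConfig()) {
  cfg <- .validateConfig(config)
  prof <- cfg$profile

  cohort <- if (!is.null(cfg$cohortPath)) readCohort(cfg$cohortPath)
            else simulateCohort(prof, cfg$truth, cfg$nSubjects,
                                seed = cfg$seed, nBroad = cfg$nBroad)
  cohort <- preprocessCohort(cohort, k = cfg$k)

  static <- staticEstimates(cohort, reference = cfg$reference, k = cfg$k)
  included <- static$subject[static$included]
  if (length(included) < 3)
    stop("pipeline error at stage 'static': fewer than 3 retained subjects")

  plan <- slidingWindows(nTransients(cohort), cfg$width, cfg$step,
                         trS(cohort))
  traces <- list()
  clusterTests <- list()
  for (m in cfg$metabolites) {
    traces[[m]] <- changeTraces(cohort, plan, m, cfg$reference,
                                subjects = included)
    clusterTests[[m]] <- clusterPermutationTest(
      traces[[m]], nPerm = cfg$nPerm, alpha = cfg$alpha,
      clusterAlpha = cfg$clusterAlpha, seed = cfg$seed,
      timesS = plan$timesS)
  }

  groupTraces <- binAcrossSubjects(cohort, cfg$binSize,
                                   metabolites = cfg$metabolites,
                                   reference = cfg$reference,
                                   subjects = included)
  norm <- lapply(groupTraces, normalizeTrace, mode = cfg$normalization)
  cc <- crossCorrelation(norm$gaba, norm$glx, minOverlap = cfg$minOverlap)
  cc <- crossCorrClusterTest(cc, nPerm = cfg$nPerm, alpha = cfg$alpha,
                             clusterAlpha = cfg$clusterAlpha,
                             seed = cfg$seed)

  lowMean <- colMeans(traces$gaba, na.rm = TRUE)
  validation <- list(gaba = validateLowHigh(lowMean, groupTraces$gaba,
                                            plan, cfg$binSize),
                     glx = validateLowHigh(colMeans(traces$glx, na.rm = TRUE),
                                           groupTraces$glx, plan,
                                           cfg$binSize))

  refFits <- referenceFits(cohort)
  retained <- retainedTransients(cohort)
  drift <- vapply(included, function(id)
    frequencyDrift(refFits[[id]], retained[[id]]), numeric(1))

  controls <- if (isTRUE(cfg$runControls))
    controlTraces(cohort, plan, subjects = included, nPerm = cfg$nPerm,
                  alpha = cfg$alpha, seed = cfg$seed) else NULL

  counts <- list(
    subjects = nSubjects(cohort),
    subjectsIncluded = length(included),
    transientsRetained = vapply(retained, sum, integer(1)),
    windows = plan$n,
    bins = groupTraces[[1]]@nBins,
    lagsPerDirection = sum(cc@lagsS <= 0)
  )

  bundle <- list(cohort = cohort, static = static, plan = plan,
                 traces = traces, clusterTests = clusterTests,
                 groupTraces = groupTraces, crossCorr = cc,
                 validation = validation, drift = drift,
                 controls = controls, counts = counts, config = cfg)
  if (!is.null(cfg$outDir)) .writeBundle(bundle, cfg)
  bundle
}

.writeBundle <- function(bundle, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  plan <- bundle$plan
  for (m in names(bundle$traces)) {
    tm <- bundle$clusterTests[[m]]
    df <- data.frame(
      region = cfg$profile@name, metabolite = m, time_s = plan$timesS,
      group_mean_pct = colMeans(bundle$traces[[m]], na.rm = TRUE),
      sem = apply(bundle$traces[[m]], 2, function(v)
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
      t = tm@tMap, significant = tm@significantMask)
    .writeCsv(df, file.path(cfg$outDir, paste0("trace_low_", m, ".csv")),
              "region,metabolite,time_s,group_mean_pct,sem,t,significant")
  }
  for (m in names(bundle$groupTraces)) {
    g <- bundle$groupTraces[[m]]
    .writeCsv(data.frame(metabolite = m, time_s = g@timesS,
                         value = g@values),
              file.path(cfg$outDir, paste0("trace_high_", m, ".csv")),
              "metabolite,time_s,value")
  }
  cc <- bundle$crossCorr
  .writeCsv(data.frame(lag_s = cc@lagsS, r = cc@r, n = cc@n,
                       ci_lo = cc@ciLo, ci_hi = cc@ciHi, t = cc@t,
                       significant = cc@significantMask),
            file.path(cfg$outDir, "crosscorr.csv"),
            "lag_s,r,n,ci_lo,ci_hi,t,significant")
  .writeCsv(bundle$static, file.path(cfg$outDir, "static.csv"),
            paste(names(bundle$static), collapse = ","))
  refFits <- referenceFits(bundle$cohort)
  retained <- retainedTransients(bundle$cohort)
  rf <- do.call(rbind, lapply(names(refFits), function(id) {
    cbind(data.frame(subject = id), refFits[[id]],
          retained = retained[[id]])
  }))
  .writeCsv(rf, file.path(cfg$outDir, "reference_fits.csv"),
            "subject,freqPpm,phaseDeg,area,fwhmHz,residSd,ok,condition,index,retained")
  manifest <- list(
    profile = cfg$profile@name, nSubjects = cfg$nSubjects,
    seed = cfg$seed, width = cfg$width, step = cfg$step,
    binSize = cfg$binSize, minOverlap = cfg$minOverlap,
    nPerm = cfg$nPerm, alpha = cfg$alpha, reference = cfg$reference,
    counts = lapply(bundle$counts, function(x)
      if (length(x) > 1) unname(as.list(x)) else x),
    package = as.character(utils::packageVersion("megadyn")))
  yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yaml"))
}

#' Write / read a cohort
#'
#' Serializes a [MegaCohort-class] to an RDS file plus a human-readable YAML
#' sidecar (\code{<path>.yaml}) carrying the tissue fractions and, for
#' synthetic cohorts, the generating ground-truth parameters.  The
#' round-trip is lossless.
#'
#' @param cohort a [MegaCohort-class].
#' @param path file path (conventionally \code{.rds}).
#' @return \code{writeCohort}: the path, invisibly; \code{readCohort}: the
#'   [MegaCohort-class].
#' @rdname cohortIO
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "MegaCohort"))
  payload <- list(
    format = "megadyn-cohort-1",
    spectra = cohort@spectra, conditions = cohort@conditions,
    ppm = cohort@ppm,
    profile = list(name = cohort@profile@name,
                   nTransients = cohort@profile@nTransients,
                   trS = cohort@profile@trS,
                   nPoints = cohort@profile@nPoints,
                   sweepHz = cohort@profile@sweepHz,
                   larmorMhz = cohort@profile@larmorMhz,
                   residualWater = cohort@profile@residualWater),
    tissue = cohort@tissue, truth = cohort@truth,
    processing = cohort@processing)
  saveRDS(payload, path)
  sidecar <- list(format = payload$format,
                  profile = payload$profile,
                  tissue = as.list(cohort@tissue))
  if (!is.null(cohort@truth)) {
    tr <- cohort@truth$truth
    sidecar$groundTruth <- list(
      baselineRatio = as.list(tr@baselineRatio),
      driftTotal = as.list(tr@driftTotal),
      latentSd = tr@latentSd, latentAr = tr@latentAr,
      couplingKappa = tr@couplingKappa,
      couplingDelayBins = tr@couplingDelayBins,
      innovationSd = tr@innovationSd, noiseSd = tr@noiseSd,
      freqJitterPpm = tr@freqJitterPpm,
      scannerDriftPpm = tr@scannerDriftPpm,
      phaseJitterDeg = tr@phaseJitterDeg,
      editEfficiency = tr@editEfficiency,
      seed = cohort@truth$seed)
  }
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname cohortIO
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  payload <- readRDS(path)
  if (!identical(payload$format, "megadyn-cohort-1"))
    stop("not a megadyn cohort file (missing/unknown 'format')")
  for (el in c("spectra", "conditions", "ppm", "profile", "tissue"))
    if (is.null(payload[[el]]))
      stop("malformed cohort file: missing element '", el, "'")
  p <- payload$profile
  for (at in c("name", "nTransients", "trS", "nPoints", "sweepHz",
               "larmorMhz"))
    if (is.null(p[[at]]))
      stop("malformed cohort file: missing profile attribute '", at, "'")
  prof <- acquisitionProfile(p$name, p$nTransients, p$trS, p$nPoints,
                             p$sweepHz, p$larmorMhz,
                             isTRUE(p$residualWater))
  new("MegaCohort", spectra = payload$spectra,
      conditions = payload$conditions, ppm = payload$ppm, profile = prof,
      tissue = payload$tissue, truth = payload$truth,
      processing = payload$processing %||% list())
}
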