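#' @include AllClasses.R
NULL

#' Construct a ground-truth parameter set
#'
#' All arguments have defaults equal to the calibrated visual-cortex study
#' conditions; see [defaultGroundTruth()] and [nullGroundTruth()] for the two
#' standard configurations and the methods vignette for how the defaults were
#' chosen.
#'
#' @param baselineRatio named means of GABA+:tCr, Glx:tCr, tNAA:tCr.
#' @param baselineSd across-subject SDs of the same ratios.
#' @param driftTotal fractional endpoint-to-endpoint linear concentration
#'   change per metabolite over the acquisition.
#' @param latentSd stationary SD of the cohort-shared AR(1) GABA fluctuation
#'   (fractional units per high-resolution bin).
#' @param latentAr AR(1) coefficient of the GABA latent.
#' @param couplingKappa strength of the delayed GABA-to-Glx anti-coupling.
#' @param couplingDelayBins coupling delay in high-resolution bins.
#' @param innovationSd SD of the independent Glx latent innovation.
#' @param noiseSd complex noise SD per point per transient.
#' @param freqJitterPpm per-transient frequency jitter SD in ppm.
#' @param scannerDriftPpm total linear frequency drift in ppm.
#' @param phaseJitterDeg per-transient zero-order phase SD in degrees.
#' @param editEfficiency scale of the edited difference-spectrum signature.
#' @param naaEditRatio edited negative tNAA area as a fraction of tCr area.
#' @param tissueMean mean GM/WM/CSF voxel fractions.
#' @param tissueConcentration Dirichlet concentration of the tissue draws.
#' @return a [GroundTruth-class].
#' @export
GroundTruth <- function(baselineRatio = c(gaba = 0.12, glx = 0.15, tnaa = 1.40),
                        baselineSd = c(gaba = 0.012, glx = 0.015, tnaa = 0.10),
                        driftTotal = c(gaba = -0.100, glx = 0.054, tnaa = 0),
                        latentSd = 0.02,
                        latentAr = 0.5,
                        couplingKappa = 0.5,
                        couplingDelayBins = 10L,
                        innovationSd = 0.025,
                        noiseSd = 0.01,
                        freqJitterPpm = 0.0088,
                        scannerDriftPpm = 0,
                        phaseJitterDeg = 5,
                        editEfficiency = 1,
                        naaEditRatio = 0.45,
                        tissueMean = c(gm = 0.50, wm = 0.35, csf = 0.15),
                        tissueConcentration = 100) {
  new("GroundTruth",
      baselineRatio = baselineRatio, baselineSd = baselineSd,
      driftTotal = driftTotal, latentSd = latentSd, latentAr = latentAr,
      couplingKappa = couplingKappa,
      couplingDelayBins = as.integer(couplingDelayBins),
      innovationSd = innovationSd, noiseSd = noiseSd,
      freqJitterPpm = freqJitterPpm, scannerDriftPpm = scannerDriftPpm,
      phaseJitterDeg = phaseJitterDeg, editEfficiency = editEfficiency,
      naaEditRatio = naaEditRatio, tissueMean = tissueMean,
      tissueConcentration = tissueConcentration)
}

#' Standard ground-truth configurations
#'
#' \code{defaultGroundTruth()} holds the calibrated visual-cortex dynamics:
#' a -10.0\% linear GABA+ drift and +5.4\% Glx drift over the acquisition
#' (which the 128-transient sliding window smooths to maxima of about -5\%
#' and +2.7\%), and a cohort-shared latent fluctuation in which the GABA+
#' latent anti-drives the Glx latent 10 high-resolution bins (120 s) later.
#' \code{nullGroundTruth()} zeroes every dynamic component (drifts, coupling
#' and the shared latent) while keeping the instrument model, and is the
#' configuration used for type-I-error studies and for the posterior
#' cingulate profile, where no dynamics were observed.
#'
#' @param ... overrides passed to [GroundTruth()].
#' @return a [GroundTruth-class].
#' @rdname standardTruths
#' @export
defaultGroundTruth <- function(...) GroundTruth(...)

#' @rdname standardTruths
#' @export
nullGroundTruth <- function(...) {
  args <- list(...)
  base <- list(driftTotal = c(gaba = 0, glx = 0, tnaa = 0),
               latentSd = 0, couplingKappa = 0, innovationSd = 0)
  do.call(GroundTruth, utils::modifyList(base, args))
}
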