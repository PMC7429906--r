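#' @include AllClasses.R profiles.R truth.R lineshapes.R utils.R
NULL

#' Simulate the cohort-shared latent metabolite fluctuations
#'
#' The GABA+ latent is a stationary AR(1) process (per high-resolution bin)
#' with stationary SD \code{latentSd} and coefficient \code{latentAr}.  The
#' Glx latent at bin \code{t} is \code{-couplingKappa} times the GABA+ latent
#' at bin \code{t - couplingDelayBins} plus an independent Gaussian
#' innovation: a change in GABA+ drives the opposite change in Glx one
#' coupling delay later.  The GABA+ process is burnt in over the delay so the
#' coupling is defined at every returned bin.
#'
#' @param truth a [GroundTruth-class].
#' @param nBins number of high-resolution bins (> \code{couplingDelayBins}).
#' @param seed optional integer; when NULL the caller's RNG stream is used.
#' @return list with numeric vectors \code{gaba} and \code{glx} (length
#'   \code{nBins}) and \code{drift}, the deterministic fractional linear
#'   drift component per metabolite on the same bin grid.
#' @examples
#' lat <- simulateLatentTimecourses(defaultGroundTruth(), 64, seed = 1)
#' cor(lat$gaba[1:54], lat$glx[11:64])  # negative at the coupling delay
#' @export
simulateLatentTimecourses <- function(truth, nBins, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  d <- truth@couplingDelayBins
  if (nBins <= d)
    stop("nBins (", nBins, ") must exceed couplingDelayBins (", d, ")")
  .withSeed(seed, {
    phi <- truth@latentAr
    sg <- truth@latentSd
    m <- nBins + d
    g <- numeric(m)
    if (sg > 0) {
      g[1] <- stats::rnorm(1, 0, sg)
      innov <- stats::rnorm(m - 1, 0, sg * sqrt(1 - phi^2))
      for (i in seq_len(m - 1)) g[i + 1] <- phi * g[i] + innov[i]
    }
    gaba <- g[(d + 1):m]
    glx <- -truth@couplingKappa * g[1:nBins] +
      stats::rnorm(nBins, 0, truth@innovationSd)
    tau <- if (nBins > 1) (0:(nBins - 1)) / (nBins - 1) else 0
    drift <- lapply(c(gaba = "gaba", glx = "glx", tnaa = "tnaa"),
                    function(m) truth@driftTotal[[m]] * tau)
    list(gaba = gaba, glx = glx, drift = drift)
  })
}

#' Synthesize one MEGA-PRESS transient
#'
#' OFF transients contain the Lorentzian tCr (3.0 ppm) and tNAA (2.0 ppm)
#' resonances, an optional broad residual-water component, a linear baseline
#' and complex Gaussian noise.  ON transients add the edited
#' difference-spectrum signature scaled by \code{editEfficiency}: a positive
#' GABA+ Gaussian at 3.0 ppm, a positive double-Gaussian Glx complex at
#' 3.71/3.79 ppm and a negative (co-edited) tNAA Lorentzian at 2.0 ppm.
#' Frequency offsets shift every resonance; the phase offset is applied as a
#' complex rotation of the resonances (not the baseline).
#'
#' @param profile an [AcquisitionProfile-class].
#' @param areas named numeric peak areas (intensity x ppm units) with
#'   elements \code{tcr}, \code{tnaa}, \code{gaba}, \code{glx},
#'   \code{naaedit}; all must be >= 0.
#' @param condition \code{"ON"} or \code{"OFF"}.
#' @param freqOffsetPpm frequency offset applied to all resonances (ppm).
#' @param phaseOffsetDeg zero-order phase offset (degrees).
#' @param noiseSd SD of the complex noise added to each point (uses the
#'   caller's RNG stream).
#' @param baselineCoef intercept and slope (per ppm, about 4.7 ppm) of the
#'   real-channel linear baseline.
#' @param editEfficiency scale of the edited signature.
#' @param lwMult linewidth multiplier (areas are preserved).
#' @return complex vector of length \code{nPoints} over [ppmAxis()].
#' @export
synthesizeTransient <- function(profile, areas, condition = c("OFF", "ON"),
                                freqOffsetPpm = 0, phaseOffsetDeg = 0,
                                noiseSd = 0, baselineCoef = c(0, 0),
                                editEfficiency = 1, lwMult = 1) {
  condition <- match.arg(condition)
  stopifnot(is(profile, "AcquisitionProfile"))
  need <- c("tcr", "tnaa", "gaba", "glx", "naaedit")
  if (!all(need %in% names(areas)))
    stop("areas must be named with ", paste(need, collapse = ", "))
  if (any(areas[need] < 0)) stop("peak areas must be >= 0")

  ppm <- ppmAxis(profile)
  ls <- .lineshapeDefaults(profile@larmorMhz)
  off <- freqOffsetPpm
  gCr <- ls$crGammaPpm * lwMult
  gNaa <- ls$naaGammaPpm * lwMult
  sGaba <- ls$gabaSigmaPpm * lwMult
  sGlx <- ls$glxSigmaPpm * lwMult

  det <- .complexLorentzian(ppm, areas[["tcr"]] / (pi * gCr),
                            ls$crCenter + off, gCr) +
         .complexLorentzian(ppm, areas[["tnaa"]] / (pi * gNaa),
                            ls$naaCenter + off, gNaa)
  if (profile@residualWater)
    det <- det + .complexLorentzian(ppm, ls$waterAmplitude,
                                    ls$waterCenter + off, ls$waterGammaPpm)
  if (condition == "ON") {
    aGlx <- areas[["glx"]] / 2
    edited <- complex(real =
      .realGaussian(ppm, areas[["gaba"]] / (sGaba * sqrt(2 * pi)),
                    ls$gabaCenter + off, sGaba) +
      .realGaussian(ppm, aGlx / (sGlx * sqrt(2 * pi)),
                    ls$glxCenters[1] + off, sGlx) +
      .realGaussian(ppm, aGlx / (sGlx * sqrt(2 * pi)),
                    ls$glxCenters[2] + off, sGlx),
      imaginary = 0)
    edited <- edited - .complexLorentzian(ppm, areas[["naaedit"]] / (pi * gNaa),
                                          ls$naaCenter + off, gNaa)
    det <- det + editEfficiency * edited
  }
  det <- det * exp(1i * phaseOffsetDeg * pi / 180)
  det <- det + complex(real = baselineCoef[1] + baselineCoef[2] * (ppm - 4.7),
                       imaginary = 0)
  if (noiseSd > 0) {
    n <- length(ppm)
    det <- det + complex(real = stats::rnorm(n, 0, noiseSd),
                         imaginary = stats::rnorm(n, 0, noiseSd))
  }
  det
}

# Vectorised synthesis of one subject's full transient matrix; identical
# model to synthesizeTransient(), evaluated for all transients at once.
.synthesizeSubject <- function(profile, ppm, ls, conditions, areasMat,
                               freqOff, phaseOff, baseCoef, noiseSd,
                               editEfficiency, lwMult) {
  nT <- length(freqOff)
  np <- length(ppm)
  onCol <- conditions == "ON"

  # real/imaginary accumulators; complex conversion happens once at the end
  RE <- matrix(0, np, nT)
  IM <- matrix(0, np, nT)
  colScale <- function(amps) rep(amps, each = np)
  addLor <- function(amps, center, gamma) {
    U <- outer(ppm, center + freqOff, `-`) / gamma
    W <- colScale(amps) / (1 + U * U)
    RE <<- RE + W
    IM <<- IM - W * U
    invisible()
  }
  addGauss <- function(amps, center, sigma) {
    U <- outer(ppm, center + freqOff, `-`) / sigma
    RE <<- RE + colScale(amps) * exp(-0.5 * U * U)
    invisible()
  }

  gCr <- ls$crGammaPpm * lwMult
  gNaa <- ls$naaGammaPpm * lwMult
  sGaba <- ls$gabaSigmaPpm * lwMult
  sGlx <- ls$glxSigmaPpm * lwMult

  addLor(areasMat[, "tcr"] / (pi * gCr), ls$crCenter, gCr)
  addLor(areasMat[, "tnaa"] / (pi * gNaa), ls$naaCenter, gNaa)
  if (profile@residualWater)
    addLor(rep(ls$waterAmplitude, nT), ls$waterCenter, ls$waterGammaPpm)
  edGaba <- ifelse(onCol, editEfficiency * areasMat[, "gaba"], 0)
  edGlx <- ifelse(onCol, editEfficiency * areasMat[, "glx"] / 2, 0)
  edNaa <- ifelse(onCol, editEfficiency * areasMat[, "naaedit"], 0)
  addGauss(edGaba / (sGaba * sqrt(2 * pi)), ls$gabaCenter, sGaba)
  addGauss(edGlx / (sGlx * sqrt(2 * pi)), ls$glxCenters[1], sGlx)
  addGauss(edGlx / (sGlx * sqrt(2 * pi)), ls$glxCenters[2], sGlx)
  addLor(-edNaa / (pi * gNaa), ls$naaCenter, gNaa)

  cp <- colScale(cos(phaseOff * pi / 180))
  sp <- colScale(sin(phaseOff * pi / 180))
  RE2 <- RE * cp - IM * sp
  IM2 <- RE * sp + IM * cp
  RE2 <- RE2 + (baseCoef[1] + baseCoef[2] * (ppm - 4.7))
  if (noiseSd > 0) {
    RE2 <- RE2 + stats::rnorm(np * nT, 0, noiseSd)
    IM2 <- IM2 + stats::rnorm(np * nT, 0, noiseSd)
  }
  M <- complex(real = RE2, imaginary = IM2)
  dim(M) <- c(np, nT)
  M
}

#' Draw per-subject voxel tissue fractions
#'
#' Dirichlet draws (via normalised gamma variates) of gray matter, white
#' matter and CSF proportions.  Fractions sum to one exactly and CSF is
#' strictly below one.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param seed optional integer seed; NULL uses the caller's RNG stream.
#' @param mean named mean proportions (gm, wm, csf), summing to 1.
#' @param concentration Dirichlet concentration (larger = tighter spread).
#' @return data.frame with columns subject, gm, wm, csf.
#' @export
generateTissueFractions <- function(nSubjects, seed = NULL,
                                    mean = c(gm = 0.50, wm = 0.35, csf = 0.15),
                                    concentration = 100) {
  stopifnot(nSubjects >= 1, abs(sum(mean) - 1) < 1e-8, all(mean > 0))
  .withSeed(seed, {
    draws <- vapply(mean * concentration,
                    function(a) stats::rgamma(nSubjects, shape = a),
                    numeric(nSubjects))
    draws <- matrix(draws, nrow = nSubjects)
    draws <- draws / rowSums(draws)
    data.frame(subject = sprintf("S%03d", seq_len(nSubjects)),
               gm = draws[, 1], wm = draws[, 2], csf = draws[, 3])
  })
}

#' Simulate a synthetic MEGA-PRESS cohort
#'
#' Generates \code{nSubjects} subjects under an acquisition profile and a
#' ground truth: per-subject baseline ratios and intensity scales, linear
#' concentration drifts, the cohort-shared latent fluctuation (identical
#' across subjects, defined per 12 s bin), per-transient frequency/phase
#' jitter with optional linear scanner drift, per-subject linear baselines,
#' alternating OFF/ON transients and complex noise.  The full generative
#' record (parameters, realized latents and per-subject draws) is attached to
#' the cohort and retrievable with [groundTruth()].
#'
#' @param profile an [AcquisitionProfile-class].
#' @param truth a [GroundTruth-class].
#' @param nSubjects number of subjects (>= 2).
#' @param seed integer seed; the cohort is a deterministic function of
#'   (profile, truth, nSubjects, seed, nBroad).
#' @param nBroad number of subjects given a grossly broadened linewidth
#'   (1.5x), emulating participants excluded by the FWHM criterion; they are
#'   appended last.
#' @return a [MegaCohort-class].
#' @examples
#' coh <- simulateCohort(vcProfile(), nullGroundTruth(), nSubjects = 3, seed = 1)
#' coh
#' @export
simulateCohort <- function(profile, truth = defaultGroundTruth(),
                           nSubjects = 58, seed = 1, nBroad = 0) {
  stopifnot(is(profile, "AcquisitionProfile"), is(truth, "GroundTruth"))
  if (nSubjects < 2) stop("nSubjects must be >= 2")
  validObject(profile)
  validObject(truth)

  nT <- profile@nTransients
  binSize <- binSizeForProfile(profile)
  nBins <- nT %/% binSize
  ppm <- ppmAxis(profile)
  conditions <- rep(c("OFF", "ON"), length.out = nT)
  ls <- .lineshapeDefaults(profile@larmorMhz)

  .withSeed(seed, {
    lat <- simulateLatentTimecourses(truth, nBins, seed = NULL)
    tissue <- generateTissueFractions(nSubjects, seed = NULL,
                                      mean = truth@tissueMean,
                                      concentration = truth@tissueConcentration)
    # bin index (1-based) per transient; leftover transients past the last
    # full bin reuse the final bin's latent value
    binOf <- pmin((seq_len(nT) - 1) %/% binSize + 1L, nBins)
    tau <- (seq_len(nT) - 1) / (nT - 1)

    subjectTab <- data.frame(subject = tissue$subject,
                             scale = exp(stats::rnorm(nSubjects, 0, 0.10)),
                             lwMult = exp(stats::rnorm(nSubjects, 0, 0.02)),
                             gabaRatio = stats::rnorm(nSubjects,
                               truth@baselineRatio[["gaba"]],
                               truth@baselineSd[["gaba"]]),
                             glxRatio = stats::rnorm(nSubjects,
                               truth@baselineRatio[["glx"]],
                               truth@baselineSd[["glx"]]),
                             tnaaRatio = stats::rnorm(nSubjects,
                               truth@baselineRatio[["tnaa"]],
                               truth@baselineSd[["tnaa"]]))
    if (nBroad > 0) {
      idx <- seq.int(nSubjects - nBroad + 1, nSubjects)
      subjectTab$lwMult[idx] <- 1.5
    }

    spectra <- vector("list", nSubjects)
    names(spectra) <- subjectTab$subject
    for (s in seq_len(nSubjects)) {
      tcrArea <- subjectTab$scale[s] * lorentzianArea(1, ls$crGammaPpm)
      ratios <- cbind(
        gaba = subjectTab$gabaRatio[s] *
          (1 + truth@driftTotal[["gaba"]] * tau + lat$gaba[binOf]),
        glx = subjectTab$glxRatio[s] *
          (1 + truth@driftTotal[["glx"]] * tau + lat$glx[binOf]),
        tnaa = subjectTab$tnaaRatio[s] *
          (1 + truth@driftTotal[["tnaa"]] * tau))
      ratios[ratios < 0] <- 0
      freqOff <- stats::rnorm(nT, 0, truth@freqJitterPpm) +
        truth@scannerDriftPpm * tau
      phaseOff <- stats::rnorm(nT, 0, truth@phaseJitterDeg)
      baseCoef <- c(stats::rnorm(1, 0, 0.004), stats::rnorm(1, 0, 0.002))

      areasMat <- cbind(tcr = rep(tcrArea, nT),
                        tnaa = ratios[, "tnaa"] * tcrArea,
                        gaba = ratios[, "gaba"] * tcrArea,
                        glx = ratios[, "glx"] * tcrArea,
                        naaedit = rep(truth@naaEditRatio * tcrArea, nT))
      spectra[[s]] <- .synthesizeSubject(profile, ppm, ls, conditions,
                                         areasMat, freqOff, phaseOff,
                                         baseCoef, truth@noiseSd,
                                         truth@editEfficiency,
                                         subjectTab$lwMult[s])
    }

    new("MegaCohort", spectra = spectra, conditions = conditions, ppm = ppm,
        profile = profile, tissue = tissue,
        truth = list(truth = truth, latents = lat, subjects = subjectTab,
                     binSize = binSize, seed = seed),
        processing = list())
  })
}
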