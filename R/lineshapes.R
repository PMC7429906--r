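# Analytic line shapes on a ppm axis.
#
# The complex Lorentzian is the Fourier transform of a decaying exponential:
# real part absorption A/(1+u^2), imaginary part dispersion -A*u/(1+u^2),
# u = (f - f0)/gamma with gamma the half width at half maximum in ppm.
# Gaussians are used for the edited peaks; only their absorption component is
# modelled (their dispersion part never enters the real-channel fits).

.complexLorentzian <- function(ppm, A, f0, gammaPpm) {
  u <- (ppm - f0) / gammaPpm
  den <- 1 + u * u
  complex(real = A / den, imaginary = -A * u / den)
}

.realGaussian <- function(ppm, A, f0, sigmaPpm) {
  A * exp(-0.5 * ((ppm - f0) / sigmaPpm)^2)
}

#' Closed-form peak areas and widths
#'
#' Area under a Lorentzian absorption peak of amplitude \code{A} and
#' half-width \code{gamma} is \code{pi * A * gamma}; under a Gaussian of
#' amplitude \code{A} and SD \code{sigma} it is \code{A * sigma * sqrt(2*pi)}.
#' FWHM is \code{2 * gamma} (Lorentzian) or \code{2 * sigma * sqrt(2*log(2))}
#' (Gaussian), in the units of the width argument.
#'
#' @param A amplitude.
#' @param gamma,sigma width parameter (any unit; area is in
#'   amplitude x width units).
#' @return numeric scalar.
#' @rdname lineshapeAreas
#' @export
lorentzianArea <- function(A, gamma) pi * A * gamma

#' @rdname lineshapeAreas
#' @export
gaussianArea <- function(A, sigma) A * sigma * sqrt(2 * pi)

#' @rdname lineshapeAreas
#' @export
lorentzianFwhm <- function(gamma) 2 * gamma

#' @rdname lineshapeAreas
#' @export
gaussianFwhm <- function(sigma) 2 * sigma * sqrt(2 * log(2))

# Default line-shape geometry of the simulated spectra.  Widths target the
# study's reported quality metrics at 3 T (127.7 Hz/ppm): tCr and tNAA
# Lorentzians with FWHM 8.5 and 8.4 Hz, a GABA+ Gaussian with FWHM 25 Hz,
# and a double-Gaussian Glx complex with sub-peaks at 3.71 and 3.79 ppm.
.lineshapeDefaults <- function(larmorMhz = 127.7) {
  list(
    crCenter = 3.0,  crGammaPpm = (8.5 / 2) / larmorMhz,
    naaCenter = 2.0, naaGammaPpm = (8.4 / 2) / larmorMhz,
    gabaCenter = 3.0,
    gabaSigmaPpm = (25 / (2 * sqrt(2 * log(2)))) / larmorMhz,
    glxCenters = c(3.71, 3.79),
    glxSigmaPpm = (14 / (2 * sqrt(2 * log(2)))) / larmorMhz,
    waterCenter = 4.7, waterGammaPpm = 0.15, waterAmplitude = 2.0
  )
}
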