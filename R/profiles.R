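#' @include AllClasses.R
NULL

#' Construct an acquisition profile
#'
#' @param name profile label.
#' @param nTransients even number of transients (alternating OFF/ON).
#' @param trS repetition time in seconds.
#' @param nPoints spectral points per transient (>= 512).
#' @param sweepHz spectral width in Hz.
#' @param larmorMhz proton frequency in MHz; 127.7 corresponds to 3 T.
#' @param residualWater include a broad residual-water component at 4.7 ppm
#'   in simulated spectra.
#' @return an [AcquisitionProfile-class].
#' @examples
#' vcProfile()
#' pccProfile()
#' @export
acquisitionProfile <- function(name, nTransients, trS, nPoints,
                               sweepHz = 2000, larmorMhz = 127.7,
                               residualWater = FALSE) {
  new("AcquisitionProfile", name = name,
      nTransients = as.integer(nTransients), trS = trS,
      nPoints = as.integer(nPoints), sweepHz = sweepHz,
      larmorMhz = larmorMhz, residualWater = residualWater)
}

#' Built-in acquisition profiles
#'
#' \code{vcProfile()} is the visual-cortex acquisition (256 transients of
#' 2048 points, TR 3 s); \code{pccProfile()} is the posterior-cingulate
#' acquisition (320 transients, TR 2 s).  Both assume a 3 T proton frequency
#' (127.7 MHz) and a 2000 Hz sweep.  The posterior-cingulate acquisition was
#' not water suppressed, so its profile includes a residual-water component.
#'
#' @return an [AcquisitionProfile-class].
#' @rdname builtinProfiles
#' @export
vcProfile <- function() {
  acquisitionProfile("vc", 256L, 3, 2048L, residualWater = FALSE)
}

#' @rdname builtinProfiles
#' @export
pccProfile <- function() {
  acquisitionProfile("pcc", 320L, 2, 2048L, residualWater = TRUE)
}

#' High-resolution bin size giving 12 s temporal resolution
#'
#' Number of transients per across-subject bin so that one bin spans 12 s:
#' four transients at TR 3 s, six at TR 2 s.
#'
#' @param profile an [AcquisitionProfile-class].
#' @param resolutionS target bin duration in seconds (default 12).
#' @return integer bin size in transients.
#' @export
binSizeForProfile <- function(profile, resolutionS = 12) {
  bs <- as.integer(round(resolutionS / profile@trS))
  if (bs < 1L) stop("TR longer than the requested resolution")
  bs
}
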