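# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG state seeded by `seed`; restores the caller's
# RNG afterwards so library code never clobbers user-level reproducibility.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Chemical-shift axis of an acquisition profile
#'
#' The ppm axis implied by the digitisation: \code{nPoints} uniformly spaced
#' values spanning \code{sweepHz / larmorMhz} ppm, referenced so the carrier
#' (4.7 ppm, water) sits at the centre, stored high-to-low.
#'
#' @param profile an [AcquisitionProfile-class].
#' @return numeric vector of length \code{nPoints}, strictly decreasing.
#' @export
ppmAxis <- function(profile) {
  stopifnot(is(profile, "AcquisitionProfile"))
  span <- profile@sweepHz / profile@larmorMhz
  4.7 + span * (0.5 - (seq_len(profile@nPoints) - 1) / profile@nPoints)
}

# index (1-based, fractional) of a ppm value on a decreasing uniform axis
.ppmToIndex <- function(ppmAxis, p) {
  step <- ppmAxis[1] - ppmAxis[2]
  (ppmAxis[1] - p) / step + 1
}

.ppmWindowIdx <- function(ppmAxis, windowPpm) {
  idx <- which(ppmAxis >= min(windowPpm) & ppmAxis <= max(windowPpm))
  if (!length(idx))
    stop("fit window [", min(windowPpm), ", ", max(windowPpm),
         "] ppm is outside the spectral axis")
  idx
}

# Shift the columns of a complex spectrum matrix by per-column ppm offsets
# (content at ppm p moves to p + shiftPpm), via the time-domain phase ramp.
.shiftSpectra <- function(S, ppmAxis, shiftPpm) {
  S <- as.matrix(S)
  n <- nrow(S)
  step <- ppmAxis[1] - ppmAxis[2]        # ppm per index (axis decreasing)
  dIdx <- -shiftPpm / step               # +ppm shift = earlier index
  fid <- stats::mvfft(S, inverse = TRUE) / n
  # signed time index so fractional shifts add no constant phase regardless
  # of where the implied FID energy sits
  tt <- 0:(n - 1)
  tt[tt > n / 2] <- tt[tt > n / 2] - n
  ramp <- exp(2i * pi * outer(tt, dIdx) / n)
  stats::mvfft(fid * ramp)
}

.writeCsv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", schema), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}
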