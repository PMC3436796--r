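#' Threshold-based normalization of raw readout values
#'
#' Maps raw (arbitrary-unit) measurements at a baseline and a later
#' acquisition time to activation levels in [0, 1]. Per data point the
#' relative change r = (x_t - x_0) / max(x_0, noiseFloor) is computed;
#' changes within the noise floor map to 0, values at or above the
#' saturation level map to 1, and everything else is passed through a
#' Hill transform |r|^h / (|r|^h + ec50^h) with exponent h = 2. This is a
#' deliberately simple thresholded normalization; pre-normalized data
#' (e.g. MIDAS files already in [0, 1]) bypass it.
#'
#' @param x0,xt numeric matrices (conditions x readouts) of raw values at
#'   baseline and at the training time; must be non-negative.
#' @param noiseFloor measurement-noise threshold on the raw scale
#'   (also the floor of the denominator of the relative change).
#' @param saturation raw value at which the response is considered fully
#'   saturated; must exceed \code{noiseFloor}.
#' @param ec50 relative change producing a normalized value of 0.5.
#' @param hill Hill exponent (default 2).
#' @return Matrix of normalized values in [0, 1], same shape as
#'   \code{xt}.
#' @export
normalizeData <- function(x0, xt, noiseFloor, saturation, ec50 = 0.5,
                          hill = 2) {
  if (any(x0 < 0, na.rm = TRUE) || any(xt < 0, na.rm = TRUE))
    .inputError("raw values must be non-negative")
  if (!(noiseFloor > 0 && noiseFloor < saturation))
    .inputError("need 0 < noiseFloor < saturation")
  r <- abs(xt - x0) / pmax(x0, noiseFloor)
  out <- r^hill / (r^hill + ec50^hill)
  out[abs(xt - x0) <= noiseFloor] <- 0
  out[xt >= saturation] <- 1
  out[is.na(xt) | is.na(x0)] <- NA_real_
  out
}
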