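#' Phase-preserved denoising of one slice
#'
#' Decomposes the slice with a log-Gabor bank, estimates the Rayleigh noise
#' threshold per (scale, orientation), soft-shrinks the response amplitudes
#' (phase untouched), reconstructs from the surviving even-symmetric
#' responses, and restores the slice's median intensity (the bank has no DC
#' component, and the median -- unlike the mean -- is not inflated by the
#' rectified background noise of a clamped subtraction image).
#' Deterministic.
#'
#' @param slice numeric matrix
#' @param bank a [LogGaborBank-class] matching the slice shape
#' @param c Rayleigh threshold multiplier
#' @return denoised matrix of the same shape
#' @export
denoiseSlice <- function(slice, bank, c = 1) {
  resp <- waveletResponses(slice, bank)
  model <- suppressWarnings(estimateNoiseModel(resp, c))
  reconstructImage(shrinkResponses(resp, model)) + stats::median(slice)
}

#' Phase-preserved denoising of a volume
#'
#' Runs [denoiseSlice()] on every axial slice. Applied to the subtracted
#' volume in the standard pipeline order.
#'
#' @param vol a [VolumeImage-class]
#' @param nScales,nOrientations,minWavelength,mult,sigmaOnF bank
#'   configuration, see [buildLogGaborBank()]
#' @param c Rayleigh threshold multiplier
#' @return a denoised [VolumeImage-class] of the same shape
#' @export
denoiseVolume <- function(vol, nScales = 8, nOrientations = 6,
                          minWavelength = 3, mult = 2.1, sigmaOnF = 0.55,
                          c = 1) {
  stopifnot(is(vol, "VolumeImage"))
  d <- dim(vol@data)
  bank <- buildLogGaborBank(c(d[2], d[3]), nScales = nScales,
                            nOrientations = nOrientations,
                            minWavelength = minWavelength, mult = mult,
                            sigmaOnF = sigmaOnF)
  VolumeImage(.mapSlices(vol@data, denoiseSlice, bank = bank, c = c),
              vol@spacing)
}
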