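#' Extract the voxel data array of a volume
#'
#' @param x a [VolumeImage-class] or [BinaryMask-class]
#' @return the numeric 3-D array in (z, y, x) order
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' Voxel spacing of a volume
#'
#' @param x a [VolumeImage-class]
#' @return numeric length-3 spacing (z, y, x) in mm
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Amplitude view of wavelet responses
#'
#' Amplitude \eqn{A_n = \sqrt{\mathrm{Re}_n^2 + \mathrm{Im}_n^2}} of every
#' (scale, orientation) response.
#'
#' @param x a [WaveletResponseSet-class]
#' @return list of nonnegative matrices
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' Phase view of wavelet responses
#'
#' Phase \eqn{\phi_n = \mathrm{atan2}(\mathrm{Im}_n, \mathrm{Re}_n)} of every
#' (scale, orientation) response, in \eqn{(-\pi, \pi]}.
#'
#' @param x a [WaveletResponseSet-class]
#' @return list of matrices
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' Homogeneous matrix of an affine transform
#'
#' @param x an [AffineTransform2D-class]
#' @return 3x3 numeric matrix with last row (0, 0, 1)
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' Parameter vector of an affine transform
#'
#' @param x an [AffineTransform2D-class]
#' @return named numeric vector (tx, ty, theta, k, sx, sy)
#' @export
setGeneric("affineParameters", function(x) standardGeneric("affineParameters"))

setMethod("volData", "VolumeImage", function(x) x@data)
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)
setMethod("affineMatrix", "AffineTransform2D", function(x) x@matrix)
setMethod("affineParameters", "AffineTransform2D", function(x)
  c(tx = x@tx, ty = x@ty, theta = x@theta, k = x@k, sx = x@sx, sy = x@sy))

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d (z, y, x), spacing %s mm, range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask: %d x %d x %d (z, y, x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "AffineTransform2D", function(object) {
  p <- affineParameters(object)
  cat("AffineTransform2D:",
      sprintf("tx=%.4g ty=%.4g theta=%.4g rad k=%.4g sx=%.4g sy=%.4g\n",
              p["tx"], p["ty"], p["theta"], p["k"], p["sx"], p["sy"]))
})

setMethod("show", "LogGaborBank", function(object) {
  cat(sprintf(paste0("LogGaborBank: %d scales x %d orientations on %d x %d ",
                     "grid\n  min wavelength %.3g px, mult %.3g, ",
                     "sigmaOnF %.3g\n"),
              object@nScales, object@nOrientations,
              object@shape[1], object@shape[2],
              object@minWavelength, object@mult, object@sigmaOnF))
})

setMethod("show", "RayleighNoiseModel", function(object) {
  cat(sprintf(paste0("RayleighNoiseModel: c=%.3g, sigma (finest scale) ",
                     "%.4g-%.4g, tau %.4g-%.4g%s\n"),
              object@c, min(object@sigma), max(object@sigma),
              min(object@tau), max(object@tau),
              if (object@degenerate) " [degenerate: all-zero amplitudes]" else ""))
})

setMethod("show", "CmfResult", function(object) {
  cat(sprintf(paste0("CmfResult: %s after %d iterations, residual %.3g\n",
                     "  energy: data %.6g + tv %.6g = %.6g\n"),
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual,
              object@energy$data, object@energy$tv, object@energy$total))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d\n",
              object@TP, object@FP, object@TN, object@FN))
})

setMethod("show", "MetricsReport", function(object) {
  v <- object@values
  cat("MetricsReport:\n")
  print(round(v, 5))
  if (length(object@flags))
    cat("  degenerate (0/0 -> 0):", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d x %d x %d, %d lesion(s), background ",
                     "%.3g, noise sigma %.3g, seed %d\n"),
              object@shape[1], object@shape[2], object@shape[3],
              length(object@lesions), object@background,
              object@noiseSigma, object@seed))
})

setMethod("show", "CaseResult", function(object) {
  cat("CaseResult:\n  final mask: ")
  show(object@mask)
  if (!is.null(object@metrics)) {
    cat("  ")
    show(object@metrics)
  }
  flags <- object@provenance$flags
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
})
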