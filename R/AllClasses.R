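#' @import methods
NULL

#' VolumeImage: a 3-D scalar image volume
#'
#' Carrier for every image stage of the pipeline. Voxel data are stored in
#' \code{(z, y, x)} axis order -- the first index selects the axial slice, and
#' each slice is a \code{(y, x)} matrix. Intensities are real and finite, with
#' a nominal dynamic range of 0--255 (the MR gray-level convention this
#' package assumes for PSNR peaks and default filter parameters, not a hard
#' constraint).
#'
#' @slot data numeric 3-D array, axis order (z, y, x); all values finite.
#' @slot spacing numeric length-3 voxel spacing in mm, (z, y, x) order,
#'   strictly positive.
#'
#' @seealso [VolumeImage()] for the constructor, [readVolume()],
#'   [writeVolume()]
#' @export
setClass("VolumeImage",
  representation(data = "array", spacing = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1))
)

setValidity("VolumeImage", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array (z, y, x)")
  if (any(dim(d) < 1L))
    return("all dimensions must be >= 1")
  if (!all(is.finite(d)))
    return("all voxel values must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite numbers (z, y, x)")
  TRUE
})

#' BinaryMask: a binary 3-D segmentation mask
#'
#' A [VolumeImage-class] whose voxels are exactly 0 or 1. Used for lesion
#' ground truth and segmentation output.
#'
#' @seealso [BinaryMask()], [asBinaryMask()]
#' @export
setClass("BinaryMask", contains = "VolumeImage")

setValidity("BinaryMask", function(object) {
  if (!all(object@data %in% c(0, 1)))
    return("mask values must be exactly 0 or 1")
  TRUE
})

#' AffineTransform2D: six-parameter in-plane affine transform
#'
#' The transform is the product Translation . Rotation . Shear . Scale of four
#' elementary matrices; its 3x3 homogeneous matrix is
#' \deqn{\begin{pmatrix} s_x\cos\theta & s_y(k\cos\theta-\sin\theta) & t_x \\
#'  s_x\sin\theta & s_y(k\sin\theta+\cos\theta) & t_y \\ 0 & 0 & 1
#'  \end{pmatrix}}
#' with \eqn{\theta} measured clockwise in the image (y-down) convention.
#'
#' @slot tx,ty translation in pixels.
#' @slot theta rotation in radians (clockwise).
#' @slot k shear factor.
#' @slot sx,sy scale factors, strictly positive.
#' @slot matrix the 3x3 homogeneous matrix.
#'
#' @seealso [composeAffine()], [applyAffine()], [invertAffine()]
#' @export
setClass("AffineTransform2D",
  representation(tx = "numeric", ty = "numeric", theta = "numeric",
                 k = "numeric", sx = "numeric", sy = "numeric",
                 matrix = "matrix")
)

setValidity("AffineTransform2D", function(object) {
  if (object@sx <= 0 || object@sy <= 0)
    return("scale factors sx, sy must be > 0")
  m <- object@matrix
  if (!all(dim(m) == c(3L, 3L)))
    return("matrix must be 3x3")
  if (!isTRUE(all.equal(m[3, ], c(0, 0, 1))))
    return("last row of matrix must be (0, 0, 1)")
  mm <- .affineMatrixFromParams(object@tx, object@ty, object@theta,
                                object@k, object@sx, object@sy)
  if (max(abs(m - mm)) > 1e-8)
    return("matrix does not match the product of the four factor matrices")
  TRUE
})

#' LogGaborBank: a polar-separable log-Gabor filter bank
#'
#' Frequency-domain transfer functions on a fixed 2-D grid, one nonnegative
#' real filter per (scale, orientation). Every filter has zero DC gain and
#' unit peak transfer. Center wavelengths grow geometrically:
#' \code{minWavelength * mult^(scale-1)}.
#'
#' @slot nScales,nOrientations bank grid size.
#' @slot minWavelength finest center wavelength in pixels.
#' @slot mult wavelength ratio between successive scales.
#' @slot sigmaOnF radial bandwidth (ratio of the Gaussian sigma to the center
#'   frequency on the log-frequency axis).
#' @slot angularFactor angular spread divisor: the angular Gaussian sigma is
#'   \code{pi / nOrientations / angularFactor}.
#' @slot shape (rows, cols) of the frequency grid.
#' @slot filters list of \code{nScales * nOrientations} transfer matrices in
#'   FFT (unshifted) order; element \code{[[(s-1)*nOrientations + o]]}.
#' @slot filterEnergy matrix (nScales x nOrientations) of the summed squared
#'   transfer of each filter; used to propagate noise amplitude across scales.
#' @slot evenCoverage summed even-symmetric transfer of the whole bank,
#'   used by [reconstructImage()] to normalize the reconstruction.
#'
#' @seealso [buildLogGaborBank()]
#' @export
setClass("LogGaborBank",
  representation(nScales = "integer", nOrientations = "integer",
                 minWavelength = "numeric", mult = "numeric",
                 sigmaOnF = "numeric", angularFactor = "numeric",
                 shape = "integer", filters = "list",
                 filterEnergy = "matrix", evenCoverage = "matrix")
)

setValidity("LogGaborBank", function(object) {
  if (length(object@filters) != object@nScales * object@nOrientations)
    return("bank cardinality must be nScales * nOrientations")
  for (f in object@filters) {
    if (!all(dim(f) == object@shape)) return("filter shape mismatch")
    if (abs(f[1, 1]) > 1e-12) return("every filter must have zero DC gain")
    if (abs(max(f) - 1) > 1e-9) return("every filter must have unit peak transfer")
    if (min(f) < 0) return("transfer functions must be nonnegative")
  }
  TRUE
})

#' WaveletResponseSet: complex log-Gabor responses of one slice
#'
#' One complex 2-D field per (scale, orientation): the real part is the
#' even-symmetric filter response, the imaginary part the odd-symmetric one.
#' Amplitude and phase views are available through [amplitudes()] and
#' [phases()].
#'
#' @slot responses list of complex matrices, same indexing as the bank.
#' @slot bank the [LogGaborBank-class] that produced the responses.
#'
#' @seealso [waveletResponses()], [shrinkResponses()], [reconstructImage()]
#' @export
setClass("WaveletResponseSet",
  representation(responses = "list", bank = "LogGaborBank")
)

setValidity("WaveletResponseSet", function(object) {
  if (length(object@responses) !=
      object@bank@nScales * object@bank@nOrientations)
    return("response count must match the bank cardinality")
  TRUE
})

#' RayleighNoiseModel: Rayleigh noise amplitude model and shrink thresholds
#'
#' Background amplitude in magnitude MR images follows a Rayleigh distribution
#' with scale \eqn{\sigma}: mean \eqn{\sigma\sqrt{\pi/2}}, variance
#' \eqn{(4-\pi)\sigma^2/2}, median \eqn{\sigma\sqrt{2\ln 2}}. The scale is
#' estimated from the median response amplitude at the finest wavelet scale
#' (one estimate per orientation), propagated to coarser scales by the bank's
#' noise-gain ratio, and turned into a per-(scale, orientation) threshold
#' \eqn{\tau = \mu_R + c\,\sigma_R}.
#'
#' @slot sigma numeric vector: estimated Rayleigh scale per orientation at the
#'   finest wavelet scale.
#' @slot c threshold multiplier (number of Rayleigh standard deviations above
#'   the Rayleigh mean).
#' @slot tau matrix (nScales x nOrientations) of amplitude thresholds.
#' @slot degenerate TRUE when all amplitudes were zero (tau = 0, flagged).
#'
#' @seealso [estimateNoiseModel()], [rayleighMean()], [rayleighThreshold()]
#' @export
setClass("RayleighNoiseModel",
  representation(sigma = "numeric", c = "numeric", tau = "matrix",
                 degenerate = "logical")
)

setValidity("RayleighNoiseModel", function(object) {
  if (any(object@tau < 0)) return("thresholds must be nonnegative")
  if (any(object@sigma < 0)) return("sigma must be nonnegative")
  TRUE
})

#' CapacityField: two-label continuous max-flow capacities
#'
#' Pixel-wise capacities of the two-label flow model: source capacity
#' \code{Cs}, sink capacity \code{Ct}, and spatial flow capacity \code{C}.
#' All nonnegative and finite.
#'
#' @slot Cs,Ct,C numeric matrices of identical shape.
#'
#' @seealso [buildCapacities()], [solveCmfTwoLabel()]
#' @export
setClass("CapacityField",
  representation(Cs = "matrix", Ct = "matrix", C = "matrix")
)

setValidity("CapacityField", function(object) {
  if (!all(dim(object@Cs) == dim(object@Ct)) ||
      !all(dim(object@Cs) == dim(object@C)))
    return("Cs, Ct and C must have identical shape")
  if (any(!is.finite(object@Cs)) || any(!is.finite(object@Ct)) ||
      any(!is.finite(object@C)))
    return("capacities must be finite")
  if (min(object@Cs) < 0 || min(object@Ct) < 0 || min(object@C) < 0)
    return("capacities must be nonnegative")
  TRUE
})

#' PottsCapacity: n-label Potts model capacities
#'
#' Per-label data costs \eqn{\rho(L_i, x)} and spatial flow capacities for the
#' convex-relaxed Potts model.
#'
#' @slot costs numeric 3-D array (rows, cols, nLabels) of assignment costs.
#' @slot C numeric matrix of spatial capacities shared by all labels.
#'
#' @seealso [solveCmfPotts()]
#' @export
setClass("PottsCapacity",
  representation(costs = "array", C = "matrix")
)

setValidity("PottsCapacity", function(object) {
  d <- dim(object@costs)
  if (length(d) != 3L || d[3] < 2L)
    return("costs must be (rows, cols, nLabels) with nLabels >= 2")
  if (!all(dim(object@C) == d[1:2]))
    return("C must match the in-plane cost shape")
  if (any(!is.finite(object@costs)) || min(object@costs) < 0 ||
      any(!is.finite(object@C)) || min(object@C) < 0)
    return("capacities must be nonnegative and finite")
  TRUE
})

#' CmfResult: continuous max-flow solver state and solution
#'
#' @slot u numeric matrix (two-label, values in [0,1]) or 3-D array
#'   (rows, cols, nLabels; simplex-valued) of label functions.
#' @slot flows list of terminal and spatial flow fields at the last iterate.
#' @slot residual maximum absolute flow-conservation violation at the last
#'   iterate.
#' @slot converged whether the mean label update fell below tolerance before
#'   \code{maxIter}.
#' @slot iterations iterations actually run.
#' @slot energy list with components \code{data}, \code{tv}, \code{total}:
#'   the primal segmentation energy of \code{u}.
#'
#' @seealso [solveCmfTwoLabel()], [solveCmfPotts()], [thresholdLabels()]
#' @export
setClass("CmfResult",
  representation(u = "ANY", flows = "list", residual = "numeric",
                 converged = "logical", iterations = "integer",
                 energy = "list")
)

setValidity("CmfResult", function(object) {
  e <- object@energy
  if (!all(c("data", "tv", "total") %in% names(e)))
    return("energy must have data, tv and total components")
  if (e$tv < -1e-9) return("tv term must be nonnegative")
  if (abs(e$total - (e$data + e$tv)) > 1e-6 * max(1, abs(e$total)))
    return("total energy must equal data + tv")
  TRUE
})

#' StructuringElement: origin-centered pixel set for morphology
#'
#' @slot offsets integer matrix with columns (dy, dx); contains (0, 0).
#' @slot radius disc radius in pixels (NA for non-disc elements).
#'
#' @seealso [makeDiscSE()], [dilateMask()], [erodeMask()]
#' @export
setClass("StructuringElement",
  representation(offsets = "matrix", radius = "numeric")
)

setValidity("StructuringElement", function(object) {
  o <- object@offsets
  if (ncol(o) != 2L) return("offsets must have two columns (dy, dx)")
  if (!any(o[, 1] == 0 & o[, 2] == 0)) return("offsets must contain (0, 0)")
  TRUE
})

#' ConfusionCounts: pixel-wise confusion matrix
#'
#' @slot TP,FP,TN,FN nonnegative integer pixel counts.
#' @seealso [confusionCounts()], [computeMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(TP = "numeric", FP = "numeric", TN = "numeric",
                 FN = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (any(v < 0) || any(v != round(v))) return("counts must be nonnegative integers")
  TRUE
})

#' MetricsReport: segmentation evaluation metrics
#'
#' Holds the nine pixel-classification metrics (plus optional PSNR):
#' Acc, Se, Sp, P, ER, Vs as fractions in [0, 1]; DSC and JC as percentages;
#' AUC in [0, 1]; PSNR in dB. Ratios whose denominator is zero are reported
#' as 0 and flagged \code{degenerate}.
#'
#' @slot values named numeric vector (names Acc, Se, Sp, P, ER, Vs, DSC, JC,
#'   and optionally AUC, PSNR).
#' @slot counts the [ConfusionCounts-class] the ratios were computed from.
#' @slot flags character vector naming metrics with 0/0 denominators.
#'
#' @seealso [computeMetrics()], [metricsTable()]
#' @export
setClass("MetricsReport",
  representation(values = "numeric", counts = "ConfusionCounts",
                 flags = "character")
)

#' PhantomSpec: synthetic DCE-MRI case description
#'
#' Describes a reproducible synthetic pre/post contrast pair: a textured
#' background, one or more ellipsoidal enhancing lesions, Rician magnitude
#' noise, and an in-plane misalignment of the post frame.
#'
#' @slot shape integer (z, y, x) volume shape.
#' @slot lesions list of lesions, each a list with \code{center} (z, y, x;
#'   0-based voxel coordinates), \code{radii} (z, y, x semi-axes in voxels)
#'   and \code{delta} (contrast enhancement, gray levels > 0).
#' @slot background background intensity (gray levels).
#' @slot textureAmplitude amplitude of the smooth low-frequency background
#'   texture (gray levels).
#' @slot noiseSigma Rician noise sigma (gray levels, >= 0).
#' @slot misalignment [AffineTransform2D-class] applied to the post frame.
#' @slot seed RNG seed making the case bit-reproducible.
#'
#' @seealso [phantomSpec()], [generateCase()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", lesions = "list", background = "numeric",
                 textureAmplitude = "numeric", noiseSigma = "numeric",
                 misalignment = "AffineTransform2D", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive integers (z, y, x)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  for (les in object@lesions) {
    if (!all(c("center", "radii", "delta") %in% names(les)))
      return("each lesion needs center, radii and delta")
    if (les$delta <= 0) return("lesion enhancement delta must be > 0")
    lo <- les$center - les$radii
    hi <- les$center + les$radii
    if (any(lo < 0) || any(hi > object@shape - 1))
      return("lesion ellipsoid must lie within the volume bounds")
  }
  TRUE
})

#' CaseResult: output of the end-to-end segmentation pipeline
#'
#' @slot mask final refined [BinaryMask-class].
#' @slot maskRaw thresholded CMF mask before morphological refinement.
#' @slot u soft label function volume (values in [0, 1]).
#' @slot transform recovered [AffineTransform2D-class] (post -> pre).
#' @slot intermediates named list of intermediate [VolumeImage-class]s
#'   (registered, subtracted, denoised, smoothed).
#' @slot metrics [MetricsReport-class] against ground truth, or NULL.
#' @slot provenance list (package version, config, flags) sufficient to
#'   reproduce the result.
#'
#' @seealso [segmentCase()]
#' @export
setClass("CaseResult",
  representation(mask = "BinaryMask", maskRaw = "BinaryMask", u = "array",
                 transform = "AffineTransform2D", intermediates = "list",
                 metrics = "ANY", provenance = "list")
)
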