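# Synthetic DCE-MRI case generation.
#
# Emulates what the pipeline needs from a clinical pre/post contrast pair:
# a smooth textured background, ellipsoidal lesions that enhance by a fixed
# increment in the post frame, Rician magnitude noise, and a small in-plane
# misalignment of the post acquisition.

#' Describe a synthetic DCE-MRI case
#'
#' Defaults produce one case sized so the full pipeline runs in seconds:
#' an 8 x 128 x 128 volume, background 60 with a low-frequency sinusoidal
#' texture of amplitude 10, one centered ellipsoidal lesion of semi-axes
#' (3, 10, 12) voxels enhancing by 80 gray levels, Rician noise sigma 8, and
#' a post-frame misalignment of (tx = 2.5, ty = -1.5, theta = 0.01 rad).
#'
#' @param shape volume shape (z, y, x)
#' @param lesions list of lesions (\code{center}, \code{radii} in 0-based
#'   voxel coordinates, \code{delta} enhancement); NULL places one default
#'   lesion at the volume center
#' @param background background intensity
#' @param textureAmplitude amplitude of the smooth background texture
#' @param noiseSigma Rician sigma (0 = noise-free)
#' @param misalignment an [AffineTransform2D-class] warping the post frame
#' @param seed RNG seed
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(shape = c(8, 128, 128), lesions = NULL,
                        background = 60, textureAmplitude = 10,
                        noiseSigma = 8,
                        misalignment = composeAffine(2.5, -1.5, 0.01),
                        seed = 42) {
  shape <- as.integer(shape)
  if (is.null(lesions))
    lesions <- list(list(center = (shape - 1) / 2, radii = c(3, 10, 12),
                         delta = 80))
  new("PhantomSpec", shape = shape, lesions = lesions,
      background = background, textureAmplitude = textureAmplitude,
      noiseSigma = noiseSigma, misalignment = misalignment,
      seed = as.integer(seed))
}

#' Add Rician noise to a volume
#'
#' \code{out = sqrt((img + g1)^2 + g2^2)} with \code{g1}, \code{g2}
#' independent zero-mean Gaussians of standard deviation \code{sigma} -- the
#' magnitude-image noise model of MR. At zero signal the output is Rayleigh
#' distributed; \code{sigma = 0} is the identity.
#'
#' @param img a [VolumeImage-class] or numeric array
#' @param sigma noise standard deviation (>= 0)
#' @param seed optional RNG seed
#' @return same kind as \code{img}
#' @export
ricianNoise <- function(img, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  a <- if (is(img, "VolumeImage")) img@data else img
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    g1 <- stats::rnorm(length(a), 0, sigma)
    g2 <- stats::rnorm(length(a), 0, sigma)
    a <- array(sqrt((as.numeric(a) + g1)^2 + g2^2), dim(a))
  }
  if (is(img, "VolumeImage")) VolumeImage(a, img@spacing) else a
}

.ellipsoidMask <- function(shape, center, radii) {
  z <- array(rep(0:(shape[1] - 1), times = shape[2] * shape[3]), shape)
  y <- array(rep(rep(0:(shape[2] - 1), each = shape[1]), times = shape[3]),
             shape)
  x <- array(rep(0:(shape[3] - 1), each = shape[1] * shape[2]), shape)
  ((z - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
    ((x - center[3]) / radii[3])^2 <= 1
}

#' Generate a synthetic pre/post contrast pair with known ground truth
#'
#' The clean pre volume is background + smooth texture; the clean post adds
#' the enhancement inside each lesion ellipsoid and is then warped slice-wise
#' by the misalignment (bicubic). Rician noise is applied independently to
#' both frames. Ground truth is the lesion voxel set in pre-frame
#' coordinates. Fully reproducible from the seed.
#'
#' @param spec a [PhantomSpec-class]
#' @return list with \code{pre}, \code{post} ([VolumeImage-class]s),
#'   \code{gt} ([BinaryMask-class]), and \code{clean} (noise-free
#'   \code{pre}, \code{post} (unwarped) and \code{sub}traction volumes)
#' @examples
#' case <- generateCase(phantomSpec(shape = c(4, 32, 32),
#'   lesions = list(list(center = c(1.5, 15.5, 15.5), radii = c(1, 5, 6),
#'                       delta = 80)), noiseSigma = 0,
#'   misalignment = composeAffine()))
#' sum(volData(case$gt))
#' @export
generateCase <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@shape
  # smooth low-frequency background texture (deterministic)
  yN <- matrix(rep((0:(d[2] - 1)) / d[2], times = d[3]), d[2], d[3])
  xN <- matrix(rep((0:(d[3] - 1)) / d[3], each = d[2]), d[2], d[3])
  tex2 <- sin(2 * pi * 1.3 * xN + 0.7) * sin(2 * pi * 0.9 * yN + 0.3)
  preClean <- array(0, d)
  for (z in seq_len(d[1]))
    preClean[z, , ] <- spec@background +
      spec@textureAmplitude * tex2 * cos(pi * (z - 1) / max(1, d[1] - 1) / 2)
  gt <- array(0, d)
  postClean <- preClean
  for (les in spec@lesions) {
    m <- .ellipsoidMask(d, les$center, les$radii)
    gt[m] <- 1
    postClean[m] <- postClean[m] + les$delta
  }
  postWarped <- applyAffineVolume(VolumeImage(postClean),
                                  spec@misalignment,
                                  interpolation = "bicubic")@data
  set.seed(spec@seed)
  pre <- ricianNoise(preClean, spec@noiseSigma)
  post <- ricianNoise(postWarped, spec@noiseSigma)
  list(pre = VolumeImage(pre), post = VolumeImage(post),
       gt = BinaryMask(gt),
       clean = list(pre = VolumeImage(preClean),
                    post = VolumeImage(postClean),
                    sub = VolumeImage(pmax(postClean - preClean, 0))))
}

#' Serialize a phantom spec to a YAML-friendly list
#'
#' @param spec a [PhantomSpec-class]
#' @param path optional YAML output path
#' @return list (invisibly when written)
#' @export
phantomSpecAsList <- function(spec, path = NULL) {
  x <- list(shape = as.integer(spec@shape),
            lesions = lapply(spec@lesions, function(l)
              list(center = as.numeric(l$center),
                   radii = as.numeric(l$radii), delta = l$delta)),
            background = spec@background,
            texture_amplitude = spec@textureAmplitude,
            noise_sigma = spec@noiseSigma,
            misalignment = as.list(affineParameters(spec@misalignment)),
            seed = spec@seed)
  if (!is.null(path)) {
    yaml::write_yaml(x, path)
    return(invisible(x))
  }
  x
}
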