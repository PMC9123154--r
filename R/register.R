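# Affine registration of the post-contrast (moving) volume onto the
# pre-contrast (fixed) volume: mono-modal robust mean-squared-error metric,
# derivative-free simplex optimization, optional multiresolution pyramid. The
# pair share a scanner, so an intensity metric suffices; residuals beyond
# robustK median absolute deviations are excluded, which makes the metric
# robust to the contrast enhancement itself: the enhancement appears only in
# the post frame and would otherwise bias the plain MSE optimum away from
# the true alignment. A MAD cut (rather than a fixed trim fraction) adapts
# to any lesion size.
#
# Two noise-robustness measures for the shared-transform mode: the metric is
# computed on the z-mean slab (the transform is common to all slices, so
# averaging boosts SNR by sqrt(nz) without touching the alignment signal),
# and both slabs are Gaussian-prefiltered. The prefilter also damps a subtle
# interpolation artifact: resampling smooths noise by a fractional-shift-
# dependent factor, which under heavy noise rewards half-pixel shifts and
# zero rotation over true alignment.

# 2x in-plane block-mean downsampling of a (z, y, x) array
.downsample2 <- function(a) {
  d <- dim(a)
  nr <- d[2] %/% 2L; nc <- d[3] %/% 2L
  if (nr < 8L || nc < 8L) return(NULL)
  a <- a[, seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
  (a[, seq(1, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
   a[, seq(2, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
   a[, seq(1, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE] +
   a[, seq(2, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE]) / 4
}

# robust MSE between fixed and warped moving over a central crop (the crop
# discards the zero-filled band the warp vacates near the border; the MAD
# cut discards the enhancement residuals)
.regObjective <- function(params, moving, fixed, mode, robustK) {
  t <- .paramsToTransform(params, mode)
  d <- dim(fixed)
  my <- max(2L, ceiling(0.1 * d[2])); mx <- max(2L, ceiling(0.1 * d[3]))
  ys <- (my + 1L):(d[2] - my); xs <- (mx + 1L):(d[3] - mx)
  r <- numeric(0)
  for (z in seq_len(d[1])) {
    w <- applyAffine(moving[z, , , drop = TRUE], t, interpolation = "bilinear")
    r <- c(r, w[ys, xs] - fixed[z, ys, xs, drop = TRUE])
  }
  if (robustK > 0) {
    md <- stats::mad(r)
    if (md > 1e-12) r <- r[abs(r) <= robustK * md]
  }
  mean(r^2)
}

.paramsToTransform <- function(p, mode) {
  if (mode == "rigid") composeAffine(p[1], p[2], p[3])
  else composeAffine(p[1], p[2], p[3], p[4], exp(p[5]), exp(p[6]))
}

#' Register the post-contrast volume to the pre-contrast volume
#'
#' Estimates one in-plane affine transform \code{t} (shared by all slices by
#' default; rigid-body patient shift assumption) minimizing the trimmed
#' mean-squared intensity error between \code{applyAffine(moving, t)} and
#' \code{fixed}, over a multiresolution pyramid with deterministic identity
#' initialization. Residuals beyond \code{robustK} median absolute
#' deviations are excluded from the metric, keeping it insensitive to the
#' contrast enhancement, which exists only in the post frame and would
#' otherwise drag a plain MSE optimum off the true alignment.
#' \code{perSlice = TRUE} estimates an independent transform per slice.
#'
#' @param moving,fixed [VolumeImage-class]s of identical shape (moving = post,
#'   fixed = pre)
#' @param mode \code{"rigid"} (tx, ty, theta; default) or \code{"affine"}
#'   (all six parameters)
#' @param levels pyramid levels (coarsest is \code{2^(levels-1)}-fold
#'   downsampled). The default is single-resolution: the robust metric's
#'   MAD cut becomes unreliable on heavily downsampled slabs where the
#'   lesion dominates the pixel count, and the simplex search on the z-mean
#'   slab has ample capture range for patient-shift-scale misalignments.
#' @param maxIter optimizer iterations per level
#' @param tol relative convergence tolerance of the optimizer
#' @param robustK residuals beyond this many median absolute deviations are
#'   excluded from the metric (0 = plain MSE)
#' @param smoothSigma Gaussian prefilter sigma (px) applied to both inputs
#'   before the metric (0 disables)
#' @param perSlice estimate one transform per slice
#' @return a list with components \code{transform} (an
#'   [AffineTransform2D-class], or list of them when \code{perSlice}),
#'   \code{metric} (final MSE) and \code{converged}
#' @export
registerAffine <- function(moving, fixed, mode = c("rigid", "affine"),
                           levels = 1, maxIter = 400, tol = 1e-6,
                           robustK = 6, smoothSigma = 1.5, perSlice = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(moving, "VolumeImage"), is(fixed, "VolumeImage"))
  if (!all(dim(moving@data) == dim(fixed@data)))
    stop("moving and fixed volumes must have identical shape", call. = FALSE)
  if (!perSlice) {
    # shared transform: collapse to the z-mean slab
    mov <- .zmeanSlab(moving@data, smoothSigma)
    fix <- .zmeanSlab(fixed@data, smoothSigma)
    return(.registerArrays(mov, fix, mode, levels, maxIter, tol, robustK))
  }
  d <- dim(moving@data)
  res <- lapply(seq_len(d[1]), function(z)
    .registerArrays(.zmeanSlab(moving@data[z, , , drop = FALSE], smoothSigma),
                    .zmeanSlab(fixed@data[z, , , drop = FALSE], smoothSigma),
                    mode, levels, maxIter, tol, robustK))
  list(transform = lapply(res, `[[`, "transform"),
       metric = vapply(res, `[[`, numeric(1), "metric"),
       converged = all(vapply(res, `[[`, logical(1), "converged")))
}

# z-mean a (z, y, x) array into a 1-slice array, with optional Gaussian blur
.zmeanSlab <- function(a, smoothSigma) {
  m <- matrix(apply(a, c(2, 3), mean), dim(a)[2], dim(a)[3])
  array(.gaussBlur(m, smoothSigma), c(1L, dim(m)))
}

.registerArrays <- function(mov, fix, mode, levels, maxIter, tol, robustK) {
  pyrM <- list(mov); pyrF <- list(fix)
  for (l in seq_len(levels - 1)) {
    dn <- .downsample2(pyrM[[1]])
    if (is.null(dn)) break
    pyrM <- c(list(dn), pyrM)
    pyrF <- c(list(.downsample2(pyrF[[1]])), pyrF)
  }
  np <- if (mode == "rigid") 3L else 6L
  p <- numeric(np)  # identity
  scale <- if (mode == "rigid") c(1, 1, 0.02) else c(1, 1, 0.02, 0.02, 0.02, 0.02)
  conv <- TRUE
  for (l in seq_along(pyrM)) {
    if (l > 1) p[1:2] <- p[1:2] * 2   # translations double with resolution
    opt <- stats::optim(p, .regObjective, moving = pyrM[[l]], fixed = pyrF[[l]],
                        mode = mode, robustK = robustK, method = "Nelder-Mead",
                        control = list(maxit = maxIter, reltol = tol,
                                       parscale = scale))
    p <- opt$par
    conv <- conv && (opt$convergence == 0L)
  }
  list(transform = .paramsToTransform(p, mode),
       metric = opt$value, converged = conv)
}
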