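# In-plane affine transforms and slice resampling.

.affineMatrixFromParams <- function(tx, ty, theta, k, sx, sy) {
  tc <- cos(theta); ts <- sin(theta)
  matrix(c(sx * tc, sx * ts, 0,
           sy * (k * tc - ts), sy * (k * ts + tc), 0,
           tx, ty, 1), 3, 3)
}

#' Compose a six-parameter in-plane affine transform
#'
#' Builds the product Translation . Rotation . Shear . Scale:
#' \deqn{A = \begin{pmatrix}1&0&t_x\\0&1&t_y\\0&0&1\end{pmatrix}
#' \begin{pmatrix}\cos\theta&-\sin\theta&0\\\sin\theta&\cos\theta&0\\0&0&1\end{pmatrix}
#' \begin{pmatrix}1&k&0\\0&1&0\\0&0&1\end{pmatrix}
#' \begin{pmatrix}s_x&0&0\\0&s_y&0\\0&0&1\end{pmatrix}}
#'
#' @param tx,ty translation in pixels
#' @param theta rotation in radians, clockwise in the y-down image convention
#' @param k shear factor
#' @param sx,sy scale factors (> 0)
#' @return an [AffineTransform2D-class]
#' @examples
#' affineMatrix(composeAffine(2, 3))          # pure translation
#' affineMatrix(composeAffine(theta = pi/2))  # pure rotation
#' @export
composeAffine <- function(tx = 0, ty = 0, theta = 0, k = 0, sx = 1, sy = 1) {
  if (sx <= 0 || sy <= 0)
    stop("scale factors must be positive", call. = FALSE)
  tx <- unname(tx); ty <- unname(ty); theta <- unname(theta)
  k <- unname(k); sx <- unname(sx); sy <- unname(sy)
  new("AffineTransform2D", tx = tx, ty = ty, theta = theta, k = k,
      sx = sx, sy = sy,
      matrix = .affineMatrixFromParams(tx, ty, theta, k, sx, sy))
}

# recover (tx, ty, theta, k, sx, sy) from a homogeneous matrix in the
# T.R.Sh.Sc parameterization
.affineDecompose <- function(m) {
  sx <- sqrt(m[1, 1]^2 + m[2, 1]^2)
  theta <- atan2(m[2, 1], m[1, 1])
  tc <- cos(theta); ts <- sin(theta)
  # rotate the second column back: R(-theta) %*% col2 = (sy*k, sy)
  r2 <- c(tc * m[1, 2] + ts * m[2, 2], -ts * m[1, 2] + tc * m[2, 2])
  sy <- r2[2]
  k <- if (abs(sy) > .Machine$double.eps) r2[1] / sy else 0
  c(tx = m[1, 3], ty = m[2, 3], theta = theta, k = k, sx = sx, sy = sy)
}

#' Invert an affine transform
#'
#' @param t an [AffineTransform2D-class]
#' @return the inverse [AffineTransform2D-class]
#' @export
invertAffine <- function(t) {
  m <- solve(affineMatrix(t))
  p <- .affineDecompose(m)
  if (p["sy"] <= 0)
    stop("inverse leaves the T.R.Sh.Sc parameter domain (sy <= 0)",
         call. = FALSE)
  composeAffine(p["tx"], p["ty"], p["theta"], p["k"], p["sx"], p["sy"])
}

# gather img values at (possibly out-of-range) 1-based integer indices
.sampleAt <- function(img, iy, ix, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- iy >= 1L & iy <= nr & ix >= 1L & ix <= nc
  v <- rep(fill, length(iy))
  v[ok] <- img[cbind(iy[ok], ix[ok])]
  v
}

# Keys cubic-convolution kernel, a = -0.5 (bicubic)
.cubicKernel <- function(t) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (1.5 * at[i1] - 2.5) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- ((-0.5 * at[i2] + 2.5) * at[i2] - 4) * at[i2] + 2
  w
}

#' Resample a 2-D slice under an affine transform
#'
#' Output pixels pull intensities from the inverse-mapped source position:
#' \code{out(p) = img(Ac^{-1}(p))}, where \code{Ac} is the transform applied
#' about the image center (pixel centers at 0-based indices, center at
#' \code{((ncol-1)/2, (nrow-1)/2)}); a pure translation is unaffected by the
#' centering. Out-of-domain samples are filled with \code{fill}.
#'
#' @param img numeric matrix (y, x)
#' @param t an [AffineTransform2D-class]
#' @param interpolation \code{"bicubic"} (Keys cubic convolution, a = -0.5),
#'   \code{"bilinear"} or \code{"nearest"}
#' @param fill out-of-field value (default 0)
#' @return resampled matrix of the same shape
#' @export
applyAffine <- function(img, t,
                        interpolation = c("bicubic", "bilinear", "nearest"),
                        fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.matrix(img), all(is.finite(img)))
  m <- affineMatrix(t)
  if (abs(det(m[1:2, 1:2])) < 1e-12)
    stop("singular transform matrix", call. = FALSE)
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  minv <- solve(m)
  # output pixel grid, 0-based, centered
  px <- rep(0:(nc - 1), each = nr) - cx
  py <- rep(0:(nr - 1), times = nc) - cy
  sx <- minv[1, 1] * px + minv[1, 2] * py + minv[1, 3] + cx
  sy <- minv[2, 1] * px + minv[2, 2] * py + minv[2, 3] + cy

  out <- switch(interpolation,
    nearest = .sampleAt(img, as.integer(round(sy)) + 1L,
                        as.integer(round(sx)) + 1L, fill),
    bilinear = {
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      v00 <- .sampleAt(img, y0 + 1L, x0 + 1L, fill)
      v01 <- .sampleAt(img, y0 + 1L, x0 + 2L, fill)
      v10 <- .sampleAt(img, y0 + 2L, x0 + 1L, fill)
      v11 <- .sampleAt(img, y0 + 2L, x0 + 2L, fill)
      (1 - fy) * ((1 - fx) * v00 + fx * v01) +
        fy * ((1 - fx) * v10 + fx * v11)
    },
    bicubic = {
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      acc <- numeric(length(sx))
      for (j in -1:2) {
        wyj <- .cubicKernel(fy - j)
        rowacc <- numeric(length(sx))
        for (i in -1:2) {
          wxi <- .cubicKernel(fx - i)
          rowacc <- rowacc +
            wxi * .sampleAt(img, y0 + 1L + j, x0 + 1L + i, fill)
        }
        acc <- acc + wyj * rowacc
      }
      acc
    })
  matrix(out, nr, nc)
}

#' Resample every slice of a volume under one in-plane transform
#'
#' @param vol a [VolumeImage-class]
#' @param t an [AffineTransform2D-class] (shared by all slices) or a list of
#'   per-slice transforms
#' @inheritParams applyAffine
#' @return a [VolumeImage-class]
#' @export
applyAffineVolume <- function(vol, t, interpolation = "bicubic", fill = 0) {
  stopifnot(is(vol, "VolumeImage"))
  d <- dim(vol@data)
  out <- vol@data
  for (z in seq_len(d[1])) {
    tz <- if (is.list(t)) t[[z]] else t
    out[z, , ] <- applyAffine(vol@data[z, , , drop = TRUE], tz,
                              interpolation = interpolation, fill = fill)
  }
  VolumeImage(out, vol@spacing)
}

#' Subtract the pre-contrast volume from the registered post-contrast volume
#'
#' \code{Isub = max(Ireg - Ipre, 0)}: negative differences are clamped to 0 so
#' downstream amplitude statistics stay nonnegative.
#'
#' @param postRegistered,pre [VolumeImage-class]s of identical shape
#' @return a [VolumeImage-class]
#' @export
subtractVolumes <- function(postRegistered, pre) {
  stopifnot(is(postRegistered, "VolumeImage"), is(pre, "VolumeImage"))
  if (!all(dim(postRegistered@data) == dim(pre@data)))
    stop("shape mismatch between volumes", call. = FALSE)
  VolumeImage(pmax(postRegistered@data - pre@data, 0), pre@spacing)
}

#' Serialize an affine transform to a 6-number JSON record
#'
#' @param t an [AffineTransform2D-class]
#' @param path optional output file; when NULL the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
exportAffineJSON <- function(t, path = NULL) {
  js <- jsonlite::toJSON(as.list(affineParameters(t)),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
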