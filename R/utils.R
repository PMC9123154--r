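# Internal helpers shared across modules.

#' Construct a VolumeImage
#'
#' @param data numeric 3-D array in (z, y, x) order, or a matrix (treated as a
#'   single slice).
#' @param spacing voxel spacing (z, y, x) in mm.
#' @return a [VolumeImage-class]
#' @export
VolumeImage <- function(data, spacing = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  new("VolumeImage", data = data, spacing = as.numeric(spacing))
}

#' Construct a BinaryMask
#'
#' @inheritParams VolumeImage
#' @return a [BinaryMask-class]
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  new("BinaryMask", data = data, spacing = as.numeric(spacing))
}

#' Binarize a volume into a mask
#'
#' Any value greater than zero maps to 1 (tolerant of \{0, 255\} mask
#' exports); the operation is idempotent.
#'
#' @param vol a [VolumeImage-class], array or matrix
#' @return a [BinaryMask-class]
#' @export
asBinaryMask <- function(vol) {
  if (is(vol, "BinaryMask")) return(vol)
  if (is(vol, "VolumeImage")) {
    BinaryMask((vol@data > 0) * 1, vol@spacing)
  } else {
    BinaryMask((vol > 0) * 1)
  }
}

# apply a per-slice function over a (z, y, x) volume array
.mapSlices <- function(vol, f, ...) {
  d <- dim(vol)
  out <- vol
  for (z in seq_len(d[1])) out[z, , ] <- f(vol[z, , , drop = TRUE], ...)
  out
}

# shift a matrix by (dy, dx), filling vacated cells
.shiftMatrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  if (dy <= -nr || dy >= nr || dx <= -nc || dx >= nc) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# reflect-pad a matrix by r rows/cols on each side (edge mirrored, no repeat
# of the border pixel beyond what reflection gives)
.padReflect <- function(m, ry, rx = ry) {
  nr <- nrow(m); nc <- ncol(m)
  iy <- c(rev(seq_len(min(ry, nr))), seq_len(nr),
          nr + 1 - rev(seq_len(min(ry, nr))))
  if (ry > nr) iy <- rep(iy, length.out = nr + 2 * ry)  # degenerate tiny input
  ix <- c(rev(seq_len(min(rx, nc))), seq_len(nc),
          nc + 1 - rev(seq_len(min(rx, nc))))
  m[iy, ix, drop = FALSE]
}

# local (moving-window) mean with reflect padding, window (Y, X) odd
.localMean <- function(m, win) {
  ry <- (win[1] - 1L) %/% 2L
  rx <- (win[2] - 1L) %/% 2L
  p <- .padReflect(m, ry, rx)
  # separable box filter via cumulative sums
  cs <- apply(p, 2, cumsum)
  rowsum <- cs[(1 + 2 * ry):nrow(p), , drop = FALSE]
  if (ry > 0)
    rowsum <- rowsum - rbind(0, cs[seq_len(nrow(p) - 2 * ry - 1), , drop = FALSE])
  cs2 <- t(apply(rowsum, 1, cumsum))
  if (nrow(rowsum) == 1L) cs2 <- matrix(cumsum(rowsum[1, ]), 1L)
  total <- cs2[, (1 + 2 * rx):ncol(p), drop = FALSE]
  if (rx > 0)
    total <- total - cbind(0, cs2[, seq_len(ncol(p) - 2 * rx - 1), drop = FALSE])
  total / (win[1] * win[2])
}

# separable Gaussian blur with reflect padding, kernel truncated at 3 sigma
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  p <- .padReflect(m, r, r)
  a <- apply(p, 2, function(col)
    stats::filter(col, k)[(r + 1):(length(col) - r)])
  t(apply(a, 1, function(row)
    stats::filter(row, k)[(r + 1):(length(row) - r)]))
}

.stopIfNot3D <- function(a, what = "volume") {
  if (length(dim(a)) != 3L)
    stop(what, " must be 3-D (z, y, x); got ",
         paste(dim(a), collapse = " x "), call. = FALSE)
}
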