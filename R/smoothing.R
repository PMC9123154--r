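# Edge-preserving smoothing between denoising and segmentation.

#' Pixel-wise adaptive Wiener filter
#'
#' \deqn{out = m_f + \frac{\sigma_f^2 - v^2}{\sigma_f^2}(img - m_f)}
#' with local mean \eqn{m_f} and variance \eqn{\sigma_f^2} over an odd
#' \code{(X, Y)} window (reflect padding). The gain
#' \eqn{(\sigma_f^2 - v^2)/\sigma_f^2} is clamped to [0, 1]: pixels whose
#' local variance is at or below the noise power \eqn{v^2} collapse to the
#' local mean, pixels far above it pass through. When \code{v2} is omitted it
#' is estimated as the mean of \eqn{\sigma_f^2} over the image.
#'
#' @param img numeric matrix
#' @param window odd window extents (Y, X); default 5 x 5
#' @param v2 noise variance; NULL to estimate
#' @return filtered matrix
#' @export
adaptiveWiener <- function(img, window = c(5, 5), v2 = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  window <- as.integer(window)
  if (length(window) == 1L) window <- c(window, window)
  if (any(window < 1L) || any(window %% 2L == 0L))
    stop("window extents must be odd and >= 1", call. = FALSE)
  mf <- .localMean(img, window)
  varf <- pmax(.localMean(img^2, window) - mf^2, 0)
  if (is.null(v2)) v2 <- mean(varf)
  if (v2 < 0) stop("noise variance must be >= 0", call. = FALSE)
  gain <- (varf - v2) / pmax(varf, 1e-12)
  gain <- pmin(pmax(gain, 0), 1)
  mf + gain * (img - mf)
}

#' Bilateral filter
#'
#' Normalized product of a spatial Gaussian (sigma \code{sigmaSpatial},
#' truncated at 3 sigma) and a range Gaussian (sigma \code{sigmaRange}) over
#' the neighborhood, with reflect padding. Output intensities stay within
#' \code{[min(img), max(img)]}.
#'
#' @param img numeric matrix
#' @param sigmaSpatial spatial standard deviation in pixels (> 0)
#' @param sigmaRange range (intensity) standard deviation (> 0)
#' @return filtered matrix
#' @export
bilateralFilter <- function(img, sigmaSpatial = 2, sigmaRange = 15) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (sigmaSpatial <= 0 || sigmaRange <= 0)
    stop("both sigmas must be positive", call. = FALSE)
  r <- max(1L, as.integer(ceiling(3 * sigmaSpatial)))
  p <- .padReflect(img, r, r)
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(0, nr, nc)
  wsum <- matrix(0, nr, nc)
  inv2ss <- 1 / (2 * sigmaSpatial^2)
  inv2sr <- 1 / (2 * sigmaRange^2)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ws <- exp(-(dy * dy + dx * dx) * inv2ss)
      nb <- p[(r + 1 + dy):(r + nr + dy), (r + 1 + dx):(r + nc + dx)]
      w <- ws * exp(-(nb - img)^2 * inv2sr)
      acc <- acc + w * nb
      wsum <- wsum + w
    }
  }
  acc / wsum
}
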