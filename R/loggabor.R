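# Log-Gabor wavelet filter bank on the 2-D frequency grid.
#
# Radial transfer: exp(-(ln(f/f0))^2 / (2 ln(sigmaOnF)^2)), Gaussian in log
# frequency, hence strictly zero DC gain. Angular window: Gaussian in the
# angular distance to the orientation axis (one-sided, so the complex inverse
# transform yields an even/odd quadrature pair). A high-order Butterworth
# low-pass (cutoff 0.45 cycles/px) suppresses the frequency-plane corners.

# frequency coordinate along an axis of length n, FFT (unshifted) order,
# cycles per pixel
.fftFreq <- function(n) {
  (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Build a log-Gabor filter bank
#'
#' @param shape (rows, cols) of the slices the bank will filter; both >= 8
#' @param nScales number of wavelet scales (>= 1)
#' @param nOrientations number of orientations (>= 1)
#' @param minWavelength center wavelength of the finest scale, in pixels;
#'   must not exceed the image extent
#' @param mult wavelength multiplier between successive scales
#' @param sigmaOnF radial bandwidth parameter in (0, 1)
#' @param angularFactor angular spread divisor; angular sigma =
#'   \code{pi / nOrientations / angularFactor}
#' @return a [LogGaborBank-class]
#' @examples
#' bank <- buildLogGaborBank(c(64, 64), nScales = 2, nOrientations = 15)
#' length(bank@filters)  # 30
#' @export
buildLogGaborBank <- function(shape, nScales = 8, nOrientations = 6,
                              minWavelength = 3, mult = 2.1,
                              sigmaOnF = 0.55, angularFactor = 1.5) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    stop("shape must be (rows, cols) with both dimensions >= 8", call. = FALSE)
  if (nScales < 1L || nOrientations < 1L)
    stop("need at least one scale and one orientation", call. = FALSE)
  if (minWavelength < 2)
    stop("minWavelength below 2 px exceeds the Nyquist limit", call. = FALSE)
  if (minWavelength > min(shape))
    stop("minWavelength exceeds the image extent", call. = FALSE)
  if (sigmaOnF <= 0 || sigmaOnF >= 1)
    stop("sigmaOnF must lie in (0, 1)", call. = FALSE)

  nr <- shape[1]; nc <- shape[2]
  uy <- .fftFreq(nr); ux <- .fftFreq(nc)
  UX <- matrix(ux, nr, nc, byrow = TRUE)
  UY <- matrix(uy, nr, nc)
  radius <- sqrt(UX^2 + UY^2)
  radius[1, 1] <- 1          # avoid log(0); DC forced to zero below
  angle <- atan2(UY, UX)
  sintheta <- sin(angle); costheta <- cos(angle)
  lowpass <- 1 / (1 + (radius / 0.45)^30)

  thetaSigma <- pi / nOrientations / angularFactor
  logSigma2 <- 2 * log(sigmaOnF)^2

  filters <- vector("list", nScales * nOrientations)
  energy <- matrix(0, nScales, nOrientations)
  coverage <- matrix(0, nr, nc)
  flipIdx <- list(c(1L, if (nr > 1) nr:2L), c(1L, if (nc > 1) nc:2L))

  for (s in seq_len(nScales)) {
    f0 <- 1 / (minWavelength * mult^(s - 1))
    radial <- exp(-(log(radius / f0))^2 / logSigma2) * lowpass
    radial[1, 1] <- 0
    for (o in seq_len(nOrientations)) {
      angl <- (o - 1) * pi / nOrientations
      ds <- sintheta * cos(angl) - costheta * sin(angl)
      dc <- costheta * cos(angl) + sintheta * sin(angl)
      dtheta <- abs(atan2(ds, dc))
      f <- radial * exp(-dtheta^2 / (2 * thetaSigma^2))
      mx <- max(f)
      if (mx <= 0) stop("degenerate filter (all-zero transfer)", call. = FALSE)
      f <- f / mx
      filters[[(s - 1) * nOrientations + o]] <- f
      energy[s, o] <- sum(f^2)
      coverage <- coverage + (f + f[flipIdx[[1]], flipIdx[[2]]]) / 2
    }
  }
  new("LogGaborBank", nScales = as.integer(nScales),
      nOrientations = as.integer(nOrientations),
      minWavelength = minWavelength, mult = mult, sigmaOnF = sigmaOnF,
      angularFactor = angularFactor, shape = shape, filters = filters,
      filterEnergy = energy, evenCoverage = coverage)
}

#' Complex wavelet responses of a slice
#'
#' For each (scale, orientation) filter \code{M}, the response is the inverse
#' FFT of \code{fft(slice) * M}. Because the filters are one-sided in the
#' frequency plane, the real part of the complex response is the
#' even-symmetric filter output and the imaginary part the odd-symmetric one;
#' amplitude and phase follow as \code{Mod} and \code{Arg}.
#'
#' @param slice numeric matrix matching the bank's shape
#' @param bank a [LogGaborBank-class]
#' @return a [WaveletResponseSet-class]
#' @export
waveletResponses <- function(slice, bank) {
  stopifnot(is(bank, "LogGaborBank"))
  if (!is.matrix(slice) || !all(dim(slice) == bank@shape))
    stop("slice shape does not match the bank", call. = FALSE)
  if (!all(is.finite(slice))) stop("slice must be finite", call. = FALSE)
  spec <- stats::fft(slice)
  n <- length(slice)
  responses <- lapply(bank@filters, function(f)
    stats::fft(spec * f, inverse = TRUE) / n)
  new("WaveletResponseSet", responses = responses, bank = bank)
}

setMethod("amplitudes", "WaveletResponseSet", function(x)
  lapply(x@responses, Mod))

setMethod("phases", "WaveletResponseSet", function(x)
  lapply(x@responses, Arg))

#' Reconstruct a slice from wavelet responses
#'
#' Sums the even-symmetric (real) response parts over all scales and
#' orientations, then divides the summed spectrum by the bank's even-coverage
#' transfer wherever that transfer exceeds 20% of its peak. The overlapping
#' radial and angular windows give the raw sum a passband gain well above 1;
#' the normalization makes reconstruction close to the identity on the
#' covered band. Frequencies outside the covered band (including DC) are not
#' recoverable and come back as 0.
#'
#' @param resp a [WaveletResponseSet-class]
#' @param normalize divide by the even-coverage transfer (default TRUE);
#'   FALSE returns the plain sum of even-symmetric responses
#' @return numeric matrix
#' @export
reconstructImage <- function(resp, normalize = TRUE) {
  stopifnot(is(resp, "WaveletResponseSet"))
  s <- Reduce(`+`, lapply(resp@responses, Re))
  if (!normalize) return(s)
  cov <- resp@bank@evenCoverage
  w <- ifelse(cov > 0.2 * max(cov), 1 / pmax(cov, 1e-12), 0)
  Re(stats::fft(stats::fft(s) * w, inverse = TRUE)) / length(s)
}
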