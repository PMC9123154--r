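# Rayleigh noise model for wavelet amplitude shrinkage.
#
# The amplitude of filtered complex Gaussian background noise is Rayleigh
# distributed. Its scale at the finest wavelet scale is estimated robustly
# from the median amplitude (median = sigma*sqrt(2 ln 2)), propagated to
# coarser scales through each filter's noise gain (square root of the
# transfer-energy ratio), and converted into the shrink threshold
# tau = mu_R + c * sd_R.

#' Rayleigh distribution moments and threshold
#'
#' Closed forms for a Rayleigh distribution with scale \code{sigma}:
#' mean \eqn{\sigma\sqrt{\pi/2}}, variance \eqn{(4-\pi)\sigma^2/2},
#' median \eqn{\sigma\sqrt{2\ln 2}}, and the noise threshold
#' \eqn{\tau = \mu_R + c\,\sigma_R}.
#'
#' @param sigma Rayleigh scale parameter (>= 0)
#' @param c threshold multiplier (defaults to 1)
#' @return numeric
#' @examples
#' rayleighMedian(1)        # 1.1774
#' rayleighThreshold(1, 1)  # 1.9084
#' @export
rayleighMean <- function(sigma) sigma * sqrt(pi / 2)

#' @rdname rayleighMean
#' @export
rayleighVar <- function(sigma) (4 - pi) / 2 * sigma^2

#' @rdname rayleighMean
#' @export
rayleighMedian <- function(sigma) sigma * sqrt(2 * log(2))

#' @rdname rayleighMean
#' @export
rayleighThreshold <- function(sigma, c = 1) {
  if (any(c < 0)) stop("threshold multiplier must be >= 0", call. = FALSE)
  rayleighMean(sigma) + c * sqrt(rayleighVar(sigma))
}

#' Estimate the Rayleigh noise model from wavelet responses
#'
#' For each orientation, the Rayleigh scale is estimated at the smallest
#' (finest) wavelet scale by inverting the median formula:
#' \code{sigma = median(A) / sqrt(2 ln 2)}. The finest scale carries the
#' least signal energy relative to noise, making its median a robust noise
#' statistic. Scales 2..n inherit the estimate multiplied by the noise-gain
#' ratio \code{sqrt(E_s / E_1)} of the bank's transfer energies, and every
#' (scale, orientation) gets the threshold \code{tau = mu_R + c * sd_R}.
#'
#' @param resp a [WaveletResponseSet-class]
#' @param c threshold multiplier; \code{c = 1} rejects noise up to one
#'   Rayleigh standard deviation above the Rayleigh mean
#' @return a [RayleighNoiseModel-class]; all-zero amplitudes yield tau = 0
#'   with the \code{degenerate} flag set (and a warning)
#' @export
estimateNoiseModel <- function(resp, c = 1) {
  stopifnot(is(resp, "WaveletResponseSet"))
  if (c < 0) stop("threshold multiplier must be >= 0", call. = FALSE)
  bank <- resp@bank
  nS <- bank@nScales; nO <- bank@nOrientations
  sigma <- numeric(nO)
  tau <- matrix(0, nS, nO)
  for (o in seq_len(nO)) {
    a1 <- Mod(resp@responses[[o]])    # scale 1 stored first
    sigma[o] <- stats::median(a1) / sqrt(2 * log(2))
    gain <- sqrt(bank@filterEnergy[, o] / bank@filterEnergy[1, o])
    tau[, o] <- rayleighThreshold(sigma[o] * gain, c)
  }
  degenerate <- all(tau == 0)
  if (degenerate)
    warning("all response amplitudes are zero; noise threshold is 0",
            call. = FALSE)
  new("RayleighNoiseModel", sigma = sigma, c = c, tau = tau,
      degenerate = degenerate)
}

#' Soft-shrink response amplitudes against the noise threshold
#'
#' Amplitudes are reduced by the per-(scale, orientation) threshold,
#' \code{A' = max(A - tau, 0)}, while the phase of every surviving response
#' is preserved exactly. Amplitudes never increase.
#'
#' @param resp a [WaveletResponseSet-class]
#' @param model a [RayleighNoiseModel-class] (or a single nonnegative
#'   threshold applied to every filter)
#' @return a shrunk [WaveletResponseSet-class]
#' @export
shrinkResponses <- function(resp, model) {
  stopifnot(is(resp, "WaveletResponseSet"))
  bank <- resp@bank
  tau <- if (is(model, "RayleighNoiseModel")) model@tau
         else matrix(model, bank@nScales, bank@nOrientations)
  if (any(tau < 0)) stop("negative threshold", call. = FALSE)
  out <- resp@responses
  for (s in seq_len(bank@nScales)) {
    for (o in seq_len(bank@nOrientations)) {
      i <- (s - 1) * bank@nOrientations + o
      a <- Mod(out[[i]])
      shrunk <- pmax(a - tau[s, o], 0)
      ratio <- ifelse(a > 0, shrunk / a, 0)
      out[[i]] <- out[[i]] * ratio
    }
  }
  new("WaveletResponseSet", responses = out, bank = bank)
}
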