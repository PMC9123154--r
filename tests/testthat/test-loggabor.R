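test_that("bank invariants: zero DC, unit peak, cardinality", {
  bank <- buildLogGaborBank(c(64, 64), nScales = 2, nOrientations = 15)
  expect_length(bank@filters, 30)
  for (f in bank@filters) {
    expect_equal(f[1, 1], 0)
    expect_equal(max(f), 1, tolerance = 1e-12)
    expect_gte(min(f), 0)
  }
  expect_error(buildLogGaborBank(c(4, 4)), ">= 8")
  expect_error(buildLogGaborBank(c(64, 64), minWavelength = 100), "extent")
})

test_that("a constant slice produces (near) zero responses everywhere", {
  bank <- buildLogGaborBank(c(32, 32), nScales = 3, nOrientations = 4)
  resp <- waveletResponses(matrix(123.4, 32, 32), bank)
  for (a in amplitudes(resp)) expect_lt(max(a), 1e-9 * 255)
})

test_that("amplitude and phase reassemble the complex response", {
  set.seed(6)
  bank <- buildLogGaborBank(c(32, 32), nScales = 2, nOrientations = 4)
  resp <- waveletResponses(matrix(rnorm(1024), 32), bank)
  A <- amplitudes(resp); ph <- phases(resp)
  for (i in seq_along(resp@responses)) {
    expect_lt(max(Mod(A[[i]] * exp(1i * ph[[i]]) - resp@responses[[i]])),
              1e-10)
    expect_gte(min(A[[i]]), 0)
    expect_true(all(ph[[i]] > -pi - 1e-12 & ph[[i]] <= pi + 1e-12))
  }
})

test_that("a pure cosine excites its matched filter most", {
  bank <- buildLogGaborBank(c(64, 64), nScales = 3, nOrientations = 4)
  x <- t(matrix(rep(0:63, 64), 64))
  f0 <- 1 / (3 * 2.1)               # center frequency of scale 2
  img <- cos(2 * pi * f0 * x)       # orientation 1 (variation along x)
  resp <- waveletResponses(img, bank)
  # oracle: direct frequency-domain multiplication per filter
  spec <- fft(img)
  tot <- vapply(bank@filters, function(f)
    sum(Mod(fft(spec * f, inverse = TRUE) / length(img))), numeric(1))
  expect_equal(which.max(tot), 1 * 4 + 1)   # scale 2, orientation 1
  expect_equal(vapply(amplitudes(resp), sum, numeric(1)), tot,
               tolerance = 1e-9)
})

test_that("reconstruction is linear, null on zero, near-identity in-band", {
  bank <- buildLogGaborBank(c(64, 64))
  y <- matrix(rep(0:63, 64), 64); x <- t(y)
  img <- cos(2 * pi * x / 8) + 0.5 * sin(2 * pi * (x + y) / 16) +
    0.3 * cos(2 * pi * y / 24)
  resp <- waveletResponses(img, bank)
  shr <- shrinkResponses(resp, 0)           # tau = 0: identity on responses
  rec <- reconstructImage(shr)
  expect_lt(sqrt(mean((rec - img)^2)) / sqrt(mean(img^2)), 0.05)
  # linearity
  resp2 <- resp
  resp2@responses <- lapply(resp@responses, function(r) 2.5 * r)
  expect_equal(reconstructImage(resp2), 2.5 * rec, tolerance = 1e-9)
  respZ <- resp
  respZ@responses <- lapply(resp@responses, function(r) r * 0)
  expect_true(all(reconstructImage(respZ) == 0))
})

test_that("Rayleigh closed forms hold to 1e-12", {
  expect_equal(rayleighMean(1) / 1, sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(rayleighVar(3) / 9, (4 - pi) / 2, tolerance = 1e-12)
  expect_equal(rayleighMedian(2) / 2, sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(rayleighThreshold(1, 1),
               sqrt(pi / 2) + sqrt((4 - pi) / 2), tolerance = 1e-12)
  expect_equal(rayleighThreshold(1, 1), 1.9084, tolerance = 1e-4)
})

test_that("noise model inverts the median and scales across the bank", {
  bank <- buildLogGaborBank(c(16, 16), nScales = 2, nOrientations = 2)
  resp <- waveletResponses(matrix(0, 16, 16), bank)
  # plant constant amplitude 1.1774 at the finest scale of each orientation
  for (o in 1:2)
    resp@responses[[o]] <- matrix(complex(modulus = 1.17741,
                                          argument = 0.3), 16, 16)
  model <- estimateNoiseModel(resp, c = 1)
  expect_equal(unname(model@sigma), c(1, 1), tolerance = 1e-4)
  gain <- sqrt(bank@filterEnergy[2, ] / bank@filterEnergy[1, ])
  expect_equal(model@tau[2, ], rayleighThreshold(gain, 1), tolerance = 1e-4)
  # degenerate flag on all-zero input
  respZ <- waveletResponses(matrix(0, 16, 16), bank)
  expect_warning(mz <- estimateNoiseModel(respZ), "zero")
  expect_true(mz@degenerate)
  expect_true(all(mz@tau == 0))
})

test_that("the median sigma estimator is consistent (Monte Carlo)", {
  set.seed(7)
  sigmaHat <- function(n)
    median(sqrt(rnorm(n, 0, 2)^2 + rnorm(n, 0, 2)^2)) / sqrt(2 * log(2))
  expect_gt(sigmaHat(1e6), 1.99)
  expect_lt(sigmaHat(1e6), 2.01)
  expect_lt(abs(sigmaHat(1e6) - 2), abs(sigmaHat(1e4) - 2) + 0.005)
})

test_that("shrinkage contracts amplitudes and preserves phase exactly", {
  set.seed(8)
  bank <- buildLogGaborBank(c(32, 32), nScales = 2, nOrientations = 3)
  resp <- waveletResponses(matrix(rnorm(1024, 0, 20), 32), bank)
  # pointwise soft-shrink rule
  resp@responses[[1]][1, 1] <- complex(modulus = 5, argument = 1.1)
  resp@responses[[1]][1, 2] <- complex(modulus = 1, argument = -2)
  shr <- shrinkResponses(resp, 2)
  expect_equal(Mod(shr@responses[[1]][1, 1]), 3, tolerance = 1e-12)
  expect_equal(Arg(shr@responses[[1]][1, 1]), 1.1, tolerance = 1e-12)
  expect_equal(Mod(shr@responses[[1]][1, 2]), 0)
  for (i in seq_along(resp@responses)) {
    a0 <- Mod(resp@responses[[i]]); a1 <- Mod(shr@responses[[i]])
    expect_true(all(a1 <= a0 + 1e-12))
    keep <- a1 > 0
    expect_equal(Arg(shr@responses[[i]])[keep],
                 Arg(resp@responses[[i]])[keep], tolerance = 1e-12)
  }
  expect_error(shrinkResponses(resp, -1), "negative")
  # tau = 0 is the identity
  same <- shrinkResponses(resp, 0)
  expect_equal(same@responses, resp@responses, tolerance = 1e-12)
})

test_that("larger c never increases the output amplitude energy", {
  set.seed(9)
  bank <- buildLogGaborBank(c(32, 32), nScales = 3, nOrientations = 4)
  resp <- waveletResponses(matrix(rnorm(1024, 0, 10), 32), bank)
  energy <- vapply(c(0, 0.5, 1, 2, 4), function(cc) {
    shr <- shrinkResponses(resp, estimateNoiseModel(resp, cc))
    sum(vapply(amplitudes(shr), function(a) sum(a^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(energy) <= 1e-9))
})

test_that("denoising a volume is deterministic and shape-preserving", {
  case <- generateCase(smallPhantomSpec())
  noisy <- subtractVolumes(case$post, case$pre)
  d1 <- denoiseVolume(noisy, nScales = 4)
  d2 <- denoiseVolume(noisy, nScales = 4)
  expect_identical(volData(d1), volData(d2))
  expect_identical(dim(volData(d1)), dim(volData(noisy)))
  # a noise-free smooth slice passes nearly unchanged
  y <- matrix(rep(0:63, 64), 64)
  smooth <- 100 + 30 * sin(2 * pi * y / 16) * cos(2 * pi * t(y) / 12)
  bank <- buildLogGaborBank(c(64, 64), nScales = 4)
  out <- denoiseSlice(smooth, bank)
  expect_lt(sqrt(mean((out - smooth)^2)) / sqrt(mean(smooth^2)), 0.10)
})
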