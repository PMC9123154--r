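test_that("composeAffine reproduces the elementary and composite matrices", {
  expect_equal(affineMatrix(composeAffine(2, 3)),
               matrix(c(1, 0, 0, 0, 1, 0, 2, 3, 1), 3))
  expect_equal(affineMatrix(composeAffine(theta = pi / 2)),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3), tolerance = 1e-12)
  # product of the four factor matrices, multiplied numerically
  expect_equal(affineMatrix(composeAffine(0, 0, 0, k = 1, sx = 2, sy = 3)),
               matrix(c(2, 0, 0, 3, 3, 0, 0, 0, 1), 3))
  expect_equal(affineMatrix(composeAffine()), diag(3))
  expect_error(composeAffine(sx = -1), "positive")
})

test_that("the matrix always equals the product of the four factors", {
  set.seed(3)
  for (i in 1:20) {
    p <- c(runif(2, -5, 5), runif(1, -0.5, 0.5), runif(1, -0.3, 0.3),
           runif(2, 0.7, 1.4))
    tr <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3)
    rot <- function(th) matrix(c(cos(th), sin(th), 0,
                                 -sin(th), cos(th), 0, 0, 0, 1), 3)
    shear <- function(k) matrix(c(1, 0, 0, k, 1, 0, 0, 0, 1), 3)
    scl <- function(sx, sy) diag(c(sx, sy, 1))
    expect_equal(affineMatrix(composeAffine(p[1], p[2], p[3], p[4], p[5], p[6])),
                 tr(p[1], p[2]) %*% rot(p[3]) %*% shear(p[4]) %*%
                   scl(p[5], p[6]),
                 tolerance = 1e-12)
    inv <- invertAffine(composeAffine(p[1], p[2], p[3], p[4], p[5], p[6]))
    expect_equal(affineMatrix(inv),
                 solve(affineMatrix(composeAffine(p[1], p[2], p[3], p[4],
                                                  p[5], p[6]))),
                 tolerance = 1e-9)
  }
})

test_that("applyAffine with the identity is exact", {
  set.seed(4)
  img <- matrix(rnorm(12 * 10), 12, 10)
  for (interp in c("nearest", "bilinear", "bicubic"))
    expect_equal(applyAffine(img, composeAffine(), interp), img)
})

test_that("integer translation matches the index-shift oracle", {
  set.seed(5)
  img <- matrix(runif(16 * 16), 16, 16)
  out <- applyAffine(img, composeAffine(2, 3), "bicubic")
  oracle <- matrix(0, 16, 16)
  oracle[4:16, 3:16] <- img[1:13, 1:14]   # content moves +3 rows, +2 cols
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_true(all(out[1:3, ] == 0) && all(out[, 1:2] == 0))
})

test_that("90-degree rotation permutes grid pixels as the mapping predicts", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)  # asymmetric corner pattern
  t90 <- composeAffine(theta = pi / 2)
  out <- applyAffine(img, t90, "nearest")
  # oracle: independent inverse mapping about the center (0.5, 0.5)
  minv <- solve(affineMatrix(t90))
  oracle <- img
  for (y0 in 0:1) for (x0 in 0:1) {
    src <- minv[1:2, 1:2] %*% c(x0 - 0.5, y0 - 0.5) + 0.5
    oracle[y0 + 1, x0 + 1] <- img[round(src[2]) + 1, round(src[1]) + 1]
  }
  expect_equal(out, oracle)
  expect_setequal(as.numeric(out), 1:4)
})

test_that("warping forward then back is near-identity on the interior", {
  y <- matrix(rep(1:32, 32), 32); x <- t(y)
  img <- 100 + 40 * sin(x / 5) * cos(y / 7)
  t <- composeAffine(1.3, -0.7, 0.1)
  back <- applyAffine(applyAffine(img, t, "bicubic"), invertAffine(t),
                      "bicubic")
  inner <- 8:25
  expect_lt(max(abs((back - img)[inner, inner])) / diff(range(img)), 1e-3)
})

test_that("singular transforms are rejected", {
  t <- composeAffine()
  t@matrix[1, 1] <- 0; t@matrix[2, 1] <- 0   # collapse the x axis
  expect_error(applyAffine(matrix(0, 8, 8), t), "singular")
})

test_that("subtraction clamps negatives and preserves localized enhancement", {
  a <- VolumeImage(array(50, c(2, 6, 6)))
  expect_true(all(volData(subtractVolumes(a, a)) == 0))
  b <- volData(a); b[1, 2:3, 2:3] <- 60
  s <- subtractVolumes(VolumeImage(b), a)
  expect_equal(sum(volData(s) == 10), 4)
  expect_equal(sum(volData(s)), 40)
  lower <- VolumeImage(volData(a) - 5)
  expect_true(all(volData(subtractVolumes(lower, a)) == 0))
  expect_error(subtractVolumes(a, VolumeImage(array(0, c(1, 6, 6)))),
               "mismatch")
})

test_that("registration recovers identity and injected transforms", {
  case <- generateCase(smallPhantomSpec(noiseSigma = 0,
                                        misalignment = composeAffine()))
  reg <- registerAffine(case$post, case$pre)
  p <- affineParameters(reg$transform)
  expect_lt(abs(p["tx"]), 0.1)
  expect_lt(abs(p["ty"]), 0.1)
  expect_lt(abs(p["theta"]), 0.005)

  for (inj in list(c(3.5, -2.25, 0), c(2, -1, 0.05))) {
    case <- generateCase(smallPhantomSpec(
      noiseSigma = 0, misalignment = composeAffine(inj[1], inj[2], inj[3])))
    reg <- registerAffine(case$post, case$pre)
    rec <- affineParameters(invertAffine(reg$transform))
    expect_lt(abs(rec["tx"] - inj[1]), 0.5)
    expect_lt(abs(rec["ty"] - inj[2]), 0.5)
    expect_lt(abs(rec["theta"] - inj[3]), 0.01)
  }
})

test_that("translation recovery error shrinks with the injected magnitude", {
  errs <- vapply(c(4, 2, 0.5), function(mag) {
    case <- generateCase(smallPhantomSpec(
      noiseSigma = 0, misalignment = composeAffine(mag, -mag / 2, 0)))
    rec <- affineParameters(invertAffine(registerAffine(case$post,
                                                        case$pre)$transform))
    sqrt(mean((rec[c("tx", "ty")] - c(mag, -mag / 2))^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-3))  # non-increasing (tiny float slack)
})
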