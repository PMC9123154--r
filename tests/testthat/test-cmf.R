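test_that("capacity construction matches its defining formulas", {
  img <- matrix(c(10, 10, 80, 80), 2, 2)
  cap <- buildCapacities(img, fgMean = 80, bgMean = 10, alpha = 1,
                         lambdaTV = 2)
  expect_true(all(cap@Ct[img == 80] == 0))
  expect_true(all(cap@Cs[img == 10] == 0))
  expect_equal(cap@Cs, abs(img - 10))
  expect_equal(cap@Ct, abs(img - 80))
  expect_true(all(cap@C == 2))
  # flat image with edge-adaptive capacities: C stays at lambda
  flat <- matrix(5, 4, 4)
  capF <- buildCapacities(flat, fgMean = 9, bgMean = 1, lambdaTV = 3,
                          edgeAdaptive = TRUE)
  expect_true(all(capF@C == 3))
  expect_error(buildCapacities(flat), "single-intensity")
  expect_error(buildCapacities(img, fgMean = 5, bgMean = 5), "degenerate")
})

test_that("trivial flow instances reach the cheapest cut", {
  cap <- capacityField(Cs = matrix(2, 1, 1), Ct = matrix(1, 1, 1),
                       C = matrix(0, 1, 1))
  res <- solveCmfTwoLabel(cap, maxIter = 1000, tol = 1e-7)
  expect_equal(as.numeric(res@u), 1, tolerance = 1e-3)
  expect_equal(res@energy$total, 1, tolerance = 1e-3)

  cap2 <- capacityField(Cs = matrix(c(3, 0), 1), Ct = matrix(c(0, 3), 1),
                        C = matrix(1, 1, 2))
  # independent oracle: enumerate the four binary labelings
  labelings <- expand.grid(u1 = 0:1, u2 = 0:1)
  energies <- apply(labelings, 1, function(u)
    (1 - u[1]) * 3 + u[2] * 3 + 1 * abs(u[1] - u[2]))
  expect_equal(min(energies), 1)
  res2 <- solveCmfTwoLabel(cap2, maxIter = 2000, tol = 1e-7,
                           tv = "anisotropic")
  expect_equal(as.numeric(thresholdLabels(res2)), c(1, 0))
  expect_equal(res2@energy$total, 1, tolerance = 0.01)
})

test_that("CMF energy matches the discrete min-cut oracle on 6x6 grids", {
  for (seed in 1:5) {
    cap <- randomCapacities(6, 300 + seed)
    res <- solveCmfTwoLabel(cap, maxIter = 3000, tol = 1e-6,
                            tv = "anisotropic")
    oracle <- gridMinCut(cap)
    expect_lt(abs(res@energy$total - oracle$energy) / oracle$energy, 0.01)
  }
})

test_that("solver state is feasible and the residual is reported", {
  cap <- randomCapacities(8, 314, Cconst = 0.3)
  res <- solveCmfTwoLabel(cap, maxIter = 1000, tol = 1e-6,
                          tv = "anisotropic")
  expect_true(res@converged)
  expect_true(all(res@flows$Fs <= cap@Cs + 1e-9))
  expect_true(all(res@flows$Ft <= cap@Ct + 1e-9))
  expect_true(all(abs(res@flows$Fx) <= 0.3 + 1e-9))
  expect_true(all(abs(res@flows$Fy) <= 0.3 + 1e-9))
  expect_lt(res@residual, 0.05)
  expect_true(all(res@u >= 0 & res@u <= 1))
  # hitting maxIter flags non-convergence
  quick <- solveCmfTwoLabel(cap, maxIter = 3, tol = 1e-12)
  expect_false(quick@converged)
})

test_that("primal energy decreases monotonically past the multiplier transient", {
  # the multiplier iterates are infeasible early on, so the primal energy can
  # oscillate slightly during the first ~100 iterations; past that transient
  # it must decrease monotonically toward the optimum
  for (seed in c(271, 5)) {
    cap <- randomCapacities(8, seed, Cconst = 0.3)
    checkpoints <- seq(10, 400, 10)
    energies <- vapply(checkpoints, function(k)
      solveCmfTwoLabel(cap, maxIter = k, tol = 0,
                       tv = "anisotropic")@energy$total, numeric(1))
    settled <- energies[checkpoints >= 150]
    expect_true(all(diff(settled) <= 1e-9))
    expect_lt(energies[length(energies)], energies[1])
  }
})

test_that("scaling all capacities scales the energy and keeps the mask", {
  cap <- randomCapacities(6, 55)
  a <- 3.7
  capS <- capacityField(a * cap@Cs, a * cap@Ct, a * cap@C)
  r1 <- solveCmfTwoLabel(cap, maxIter = 2000, tol = 1e-6, tv = "anisotropic")
  r2 <- solveCmfTwoLabel(capS, maxIter = 2000, tol = 1e-6, tv = "anisotropic")
  expect_equal(r2@energy$total, a * r1@energy$total, tolerance = 1e-3)
  expect_equal(thresholdLabels(r2), thresholdLabels(r1))
})

test_that("Potts pointwise and tie cases behave as defined", {
  res <- solveCmfPotts(array(c(0.5, 0.2, 0.9), c(1, 1, 3)), C = 0,
                       maxIter = 2000, tol = 1e-7)
  expect_equal(as.numeric(thresholdLabels(res)), 2)
  expect_equal(res@energy$total, 0.2, tolerance = 1e-3)
  # uniform equal costs: simplex constraint holds, energy = cost * pixels
  resU <- solveCmfPotts(array(0.4, c(3, 3, 3)), C = 0.1, maxIter = 500)
  expect_equal(apply(resU@u, c(1, 2), sum), matrix(1, 3, 3),
               tolerance = 1e-6)
  expect_equal(resU@energy$total, 0.4 * 9, tolerance = 1e-3)
})

test_that("Potts relaxation matches exhaustive enumeration on 3x3 grids", {
  for (seed in 1:2) {
    set.seed(400 + seed)
    costs <- array(runif(27), c(3, 3, 3))
    res <- solveCmfPotts(costs, C = 0.15, maxIter = 5000, tol = 1e-7,
                         tv = "anisotropic")
    oracle <- pottsEnumerate(costs, C = 0.15)
    expect_lt(abs(res@energy$total - oracle$energy) / oracle$energy, 0.02)
  }
})

test_that("thresholding follows the >= rule and lowest-index ties", {
  expect_equal(thresholdLabels(matrix(0.7, 1, 1)), matrix(1, 1, 1))
  expect_equal(thresholdLabels(matrix(0.5, 1, 1)), matrix(1, 1, 1))
  expect_equal(thresholdLabels(matrix(0.49, 1, 1)), matrix(0, 1, 1))
  u <- array(c(0.4, 0.4, 0.2), c(1, 1, 3))
  expect_equal(as.numeric(thresholdLabels(u)), 1)
})

test_that("the min-cut oracle is exact on a hand-checkable instance", {
  # 1x2 grid: keeping both labels equal avoids the spatial cost
  cap <- capacityField(Cs = matrix(c(5, 4), 1), Ct = matrix(c(1, 2), 1),
                       C = matrix(10, 1, 2))
  oracle <- gridMinCut(cap)
  expect_equal(oracle$energy, 3)           # cut both sink links: 1 + 2
  expect_equal(as.numeric(oracle$mask), c(1, 1))
})
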