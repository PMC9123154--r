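# Continuous max-flow segmentation.
#
# Two-label model: maximize the total source flow subject to the capacity
# constraints Fs <= Cs, Ft <= Ct, |F| <= C and exact flow conservation
# Ft - Fs + div F = 0 at every pixel. Its dual is the TV-regularized binary
# labeling min_u sum (1-u) Cs + u Ct + C |grad u|, u in [0, 1]. The n-label
# Potts relaxation shares one unconstrained source flow across labels, with
# per-label sink capacities rho(L_i, x) and spatial capacities.
#
# Solver: augmented-Lagrangian multiplier scheme -- projected-gradient update
# of the spatial flows (Chambolle-style projection onto |F| <= C),
# closed-form source/sink flow updates, label functions as multipliers.
# Forward differences, Neumann (zero-flux) boundary; deterministic (zero flow
# init, u at 0.5 / uniform simplex).

# forward difference along columns (x): g[, j] = f[, j+1] - f[, j], last 0
.dxF <- function(f) cbind(f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE], 0)
.dyF <- function(f) rbind(f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE], 0)

# backward-difference divergence adjoint to (.dxF, .dyF); px[, nc] and
# py[nr, ] are kept at 0 (zero-flux boundary)
.divergence <- function(px, py) {
  dx <- px
  dx[, -1] <- px[, -1, drop = FALSE] - px[, -ncol(px), drop = FALSE]
  dy <- py
  dy[-1, ] <- py[-1, , drop = FALSE] - py[-nrow(py), , drop = FALSE]
  dx + dy
}

# total-variation term of a label function for given spatial capacities
.tvEnergy <- function(u, C, tv) {
  gx <- .dxF(u); gy <- .dyF(u)
  if (tv == "anisotropic") {
    Cx <- pmin(C, cbind(C[, -1, drop = FALSE], Inf))
    Cy <- pmin(C, rbind(C[-1, , drop = FALSE], Inf))
    sum(Cx * abs(gx)) + sum(Cy * abs(gy))
  } else {
    sum(C * sqrt(gx^2 + gy^2))
  }
}

#' Construct a CapacityField
#'
#' @param Cs,Ct,C nonnegative matrices of identical shape: source, sink and
#'   spatial capacities
#' @return a [CapacityField-class]
#' @export
capacityField <- function(Cs, Ct, C) {
  new(Class = "CapacityField", Cs = Cs, Ct = Ct, C = C)
}

#' Construct a PottsCapacity
#'
#' @param costs (rows, cols, nLabels) array of per-label data costs
#' @param C spatial capacity matrix or scalar
#' @return a [PottsCapacity-class]
#' @export
pottsCapacity <- function(costs, C) {
  if (length(C) == 1L) C <- matrix(C, dim(costs)[1], dim(costs)[2])
  new(Class = "PottsCapacity", costs = costs, C = C)
}

#' Build two-label CMF capacities from slice intensities
#'
#' Source/sink capacities measure the intensity distance to the background
#' and foreground class means: \code{Cs = alpha |img - bgMean|},
#' \code{Ct = alpha |img - fgMean|} (cutting the source link assigns
#' background). Spatial capacity is the constant \code{lambdaTV}, or
#' \code{lambdaTV * exp(-|grad img|^2 / (2 beta^2))} when
#' \code{edgeAdaptive}, which cheapens boundaries along strong edges. Class
#' means default to a deterministic 2-class k-means of the slice intensities
#' (Lloyd iterations started from the intensity extremes).
#'
#' @param img numeric slice matrix
#' @param fgMean,bgMean class means; NULL to estimate by clustering
#' @param alpha data-term weight (> 0)
#' @param lambdaTV spatial capacity / boundary-length weight (> 0)
#' @param edgeAdaptive modulate C by the image gradient
#' @param beta edge sensitivity (gray levels) for the adaptive capacity
#' @return a [CapacityField-class]
#' @export
buildCapacities <- function(img, fgMean = NULL, bgMean = NULL, alpha = 1,
                            lambdaTV = 25, edgeAdaptive = FALSE, beta = 10) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (alpha <= 0 || lambdaTV <= 0)
    stop("alpha and lambdaTV must be positive", call. = FALSE)
  if (is.null(fgMean) || is.null(bgMean)) {
    cl <- .twoClassMeans(img)
    if (is.null(bgMean)) bgMean <- cl[1]
    if (is.null(fgMean)) fgMean <- cl[2]
  }
  if (fgMean == bgMean)
    stop("degenerate clustering: foreground and background means coincide",
         call. = FALSE)
  Cs <- alpha * abs(img - bgMean)
  Ct <- alpha * abs(img - fgMean)
  C <- if (edgeAdaptive) {
    gx <- .dxF(img); gy <- .dyF(img)
    lambdaTV * exp(-(gx^2 + gy^2) / (2 * beta^2))
  } else {
    matrix(lambdaTV, nrow(img), ncol(img))
  }
  capacityField(Cs, Ct, C)
}

# deterministic 2-means of intensities: Lloyd iterations from the extremes
.twoClassMeans <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps)
    stop("degenerate clustering: single-intensity image", call. = FALSE)
  m <- c(lo, hi)
  for (i in 1:50) {
    assignHi <- abs(v - m[2]) < abs(v - m[1])
    newm <- c(mean(v[!assignHi]), mean(v[assignHi]))
    if (any(is.nan(newm))) break
    if (max(abs(newm - m)) < 1e-10) { m <- newm; break }
    m <- newm
  }
  sort(m)
}

#' Solve the two-label continuous max-flow problem
#'
#' @param cap a [CapacityField-class]
#' @param step gradient step for the spatial flow update
#' @param cc augmented-Lagrangian penalty
#' @param maxIter iteration cap; the solver returns flagged non-converged
#'   when the tolerance is not met
#' @param tol convergence tolerance on the mean absolute label update
#' @param tv \code{"isotropic"} (production default) or \code{"anisotropic"}
#'   (matches the 4-neighbor discrete min-cut oracle exactly)
#' @return a [CmfResult-class]; \code{u} in [0, 1], energy components of the
#'   relaxed labeling, flow feasibility maintained by projection at every
#'   iterate
#' @examples
#' cap <- capacityField(Cs = matrix(c(3, 0), 1), Ct = matrix(c(0, 3), 1),
#'                      C = matrix(1, 1, 2))
#' res <- solveCmfTwoLabel(cap, tv = "anisotropic")
#' round(res@u)     # 1, 0
#' res@energy$total # about 1
#' @export
solveCmfTwoLabel <- function(cap, step = 0.16, cc = 0.3, maxIter = 300,
                             tol = 1e-4, tv = c("isotropic", "anisotropic")) {
  tv <- match.arg(tv)
  stopifnot(is(cap, "CapacityField"))
  Cs <- cap@Cs; Ct <- cap@Ct; C <- cap@C
  nr <- nrow(Cs); nc <- ncol(Cs)
  # edge capacities as the min of the two endpoint capacities; the last
  # column/row of the flow arrays stays 0 (zero-flux boundary)
  Cx <- pmin(C, cbind(C[, -1, drop = FALSE], Inf)); Cx[, nc] <- 0
  Cy <- pmin(C, rbind(C[-1, , drop = FALSE], Inf)); Cy[nr, ] <- 0

  u <- matrix(0.5, nr, nc)
  px <- matrix(0, nr, nc); py <- matrix(0, nr, nc)
  ps <- pmin(Cs, Ct); pt <- ps
  divp <- matrix(0, nr, nc)
  iter <- 0L; converged <- FALSE

  while (iter < maxIter) {
    iter <- iter + 1L
    f <- divp - ps + pt - u / cc
    px <- px + step * .dxF(f)
    py <- py + step * .dyF(f)
    if (tv == "anisotropic") {
      px <- pmin(pmax(px, -Cx), Cx)
      py <- pmin(pmax(py, -Cy), Cy)
    } else {
      nrm <- sqrt(px^2 + py^2)
      sc <- ifelse(nrm > C, C / pmax(nrm, 1e-12), 1)
      px <- px * sc; py <- py * sc
      px[, nc] <- 0; py[nr, ] <- 0
    }
    divp <- .divergence(px, py)
    ps <- pmin(divp + pt - u / cc + 1 / cc, Cs)
    pt <- pmin(ps - divp + u / cc, Ct)
    erru <- cc * (divp - ps + pt)
    u <- u - erru
    if (mean(abs(erru)) <= tol * cc) { converged <- TRUE; break }
  }

  uc <- pmin(pmax(u, 0), 1)
  dataE <- sum((1 - uc) * Cs + uc * Ct)
  tvE <- .tvEnergy(uc, C, tv)
  new("CmfResult", u = uc,
      flows = list(Fs = ps, Ft = pt, Fx = px, Fy = py),
      residual = max(abs(pt - ps + divp)),
      converged = converged, iterations = iter,
      energy = list(data = dataE, tv = tvE, total = dataE + tvE))
}

#' Solve the n-label Potts model by convex relaxation
#'
#' Minimizes \eqn{\sum_i \int u_i \rho(L_i, x) + \sum_i \int C |\nabla u_i|}
#' over the simplex (\eqn{u_i \ge 0}, \eqn{\sum_i u_i = 1} per pixel) through
#' its max-flow dual: one shared, unconstrained source flow, per-label sink
#' flows bounded by the data costs, and per-label spatial flows bounded by
#' the spatial capacities.
#'
#' @param costs a [PottsCapacity-class], or a (rows, cols, nLabels) array of
#'   data costs with spatial capacity \code{C}
#' @param C spatial capacity matrix or scalar (used when \code{costs} is an
#'   array)
#' @inheritParams solveCmfTwoLabel
#' @return a [CmfResult-class]; \code{u} is a (rows, cols, nLabels) array on
#'   the simplex
#' @export
solveCmfPotts <- function(costs, C = NULL, step = 0.16, cc = 0.3,
                          maxIter = 300, tol = 1e-4,
                          tv = c("isotropic", "anisotropic")) {
  tv <- match.arg(tv)
  if (is(costs, "PottsCapacity")) {
    rho <- costs@costs; C <- costs@C
  } else {
    rho <- costs
    if (is.null(C)) stop("spatial capacity C is required", call. = FALSE)
    if (length(C) == 1L) C <- matrix(C, dim(rho)[1], dim(rho)[2])
    costs <- pottsCapacity(rho, C)
  }
  d <- dim(rho); nr <- d[1]; nc <- d[2]; L <- d[3]
  if (L < 2L) stop("need at least two labels", call. = FALSE)
  Cx <- pmin(C, cbind(C[, -1, drop = FALSE], Inf)); Cx[, nc] <- 0
  Cy <- pmin(C, rbind(C[-1, , drop = FALSE], Inf)); Cy[nr, ] <- 0

  slab <- function(a, i) matrix(a[, , i], nr, nc)
  u <- array(1 / L, d)
  px <- array(0, d); py <- array(0, d); divp <- array(0, d)
  pt <- array(0, d)
  minCost <- matrix(apply(rho, c(1, 2), min), nr, nc)
  for (i in seq_len(L)) pt[, , i] <- minCost
  ps <- minCost
  iter <- 0L; converged <- FALSE

  while (iter < maxIter) {
    iter <- iter + 1L
    for (i in seq_len(L)) {
      f <- slab(divp, i) - ps + slab(pt, i) - slab(u, i) / cc
      qx <- slab(px, i) + step * .dxF(f)
      qy <- slab(py, i) + step * .dyF(f)
      if (tv == "anisotropic") {
        qx <- pmin(pmax(qx, -Cx), Cx)
        qy <- pmin(pmax(qy, -Cy), Cy)
      } else {
        nrm <- sqrt(qx^2 + qy^2)
        sc <- ifelse(nrm > C, C / pmax(nrm, 1e-12), 1)
        qx <- qx * sc; qy <- qy * sc
        qx[, nc] <- 0; qy[nr, ] <- 0
      }
      px[, , i] <- qx; py[, , i] <- qy
      divp[, , i] <- .divergence(qx, qy)
      pt[, , i] <- pmin(ps - slab(divp, i) + slab(u, i) / cc, slab(rho, i))
    }
    ps <- (matrix(apply(divp + pt - u / cc, c(1, 2), sum), nr, nc) + 1 / cc) / L
    erru <- array(0, d)
    for (i in seq_len(L)) {
      erru[, , i] <- cc * (slab(divp, i) - ps + slab(pt, i))
      u[, , i] <- slab(u, i) - slab(erru, i)
    }
    if (mean(abs(erru)) <= tol * cc) { converged <- TRUE; break }
  }

  # project the multiplier estimate back onto the simplex for reporting
  uc <- pmax(u, 0)
  tot <- matrix(apply(uc, c(1, 2), sum), nr, nc)
  for (i in seq_len(L)) uc[, , i] <- slab(uc, i) / pmax(tot, 1e-12)
  dataE <- sum(uc * rho)
  tvE <- sum(vapply(seq_len(L),
                    function(i) .tvEnergy(slab(uc, i), C, tv), numeric(1)))
  new("CmfResult", u = uc,
      flows = list(Fs = ps, Fi = pt, Fx = px, Fy = py),
      residual = max(abs(sweep(divp + pt, c(1, 2), ps))),
      converged = converged, iterations = iter,
      energy = list(data = dataE, tv = tvE, total = dataE + tvE))
}

#' Threshold soft labels into a hard segmentation
#'
#' Two-label: \code{u >= level} (the boundary value maps to foreground).
#' n-label: argmax over labels with lowest-index tie-break.
#'
#' @param u matrix (two-label) or (rows, cols, nLabels) array, or a
#'   [CmfResult-class]
#' @param level threshold for the two-label case (default 0.5)
#' @return binary matrix (two-label) or integer label matrix (n-label)
#' @export
thresholdLabels <- function(u, level = 0.5) {
  if (is(u, "CmfResult")) u <- u@u
  if (is.matrix(u)) return((u >= level) * 1)
  d <- dim(u)
  if (length(d) != 3L) stop("u must be a matrix or a 3-D label array",
                            call. = FALSE)
  flat <- matrix(u, d[1] * d[2], d[3])
  matrix(max.col(flat, ties.method = "first"), d[1], d[2])
}
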