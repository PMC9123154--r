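# Discrete validation oracles for the continuous max-flow solvers.
#
# Independent code paths: the grid min-cut oracle solves the equivalent
# 4-neighbor graph problem with Edmonds-Karp augmenting paths; the Potts
# oracle enumerates every hard labeling. Both are exact and intended for
# tiny instances.

#' Exact discrete min-cut energy on a 4-neighbor grid
#'
#' Builds the grid graph with terminal edges \code{s -> x} of capacity
#' \code{Cs(x)}, \code{x -> t} of capacity \code{Ct(x)}, and neighbor edges
#' of capacity \code{min(C(a), C(b))} in both directions, then computes the
#' max flow by Edmonds-Karp. The min-cut value equals
#' \eqn{\min_{u \in \{0,1\}} \sum (1-u) C_s + u\, C_t + \sum C_e |u_a - u_b|},
#' the anisotropic-TV binary segmentation energy.
#'
#' @param cap a [CapacityField-class]
#' @return list with \code{energy} (max-flow = min-cut value) and \code{mask}
#'   (a minimum cut: 1 = source side / foreground)
#' @export
gridMinCut <- function(cap) {
  stopifnot(is(cap, "CapacityField"))
  Cs <- cap@Cs; Ct <- cap@Ct; C <- cap@C
  nr <- nrow(Cs); nc <- ncol(Cs)
  n <- nr * nc
  s <- n + 1L; t <- n + 2L
  capm <- matrix(0, n + 2L, n + 2L)
  idx <- function(i, j) (j - 1L) * nr + i
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      v <- idx(i, j)
      capm[s, v] <- Cs[i, j]
      capm[v, t] <- Ct[i, j]
      if (i < nr) {
        ce <- min(C[i, j], C[i + 1, j])
        capm[v, idx(i + 1L, j)] <- ce
        capm[idx(i + 1L, j), v] <- ce
      }
      if (j < nc) {
        ce <- min(C[i, j], C[i, j + 1])
        capm[v, idx(i, j + 1L)] <- ce
        capm[idx(i, j + 1L), v] <- ce
      }
    }
  }
  res <- capm
  flow <- 0
  repeat {
    # BFS for an augmenting path in the residual graph
    parent <- rep(0L, n + 2L)
    parent[s] <- s
    queue <- s
    while (length(queue) && parent[t] == 0L) {
      v <- queue[1]; queue <- queue[-1]
      nxt <- which(res[v, ] > 1e-12 & parent == 0L)
      parent[nxt] <- v
      queue <- c(queue, nxt)
    }
    if (parent[t] == 0L) break
    # bottleneck along the path
    path <- t; v <- t
    while (v != s) { v <- parent[v]; path <- c(v, path) }
    bott <- Inf
    for (e in seq_len(length(path) - 1))
      bott <- min(bott, res[path[e], path[e + 1]])
    for (e in seq_len(length(path) - 1)) {
      res[path[e], path[e + 1]] <- res[path[e], path[e + 1]] - bott
      res[path[e + 1], path[e]] <- res[path[e + 1], path[e]] + bott
    }
    flow <- flow + bott
  }
  # source side of the cut = nodes reachable from s in the residual graph
  reach <- rep(FALSE, n + 2L)
  reach[s] <- TRUE
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- which(res[v, ] > 1e-12 & !reach)
    reach[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  list(energy = flow, mask = matrix(as.numeric(reach[seq_len(n)]), nr, nc))
}

#' Exhaustive Potts energy minimization
#'
#' Enumerates all \code{nLabels^nPixels} hard labelings of a tiny grid and
#' returns the minimum of the anisotropic Potts energy
#' \eqn{\sum_x \rho(L(x), x) + \sum_i \sum_e C_e |1_{L=i}(a) - 1_{L=i}(b)|}
#' (each boundary edge is counted once per label whose indicator changes,
#' i.e. twice in total, matching the relaxed objective's TV sum).
#'
#' @param costs (rows, cols, nLabels) array of data costs, or a
#'   [PottsCapacity-class]
#' @param C spatial capacity matrix or scalar (when \code{costs} is an array)
#' @return list with \code{energy} and the optimal \code{labels} matrix
#' @export
pottsEnumerate <- function(costs, C = NULL) {
  if (is(costs, "PottsCapacity")) {
    rho <- costs@costs; C <- costs@C
  } else {
    rho <- costs
    if (length(C) == 1L) C <- matrix(C, dim(rho)[1], dim(rho)[2])
  }
  d <- dim(rho); nr <- d[1]; nc <- d[2]; L <- d[3]
  n <- nr * nc
  if (L^n > 4e6) stop("instance too large for exhaustive enumeration",
                      call. = FALSE)
  Cx <- pmin(C, cbind(C[, -1, drop = FALSE], Inf)); Cx <- Cx[, -nc, drop = FALSE]
  Cy <- pmin(C, rbind(C[-1, , drop = FALSE], Inf)); Cy <- Cy[-nr, , drop = FALSE]
  best <- Inf; bestLab <- NULL
  lab <- integer(n)   # 0-based digits
  rhoFlat <- matrix(rho, n, L)
  for (code in 0:(L^n - 1)) {
    x <- code
    for (p in seq_len(n)) { lab[p] <- x %% L; x <- x %/% L }
    m <- matrix(lab, nr, nc)
    e <- sum(rhoFlat[cbind(seq_len(n), lab + 1L)])
    # each differing neighbor pair costs 2 * Ce (two indicator jumps)
    if (nc > 1)
      e <- e + 2 * sum(Cx * (m[, -1, drop = FALSE] != m[, -nc, drop = FALSE]))
    if (nr > 1)
      e <- e + 2 * sum(Cy * (m[-1, , drop = FALSE] != m[-nr, , drop = FALSE]))
    if (e < best) { best <- e; bestLab <- m + 1L }
  }
  list(energy = best, labels = bestLab)
}
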