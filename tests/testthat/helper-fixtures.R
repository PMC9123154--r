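# Shared fixtures, built in code.

# small phantom that keeps unit tests fast
smallPhantomSpec <- function(noiseSigma = 8,
                             misalignment = composeAffine(1.5, -1, 0.01),
                             seed = 11) {
  phantomSpec(shape = c(4, 64, 64),
              lesions = list(list(center = c(1.5, 31.5, 31.5),
                                  radii = c(1.5, 7, 8), delta = 80)),
              noiseSigma = noiseSigma, misalignment = misalignment,
              seed = seed)
}

# binary matrix with a filled disc
discMatrix <- function(n, cy, cx, r) {
  y <- matrix(rep(seq_len(n), n), n)
  x <- t(y)
  ((y - cy)^2 + (x - cx)^2 <= r^2) * 1
}

randomCapacities <- function(n, seed, Cconst = NULL) {
  set.seed(seed)
  capacityField(Cs = matrix(stats::runif(n * n), n),
                Ct = matrix(stats::runif(n * n), n),
                C = if (is.null(Cconst)) matrix(stats::runif(n * n), n)
                    else matrix(Cconst, n, n))
}
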