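# Shared fixtures: random SPD tensors, independent matrix-log oracle, and a
# compact three-class phantom builder used across module tests.

randomSPD <- function(jitter = 0.1) {
  A <- matrix(rnorm(9), 3)
  crossprod(A) + diag(3) * jitter
}

# independent matrix logarithm via eigendecomposition, used as the oracle
# for the vectorisation isometry
matLog <- function(T) {
  e <- eigen((T + t(T)) / 2, symmetric = TRUE)
  e$vectors %*% (log(e$values) * t(e$vectors))
}

frob <- function(M) sqrt(sum(M^2))

angleDeg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# three-class study condition on a small cube; wraps demoPhantom
smallPhantom <- function(size = 12L, family = "dswbeta", seed = 1L,
                         overlap = FALSE) {
  demoPhantom(size = size, family = family, seed = seed, overlap = overlap)
}

fastConfig <- function(...) {
  modifyList(list(max_cycles = 2, max_inner = 8, deform_iter = 3,
                  seed = 5L), list(...))
}
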