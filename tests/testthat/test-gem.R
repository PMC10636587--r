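# GEM engine: objective, E step against a brute-force oracle, M-step weight
# updates and bound monotonicity, epsilon policy, posterior volumes and the
# end-to-end driver's determinism.

# small random problem instance over an explicit support
makeToyInstance <- function(V = 8, C = 2, G = 2, W = 2, seed = 70) {
  set.seed(seed)
  logPrior <- log(matrix(runif(V * C) + 0.1, V, C))
  logPrior <- logPrior - log(rowSums(exp(logPrior)))
  Ls <- matrix(rnorm(V * G), V, G)
  Ld <- matrix(rnorm(V * W), V, W)
  spec <- mixtureSpec(paste0("c", seq_len(C)),
                      sSupport = matrix(TRUE, C, G),
                      dSupport = matrix(TRUE, C, W),
                      dFamily = "loggauss",
                      mergeMap = seq_len(C) - 1L)
  # randomise the weights away from the uniform start
  g <- matrix(runif(C * G) + 0.2, C, G); g <- g / rowSums(g)
  w <- matrix(runif(C * W) + 0.2, C, W); w <- w / rowSums(w)
  attr(spec, "g") <- g
  attr(spec, "w") <- w
  list(logPrior = logPrior, Ls = Ls, Ld = Ld, spec = spec)
}

# brute-force enumeration oracle for q and the objective
bruteForce <- function(inst, epsilon) {
  V <- nrow(inst$logPrior)
  C <- ncol(inst$logPrior); G <- ncol(inst$Ls); W <- ncol(inst$Ld)
  qArr <- array(0, c(V, C, G, W))
  for (v in 1:V) for (c. in 1:C) for (i in 1:G) for (j in 1:W)
    qArr[v, c., i, j] <- inst$spec@g[c., i] * inst$spec@w[c., j] *
      exp(inst$logPrior[v, c.]) * exp(inst$Ls[v, i]) *
      exp(inst$Ld[v, j])^epsilon
  norm <- apply(qArr, 1, sum)
  list(q = qArr / norm, obj = sum(log(norm)))
}

test_that("E step matches brute-force enumeration on small instances", {
  for (seed in 70:72) {
    inst <- makeToyInstance(V = 10, C = 3, G = 2, W = 2, seed = seed)
    for (eps in c(1, 0.37)) {
      bf <- bruteForce(inst, eps)
      es <- eStep(inst$logPrior, inst$Ls, inst$Ld, inst$spec, eps)
      worst <- 0
      for (k in seq_len(nrow(es$tuples))) {
        tc <- es$tuples[k, ]
        worst <- max(worst,
                     max(abs(es$q[, k] - bf$q[, tc[1], tc[2], tc[3]])))
      }
      expect_lt(worst, 1e-12)
      expect_equal(gemObjective(inst$logPrior, inst$Ls, inst$Ld, inst$spec,
                                eps), bf$obj, tolerance = 1e-12)
    }
  }
})

test_that("E step: uniform inputs give uniform q; delta prior concentrates", {
  V <- 5
  spec <- mixtureSpec(c("a", "b"), matrix(TRUE, 2, 2), matrix(TRUE, 2, 2),
                      dFamily = "loggauss")
  unif <- eStep(matrix(log(0.5), V, 2), matrix(0, V, 2), matrix(0, V, 2),
                spec, 1)
  expect_equal(unif$q, matrix(1 / 8, V, 8), ignore_attr = TRUE)

  delta <- eStep(log(cbind(rep(1, V), rep(1e-300, V))),
                 matrix(0, V, 2), matrix(0, V, 2), spec, 1)
  onB <- delta$tuples[, 1] == 2
  expect_lt(max(delta$q[, onB]), 1e-250)
  expect_equal(rowSums(delta$q), rep(1, V))
})

test_that("objective: degenerate mixture reduces to summed log-densities and
           the diffusion factor obeys the power rule", {
  V <- 6
  set.seed(73)
  spec1 <- mixtureSpec("only", matrix(TRUE, 1, 1), matrix(TRUE, 1, 1),
                       dFamily = "loggauss", mergeMap = 1L)
  Ls <- matrix(rnorm(V), V, 1); Ld <- matrix(rnorm(V), V, 1)
  lp <- matrix(0, V, 1)
  expect_equal(gemObjective(lp, Ls, Ld, spec1, 1), sum(Ls) + sum(Ld),
               tolerance = 1e-12)
  o1 <- gemObjective(lp, Ls, Ld, spec1, 1)
  oh <- gemObjective(lp, Ls, Ld, spec1, 0.5)
  expect_equal(o1 - oh, 0.5 * sum(Ld), tolerance = 1e-12)
})

test_that("the closed-form weight update recovers posterior mass ratios", {
  # one class, two structural components with q mass split 3:1
  V <- 4
  spec <- mixtureSpec("a", matrix(TRUE, 1, 2), matrix(TRUE, 1, 1),
                      dFamily = "loggauss", mergeMap = 1L)
  q <- cbind(rep(0.75, V), rep(0.25, V))
  es <- list(q = q, tuples = cbind(c = c(1L, 1L), i = c(1L, 2L),
                                   j = c(1L, 1L)))
  stats <- list(logvecs = matrix(0, V, 6), inv6 = matrix(0, V, 6),
                logdetInv = numeric(V), fa = rep(0.5, V),
                pdir = matrix(rep(c(1, 0, 0), V), V, 3, byrow = TRUE),
                valid = rep(FALSE, V))   # diffusion inert in this check
  state <- list(structParams = list(
                  new("GaussianParams", mean = 0, cov = matrix(1, 1, 1)),
                  new("GaussianParams", mean = 1, cov = matrix(1, 1, 1))),
                diffParams = list(logGaussianParams(rep(0, 6), 1)),
                plane = reflectionPlane(c(1, 0, 0)), flags = character())
  out <- mStep(es, matrix(rnorm(V), V, 1), stats, spec, state,
               hyper = vector("list", 2), symmetry = FALSE)
  expect_equal(out$g, matrix(c(0.75, 0.25), 1), ignore_attr = TRUE)
})

test_that("with non-informative priors the Gaussian update equals weighted
           sample moments", {
  set.seed(74)
  V <- 50
  s <- matrix(rnorm(V, 3, 2), V, 1)
  spec <- mixtureSpec("a", matrix(TRUE, 1, 1), matrix(TRUE, 1, 1),
                      dFamily = "loggauss", mergeMap = 1L)
  es <- list(q = matrix(1, V, 1),
             tuples = cbind(c = 1L, i = 1L, j = 1L))
  stats <- list(logvecs = matrix(rnorm(6 * V), V, 6),
                inv6 = matrix(0, V, 6), logdetInv = numeric(V),
                fa = rep(0.5, V), pdir = matrix(rep(c(1, 0, 0), V), V, 3,
                                                byrow = TRUE),
                valid = rep(TRUE, V))
  state <- list(structParams = list(
                  new("GaussianParams", mean = 0, cov = matrix(1, 1, 1))),
                diffParams = list(logGaussianParams(rep(0, 6), 1)),
                plane = reflectionPlane(c(1, 0, 0)), flags = character())
  out <- mStep(es, s, stats, spec, state, hyper = vector("list", 1),
               epsilon = 1, symmetry = FALSE)
  expect_equal(out$structParams[[1]]@mean, mean(s), tolerance = 1e-12)
  expect_equal(out$structParams[[1]]@cov[1, 1], mean((s - mean(s))^2),
               tolerance = 1e-12)
})

test_that("the generalised M step never decreases the bound on random
           states", {
  set.seed(75)
  V <- 60
  for (trial in 1:12) {
    fam <- c("dswbeta", "wishart", "loggauss")[(trial %% 3) + 1]
    spec <- mixtureSpec(c("a", "b"),
                        sSupport = rbind(c(1, 1), c(0, 1)),
                        dSupport = rbind(c(1, 0), c(1, 1)),
                        dFamily = fam)
    structural <- matrix(rnorm(V, sample(1:5, 1)), V, 1)
    fa <- rbeta(V, 4, 3)
    phi <- rWatson(V, rnorm(3), 10 * fa)
    t6 <- dmriseg:::axialTensor6(fa, phi, 0.7e-3)
    stats <- dmriseg:::computeDiffStats(
      logTensorField(tensorField(voxelGrid(c(V, 1L, 1L)), t6)))
    logPrior <- log(matrix(runif(V * 2) + 0.1, V, 2))
    logPrior <- logPrior - log(rowSums(exp(logPrior)))
    state <- list(
      structParams = list(
        new("GaussianParams", mean = rnorm(1), cov = matrix(1, 1, 1)),
        new("GaussianParams", mean = rnorm(1), cov = matrix(2, 1, 1))),
      diffParams = switch(fam,
        dswbeta = list(dswBetaParams(2, 3, rnorm(3), 5),
                       dswBetaParams(3, 2, rnorm(3), 15)),
        wishart = list(wishartParams(6, diag(3) * 300),
                       wishartParams(12, randomSPD() * 100)),
        loggauss = list(logGaussianParams(rnorm(6), 0.5),
                        logGaussianParams(rnorm(6), 1))),
      plane = reflectionPlane(c(1, 0, 0)), flags = character())
    hyper <- vector("list", 2)
    eps <- sample(c(1, 0.5), 1)
    evalO <- function(sp, st) {
      Ls <- dmriseg:::structuralLogLik(structural, st$structParams)
      Ld <- dmriseg:::diffusionLogLik(stats, st$diffParams, fam)
      gemObjective(logPrior, Ls, Ld, sp, eps,
                   priorTerms = dmriseg:::paramPriorTerms(st$structParams,
                     st$diffParams, hyper, fam))
    }
    before <- evalO(spec, state)
    Ls <- dmriseg:::structuralLogLik(structural, state$structParams)
    Ld <- dmriseg:::diffusionLogLik(stats, state$diffParams, fam)
    es <- eStep(logPrior, Ls, Ld, spec, eps)
    newState <- mStep(es, structural, stats, spec, state, hyper,
                      epsilon = eps, symmetry = FALSE)
    spec2 <- spec
    attr(spec2, "g") <- newState$g
    attr(spec2, "w") <- newState$w
    after <- evalO(spec2, newState)
    expect_gte(after, before - 1e-8 * max(1, abs(before)))
  }
})

test_that("epsilon policy follows the voxel-volume ratio with a unit cap", {
  s1 <- voxelGrid(c(4L, 4L, 4L), voxel_size = c(1, 1, 1))
  expect_equal(chooseEpsilon(s1, s1), 1)
  d2 <- voxelGrid(c(2L, 2L, 2L), voxel_size = c(2, 2, 2))
  expect_equal(chooseEpsilon(s1, d2), 1 / 8)
  d07 <- voxelGrid(c(6L, 6L, 6L), voxel_size = c(0.7, 0.7, 0.7))
  expect_equal(chooseEpsilon(s1, d07), 1)
  expect_equal(chooseEpsilon(s1, d2, override = 0.4), 0.4)
  expect_error(chooseEpsilon(s1, d2, override = 1.7), "epsilon")
})

test_that("k-fold voxel duplication with epsilon = 1/k reproduces the
           un-duplicated diffusion fits", {
  set.seed(76)
  n <- 800
  fa <- rbeta(n, 5, 2)
  phi <- rWatson(n, c(0, 1, 0), 25 * fa)
  t6 <- dmriseg:::axialTensor6(fa, phi, 0.7e-3)
  stats1 <- dmriseg:::computeDiffStats(
    logTensorField(tensorField(voxelGrid(c(n, 1L, 1L)), t6)))
  k <- 3
  idx <- rep(seq_len(n), each = k)
  statsK <- list(logvecs = stats1$logvecs[idx, ], inv6 = stats1$inv6[idx, ],
                 logdetInv = stats1$logdetInv[idx], fa = stats1$fa[idx],
                 pdir = stats1$pdir[idx, ], valid = stats1$valid[idx])
  for (fam in c("dswbeta", "loggauss", "wishart")) {
    f1 <- dmriseg:::fitDiffComponent(stats1, rep(1, n), fam)
    fk <- dmriseg:::fitDiffComponent(statsK, rep(1 / k, k * n), fam)
    p1 <- f1$params; pk <- fk$params
    if (fam == "dswbeta") {
      expect_lt(abs(p1@kappa - pk@kappa), 1e-6 * max(1, p1@kappa))
      expect_lt(max(abs(p1@meanDir - pk@meanDir)), 1e-6)
    } else if (fam == "loggauss") {
      expect_lt(max(abs(p1@mean - pk@mean)), 1e-6)
      expect_lt(abs(p1@var - pk@var), 1e-6)
    } else {
      expect_lt(abs(p1@dof - pk@dof), 1e-6 * p1@dof)
      expect_lt(frob(p1@scale - pk@scale), 1e-6 * frob(p1@scale))
    }
  }
})

test_that("posterior volumes: hard labels, uniform split and conservation", {
  g <- voxelGrid(c(4L, 4L, 4L), voxel_size = c(1.5, 1.5, 1.5))
  V <- nVoxels(g)
  hard <- cbind(c(rep(1, 20), rep(0, V - 20)),
                c(rep(0, 20), rep(1, V - 20)))
  vol <- posteriorVolumes(hard, g)
  expect_equal(vol, c(20, V - 20) * 1.5^3)

  unif <- matrix(0.5, V, 2)
  expect_equal(posteriorVolumes(unif, g)[1], posteriorVolumes(unif, g)[2])

  set.seed(77)
  P <- matrix(runif(V * 3), V, 3); P <- P / rowSums(P)
  expect_equal(sum(posteriorVolumes(P, g)), V * voxelVolume(g),
               tolerance = 1e-6)
})

test_that("segmentation runs are bit-identical under a fixed seed and the
           label map is the posterior argmax", {
  d <- smallPhantom(size = 10L, family = "dswbeta", seed = 4)
  ph <- d$phantom
  g <- ph$spec$grid
  r1 <- segmentJoint(ph$structural, g, ph$tensors, d$mesh, d$spec,
                     coarse = d$coarse, config = fastConfig())
  r2 <- segmentJoint(ph$structural, g, ph$tensors, d$mesh, d$spec,
                     coarse = d$coarse, config = fastConfig())
  expect_identical(r1$segmentation@labels, r2$segmentation@labels)
  expect_identical(r1$state@trace, r2$state@trace)

  mg <- r1$segmentation
  amax <- mg@labelIds[max.col(mg@posteriors, ties.method = "first")]
  expect_identical(mg@labels, as.integer(amax))
  # posterior-weighted volumes sum to the grid volume
  expect_equal(sum(mg@volumes), nVoxels(g) * voxelVolume(g),
               tolerance = 1e-6)
})
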