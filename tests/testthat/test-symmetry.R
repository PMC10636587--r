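# Reflective symmetry: parameter reflection, plane estimation and joint
# contralateral fitting.

test_that("reflection of axes: in-plane fixed, normal flipped, involution", {
  px <- reflectionPlane(c(1, 0, 0))
  p1 <- dswBetaParams(3, 2, c(0, 1, 0), 10)
  expect_equal(reflectParams(p1, px)@meanDir, c(0, 1, 0))
  p2 <- dswBetaParams(3, 2, c(1, 0, 0), 10)
  r2 <- reflectParams(p2, px)
  expect_equal(r2@meanDir, c(-1, 0, 0))
  # flipped axis gives the same density (antipodal symmetry)
  phi <- c(0.6, 0.8, 0)
  expect_equal(dswbetaLogpdf(0.5, phi, p2), dswbetaLogpdf(0.5, phi, r2))

  set.seed(51)
  for (i in 1:10) {
    pl <- reflectionPlane(rnorm(3))
    a <- dswBetaParams(2, 5, rnorm(3), 20)
    aa <- reflectParams(reflectParams(a, pl), pl)
    expect_lt(max(abs(aa@meanDir - a@meanDir)), 1e-12)
    b <- logGaussianParams(rnorm(6), 0.4)
    bb <- reflectParams(reflectParams(b, pl), pl)
    expect_lt(max(abs(bb@mean - b@mean)), 1e-12)
    w <- wishartParams(7, randomSPD())
    ww <- reflectParams(reflectParams(w, pl), pl)
    expect_lt(max(abs(ww@scale - w@scale)), 1e-12)
  }
})

test_that("reflection preserves each family's density at reflected data", {
  set.seed(52)
  for (i in 1:5) {
    pl <- reflectionPlane(rnorm(3))
    H <- householder(pl)
    # Householder invariants
    expect_equal(H %*% H, diag(3), tolerance = 1e-12)
    expect_equal(det(H), -1, tolerance = 1e-12)

    dg <- dswBetaParams(3, 2, rnorm(3), 15)
    phi <- rnorm(3); phi <- phi / sqrt(sum(phi^2))
    f <- runif(1)
    expect_equal(dswbetaLogpdf(f, drop(H %*% phi), reflectParams(dg, pl)),
                 dswbetaLogpdf(f, phi, dg), tolerance = 1e-10)

    lg <- logGaussianParams(rnorm(6), 0.3)
    d6 <- rnorm(6)
    dref <- dmriseg:::symMatToVec6(H %*% dmriseg:::vec6ToSymMat(d6) %*% H)
    expect_equal(loggaussLogpdf(dref, reflectParams(lg, pl)),
                 loggaussLogpdf(d6, lg), tolerance = 1e-10)

    wg <- wishartParams(8, randomSPD())
    Tt <- randomSPD()
    expect_equal(wishartLogpdf(H %*% Tt %*% H, reflectParams(wg, pl)),
                 wishartLogpdf(Tt, wg), tolerance = 1e-8)
  }
})

# build a two-sided DSW data set with a known reflection plane
makeMirrorData <- function(n, rtrue, psiL, kappa, seed, exact = FALSE) {
  set.seed(seed)
  H <- diag(3) - 2 * tcrossprod(rtrue)
  fL <- rbeta(n, 5, 2)
  phiL <- rWatson(n, psiL, kappa * fL)
  if (exact) {
    fR <- fL
    phiR <- phiL %*% H
  } else {
    fR <- rbeta(n, 5, 2)
    phiR <- rWatson(n, drop(H %*% psiL), kappa * fR)
  }
  stats <- list(fa = c(fL, fR), pdir = rbind(phiL, phiR),
                logvecs = matrix(0, 2 * n, 6), inv6 = matrix(0, 2 * n, 6),
                logdetInv = numeric(2 * n), valid = rep(TRUE, 2 * n))
  wts <- cbind(c(rep(1, n), rep(0, n)), c(rep(0, n), rep(1, n)))
  pl <- fitDswbeta(fL, phiL, rep(1, n))$params
  list(stats = stats, wts = wts, paramsL = pl)
}

test_that("an exactly mirror-symmetric field yields the true plane", {
  rtrue <- c(1, 0, 0)
  md <- makeMirrorData(3000, rtrue, c(0.3, 0.8, 0.52), 30, seed = 53,
                       exact = TRUE)
  res <- optimiseReflection(md$stats, md$wts, list(md$paramsL, NULL),
                            matrix(c(1L, 2L), 1),
                            reflectionPlane(c(0.95, 0.2, 0.24)), "dswbeta")
  expect_lt(angleDeg(res$plane@normal, rtrue), 1e-6 * 180 / pi + 0.001)
})

test_that("a plane tilted 5 degrees off-axis is recovered within 1 degree", {
  tilt <- 5 * pi / 180
  rtrue <- c(cos(tilt), sin(tilt), 0)
  md <- makeMirrorData(10000, rtrue, c(0.3, 0.8, 0.52), 30, seed = 54)
  res <- optimiseReflection(md$stats, md$wts, list(md$paramsL, NULL),
                            matrix(c(1L, 2L), 1),
                            reflectionPlane(c(1, 0, 0)), "dswbeta")
  expect_lt(angleDeg(res$plane@normal, rtrue), 1)
  # never below the initialisation
  init <- dmriseg:::reflectionObjective(c(1, 0, 0),
    list(dmriseg:::reflectionPairStats(md$stats, md$wts[, 2], md$paramsL,
                                       "dswbeta")), "dswbeta")$value
  expect_gte(res$value, init)
})

test_that("isotropic components leave the plane at its initialisation,
           flagged degenerate", {
  set.seed(55)
  z <- matrix(rnorm(3000), 1000, 3)
  z <- z / sqrt(rowSums(z^2))
  stats <- list(fa = runif(1000), pdir = z, logvecs = matrix(0, 1000, 6),
                inv6 = matrix(0, 1000, 6), logdetInv = numeric(1000),
                valid = rep(TRUE, 1000))
  wts <- cbind(rep(1, 1000), rep(1, 1000))
  p0 <- dswBetaParams(2, 2, c(0, 1, 0), 0)    # kappa = 0: flat objective
  r0 <- reflectionPlane(c(1, 0, 0))
  res <- optimiseReflection(stats, wts, list(p0, NULL),
                            matrix(c(1L, 2L), 1), r0, "dswbeta")
  expect_true(res$degenerate)
  expect_equal(res$plane@normal, r0@normal)
})

test_that("the reflection objective is a quartic polynomial in the normal", {
  md <- makeMirrorData(500, c(1, 0, 0), c(0.3, 0.8, 0.52), 20, seed = 56)
  ps <- list(dmriseg:::reflectionPairStats(md$stats, md$wts[, 2],
                                           md$paramsL, "dswbeta"))
  set.seed(57)
  a <- rnorm(3); b <- rnorm(3)
  ts <- seq(-1, 1, length.out = 15)
  vals <- vapply(ts, function(t)
    dmriseg:::reflectionObjective(a + t * b, ps, "dswbeta")$value,
    numeric(1))
  # degree-4 interpolant through 5 points must reproduce all 15 values
  co <- solve(outer(ts[c(1, 4, 8, 12, 15)], 0:4, "^"),
              vals[c(1, 4, 8, 12, 15)])
  pred <- drop(outer(ts, 0:4, "^") %*% co)
  expect_lt(max(abs(pred - vals)) / max(abs(vals)), 1e-9)
})

test_that("analytic reflection gradients match finite differences for all
           families", {
  set.seed(58)
  n <- 200
  stats <- list(fa = rbeta(n, 4, 2),
                pdir = { z <- matrix(rnorm(3 * n), n, 3)
                         z / sqrt(rowSums(z^2)) },
                logvecs = matrix(rnorm(6 * n), n, 6),
                inv6 = t(replicate(n, matToSym6(randomSPD()))),
                logdetInv = rnorm(n), valid = rep(TRUE, n))
  wts <- runif(n)
  params <- list(dswbeta = dswBetaParams(3, 2, rnorm(3), 12),
                 loggauss = logGaussianParams(rnorm(6), 0.5),
                 wishart = wishartParams(9, randomSPD()))
  r <- rnorm(3)
  for (family in names(params)) {
    ps <- list(dmriseg:::reflectionPairStats(stats, wts, params[[family]],
                                             family))
    ob <- dmriseg:::reflectionObjective(r, ps, family)
    for (k in 1:3) {
      h <- 1e-6
      rp <- r; rp[k] <- rp[k] + h
      rm <- r; rm[k] <- rm[k] - h
      num <- (dmriseg:::reflectionObjective(rp, ps, family)$value -
              dmriseg:::reflectionObjective(rm, ps, family)$value) / (2 * h)
      expect_equal(ob$grad[k], num, tolerance = 1e-4,
                   label = paste(family, "grad component", k))
    }
  }
})

test_that("joint pair fitting: mirror data equals one-sided fits,
           one-sided degenerates to the reflected fit", {
  rtrue <- c(1, 0, 0)
  md <- makeMirrorData(2000, rtrue, c(0.3, 0.8, 0.52), 25, seed = 59,
                       exact = TRUE)
  pl <- reflectionPlane(rtrue)
  n <- 2000
  wL <- c(rep(1, n), rep(0, n)); wR <- c(rep(0, n), rep(1, n))
  fit <- fitPairSymmetric(md$stats, wL, wR, pl, "dswbeta")
  only <- fitDswbeta(md$stats$fa[1:n], md$stats$pdir[1:n, ], rep(1, n))
  expect_lt(angleDeg(fit$left@meanDir, only$params@meanDir), 1e-6)
  expect_equal(fit$left@kappa, only$params@kappa, tolerance = 1e-6)

  # left weights zero: reflection of the right-only fit
  fit0 <- fitPairSymmetric(md$stats, 0 * wL, wR, pl, "dswbeta")
  ronly <- fitDswbeta(md$stats$fa[(n + 1):(2 * n)],
                      md$stats$pdir[(n + 1):(2 * n), ], rep(1, n))
  expect_lt(angleDeg(fit0$right@meanDir, ronly$params@meanDir), 1e-6)
  expect_equal(fit0$right@kappa, ronly$params@kappa, tolerance = 1e-4)
})

test_that("asymmetric pair fit maximises the summed paired likelihood", {
  # log-Gaussian family: the joint objective is tractable for a black-box
  # optimiser over (mean, variance)
  set.seed(60)
  pl <- reflectionPlane(c(1, 0, 0))
  H <- householder(pl)
  n <- 400
  dL <- matrix(rnorm(6 * n, mean = 0.3, sd = 0.4), n, 6)
  dR <- matrix(rnorm(6 * n, mean = -0.1, sd = 0.5), n, 6)
  stats <- list(logvecs = rbind(dL, dR),
                inv6 = matrix(rep(c(1, 1, 1, 0, 0, 0), 2 * n), 2 * n, 6,
                              byrow = TRUE),
                logdetInv = numeric(2 * n),
                fa = rep(0.5, 2 * n),
                pdir = matrix(rep(c(1, 0, 0), 2 * n), 2 * n, 3,
                              byrow = TRUE),
                valid = rep(TRUE, 2 * n))
  wL <- c(runif(n), rep(0, n)); wR <- c(rep(0, n), runif(n))
  fit <- fitPairSymmetric(stats, wL, wR, pl, "loggauss")
  obj <- function(par) {
    m <- par[1:6]; v <- exp(par[7])
    lp <- logGaussianParams(m, v)
    -(sum(wL[1:n] * loggaussLogpdf(dL, lp)) +
        sum(wR[(n + 1):(2 * n)] *
              loggaussLogpdf(dR, reflectParams(lp, pl))))
  }
  o <- optim(c(fit$left@mean, log(fit$left@var)), obj,
             control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(o$par[1:6] - fit$left@mean)), 1e-5)
  expect_lt(abs(exp(o$par[7]) - fit$left@var), 1e-5)
})
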