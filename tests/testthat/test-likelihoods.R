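# Likelihood families: log-density correctness (normalisation, closed
# forms) and weighted MAP fitters (stationarity, recovery, degeneracies).

test_that("Gaussian log-density matches closed forms and normalises", {
  p <- new("GaussianParams", mean = 0, cov = matrix(1, 1, 1))
  expect_equal(gaussianLogpdf(0, p), -0.5 * log(2 * pi))
  # 1-D normalisation by quadrature
  xs <- seq(-12, 12, length.out = 4001)
  expect_equal(sum(exp(gaussianLogpdf(matrix(xs), p))) * diff(xs)[1], 1,
               tolerance = 1e-4)
  # random multivariate case vs direct quadratic-form oracle
  set.seed(31)
  for (i in 1:10) {
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.2
    mu <- rnorm(3)
    x <- rnorm(3)
    want <- -0.5 * (3 * log(2 * pi) + log(det(S)) +
                      drop(t(x - mu) %*% solve(S) %*% (x - mu)))
    expect_equal(gaussianLogpdf(x, new("GaussianParams", mean = mu, cov = S)),
                 want, tolerance = 1e-12)
  }
  expect_error(gaussianLogpdf(0, new("GaussianParams", mean = c(0, 0),
    cov = matrix(c(1, 1, 1, 1), 2))), "positive definite")
})

test_that("Gaussian MAP fit reduces to weighted moments and matches a
           numerical optimiser under an informative prior", {
  set.seed(32)
  s <- matrix(rnorm(300, mean = c(2, -1, 4)), 100, 3, byrow = TRUE)
  wts <- runif(100)
  # non-informative limit: exact weighted moments
  fit0 <- fitGaussianMap(s, wts)
  muhat <- colSums(s * wts) / sum(wts)
  ctr <- sweep(s, 2, muhat)
  expect_equal(fit0$params@mean, muhat, tolerance = 1e-12)
  expect_equal(fit0$params@cov, crossprod(ctr * sqrt(wts)) / sum(wts),
               tolerance = 1e-12)

  # point mass: mean equals the voxel, covariance floored and flagged
  w1 <- c(1, rep(0, 99))
  fit1 <- fitGaussianMap(s, w1)
  expect_equal(fit1$params@mean, s[1, ])
  expect_true("covariance_floored" %in% fit1$flags)

  # informative hypermean: matches black-box maximisation of the objective
  hy <- niwHyper(c(0, 0, 0), n = 25)
  fit2 <- fitGaussianMap(s, wts, hy)
  obj <- function(par) {
    mu <- par[1:3]
    L <- diag(exp(par[4:6]))
    L[lower.tri(L)] <- par[7:9]
    -dmriseg:::gaussianMapObjective(mu, tcrossprod(L), s, wts, hy)
  }
  ch <- t(chol(fit2$params@cov))
  start <- c(fit2$params@mean, log(diag(ch)), ch[lower.tri(ch)])
  o <- optim(start, obj, control = list(maxit = 4000, reltol = 1e-14))
  expect_lt(max(abs(o$par[1:3] - fit2$params@mean)), 1e-5)
  expect_lte(-o$value,
             dmriseg:::gaussianMapObjective(fit2$params@mean,
               fit2$params@cov, s, wts, hy) + 1e-6)
  # shrinkage towards the hypermean
  expect_lt(sqrt(sum(fit2$params@mean^2)), sqrt(sum(fit0$params@mean^2)))
})

test_that("Wishart density normalises (importance check) and peaks at its
           mode", {
  set.seed(33)
  V <- diag(c(0.4, 0.3, 0.5)); n <- 9
  p <- wishartParams(n, V)
  # importance-sampling normalisation: draws from W(n+2, V)
  m <- 4000
  draws <- rWishart(m, n + 2, V)
  lp <- lq <- numeric(m)
  pq <- wishartParams(n + 2, V)
  for (i in 1:m) {
    Tm <- solve(draws[, , i])  # wishartLogpdf consumes the tensor T = d^-1
    lp[i] <- wishartLogpdf(Tm, p)
    lq[i] <- wishartLogpdf(Tm, pq)
  }
  expect_equal(mean(exp(lp - lq)), 1, tolerance = 0.02)
  # mean identity of sampled draws
  expect_equal(apply(draws, 1:2, mean), (n + 2) * V, tolerance = 0.05)
  # unimodality around the mode d* = (n - p - 1) V
  mode <- (n - 4) * V
  expect_gt(wishartLogpdf(solve(mode), p),
            wishartLogpdf(solve(2 * mode), p))
  expect_gt(wishartLogpdf(solve(mode), p),
            wishartLogpdf(solve(0.5 * mode), p))
  bad <- wishartParams(5, diag(3))
  slot(bad, "dof", check = FALSE) <- 1.5
  expect_error(wishartLogpdf(diag(3), bad), "dof")
})

test_that("Wishart fitter recovers simulated parameters and sits at a
           stationary point", {
  set.seed(34)
  n0 <- 10; V0 <- diag(c(0.5, 0.35, 0.6)) / n0
  draws <- rWishart(20000, n0, V0)
  t6 <- t(apply(draws, 3, function(d) matToSym6(solve(d))))
  fit <- fitWishartMap(t6, rep(1, 20000), gammaHyper = NULL)
  expect_lt(abs(fit$params@dof - n0) / n0, 0.1)
  expect_lt(frob(fit$params@scale - V0) / frob(V0), 0.05)

  # stationarity of the profiled objective in the dof (finite differences)
  st <- dmriseg:::wishartStats(t6)
  Qd <- function(n) {
    pp <- wishartParams(n, fit$params@scale)
    sum(dmriseg:::wishartLogpdfStats(st$inv6, st$logdetInv, pp))
  }
  h <- 1e-4
  grad <- (Qd(fit$params@dof + h) - Qd(fit$params@dof - h)) / (2 * h)
  expect_lt(abs(grad) / 20000, 1e-4)

  # single-sample support: dispersion unidentifiable, boundary flagged
  w1 <- c(1, rep(0, 19999))
  fit1 <- fitWishartMap(t6, w1, gammaHyper = c(0.5, 1.5))
  expect_true("dof_boundary" %in% fit1$flags)
})

test_that("weight rescaling leaves data-term fits unchanged only without a
           prior", {
  set.seed(35)
  draws <- rWishart(3000, 8, diag(3) * 0.1)
  t6 <- t(apply(draws, 3, function(d) matToSym6(solve(d))))
  wts <- runif(3000)
  noPrior1 <- fitWishartMap(t6, wts, gammaHyper = NULL)
  noPrior2 <- fitWishartMap(t6, 2 * wts, gammaHyper = NULL)
  expect_equal(noPrior1$params@dof, noPrior2$params@dof, tolerance = 1e-5)

  withPrior1 <- fitWishartMap(t6, wts, gammaHyper = c(0.5, 1.5))
  withPrior2 <- fitWishartMap(t6, 2 * wts, gammaHyper = c(0.5, 1.5))
  # the prior pulls dof down; doubling the weights moves the MAP towards
  # the (higher) data-only value
  expect_lt(withPrior1$params@dof, noPrior1$params@dof)
  expect_gt(withPrior2$params@dof, withPrior1$params@dof)
})

test_that("log-Gaussian density and fitter behave per the closed forms", {
  m <- rnorm(6); s2 <- 0.7
  p <- logGaussianParams(m, s2)
  expect_equal(loggaussLogpdf(m, p), -3 * log(2 * pi * s2))
  delta <- rnorm(6)
  expect_equal(loggaussLogpdf(m + delta, p), loggaussLogpdf(m - delta, p))
  d <- rnorm(6)
  want <- sum(-0.5 * log(2 * pi * s2) - (d - m)^2 / (2 * s2))
  expect_equal(loggaussLogpdf(d, p), want, tolerance = 1e-12)
  expect_error(loggaussLogpdf(d, {x <- p; x@var <- 1; x@var <- -1; x}))

  # degenerate/constant data hits the variance floor
  const <- matrix(m, 50, 6, byrow = TRUE)
  fitc <- fitLoggauss(const, rep(1, 50))
  expect_equal(fitc$params@mean, m)
  expect_true("variance_floored" %in% fitc$flags)

  # two equal-weight points: midpoint mean
  two <- rbind(rep(0, 6), rep(2, 6))
  expect_equal(fitLoggauss(two, c(1, 1))$params@mean, rep(1, 6))

  # random weighted fit matches a numerical maximiser
  set.seed(36)
  D <- matrix(rnorm(600, sd = 0.8), 100, 6)
  wts <- runif(100)
  fit <- fitLoggauss(D, wts)
  obj <- function(par) -sum(wts * loggaussLogpdf(D,
    logGaussianParams(par[1:6], exp(par[7]))))
  o <- optim(c(fit$params@mean, log(fit$params@var)), obj,
             control = list(maxit = 3000, reltol = 1e-14))
  expect_lt(max(abs(o$par[1:6] - fit$params@mean)), 1e-8 + 1e-5)
  expect_lt(abs(exp(o$par[7]) - fit$params@var), 1e-6)
})

test_that("Watson normaliser: uniform limit, quadrature and monotonicity", {
  expect_equal(exp(watsonLogNormaliser(0)), 4 * pi, tolerance = 1e-14)
  # numeric quadrature of the DSW density over the sphere: by rotational
  # symmetry the surface integral reduces to 2*pi * int_-1^1 exp(k t^2) dt
  for (k in c(1, 10, 100)) {
    I <- integrate(function(t) exp(k * t^2 - watsonLogNormaliser(k) +
                                     log(2 * pi)), -1, 1,
                   rel.tol = 1e-12)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  ks <- c(0, 0.5, 1, 5, 20, 29, 30, 31, 50, 200, 1e3, 1e4)
  zs <- watsonLogNormaliser(ks)
  expect_true(all(diff(zs) > 0))
  # series/asymptotic switch is seamless against direct quadrature
  for (k in c(25, 29.5, 30.5, 40)) {
    q <- integrate(function(t) exp(k * (t^2 - 1)), 0, 1,
                   rel.tol = 1e-13)$value
    expect_equal(watsonLogNormaliser(k), log(4 * pi) + k + log(q),
                 tolerance = 1e-10)
  }
  expect_error(watsonLogNormaliser(-1), "kappa")
  expect_error(watsonLogNormaliser(2e4), "cap")
})

test_that("DSW-beta density: antipodal symmetry, FA-zero limit and joint
           normalisation", {
  set.seed(37)
  p <- dswBetaParams(4, 2, c(1, 2, -1), 25)
  for (i in 1:20) {
    phi <- rnorm(3); phi <- phi / sqrt(sum(phi^2))
    f <- runif(1)
    expect_equal(dswbetaLogpdf(f, phi, p), dswbetaLogpdf(f, -phi, p))
  }
  # f = 0: direction term is exactly uniform
  phi <- c(0, 0, 1)
  expect_equal(dswbetaLogpdf(0, phi, p),
               dbeta(0, 4, 2, log = TRUE) - log(4 * pi))
  # joint normalisation by product quadrature over (f, t = cos angle)
  fs <- seq(0.0005, 0.9995, length.out = 1000)
  df <- diff(fs)[1]
  inner <- vapply(fs, function(f) {
    integrate(function(t) 2 * pi * exp(p@kappa * f * t^2 -
        watsonLogNormaliser(p@kappa * f)), -1, 1, rel.tol = 1e-10)$value
  }, numeric(1))
  total <- sum(dbeta(fs, p@shape1, p@shape2) * inner) * df
  expect_equal(total, 1, tolerance = 1e-4)
  expect_error(dswbetaLogpdf(1.2, phi, p), "FA")
})

test_that("DSW-beta fitter: null concentration on uniform directions,
           parameter recovery, degenerate cap", {
  set.seed(38)
  # uniform directions: fitted kappa ~ 0
  z <- matrix(rnorm(30000), 10000, 3)
  z <- z / sqrt(rowSums(z^2))
  f <- runif(10000)
  fit0 <- fitDswbeta(f, z, rep(1, 10000))
  expect_lt(fit0$params@kappa, 0.2)

  # recovery of a concentrated component
  psi0 <- c(1, 2, 2) / 3
  k0 <- 35
  fa <- rbeta(20000, 5, 2)
  phi <- rWatson(20000, psi0, k0 * fa)
  fit <- fitDswbeta(fa, phi, rep(1, 20000))
  expect_lt(angleDeg(fit$params@meanDir, psi0), 2)
  expect_lt(abs(fit$params@kappa - k0) / k0, 0.1)
  expect_lt(abs(fit$params@shape1 - 5) / 5, 0.1)
  expect_lt(abs(fit$params@shape2 - 2) / 2, 0.1)

  # all directions identical at FA 1: concentration hits the cap, flagged
  same <- matrix(c(1, 0, 0), 500, 3, byrow = TRUE)
  fitc <- fitDswbeta(rep(1, 500), same, rep(1, 500), kappa_cap = 1e4)
  expect_true("kappa_cap" %in% fitc$flags)
  expect_equal(fitc$params@kappa, 1e4)
})

test_that("DSW fitting is rotation-equivariant", {
  set.seed(39)
  psi0 <- c(0, 1, 0)
  fa <- rbeta(4000, 5, 2)
  phi <- rWatson(4000, psi0, 30 * fa)
  fit1 <- fitDswbeta(fa, phi, rep(1, 4000))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fit2 <- fitDswbeta(fa, phi %*% t(R), rep(1, 4000))
  expect_lt(angleDeg(fit2$params@meanDir, drop(R %*% fit1$params@meanDir)),
            1e-6)
  expect_equal(fit2$params@kappa, fit1$params@kappa, tolerance = 1e-6)
})

test_that("fitters are invariant to uniform weight rescaling without priors", {
  set.seed(40)
  s <- matrix(rnorm(200), 100, 2)
  wts <- runif(100)
  f1 <- fitGaussianMap(s, wts)$params
  f2 <- fitGaussianMap(s, wts * 7)$params
  expect_equal(f1@mean, f2@mean, tolerance = 1e-12)
  expect_equal(f1@cov, f2@cov, tolerance = 1e-12)

  fa <- rbeta(500, 4, 3)
  phi <- rWatson(500, c(0, 0, 1), 10 * fa)
  d1 <- fitDswbeta(fa, phi, wts <- runif(500))$params
  d2 <- fitDswbeta(fa, phi, wts * 3)$params
  expect_equal(d1@kappa, d2@kappa, tolerance = 1e-4)
  expect_equal(d1@meanDir, d2@meanDir, tolerance = 1e-10)
})
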