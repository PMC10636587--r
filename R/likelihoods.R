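## Likelihood families.  Each family exposes a (vectorised) log-density and a
## weighted MAP fitter -- the inner solvers of the generalised M step.  All
## densities are evaluated in log space; the diffusion densities are over the
## family's own data representation (inverse tensor for Wishart, log-Euclidean
## 6-vector for the log-Gaussian, FA/principal-direction for DSW-beta), which
## is component-independent and therefore cancels in the E-step normalisation.

## ---------------------------------------------------------------------------
## Structural Gaussian with Normal-Inverse-Wishart prior
## ---------------------------------------------------------------------------

#' Multivariate Gaussian log-density
#'
#' @param s numeric vector (one observation) or matrix with one observation
#'   per row.
#' @param params a \linkS4class{GaussianParams}.
#' @return log-density value(s).
#' @export
gaussianLogpdf <- function(s, params) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  S <- length(params@mean)
  ch <- tryCatch(chol(params@cov), error = function(e)
    stop("singular covariance in gaussianLogpdf"))
  ctr <- sweep(s, 2, params@mean)
  z <- backsolve(ch, t(ctr), transpose = TRUE)
  q <- colSums(z^2)
  drop(-0.5 * (S * log(2 * pi) + 2 * sum(log(diag(ch))) + q))
}

#' Normal-Inverse-Wishart hyperparameters
#'
#' @param M hypermean vector.
#' @param n non-negative prior strength on the mean.
#' @param Psi PSD scale matrix (default zero: non-informative).
#' @param nu degrees of freedom (default 0: non-informative).
#' @return a \linkS4class{NIWHyper}.
#' @export
niwHyper <- function(M, n = 0, Psi = NULL, nu = 0) {
  if (is.null(Psi)) Psi <- matrix(0, length(M), length(M))
  new("NIWHyper", M = as.numeric(M), n = n, Psi = Psi, nu = nu)
}

#' Weighted MAP fit of a Gaussian component
#'
#' Maximises the component's M-step objective: the weighted data
#' log-likelihood plus (when the prior strength \code{n} is positive) the
#' conjugate mean prior \code{N(mu | M, Sigma/n)}.  Following the
#' non-informative covariance setting (\code{Psi = nu = 0}) the covariance
#' prior is flat, so the MAP solution is the shrunk mean
#' \code{(wbar*muhat + n*M) / (wbar + n)} with the covariance maximising the
#' same objective.  With \code{n = 0} this reduces exactly to the weighted
#' sample mean and covariance.
#'
#' @param samples V x S matrix of intensities.
#' @param weights non-negative weights summing to > 0.
#' @param hyper a \linkS4class{NIWHyper}.
#' @param cov_floor eigenvalue floor for the covariance, as a fraction of the
#'   data variance scale.
#' @return list with \code{params} (a \linkS4class{GaussianParams}) and
#'   \code{flags} (character).
#' @export
fitGaussianMap <- function(samples, weights, hyper = NULL,
                           cov_floor = 1e-8) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  wbar <- sum(weights)
  if (wbar <= 0) stop("weights must sum to > 0")
  S <- ncol(samples)
  if (is.null(hyper)) hyper <- niwHyper(numeric(S))
  muhat <- colSums(samples * weights) / wbar
  n0 <- hyper@n
  mu <- if (n0 > 0) (wbar * muhat + n0 * hyper@M) / (wbar + n0) else muhat
  ctr <- sweep(samples, 2, mu)
  Sw <- crossprod(ctr * sqrt(weights))
  denom <- wbar
  if (n0 > 0) {
    Sw <- Sw + n0 * tcrossprod(mu - hyper@M)
    denom <- wbar + 1
  }
  Sigma <- (Sw + hyper@Psi) / (denom + hyper@nu)
  flags <- character()
  scale <- max(mean(diag(Sigma)), .Machine$double.eps)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  floorv <- cov_floor * scale
  if (any(ev$values < floorv)) {
    ev$values <- pmax(ev$values, floorv)
    Sigma <- ev$vectors %*% (ev$values * t(ev$vectors))
    flags <- c(flags, "covariance_floored")
  }
  list(params = new("GaussianParams", mean = mu, cov = Sigma), flags = flags)
}

## objective matching fitGaussianMap, used by oracle tests and safeguards
gaussianMapObjective <- function(mu, Sigma, samples, weights, hyper) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  val <- sum(weights * gaussianLogpdf(samples,
    new("GaussianParams", mean = mu, cov = Sigma)))
  if (hyper@n > 0)
    val <- val + gaussianLogpdf(matrix(mu, 1),
      new("GaussianParams", mean = hyper@M, cov = Sigma / hyper@n))
  val
}

## ---------------------------------------------------------------------------
## Wishart on the inverse tensor
## ---------------------------------------------------------------------------

## log multivariate gamma, dimension p = 3
lmvgamma3 <- function(a) {
  1.5 * log(pi) + lgamma(a) + lgamma(a - 0.5) + lgamma(a - 1)
}

#' Wishart parameters for the inverse-tensor diffusion model
#' @param dof degrees of freedom, > 2.
#' @param scale 3x3 SPD scale matrix.
#' @param gammaHyper (shape, rate) of the Gamma prior on \code{(dof-2)/2};
#'   the default (0.5, 1.5) is a non-informative choice favouring broad
#'   distributions.
#' @return a \linkS4class{WishartParams}.
#' @export
wishartParams <- function(dof, scale, gammaHyper = c(0.5, 1.5)) {
  new("WishartParams", dof = dof, scale = scale, gammaHyper = gammaHyper)
}

#' Wishart log-density of a diffusion tensor's inverse
#'
#' The model variable is \code{d = solve(T)}; the density is the standard
#' 3x3 Wishart with the multivariate gamma normaliser, evaluated at d.
#'
#' @param T SPD 3x3 tensor, or a V x 6 matrix of tensors in
#'   \code{(xx, yy, zz, xy, xz, yz)} order.
#' @param params a \linkS4class{WishartParams}.
#' @return log-density value(s).
#' @export
wishartLogpdf <- function(T, params) {
  if (params@dof <= 2) stop("Wishart dof must be > 2")
  if (!is.null(dim(T)) && all(dim(T) == c(3, 3))) T <- matrix(matToSym6(T), 1)
  st <- wishartStats(T)
  wishartLogpdfStats(st$inv6, st$logdetInv, params)
}

## per-voxel sufficient statistics for the Wishart family
wishartStats <- function(t6) {
  V <- nrow(t6)
  inv6 <- matrix(NA_real_, V, 6)
  logdetInv <- rep(NA_real_, V)
  for (v in seq_len(V)) {
    e <- eigen(sym6ToMat(t6[v, ]), symmetric = TRUE)
    if (any(e$values <= 0))
      stop("tensor is not SPD: eigenvalue ", signif(min(e$values), 6), " <= 0")
    inv6[v, ] <- matToSym6(e$vectors %*% ((1 / e$values) * t(e$vectors)))
    logdetInv[v] <- -sum(log(e$values))
  }
  list(inv6 = inv6, logdetInv = logdetInv)
}

## trace(A %*% B) for symmetric 6-form rows
trSym6 <- function(a6, b6) {
  if (is.null(dim(a6))) a6 <- matrix(a6, nrow = 1)
  if (is.null(dim(b6))) b6 <- matrix(b6, nrow = nrow(a6), ncol = 6,
                                     byrow = TRUE)
  rowSums(a6 * b6 * rep(c(1, 1, 1, 2, 2, 2), each = nrow(a6)))
}

wishartLogpdfStats <- function(inv6, logdetInv, params) {
  n <- params@dof
  Vs <- params@scale
  Vinv6 <- matToSym6(solve(Vs))
  ldV <- determinant(Vs, logarithm = TRUE)$modulus[1]
  ((n - 4) / 2) * logdetInv - 0.5 * trSym6(inv6, Vinv6) -
    (1.5 * n) * log(2) - (n / 2) * ldV - lmvgamma3(n / 2)
}

#' Weighted MAP fit of the Wishart diffusion component
#'
#' The scale is obtained in closed form given the degrees of freedom
#' (\code{V = Sbar / n} with \code{Sbar} the weighted mean inverse tensor);
#' the degrees of freedom maximise the profiled weighted objective including
#' the Gamma prior on \code{(n-2)/2}, by 1-D numerical optimisation.
#'
#' @param tensors V x 6 matrix of SPD tensors (\code{T}, not their inverses).
#' @param weights non-negative weights, sum > 0.
#' @param gammaHyper (shape, rate) Gamma prior on \code{(dof-2)/2}; NULL
#'   drops the prior.
#' @param dof_cap upper bound for the degrees of freedom search.
#' @param stats optional precomputed \code{wishartStats(tensors)}.
#' @return list with \code{params} and \code{flags}.
#' @export
fitWishartMap <- function(tensors, weights, gammaHyper = c(0.5, 1.5),
                          dof_cap = 1e4, stats = NULL) {
  wbar <- sum(weights)
  if (wbar <= 0) stop("weights must sum to > 0")
  if (is.null(stats)) stats <- wishartStats(tensors)
  pos <- weights > 0
  if (sum(pos) < 2) {
    ## dispersion unidentifiable from a single support point
    Sbar <- colSums(stats$inv6 * weights) / wbar
    n <- 2 + 1e-6
    return(list(params = wishartParams(n, sym6ToMat(Sbar) / n,
                  gammaHyper %||% c(NA_real_, NA_real_)),
                flags = "dof_boundary"))
  }
  Sbar6 <- colSums(stats$inv6 * weights) / wbar
  ldBar <- sum(stats$logdetInv * weights) / wbar
  ldS <- determinant(sym6ToMat(Sbar6), logarithm = TRUE)$modulus[1]
  prof <- function(n) {
    val <- wbar * (((n - 4) / 2) * ldBar - 1.5 * n * log(2) -
      (n / 2) * (ldS - 3 * log(n)) - 1.5 * n - lmvgamma3(n / 2))
    if (!is.null(gammaHyper))
      val <- val + (gammaHyper[1] - 1) * log((n - 2) / 2) -
        gammaHyper[2] * (n - 2) / 2
    val
  }
  ## search on log(n - 2) so the interval spans the cap cheaply but the
  ## solution is still resolved to ~1e-8 relative near the optimum
  opt <- optimize(function(u) prof(2 + exp(u)),
                  interval = c(log(1e-8), log(dof_cap - 2)), maximum = TRUE,
                  tol = 1e-9)
  n <- 2 + exp(opt$maximum)
  flags <- character()
  if (n < 2 + 1e-4) { n <- 2 + 1e-4; flags <- c(flags, "dof_boundary") }
  if (n > dof_cap * 0.999) flags <- c(flags, "dof_cap")
  list(params = wishartParams(n, sym6ToMat(Sbar6) / n,
         gammaHyper %||% c(NA_real_, NA_real_)), flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Isotropic Gaussian on log-Euclidean 6-vectors
## ---------------------------------------------------------------------------

#' Log-Gaussian parameters
#' @param mean length-6 log-domain mean vector.
#' @param var positive scalar variance.
#' @return a \linkS4class{LogGaussianParams}.
#' @export
logGaussianParams <- function(mean, var) {
  new("LogGaussianParams", mean = as.numeric(mean), var = var)
}

#' Isotropic 6-D Gaussian log-density on log-tensor vectors
#'
#' @param d length-6 vector or V x 6 matrix of log-Euclidean tensor vectors.
#' @param params a \linkS4class{LogGaussianParams}.
#' @return log-density value(s).
#' @export
loggaussLogpdf <- function(d, params) {
  if (params@var <= 0) stop("variance must be > 0")
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  q <- rowSums(sweep(d, 2, params@mean)^2)
  drop(-3 * log(2 * pi * params@var) - q / (2 * params@var))
}

#' Weighted fit of the log-Gaussian component (uniform priors)
#'
#' @param logvecs V x 6 matrix.
#' @param weights non-negative weights, sum > 0.
#' @param var_floor minimum variance.
#' @return list with \code{params} and \code{flags}.
#' @export
fitLoggauss <- function(logvecs, weights, var_floor = 1e-8) {
  wbar <- sum(weights)
  if (wbar <= 0) stop("weights must sum to > 0")
  m <- colSums(logvecs * weights) / wbar
  s <- sum(weights * rowSums(sweep(logvecs, 2, m)^2)) / (6 * wbar)
  flags <- character()
  if (s < var_floor) { s <- var_floor; flags <- "variance_floored" }
  list(params = logGaussianParams(m, s), flags = flags)
}

## ---------------------------------------------------------------------------
## Watson normaliser and joint DSW-beta
## ---------------------------------------------------------------------------

#' Log normalising constant of the Watson (DSW) axial distribution
#'
#' \code{log Z(kappa) = log(4*pi) + log M(1/2, 3/2, kappa)} with M the
#' confluent hypergeometric (Kummer) function, so that
#' \code{exp(kappa * (psi . phi)^2) / Z(kappa)} integrates to 1 over the unit
#' sphere.  Computed by power series for small kappa and by the exponential
#' asymptotic expansion for large kappa; stable up to \code{kappa = cap}.
#'
#' @param kappa non-negative concentration(s).
#' @param cap error above this value (numerical validity limit).
#' @return log Z(kappa), vectorised.
#' @examples
#' exp(watsonLogNormaliser(0)) # 4*pi: the uniform sphere measure
#' @export
watsonLogNormaliser <- function(kappa, cap = 1e4) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  if (any(kappa > cap)) stop("kappa exceeds the supported cap ", cap)
  log(4 * pi) + kummerLogM13(kappa)
}

## log M(1/2, 3/2, x) for x >= 0, vectorised
kummerLogM13 <- function(x) {
  out <- numeric(length(x))
  small <- x < 30
  if (any(small)) {
    xs <- x[small]
    ## M(1/2,3/2,x) = sum_k x^k / ((2k+1) k!)
    acc <- rep(1, length(xs))
    term <- rep(1, length(xs))
    for (k in 1:150) {
      term <- term * xs / k
      contrib <- term / (2 * k + 1)
      acc <- acc + contrib
      if (all(contrib < 1e-17 * acc)) break
    }
    out[small] <- log(acc)
  }
  if (any(!small)) {
    xl <- x[!small]
    ## M(1/2,3/2,x) ~ e^x/(2x) * sum_m (1/2)_m / x^m, truncated where the
    ## asymptotic terms stop decreasing
    acc <- rep(1, length(xl))
    term <- rep(1, length(xl))
    live <- rep(TRUE, length(xl))
    for (m in 1:25) {
      newterm <- term * (m - 0.5) / xl
      live <- live & abs(newterm) < abs(term)
      term[live] <- newterm[live]
      acc[live] <- acc[live] + term[live]
      if (!any(live)) break
    }
    out[!small] <- xl - log(2 * xl) + log(acc)
  }
  out
}

#' DSW-beta parameters
#' @param shape1,shape2 positive Beta parameters for FA.
#' @param meanDir mean axis (normalised internally).
#' @param kappa non-negative concentration.
#' @return a \linkS4class{DSWBetaParams}.
#' @export
dswBetaParams <- function(shape1, shape2, meanDir, kappa) {
  new("DSWBetaParams", shape1 = shape1, shape2 = shape2,
      meanDir = meanDir / sqrt(sum(meanDir^2)), kappa = kappa)
}

#' Joint Beta/Watson log-density of FA and principal direction
#'
#' \code{log Beta(f; a, b) + kappa*f*(psi.phi)^2 - log Z(kappa*f)}: the
#' voxel's effective concentration is the component concentration scaled by
#' its FA, so low-anisotropy voxels carry less directional information.  The
#' density is antipodally symmetric in \code{phi}.
#'
#' @param f FA value(s) in [0,1].
#' @param phi unit 3-vector or V x 3 matrix of principal directions.
#' @param params a \linkS4class{DSWBetaParams}.
#' @return log-density value(s).
#' @export
dswbetaLogpdf <- function(f, phi, params) {
  if (any(f < 0 | f > 1)) stop("FA outside [0,1]")
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1)
  t <- drop(phi %*% params@meanDir)
  keff <- params@kappa * f
  dbeta(f, params@shape1, params@shape2, log = TRUE) +
    keff * t^2 - watsonLogNormaliser(keff)
}

#' Weighted fit of the joint DSW-beta component
#'
#' The mean axis is the dominant eigenvector of the FA-weighted scatter
#' \code{sum_v w_v f_v phi_v phi_v'} (FA weighting per the effective
#' concentration model); the concentration maximises the profiled
#' directional likelihood by 1-D search; the Beta parameters maximise the
#' weighted Beta likelihood from a method-of-moments start.
#'
#' @param fas V FA values in [0,1].
#' @param pdirs V x 3 unit direction matrix.
#' @param weights non-negative weights, sum > 0.
#' @param kappa_cap,beta_cap parameter caps.
#' @param iso_tol relative eigengap below which the scatter is treated as
#'   isotropic (kappa -> 0, axis arbitrary, flagged).
#' @return list with \code{params} and \code{flags}.
#' @export
fitDswbeta <- function(fas, pdirs, weights, kappa_cap = 1e4,
                       beta_cap = 1e3, iso_tol = 1e-8) {
  wbar <- sum(weights)
  if (wbar <= 0) stop("weights must sum to > 0")
  flags <- character()
  scat <- crossprod(pdirs * sqrt(weights * fas))
  e <- eigen(scat, symmetric = TRUE)
  if ((e$values[1] - e$values[2]) <= iso_tol * max(e$values[1], 1e-300)) {
    psi <- c(1, 0, 0)
    kap <- 0
    flags <- c(flags, "isotropic_scatter")
  } else {
    psi <- fixSign(e$vectors[, 1])
    t2 <- drop(pdirs %*% psi)^2
    dirObj <- function(k) sum(weights * (k * fas * t2 -
      kummerLogM13(k * fas)))
    ## 1-D search on log(1 + kappa): wide range, fine relative resolution
    opt0 <- optimize(function(u) dirObj(expm1(u)),
                     c(0, log1p(kappa_cap)), maximum = TRUE, tol = 1e-7)
    opt <- list(maximum = expm1(opt0$maximum), objective = opt0$objective)
    kap <- opt$maximum
    ## boundary handling: compare against the endpoints explicitly
    if (dirObj(0) >= opt$objective) kap <- 0
    if (dirObj(kappa_cap) > max(opt$objective, dirObj(0))) {
      kap <- kappa_cap
      flags <- c(flags, "kappa_cap")
    }
  }
  bp <- fitBetaWeighted(fas, weights, beta_cap)
  flags <- c(flags, bp$flags)
  list(params = dswBetaParams(bp$shape1, bp$shape2, psi, kap), flags = flags)
}

## weighted Beta maximum likelihood (method of moments + quasi-Newton)
fitBetaWeighted <- function(fas, weights, beta_cap = 1e3) {
  wbar <- sum(weights)
  f <- pmin(pmax(fas, 1e-9), 1 - 1e-9)
  m <- sum(weights * f) / wbar
  v <- sum(weights * (f - m)^2) / wbar
  v <- max(v, 1e-12)
  common <- m * (1 - m) / v - 1
  a0 <- max(min(m * common, beta_cap), 1e-3)
  b0 <- max(min((1 - m) * common, beta_cap), 1e-3)
  s1 <- sum(weights * log(f)) / wbar
  s2 <- sum(weights * log(1 - f)) / wbar
  nll <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    -((a - 1) * s1 + (b - 1) * s2 - lbeta(a, b))
  }
  opt <- optim(log(c(a0, b0)), nll, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 200))
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  flags <- character()
  if (a > beta_cap || b > beta_cap) {
    a <- min(a, beta_cap); b <- min(b, beta_cap)
    flags <- "beta_cap"
  }
  list(shape1 = a, shape2 = b, flags = flags)
}

## ---------------------------------------------------------------------------
## Family dispatch used by the GEM engine and symmetry machinery
## ---------------------------------------------------------------------------

## Per-voxel diffusion sufficient statistics on the structural grid, derived
## from the resampled log-tensor field in a single spectral pass per voxel.
computeDiffStats <- function(logfield) {
  lv <- logfield@logvecs
  V <- nrow(lv)
  inv6 <- matrix(NA_real_, V, 6)
  logdetInv <- rep(NA_real_, V)
  fa <- rep(NA_real_, V)
  pdir <- matrix(NA_real_, V, 3)
  scl <- c(1, 1, 1, SQRT2, SQRT2, SQRT2)
  for (v in which(logfield@valid)) {
    e <- eigen(sym6ToMat(lv[v, ] / scl), symmetric = TRUE)
    lam <- exp(e$values)
    inv6[v, ] <- matToSym6(e$vectors %*% ((1 / lam) * t(e$vectors)))
    logdetInv[v] <- -sum(e$values)
    fa[v] <- min(1, sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) /
                   sqrt(sum(lam^2)))
    pdir[v, ] <- fixSign(e$vectors[, 1])
  }
  list(logvecs = lv, inv6 = inv6, logdetInv = logdetInv, fa = fa,
       pdir = pdir, valid = logfield@valid)
}

## V x 1 log-density of one diffusion component on precomputed stats
diffLogpdfStats <- function(stats, params, family) {
  switch(family,
    wishart = wishartLogpdfStats(stats$inv6, stats$logdetInv, params),
    loggauss = loggaussLogpdf(stats$logvecs, params),
    dswbeta = dswbetaLogpdf(stats$fa, stats$pdir, params),
    stop("unknown diffusion family ", family))
}

## weighted fit of one diffusion component on precomputed stats
fitDiffComponent <- function(stats, weights, family, opts = list()) {
  switch(family,
    wishart = fitWishartMap(NULL, weights,
      gammaHyper = opts$gammaHyper %||% c(0.5, 1.5),
      stats = list(inv6 = stats$inv6, logdetInv = stats$logdetInv)),
    loggauss = fitLoggauss(stats$logvecs, weights,
      var_floor = opts$var_floor %||% 1e-8),
    dswbeta = fitDswbeta(stats$fa, stats$pdir, weights,
      kappa_cap = opts$kappa_cap %||% 1e4),
    stop("unknown diffusion family ", family))
}
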