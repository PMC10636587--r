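## Reflective symmetry across the midline.  Contralateral diffusion
## components are modelled as reflections of each other through a plane
## whose unit normal r is estimated from the data; prior to each M step the
## plane is re-estimated and paired components are fitted jointly from the
## union of left data and reflected right data.

## symmetric matrix <-> isometric 6-vector (the log-Euclidean convention)
vec6ToSymMat <- function(d) sym6ToMat(c(d[1:3], d[4:6] / SQRT2))
symMatToVec6 <- function(M) {
  s <- matToSym6(M)
  c(s[1:3], s[4:6] * SQRT2)
}

#' Reflect diffusion component parameters through a plane
#'
#' DSW-beta: the mean axis maps to \code{H psi} (concentration and Beta
#' parameters unchanged); log-Gaussian: the mean 6-vector maps through
#' \code{H M H} in tensor space (variance unchanged); Wishart: the scale
#' maps to \code{H V H} (degrees of freedom unchanged).  Reflecting twice is
#' the identity, and each family's normalisation is preserved: the reflected
#' density at reflected data equals the original density at the original
#' data.
#'
#' @param params a diffusion component parameter object.
#' @param plane a \linkS4class{ReflectionPlane}.
#' @return parameters of the same family.
#' @export
reflectParams <- function(params, plane) {
  H <- householder(plane)
  if (is(params, "DSWBetaParams")) {
    new("DSWBetaParams", shape1 = params@shape1, shape2 = params@shape2,
        meanDir = drop(H %*% params@meanDir), kappa = params@kappa)
  } else if (is(params, "LogGaussianParams")) {
    M <- vec6ToSymMat(params@mean)
    new("LogGaussianParams", mean = symMatToVec6(H %*% M %*% H),
        var = params@var)
  } else if (is(params, "WishartParams")) {
    new("WishartParams", dof = params@dof,
        scale = H %*% params@scale %*% H, gammaHyper = params@gammaHyper)
  } else stop("unsupported parameter family")
}

## reflect per-voxel diffusion statistics (data mapped through H)
reflectStats <- function(stats, plane, family) {
  H <- householder(plane)
  out <- stats
  if (family == "dswbeta") {
    out$pdir <- stats$pdir %*% H
  } else if (family == "loggauss") {
    out$logvecs <- t(apply(stats$logvecs, 1, function(d)
      symMatToVec6(H %*% vec6ToSymMat(d) %*% H)))
  } else if (family == "wishart") {
    out$inv6 <- t(apply(stats$inv6, 1, function(d)
      matToSym6(H %*% sym6ToMat(d) %*% H)))
  } else stop("unknown family")
  out
}

## Sufficient statistics of the r-dependent objective, per pair: the right
## component's posterior-weighted data scatter plus the left component's
## location/dispersion parameters.
reflectionPairStats <- function(stats, weightsR, paramsL, family) {
  if (family == "dswbeta") {
    w <- weightsR * stats$fa
    w[!stats$valid] <- 0
    list(S = crossprod(stats$pdir[stats$valid, , drop = FALSE] *
                         sqrt(w[stats$valid])),
         psi = paramsL@meanDir, kappa = paramsL@kappa)
  } else if (family == "loggauss") {
    w <- weightsR
    w[!stats$valid] <- 0
    Dbar6 <- colSums(stats$logvecs[stats$valid, , drop = FALSE] *
                       w[stats$valid])
    list(D = vec6ToSymMat(Dbar6), M = vec6ToSymMat(paramsL@mean),
         invvar = 1 / paramsL@var)
  } else if (family == "wishart") {
    w <- weightsR
    w[!stats$valid] <- 0
    S6 <- colSums(stats$inv6[stats$valid, , drop = FALSE] * w[stats$valid])
    list(S = sym6ToMat(S6), Vinv = solve(paramsL@scale), dof = paramsL@dof)
  } else stop("unknown family")
}

#' Reflection objective and its gradient
#'
#' The r-dependent part of the GEM bound when every right-hemisphere
#' component is the reflection of its left partner: per pair,
#' DSW-beta contributes \code{kappa * psi' H S H psi} with S the FA- and
#' posterior-weighted direction scatter; log-Gaussian contributes
#' \code{(1/sigma) tr(H M H D)}; Wishart contributes
#' \code{-(n/2) tr(H V^-1 H S)}.  Dispersion parameters weight each pair, and
#' posteriors weight each voxel.  With \code{H = I - 2 r r'} (no
#' normalisation of r) the objective is a quartic polynomial in r.
#'
#' @param r 3-vector (need not be unit; see details).
#' @param pairStats list of per-pair statistic lists from the internal
#'   builder.
#' @param family diffusion family.
#' @return list with \code{value} and \code{grad}.
#' @keywords internal
reflectionObjective <- function(r, pairStats, family) {
  H <- diag(3) - 2 * tcrossprod(r)
  val <- 0
  grad <- c(0, 0, 0)
  for (ps in pairStats) {
    if (family == "dswbeta") {
      u <- drop(H %*% ps$psi)
      Su <- drop(ps$S %*% u)
      val <- val + ps$kappa * sum(u * Su)
      grad <- grad - 4 * ps$kappa *
        (drop(crossprod(r, ps$psi)) * Su + drop(crossprod(r, Su)) * ps$psi)
    } else if (family == "loggauss") {
      B <- ps$M %*% H %*% ps$D + ps$D %*% H %*% ps$M
      val <- val + ps$invvar * sum(diag(H %*% ps$M %*% H %*% ps$D))
      grad <- grad - 4 * ps$invvar * drop(B %*% r)
    } else if (family == "wishart") {
      B <- ps$Vinv %*% H %*% ps$S + ps$S %*% H %*% ps$Vinv
      val <- val - (ps$dof / 2) * sum(diag(H %*% ps$Vinv %*% H %*% ps$S))
      grad <- grad + 2 * ps$dof * drop(B %*% r)
    }
  }
  list(value = val, grad = grad)
}

#' Estimate the reflective-symmetry plane normal
#'
#' Maximises the paired-component objective (a quartic polynomial in the
#' normal) over the unit sphere by projected gradient ascent with
#' backtracking, starting from the supplied plane.  The returned objective
#' is never below the objective at the initial normal.
#'
#' @param stats per-voxel diffusion statistics (internal representation).
#' @param weights V x W matrix of per-component posterior weights.
#' @param params list of diffusion component parameters (length W).
#' @param pairs P x 2 matrix of (left, right) component indices.
#' @param plane initial \linkS4class{ReflectionPlane}.
#' @param family diffusion family.
#' @param max_iter,tol iteration cap and relative tolerance.
#' @return list with \code{plane}, \code{value}, \code{degenerate} (flat
#'   objective) and \code{converged}.
#' @export
optimiseReflection <- function(stats, weights, params, pairs, plane,
                               family, max_iter = 200, tol = 1e-12) {
  if (nrow(pairs) < 1) stop("at least one component pair is required")
  pairStats <- lapply(seq_len(nrow(pairs)), function(p)
    reflectionPairStats(stats, weights[, pairs[p, 2]],
                        params[[pairs[p, 1]]], family))
  r <- plane@normal
  ob <- reflectionObjective(r, pairStats, family)
  f0 <- ob$value
  scale0 <- max(abs(f0), 1e-8)
  degenerate <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- ob$grad
    gt <- g - sum(g * r) * r
    gn <- sqrt(sum(gt^2))
    if (gn < 1e-10 * scale0) {
      degenerate <- it == 1 && abs(f0) < 1e-10 * max(scale0, 1)
      converged <- TRUE
      break
    }
    step <- 1 / max(gn, 1e-12)
    improved <- FALSE
    for (ls in 1:40) {
      cand <- r + step * gt
      cand <- cand / sqrt(sum(cand^2))
      obc <- reflectionObjective(cand, pairStats, family)
      if (obc$value > f0) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel <- (obc$value - f0) / max(abs(f0), 1e-12)
    r <- cand
    f0 <- obc$value
    ob <- obc
    if (rel < tol) { converged <- TRUE; break }
  }
  list(plane = reflectionPlane(r), value = f0, degenerate = degenerate,
       converged = converged)
}

#' Jointly fit a contralateral component pair under reflection
#'
#' Pools the left-hemisphere data with the right-hemisphere data mapped
#' through the reflection, fits a single component of the family on the
#' union, and reports the right-hemisphere parameters as the reflection of
#' the fitted set.  With exactly mirror-symmetric data this equals the two
#' independent fits; with one side's weights zero it reduces to the
#' (reflected) one-sided fit.
#'
#' @param stats per-voxel diffusion statistics.
#' @param weightsL,weightsR per-voxel posterior weights of the left and
#'   right components.
#' @param plane the \linkS4class{ReflectionPlane}.
#' @param family diffusion family.
#' @param opts fitter options passed through.
#' @return list with \code{left}, \code{right} parameter objects and
#'   \code{flags}.
#' @export
fitPairSymmetric <- function(stats, weightsL, weightsR, plane, family,
                             opts = list()) {
  refl <- reflectStats(stats, plane, family)
  pooled <- list(
    logvecs = rbind(stats$logvecs, refl$logvecs),
    inv6 = rbind(stats$inv6, refl$inv6),
    logdetInv = c(stats$logdetInv, refl$logdetInv),
    fa = c(stats$fa, refl$fa),
    pdir = rbind(stats$pdir, refl$pdir),
    valid = c(stats$valid, refl$valid))
  wts <- c(weightsL, weightsR)
  wts[!pooled$valid] <- 0
  fit <- fitDiffComponent(maskInvalid(pooled, wts), wts, family, opts)
  list(left = fit$params, right = reflectParams(fit$params, plane),
       flags = fit$flags)
}

## zero weights on invalid voxels and replace their stats by harmless values
maskInvalid <- function(stats, weights) {
  bad <- !stats$valid
  if (!any(bad)) return(stats)
  stats$logvecs[bad, ] <- 0
  stats$inv6[bad, ] <- rep(c(1, 1, 1, 0, 0, 0), each = sum(bad))
  stats$logdetInv[bad] <- 0
  stats$fa[bad] <- 0.5
  stats$pdir[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
  stats
}
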