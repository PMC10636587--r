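## Symmetric 3x3 tensors are stored as 6-vectors in diagonal-first order
## (xx, yy, zz, xy, xz, yz).  The log-Euclidean 6-vector applies sqrt(2) to
## the off-diagonals so that Euclidean distance between vectors equals
## Frobenius distance between matrix logarithms (the isometry the whole
## log-domain machinery rests on).

SQRT2 <- sqrt(2)

#' Convert between 6-element storage and full symmetric 3x3 matrices
#'
#' @param x length-6 vector in (xx, yy, zz, xy, xz, yz) order, or a 3x3
#'   symmetric matrix.
#' @return \code{sym6ToMat}: 3x3 matrix; \code{matToSym6}: length-6 vector.
#'   Asymmetric storage is absorbed by symmetrising as \code{(T + t(T))/2}.
#' @export
sym6ToMat <- function(x) {
  matrix(c(x[1], x[4], x[5],
           x[4], x[2], x[6],
           x[5], x[6], x[3]), 3, 3)
}

#' @rdname sym6ToMat
#' @export
matToSym6 <- function(x) {
  x <- (x + t(x)) / 2
  c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[1, 3], x[2, 3])
}

## apply a scalar spectral function to each row of a V x 6 tensor matrix
batchSpectralFun <- function(t6, fun) {
  out <- t6
  for (v in seq_len(nrow(t6))) {
    e <- eigen(sym6ToMat(t6[v, ]), symmetric = TRUE)
    out[v, ] <- matToSym6(e$vectors %*% (fun(e$values) * t(e$vectors)))
  }
  out
}

#' Log-Euclidean vectorization of an SPD tensor
#'
#' Maps a symmetric positive-definite 3x3 tensor to the 6-vector
#' \code{d = (t11, t22, t33, sqrt(2) t12, sqrt(2) t13, sqrt(2) t23)} of its
#' matrix logarithm \code{t = log T}.  The scaling makes the map an isometry:
#' for any two SPD tensors the Frobenius distance between their logarithms
#' equals the Euclidean distance between their 6-vectors, so interpolating
#' the vectors interpolates the tensors in the log domain.
#'
#' @param T symmetric positive-definite 3x3 matrix (symmetrised internally).
#' @return numeric length-6 log-vector.
#' @seealso \code{\link{tensorFromLogvec}} for the inverse map.
#' @examples
#' logTensorVectorize(diag(3))           # zero vector
#' logTensorVectorize(exp(1) * diag(3))  # (1,1,1,0,0,0)
#' @export
logTensorVectorize <- function(T) {
  T <- (T + t(T)) / 2
  e <- eigen(T, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("tensor is not SPD: eigenvalue ", signif(min(e$values), 6), " <= 0")
  lt <- e$vectors %*% (log(e$values) * t(e$vectors))
  s6 <- matToSym6(lt)
  s6 * c(1, 1, 1, SQRT2, SQRT2, SQRT2)
}

#' @rdname logTensorVectorize
#' @param d length-6 log-vector.
#' @return \code{tensorFromLogvec}: the SPD 3x3 tensor \code{expm(unvec(d))}.
#' @export
tensorFromLogvec <- function(d) {
  s6 <- d / c(1, 1, 1, SQRT2, SQRT2, SQRT2)
  lt <- sym6ToMat(s6)
  e <- eigen(lt, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

## batched forms operating on V x 6 matrices ---------------------------------

logvecsFromTensors <- function(t6) {
  lt <- batchSpectralFun(t6, log)
  sweep(lt, 2, c(1, 1, 1, SQRT2, SQRT2, SQRT2), "*")
}

tensorsFromLogvecs <- function(d) {
  s6 <- sweep(d, 2, c(1, 1, 1, SQRT2, SQRT2, SQRT2), "/")
  batchSpectralFun(s6, exp)
}

#' Fractional anisotropy and principal direction of an SPD tensor
#'
#' FA is \code{sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||} over the
#' eigenvalues; the principal direction is the unit eigenvector of the
#' largest eigenvalue with the sign fixed so its first nonzero component is
#' positive (the axis is antipodally symmetric, so the sign is arbitrary).
#'
#' @param T symmetric positive-definite 3x3 tensor.
#' @param tol relative eigenvalue gap below which the principal direction is
#'   flagged degenerate.
#' @return list with \code{fa}, unit \code{pdir}, and logical
#'   \code{degenerate}.
#' @examples
#' faPrincipalDirection(diag(c(3, 2, 1)))$fa  # sqrt(3/14)
#' @export
faPrincipalDirection <- function(T, tol = 1e-6) {
  T <- (T + t(T)) / 2
  e <- eigen(T, symmetric = TRUE)
  lam <- e$values
  if (any(lam <= 0))
    stop("tensor is not SPD: eigenvalue ", signif(min(lam), 6), " <= 0")
  fa <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  fa <- min(max(fa, 0), 1)
  pdir <- e$vectors[, 1]
  degenerate <- (lam[1] - lam[2]) < tol * abs(lam[1])
  pdir <- fixSign(pdir)
  list(fa = fa, pdir = pdir, degenerate = degenerate)
}

fixSign <- function(v, tol = 1e-12) {
  nz <- which(abs(v) > tol)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  v
}

#' Construct a tensor field
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param tensors V x 6 matrix in (xx, yy, zz, xy, xz, yz) order.
#' @param valid optional logical mask; by default computed from the SPD
#'   criterion (all eigenvalues positive and finite entries, which also
#'   bounds FA in [0,1]).
#' @return a \linkS4class{TensorField}.
#' @export
tensorField <- function(grid, tensors, valid = NULL) {
  if (is.null(valid)) valid <- tensorsAreSPD(tensors)
  new("TensorField", grid = grid, tensors = tensors, valid = valid)
}

tensorsAreSPD <- function(t6) {
  v <- rep(FALSE, nrow(t6))
  finite <- rowSums(is.finite(t6)) == 6L
  for (i in which(finite)) {
    lam <- eigen(sym6ToMat(t6[i, ]), symmetric = TRUE,
                 only.values = TRUE)$values
    v[i] <- all(lam > 0)
  }
  v
}

#' Replace poorly fitted tensors by local log-domain averages
#'
#' Voxels whose tensors are not SPD (negative eigenvalues, or equivalently FA
#' outside [0,1]) are replaced by the exponential of the Gaussian-weighted
#' mean of the surrounding valid voxels' log-tensors; valid voxels pass
#' through untouched.  The kernel is an isotropic 3D Gaussian in world mm,
#' truncated at 3 sigma.
#'
#' @param field a \linkS4class{TensorField} (its \code{valid} mask marks the
#'   voxels to repair).
#' @param kernel_sigma_mm Gaussian kernel width in mm (default 2).
#' @return a \linkS4class{TensorField} with every voxel valid.
#' @export
cleanTensorField <- function(field, kernel_sigma_mm = 2) {
  bad <- which(!field@valid)
  if (!length(bad)) return(field)
  good <- which(field@valid)
  if (!length(good)) stop("no valid voxels to average from")
  d <- field@grid@dim
  vs <- voxelSize(field@grid)
  logv <- matrix(NA_real_, nrow(field@tensors), 6)
  out <- field@tensors

  ## offsets within the truncated kernel support, in voxel steps
  rad <- pmax(1L, ceiling(3 * kernel_sigma_mm / vs))
  offs <- as.matrix(expand.grid(-rad[1]:rad[1], -rad[2]:rad[2], -rad[3]:rad[3]))
  dist2 <- colSums(t(offs)^2 * vs^2)
  keep <- dist2 <= (3 * kernel_sigma_mm)^2 & dist2 > 0
  offs <- offs[keep, , drop = FALSE]
  kw <- exp(-dist2[keep] / (2 * kernel_sigma_mm^2))

  idx3 <- voxelIndexGrid(field@grid)
  for (v in bad) {
    nb <- sweep(offs, 2, idx3[v, ], "+")
    inside <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
      nb[, 3] >= 0 & nb[, 3] < d[3]
    lin <- 1L + nb[inside, 1] + d[1] * (nb[inside, 2] + d[2] * nb[inside, 3])
    wts <- kw[inside]
    ok <- field@valid[lin]
    if (!any(ok))
      stop("isolated invalid voxel at linear index ", v,
           ": no valid neighbour within the kernel support")
    lin <- lin[ok]; wts <- wts[ok]
    need <- lin[is.na(logv[lin, 1])]
    if (length(need))
      logv[need, ] <- logvecsFromTensors(out[need, , drop = FALSE])
    mean_log <- colSums(logv[lin, , drop = FALSE] * wts) / sum(wts)
    out[v, ] <- matToSym6(tensorFromLogvec(mean_log))
  }
  new("TensorField", grid = field@grid, tensors = out,
      valid = rep(TRUE, nrow(out)))
}

#' Log-Euclidean vectorization of a whole tensor field
#'
#' @param field a \linkS4class{TensorField}; invalid voxels get NA log-vectors
#'   and stay invalid.
#' @return a \linkS4class{LogTensorField}.
#' @export
logTensorField <- function(field) {
  lv <- matrix(NA_real_, nrow(field@tensors), 6)
  ok <- field@valid
  if (any(ok))
    lv[ok, ] <- logvecsFromTensors(field@tensors[ok, , drop = FALSE])
  new("LogTensorField", grid = field@grid, logvecs = lv, valid = ok)
}

#' @rdname logTensorField
#' @param logfield a \linkS4class{LogTensorField}.
#' @return \code{expLogTensorField}: the corresponding
#'   \linkS4class{TensorField}.
#' @export
expLogTensorField <- function(logfield) {
  t6 <- matrix(NA_real_, nrow(logfield@logvecs), 6)
  ok <- logfield@valid
  if (any(ok))
    t6[ok, ] <- tensorsFromLogvecs(logfield@logvecs[ok, , drop = FALSE])
  new("TensorField", grid = logfield@grid, tensors = t6, valid = ok)
}

#' Resample a log-tensor field onto a target grid
#'
#' Componentwise trilinear interpolation of the 6-vectors in world space:
#' each target voxel centre is mapped through both affines into continuous
#' source voxel coordinates.  Target voxels whose 8-neighbour support is not
#' fully inside the source field (or touches invalid source voxels) are
#' marked invalid rather than extrapolated.
#'
#' @param src a \linkS4class{LogTensorField}.
#' @param target a \linkS4class{VoxelGrid} in the same world space.
#' @return a \linkS4class{LogTensorField} on \code{target}.
#' @export
resampleLogTensors <- function(src, target) {
  if (any(target@dim < 1L)) stop("degenerate target grid")
  if (sameGrid(src@grid, target)) return(src)
  vox <- worldToVoxel(src@grid, voxelCenters(target))
  d <- src@grid@dim
  f <- floor(vox)
  w <- vox - f
  ## snap exact upper-boundary points onto the last interior cell
  for (k in 1:3) {
    hit <- abs(vox[, k] - (d[k] - 1)) < 1e-9
    f[hit, k] <- d[k] - 2
    w[hit, k] <- 1
  }
  inside <- (f[, 1] >= 0 & f[, 1] <= d[1] - 2) &
            (f[, 2] >= 0 & f[, 2] <= d[2] - 2) &
            (f[, 3] >= 0 & f[, 3] <= d[3] - 2)

  nV <- nrow(vox)
  out <- matrix(NA_real_, nV, 6)
  valid <- rep(FALSE, nV)
  ii <- which(inside)
  if (length(ii)) {
    acc <- matrix(0, length(ii), 6)
    okall <- rep(TRUE, length(ii))
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      wt <- (if (cx) w[ii, 1] else 1 - w[ii, 1]) *
            (if (cy) w[ii, 2] else 1 - w[ii, 2]) *
            (if (cz) w[ii, 3] else 1 - w[ii, 3])
      lin <- 1L + (f[ii, 1] + cx) + d[1] * ((f[ii, 2] + cy) +
             d[2] * (f[ii, 3] + cz))
      okall <- okall & (src@valid[lin] | wt < 1e-12)
      vals <- src@logvecs[lin, , drop = FALSE]
      vals[is.na(vals)] <- 0
      acc <- acc + vals * wt
    }
    out[ii[okall], ] <- acc[okall, , drop = FALSE]
    valid[ii[okall]] <- TRUE
  }
  new("LogTensorField", grid = target, logvecs = out, valid = valid)
}

#' FA and principal-direction summary of a tensor field
#'
#' @param field a \linkS4class{TensorField}.
#' @return a \linkS4class{DTISummaryField}; invalid voxels carry NA FA.
#' @export
dtiSummary <- function(field) {
  nV <- nrow(field@tensors)
  fa <- rep(NA_real_, nV)
  pdir <- matrix(NA_real_, nV, 3)
  for (v in which(field@valid)) {
    s <- faPrincipalDirection(sym6ToMat(field@tensors[v, ]))
    fa[v] <- s$fa
    pdir[v, ] <- s$pdir
  }
  new("DTISummaryField", grid = field@grid, fa = fa, pdir = pdir,
      valid = field@valid)
}
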