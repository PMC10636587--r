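## Segmentation evaluation: Dice overlap, 95th-percentile symmetric
## Hausdorff boundary distance (world mm), intraclass correlation of
## volumes, and TOPSIS multi-criteria ranking.

#' Dice similarity coefficient
#'
#' \code{2 |X & Y| / (|X| + |Y|)} over voxel sets on a common grid.  Two
#' empty masks are defined as Dice 1 (with a warning); identical non-empty
#' masks give 1, disjoint masks give 0.
#'
#' @param x,y logical vectors/arrays or integer voxel index sets on the
#'   same grid.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(x, y) {
  if (is.logical(x)) x <- which(x)
  if (is.logical(y)) y <- which(y)
  if (!length(x) && !length(y)) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * length(intersect(x, y)) / (length(x) + length(y))
}

## linear voxel indices of the 6-connectivity boundary of a mask
boundaryVoxels <- function(maskIdx, grid) {
  d <- grid@dim
  inMask <- logical(prod(d))
  inMask[maskIdx] <- TRUE
  i0 <- (maskIdx - 1L) %% d[1]
  j0 <- ((maskIdx - 1L) %/% d[1]) %% d[2]
  k0 <- (maskIdx - 1L) %/% (d[1] * d[2])
  onBoundary <- logical(length(maskIdx))
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    ii <- i0 + o[1]; jj <- j0 + o[2]; kk <- k0 + o[3]
    outside <- ii < 0 | ii >= d[1] | jj < 0 | jj >= d[2] |
      kk < 0 | kk >= d[3]
    nb <- 1L + ii + d[1] * (jj + d[2] * kk)
    onBoundary <- onBoundary | outside | !inMask[pmax(nb, 1L)]
  }
  maskIdx[onBoundary]
}

#' 95th-percentile symmetric Hausdorff boundary distance
#'
#' Boundary voxels (6-connectivity surface, voxel centres) are extracted for
#' both masks; for each boundary point the distance to the nearest point of
#' the other boundary is computed in world mm, the 95th percentile (linear
#' interpolation between order statistics) is taken in each direction, and
#' the maximum of the two directions is returned.
#'
#' @param x,y logical masks or integer voxel index sets (non-empty).
#' @param grid the \linkS4class{VoxelGrid} providing world coordinates.
#' @param probs percentile (default 0.95).
#' @return distance in mm.
#' @export
hausdorff95 <- function(x, y, grid, probs = 0.95) {
  if (is.logical(x)) x <- which(x)
  if (is.logical(y)) y <- which(y)
  if (!length(x) || !length(y)) stop("hausdorff95 requires non-empty masks")
  bx <- boundaryVoxels(x, grid)
  by <- boundaryVoxels(y, grid)
  cent <- voxelCenters(grid)
  px <- cent[bx, , drop = FALSE]
  py <- cent[by, , drop = FALSE]
  ## all-pairs squared distances (boundary sets are small)
  d2 <- outer(rowSums(px^2), rowSums(py^2), "+") - 2 * tcrossprod(px, py)
  d2[d2 < 0] <- 0
  dxy <- sqrt(apply(d2, 1, min))
  dyx <- sqrt(apply(d2, 2, min))
  max(quantile(dxy, probs, names = FALSE, type = 7),
      quantile(dyx, probs, names = FALSE, type = 7))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard mean-squares decomposition, for comparing per-subject volume
#' measurements from two acquisition conditions treated as random raters.
#'
#' @param a,b numeric vectors of paired measurements (length >= 3).
#' @return list with \code{icc} and logical \code{degenerate} (zero
#'   between-subject variance).
#' @export
iccAgreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  X <- cbind(a, b)
  n <- nrow(X); k <- 2
  rowm <- rowMeans(X); colm <- colMeans(X); gm <- mean(X)
  MSR <- k * sum((rowm - gm)^2) / (n - 1)
  MSC <- n * sum((colm - gm)^2) / (k - 1)
  SSE <- sum((X - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(MSR) < 1e-300 || abs(denom) < 1e-300)
    return(list(icc = NA_real_, degenerate = TRUE))
  list(icc = (MSR - MSE) / denom, degenerate = FALSE)
}

#' TOPSIS multi-criteria ranking
#'
#' Each measurement channel is vector-normalised; the positive (negative)
#' ideal is the per-channel best (worst) value respecting the channel's
#' direction; each candidate's L2 distances to both ideals are combined into
#' \code{score = D- / (D+ + D-)} in [0, 1].  A candidate that is best in
#' every channel scores 1 and one that is worst in every channel scores 0.
#' Channels with zero range carry no information and are dropped with a
#' warning.
#'
#' @param m candidates x channels numeric matrix.
#' @param directions character vector per channel: \code{"benefit"} (higher
#'   is better, e.g. Dice) or \code{"cost"} (lower is better, e.g. 95HD).
#' @param weights optional non-negative channel weights (default uniform).
#' @return numeric vector of scores per candidate.
#' @export
topsisScores <- function(m, directions, weights = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("TOPSIS needs at least 2 candidates")
  stopifnot(length(directions) == ncol(m))
  rng <- apply(m, 2, function(x) diff(range(x)))
  if (any(rng == 0)) {
    warning("dropping zero-range channel(s): ",
            paste(which(rng == 0), collapse = ", "))
    m <- m[, rng > 0, drop = FALSE]
    directions <- directions[rng > 0]
    if (!is.null(weights)) weights <- weights[rng > 0]
  }
  if (!ncol(m)) stop("no informative channels")
  if (is.null(weights)) weights <- rep(1, ncol(m))
  weights <- weights / sum(weights)
  z <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  z <- sweep(z, 2, weights, "*")
  best <- ifelse(directions == "benefit", apply(z, 2, max), apply(z, 2, min))
  worst <- ifelse(directions == "benefit", apply(z, 2, min), apply(z, 2, max))
  dplus <- sqrt(rowSums(sweep(z, 2, best)^2))
  dminus <- sqrt(rowSums(sweep(z, 2, worst)^2))
  dminus / (dplus + dminus)
}

#' Per-label overlap metrics between two label maps
#'
#' @param a,b integer label vectors on the same grid.
#' @param grid the \linkS4class{VoxelGrid}.
#' @param labels labels to evaluate (default: union of non-zero labels).
#' @return data.frame with label, status, dice, hd95_mm.
#' @export
evaluateLabelMaps <- function(a, b, grid, labels = NULL) {
  if (is.null(labels)) labels <- sort(setdiff(union(a, b), 0L))
  rows <- lapply(labels, function(l) {
    xa <- which(a == l); xb <- which(b == l)
    if (!length(xa) || !length(xb))
      return(data.frame(label = l, status = "missing", dice = NA_real_,
                        hd95_mm = NA_real_))
    data.frame(label = l, status = "ok",
               dice = diceCoefficient(xa, xb),
               hd95_mm = hausdorff95(xa, xb, grid))
  })
  out <- do.call(rbind, rows)
  ## whole-structure row over all listed labels
  xa <- which(a %in% labels); xb <- which(b %in% labels)
  if (length(xa) && length(xb))
    out <- rbind(out, data.frame(label = NA_integer_, status = "whole",
                                 dice = diceCoefficient(xa, xb),
                                 hd95_mm = hausdorff95(xa, xb, grid)))
  out
}
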