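## Deformable tetrahedral atlas prior.  All barycentric geometry is done in
## continuous voxel-index coordinates (barycentric coordinates are affine
## invariant, so point location there equals point location in world mm and
## bounding boxes become integer ranges for free).

## signed volumes of tetrahedra (one per row of tets)
tetVolumes <- function(vertices, tets) {
  y0 <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - y0
  e2 <- vertices[tets[, 3], , drop = FALSE] - y0
  e3 <- vertices[tets[, 4], , drop = FALSE] - y0
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Construct an atlas mesh
#'
#' @param vertices N x 3 reference vertex positions (mm).
#' @param tetrahedra M x 4 1-based vertex indices (orientation corrected
#'   automatically so signed volumes are positive).
#' @param probs N x C per-vertex class probabilities.
#' @param classNames character C (defaults to class1..classC with the first
#'   treated as background by the rasteriser).
#' @param stiffness positive deformation penalty scale.
#' @param affineToSubject 4x4 placement matrix (default identity).
#' @return an \linkS4class{AtlasMesh}.
#' @export
atlasMesh <- function(vertices, tetrahedra, probs, classNames = NULL,
                      stiffness = 1, affineToSubject = diag(4)) {
  tetrahedra <- as.matrix(tetrahedra)
  storage.mode(tetrahedra) <- "integer"
  vols <- tetVolumes(vertices, tetrahedra)
  neg <- vols < 0
  if (any(neg))  # swap two vertices to flip orientation
    tetrahedra[neg, c(1, 2)] <- tetrahedra[neg, c(2, 1)]
  if (is.null(classNames))
    classNames <- paste0("class", seq_len(ncol(probs)))
  new("AtlasMesh", vertices = vertices, tetrahedra = tetrahedra,
      probs = probs, classNames = classNames, stiffness = stiffness,
      affineToSubject = affineToSubject)
}

#' Zero deformation for a mesh
#' @param mesh an \linkS4class{AtlasMesh}.
#' @return N x 3 zero displacement matrix (subject-space mm).
#' @export
zeroDeformation <- function(mesh) {
  matrix(0, nrow(mesh@vertices), 3)
}

## vertex positions in subject world mm under a deformation
deformedVertices <- function(mesh, deform) {
  v <- cbind(mesh@vertices, 1) %*% t(mesh@affineToSubject)
  v[, 1:3, drop = FALSE] + deform
}

## Locate every voxel centre in its containing tetrahedron.
## Returns tet (integer, NA outside), bary (V x 4) in the mesh's tet order;
## ties on shared faces go to the lowest tetra index.
locateVoxels <- function(mesh, deform, grid, tol = 1e-9) {
  vertsW <- deformedVertices(mesh, deform)
  vols <- tetVolumes(vertsW, mesh@tetrahedra)
  if (any(vols <= 0))
    stop("folded mesh: tetrahedron with non-positive volume (first at index ",
         which(vols <= 0)[1], ")")
  verts <- worldToVoxel(grid, vertsW)
  d <- grid@dim
  nV <- prod(d)
  tetOf <- rep(NA_integer_, nV)
  bary <- matrix(NA_real_, nV, 4)
  M <- nrow(mesh@tetrahedra)
  for (m in seq_len(M)) {
    idx <- mesh@tetrahedra[m, ]
    Y <- verts[idx, , drop = FALSE]
    lo <- pmax(ceiling(apply(Y, 2, min) - tol), 0)
    hi <- pmin(floor(apply(Y, 2, max) + tol), d - 1)
    if (any(hi < lo)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    lin <- as.vector(outer(outer(1L + xs, d[1] * ys, "+"),
                           d[1] * d[2] * zs, "+"))
    lin <- lin[is.na(tetOf[lin])]
    if (!length(lin)) next
    pts <- cbind((lin - 1L) %% d[1],
                 ((lin - 1L) %/% d[1]) %% d[2],
                 (lin - 1L) %/% (d[1] * d[2]))
    Mm <- rbind(1, t(Y))
    N <- solve(Mm)
    b <- cbind(1, pts) %*% t(N)
    inside <- b[, 1] >= -tol & b[, 2] >= -tol & b[, 3] >= -tol & b[, 4] >= -tol
    if (any(inside)) {
      tetOf[lin[inside]] <- m
      bary[lin[inside], ] <- b[inside, , drop = FALSE]
    }
  }
  list(tet = tetOf, bary = bary, vertsVox = verts)
}

#' Rasterise atlas priors onto a voxel grid
#'
#' Each voxel centre is located in its containing tetrahedron of the deformed
#' mesh and its class prior is the barycentric combination of the four vertex
#' probability rows.  Voxels outside all tetrahedra receive the background
#' class (by default the first class) with probability 1.  A folded mesh is
#' an error, never silently rasterised.
#'
#' @param mesh an \linkS4class{AtlasMesh}.
#' @param deform N x 3 displacement matrix (mm), e.g.
#'   \code{\link{zeroDeformation}}.
#' @param grid target \linkS4class{VoxelGrid}.
#' @param background index of the background class for outside voxels.
#' @return a \linkS4class{ClassPriorField}.
#' @export
rasterisePriors <- function(mesh, deform, grid, background = 1L) {
  loc <- locateVoxels(mesh, deform, grid)
  C <- ncol(mesh@probs)
  pri <- matrix(0, prod(grid@dim), C)
  out <- is.na(loc$tet)
  pri[out, background] <- 1
  ins <- which(!out)
  if (length(ins)) {
    tv <- mesh@tetrahedra[loc$tet[ins], , drop = FALSE]
    b <- loc$bary[ins, , drop = FALSE]
    acc <- matrix(0, length(ins), C)
    for (k in 1:4)
      acc <- acc + b[, k] * mesh@probs[tv[, k], , drop = FALSE]
    ## clip tiny negatives from barycentric tolerance and renormalise
    acc[acc < 0] <- 0
    pri[ins, ] <- acc / rowSums(acc)
  }
  new("ClassPriorField", grid = grid, priors = pri,
      classNames = mesh@classNames)
}

#' Topology-preserving deformation penalty
#'
#' Per-tetrahedron barrier \code{(J + 1/J - 2)} on the deformed-to-reference
#' volume ratio J, weighted by the tetrahedron's share of the reference
#' volume and scaled by the mesh stiffness.  It is zero at the identity,
#' grows as any tetrahedron expands or contracts, diverges as a tetrahedron
#' degenerates, and is +Inf for folded (non-positive volume) configurations.
#' Rigid motions applied jointly to reference and deformed configurations
#' leave it unchanged.
#'
#' @param mesh an \linkS4class{AtlasMesh}.
#' @param deform N x 3 displacements (mm).
#' @return non-negative penalty (\code{-log} deformation prior up to a
#'   constant); +Inf when folded.
#' @export
deformationPenalty <- function(mesh, deform) {
  ref <- deformedVertices(mesh, zeroDeformation(mesh))
  cur <- ref + deform
  v0 <- tetVolumes(ref, mesh@tetrahedra)
  v1 <- tetVolumes(cur, mesh@tetrahedra)
  if (any(v1 <= 0)) return(Inf)
  J <- v1 / v0
  wts <- v0 / sum(v0)
  mesh@stiffness * sum(wts * (J + 1 / J - 2))
}

## gradient of deformationPenalty wrt displacements (N x 3), world mm
deformationPenaltyGrad <- function(mesh, deform) {
  ref <- deformedVertices(mesh, zeroDeformation(mesh))
  cur <- ref + deform
  v0 <- tetVolumes(ref, mesh@tetrahedra)
  v1 <- tetVolumes(cur, mesh@tetrahedra)
  J <- v1 / v0
  wts <- v0 / sum(v0)
  g <- matrix(0, nrow(cur), 3)
  coef <- mesh@stiffness * wts * (1 - 1 / J^2)  # d penalty / dJ
  for (m in seq_len(nrow(mesh@tetrahedra))) {
    idx <- mesh@tetrahedra[m, ]
    y0 <- cur[idx[1], ]
    E <- cbind(cur[idx[2], ] - y0, cur[idx[3], ] - y0, cur[idx[4], ] - y0)
    ## dJ/dE = J * t(solve(E)); distribute to vertices
    G <- J[m] * t(solve(E)) * coef[m]
    g[idx[2], ] <- g[idx[2], ] + G[, 1]
    g[idx[3], ] <- g[idx[3], ] + G[, 2]
    g[idx[4], ] <- g[idx[4], ] + G[, 3]
    g[idx[1], ] <- g[idx[1], ] - rowSums(G)
  }
  g
}

## prior-term value and gradient: sum_v sum_c w_vc log prior_vc.
## classWeights: V x C posterior class weights (rows may sum to <= 1).
priorTermAndGrad <- function(mesh, deform, grid, classWeights,
                             logFloor = 1e-12, wantGrad = TRUE) {
  loc <- locateVoxels(mesh, deform, grid)
  C <- ncol(mesh@probs)
  nvert <- nrow(mesh@vertices)
  val <- 0
  gVox <- matrix(0, nvert, 3)  # gradient in voxel coordinates
  ins <- which(!is.na(loc$tet))
  outs <- which(is.na(loc$tet))
  if (length(outs)) {
    ## outside voxels see the background prior: log 1 for background mass,
    ## floor for any stray non-background mass
    wOut <- classWeights[outs, , drop = FALSE]
    val <- val + sum(wOut[, -1, drop = FALSE]) * log(logFloor)
  }
  if (length(ins)) {
    ord <- order(loc$tet[ins])
    ins <- ins[ord]
    tets <- loc$tet[ins]
    runs <- rle(tets)
    pos <- c(0L, cumsum(runs$lengths))
    for (r in seq_along(runs$values)) {
      m <- runs$values[r]
      vv <- ins[(pos[r] + 1L):pos[r + 1L]]
      idx <- mesh@tetrahedra[m, ]
      b <- loc$bary[vv, , drop = FALSE]
      P <- mesh@probs[idx, , drop = FALSE]         # 4 x C
      p <- b %*% P                                 # |vv| x C priors
      p[p < logFloor] <- logFloor
      wv <- classWeights[vv, , drop = FALSE]
      val <- val + sum(wv * log(p))
      if (wantGrad) {
        dOdb <- (wv / p) %*% t(P)                  # |vv| x 4
        Y <- loc$vertsVox[idx, , drop = FALSE]
        N <- solve(rbind(1, t(Y)))                 # 4 x 4
        s <- dOdb %*% N[, 2:4, drop = FALSE]       # |vv| x 3
        gVox[idx, ] <- gVox[idx, ] - crossprod(b, s)
      }
    }
  }
  if (!wantGrad) return(list(value = val))
  ## chain voxel-coordinate gradient back to world-mm displacements
  Binv <- solve(grid@affine)[1:3, 1:3]
  list(value = val, grad = gVox %*% Binv)
}

#' Optimise the atlas deformation for fixed class posteriors
#'
#' Maximises \code{sum_v sum_c w_vc log prior_vc(theta_a) - penalty(theta_a)}
#' over vertex displacements by nonlinear conjugate gradient
#' (Polak-Ribiere) with backtracking line search.  The step is monotone: the
#' returned displacements never have a lower objective than the input, and
#' the mesh is never folded (folding steps are rejected by the line search).
#'
#' @param mesh an \linkS4class{AtlasMesh}.
#' @param deform starting N x 3 displacements.
#' @param classWeights V x C voxel class posteriors (rows sum to 1).
#' @param grid the \linkS4class{VoxelGrid}.
#' @param max_iter maximum CG iterations.
#' @param tol relative objective improvement tolerance.
#' @return list with \code{deform}, final \code{objective}, and logical
#'   \code{stuck} (TRUE when no admissible uphill step was found).
#' @export
optimiseDeformation <- function(mesh, deform, classWeights, grid,
                                max_iter = 20, tol = 1e-5) {
  objective <- function(d) {
    pen <- deformationPenalty(mesh, d)
    if (!is.finite(pen)) return(-Inf)
    priorTermAndGrad(mesh, d, grid, classWeights, wantGrad = FALSE)$value - pen
  }
  gradient <- function(d) {
    pg <- priorTermAndGrad(mesh, d, grid, classWeights)
    pg$grad - deformationPenaltyGrad(mesh, d)
  }
  cur <- deform
  f0 <- objective(cur)
  if (!is.finite(f0)) stop("starting deformation is folded")
  g <- gradient(cur)
  dir <- g
  gPrev <- g
  stuck <- FALSE
  step0 <- 0.5 / max(sqrt(sum(g^2)) / sqrt(length(g)), 1e-12)
  step0 <- min(step0, min(voxelSize(grid)))
  for (it in seq_len(max_iter)) {
    gd <- sum(g * dir)
    if (gd <= 0) { dir <- g; gd <- sum(g * g) }
    if (sqrt(gd) < 1e-12) break
    step <- step0
    accepted <- FALSE
    for (ls in 1:25) {
      cand <- cur + step * dir
      fc <- objective(cand)
      if (is.finite(fc) && fc > f0 + 1e-10 * abs(f0)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      if (it == 1) stuck <- TRUE
      break
    }
    rel <- (fc - f0) / max(abs(f0), 1)
    cur <- cand
    f0 <- fc
    gPrev <- g
    g <- gradient(cur)
    beta <- max(0, sum(g * (g - gPrev)) / max(sum(gPrev * gPrev), 1e-300))
    dir <- g + beta * dir
    if (rel < tol) break
  }
  list(deform = cur, objective = f0, stuck = stuck)
}

#' Place the atlas by moment-matching against a coarse segmentation
#'
#' Computes an axis-aligned affine (per-axis scale and translation) that
#' maps the atlas's foreground prior mass onto the coarse initial
#' segmentation's foreground: centres of mass are matched exactly and
#' per-axis standard deviations set the scales.  Used to initialise the
#' deformation when the atlas is not already in subject space.
#'
#' @param mesh an \linkS4class{AtlasMesh}.
#' @param coarse integer vector of initial labels on \code{grid} (0 =
#'   background).
#' @param grid the subject \linkS4class{VoxelGrid}.
#' @param background index of the atlas background class.
#' @return the mesh with an updated \code{affineToSubject}.
#' @export
alignAtlasToCoarse <- function(mesh, coarse, grid, background = 1L) {
  fg <- which(coarse != 0L)
  if (length(fg) < 8) stop("coarse segmentation has too few foreground voxels")
  cen <- voxelCenters(grid)[fg, , drop = FALSE]
  mu_t <- colMeans(cen)
  sd_t <- apply(cen, 2, sd)
  w <- rowSums(mesh@probs[, -background, drop = FALSE])
  verts <- cbind(mesh@vertices, 1) %*% t(mesh@affineToSubject)
  verts <- verts[, 1:3, drop = FALSE]
  mu_a <- colSums(verts * w) / sum(w)
  sd_a <- sqrt(colSums(sweep(verts, 2, mu_a)^2 * w) / sum(w))
  sc <- sd_t / pmax(sd_a, 1e-9)
  A <- diag(c(sc, 1))
  A[1:3, 4] <- mu_t - sc * mu_a
  mesh@affineToSubject <- A %*% mesh@affineToSubject
  mesh
}
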