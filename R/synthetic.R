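## Generative phantoms.  The simulator draws labels from a rasterised atlas
## prior, intensities from per-class Gaussians and tensors from the
## per-class diffusion family -- i.e. exactly the forward model the
## segmentation engine inverts -- so every module is testable without any
## external data.

#' Build a box-shaped tetrahedral atlas covering a grid
#'
#' Vertices on a regular lattice (in voxel coordinates, mapped through the
#' grid affine) spanning the grid with a one-voxel margin; each lattice cube
#' is split into six tetrahedra sharing its main diagonal, which tile the
#' cube exactly.  Vertex class probabilities default to isotropic Gaussian
#' blobs (one per non-background class) over a uniform background floor, or
#' may be supplied as an arbitrary function of world coordinates.
#'
#' @param grid the target \linkS4class{VoxelGrid}.
#' @param centers K x 3 matrix of blob centres in world mm, one row per
#'   non-background class.
#' @param width blob standard deviation(s) in mm (recycled over classes).
#' @param spacing lattice spacing in voxels (default 4).
#' @param stiffness mesh stiffness.
#' @param background_floor unnormalised background mass everywhere.
#' @param probFun optional function(xyz Nx3 world mm) -> N x C probability
#'   matrix (rows must sum to 1); overrides the blob construction.  Class 1
#'   is the background class.
#' @param classNames optional class names (first is background).
#' @return an \linkS4class{AtlasMesh} whose deformed placement is the
#'   identity (the mesh is built directly in subject space).
#' @export
makeBoxAtlas <- function(grid, centers = NULL, width = 8, spacing = 4,
                         stiffness = 1, background_floor = 0.2,
                         probFun = NULL, classNames = NULL) {
  d <- grid@dim
  if (any(d < 4L)) stop("grid must be at least 4 voxels per axis")
  ax <- lapply(1:3, function(k) {
    nk <- max(3L, ceiling((d[k] + 2) / spacing) + 1L)
    seq(-1, d[k], length.out = nk)
  })
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  world <- cbind(vox, 1) %*% t(grid@affine)
  world <- world[, 1:3, drop = FALSE]
  vid <- function(i, j, k) i + nx * ((j - 1) + ny * (k - 1))
  ## six-tetrahedra (Kuhn) split of each lattice cube
  corner <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1),
                  c(0,1,0), c(0,1,1), c(0,0,1), c(1,0,1))
  kuhn <- rbind(c(1,2,3,4), c(1,3,5,4), c(1,5,6,4),
                c(1,6,7,4), c(1,7,8,4), c(1,8,2,4))
  tets <- vector("list", (nx - 1) * (ny - 1) * (nz - 1))
  n <- 0L
  for (k in seq_len(nz - 1)) for (j in seq_len(ny - 1))
    for (i in seq_len(nx - 1)) {
      cid <- vid(i + corner[, 1], j + corner[, 2], k + corner[, 3])
      n <- n + 1L
      tets[[n]] <- matrix(cid[t(kuhn)], ncol = 4, byrow = TRUE)
    }
  tets <- do.call(rbind, tets)
  if (is.null(probFun)) {
    if (is.null(centers)) stop("supply centers or probFun")
    centers <- rbind(centers)
    width <- rep_len(width, nrow(centers))
    probFun <- function(xyz) {
      u <- vapply(seq_len(nrow(centers)), function(c.) {
        d2 <- rowSums(sweep(xyz, 2, centers[c., ])^2)
        exp(-d2 / (2 * width[c.]^2))
      }, numeric(nrow(xyz)))
      u <- cbind(background_floor, u)
      u / rowSums(u)
    }
  }
  probs <- probFun(world)
  probs <- probs / rowSums(probs)
  if (is.null(classNames))
    classNames <- c("background", paste0("class", seq_len(ncol(probs) - 1L)))
  atlasMesh(world, tets, probs, classNames = classNames,
            stiffness = stiffness)
}

#' Sample axes from the Watson (DSW) axial distribution
#'
#' Rejection sampling from the uniform sphere with envelope
#' \code{exp(kappa * t^2)}; the acceptance rate decays like
#' \code{1/(2*kappa)}, so batches are sized accordingly and a hard guard
#' errors out rather than looping forever.
#'
#' @param n number of samples.
#' @param psi mean axis (unit vector).
#' @param kappa concentration, scalar or length-n (per-sample effective
#'   concentrations).
#' @param max_batches guard on rejection rounds.
#' @return n x 3 matrix of unit axes.
#' @export
rWatson <- function(n, psi, kappa, max_batches = 2000) {
  psi <- psi / sqrt(sum(psi^2))
  kappa <- rep_len(kappa, n)
  out <- matrix(NA_real_, n, 3)
  todo <- seq_len(n)
  for (b in seq_len(max_batches)) {
    m <- length(todo)
    ## batch size scaled by the worst acceptance rate in the queue
    reps <- min(max(2, ceiling(2 * max(kappa[todo]) + 2)), 500)
    z <- matrix(rnorm(3 * m * reps), ncol = 3)
    z <- z / sqrt(rowSums(z^2))
    kk <- rep(kappa[todo], each = reps)
    t2 <- drop(z %*% psi)^2
    acc <- runif(m * reps) < exp(kk * (t2 - 1))
    if (any(acc)) {
      src <- rep(todo, each = reps)
      ## first accepted draw per pending sample
      firsts <- tapply(which(acc), src[acc], min)
      got <- as.integer(names(firsts))
      out[got, ] <- z[as.integer(firsts), , drop = FALSE]
      todo <- setdiff(todo, got)
    }
    if (!length(todo)) break
  }
  if (length(todo)) stop("Watson rejection sampler failed to converge")
  out
}

#' Phantom specification
#'
#' Bundles the study conditions for a generative phantom: grid, per-class
#' structural and diffusion parameters, diffusion family and seed.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param structParams list of \linkS4class{GaussianParams}, one per class.
#' @param diffParams list of diffusion parameters, one per class, all of
#'   \code{family}.
#' @param family \code{"dswbeta"}, \code{"wishart"} or \code{"loggauss"}.
#' @param seed integer RNG seed: sampling is deterministic given the spec.
#' @param mean_diffusivity mm^2/s scale used to reconstruct axially
#'   symmetric tensors for the DSW-beta family (typical parenchyma value).
#' @return a list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(grid, structParams, diffParams,
                        family = c("dswbeta", "wishart", "loggauss"),
                        seed = 1L, mean_diffusivity = 0.7e-3) {
  family <- match.arg(family)
  structure(list(grid = grid, structParams = structParams,
                 diffParams = diffParams, family = family,
                 seed = as.integer(seed),
                 mean_diffusivity = mean_diffusivity),
            class = "PhantomSpec")
}

## axially symmetric tensor with given FA (about axis phi) and fixed MD
axialTensor6 <- function(fa, phi, md) {
  fa <- pmin(fa, 0.995)
  delta <- fa / sqrt(3 - 2 * fa^2)
  lpar <- md * (1 + 2 * delta)
  lperp <- md * (1 - delta)
  t6 <- cbind(lperp + (lpar - lperp) * phi[, 1]^2,
              lperp + (lpar - lperp) * phi[, 2]^2,
              lperp + (lpar - lperp) * phi[, 3]^2,
              (lpar - lperp) * phi[, 1] * phi[, 2],
              (lpar - lperp) * phi[, 1] * phi[, 3],
              (lpar - lperp) * phi[, 2] * phi[, 3])
  t6
}

#' Sample a phantom from the generative model
#'
#' Labels are drawn voxelwise from the rasterised atlas prior, intensities
#' from each class's Gaussian, and tensors from each class's diffusion
#' model: Wishart draws are inverted to tensors, log-Gaussian draws
#' exponentiated, and DSW-beta draws reconstructed as axially symmetric SPD
#' tensors whose FA equals the sampled Beta value and whose axis is the
#' sampled Watson direction (effective concentration kappa * FA).
#'
#' @param mesh an \linkS4class{AtlasMesh} (e.g. \code{\link{makeBoxAtlas}}).
#' @param spec a \code{\link{phantomSpec}}.
#' @param deform optional true deformation applied before rasterising.
#' @return list with \code{labels} (integer V), \code{structural} (V x S),
#'   \code{tensors} (a \linkS4class{TensorField}), \code{prior} (the
#'   \linkS4class{ClassPriorField} sampled from), and \code{spec}.
#' @export
samplePhantom <- function(mesh, spec, deform = NULL) {
  set.seed(spec$seed)
  grid <- spec$grid
  if (is.null(deform)) deform <- zeroDeformation(mesh)
  prior <- rasterisePriors(mesh, deform, grid)
  P <- prior@priors
  V <- nrow(P)
  C <- ncol(P)
  u <- runif(V)
  cum <- t(apply(P, 1, cumsum))
  labels <- 1L + rowSums(cum < u)
  labels[labels > C] <- C
  S <- length(spec$structParams[[1]]@mean)
  structural <- matrix(NA_real_, V, S)
  t6 <- matrix(NA_real_, V, 6)
  for (c. in seq_len(C)) {
    vv <- which(labels == c.)
    if (!length(vv)) next
    gp <- spec$structParams[[c.]]
    ch <- chol(gp@cov)
    structural[vv, ] <- matrix(rnorm(length(vv) * S), ncol = S) %*% ch +
      matrix(gp@mean, length(vv), S, byrow = TRUE)
    dp <- spec$diffParams[[c.]]
    t6[vv, ] <- switch(spec$family,
      wishart = {
        dr <- rWishart(length(vv), dp@dof, dp@scale)
        t(apply(dr, 3, function(m) matToSym6(solve(m))))
      },
      loggauss = {
        dv <- matrix(rnorm(length(vv) * 6, sd = sqrt(dp@var)), ncol = 6) +
          matrix(dp@mean, length(vv), 6, byrow = TRUE)
        t(apply(dv, 1, function(d) matToSym6(tensorFromLogvec(d))))
      },
      dswbeta = {
        f <- rbeta(length(vv), dp@shape1, dp@shape2)
        phi <- rWatson(length(vv), dp@meanDir, dp@kappa * f)
        axialTensor6(f, phi, spec$mean_diffusivity)
      })
  }
  tf <- new("TensorField", grid = grid, tensors = t6,
            valid = rep(TRUE, V))
  list(labels = labels, structural = structural, tensors = tf,
       prior = prior, spec = spec)
}

#' Downsample a tensor field by log-domain block averaging
#'
#' Averages the log-Euclidean 6-vectors over \code{factor^3} blocks and
#' exponentiates back, yielding a field on a coarser grid with aligned voxel
#' centres -- useful for resolution-mismatch experiments with a known ratio
#' of source to target voxel counts.
#'
#' @param field a \linkS4class{TensorField} (all voxels valid).
#' @param factor integer >= 1 downsampling factor per axis.
#' @return a \linkS4class{TensorField} on the coarser grid.
#' @export
degradeResolution <- function(field, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(field)
  d <- field@grid@dim
  if (any(d %% factor != 0L)) {
    warning("grid not divisible by factor; cropping")
    d <- (d %/% factor) * factor
  }
  dn <- d %/% factor
  lv <- logTensorField(field)@logvecs
  idx3 <- voxelIndexGrid(field@grid)
  keep <- idx3[, 1] < d[1] & idx3[, 2] < d[2] & idx3[, 3] < d[3]
  blk <- 1L + (idx3[keep, 1] %/% factor) +
    dn[1] * ((idx3[keep, 2] %/% factor) + dn[2] * (idx3[keep, 3] %/% factor))
  ## rowsum orders rows by numeric group value, i.e. block linear index
  acc <- rowsum(lv[keep, , drop = FALSE], blk)
  cnt <- as.vector(rowsum(rep(1, sum(keep)), blk))
  mean_lv <- acc / cnt
  newAff <- field@grid@affine
  newAff[1:3, 1:3] <- newAff[1:3, 1:3] * factor
  ## shift origin so coarse voxel 0 is centred on its source block
  newAff[1:3, 4] <- newAff[1:3, 4] +
    field@grid@affine[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  ngrid <- new("VoxelGrid", dim = dn, affine = newAff)
  t6 <- tensorsFromLogvecs(mean_lv)
  new("TensorField", grid = ngrid, tensors = t6,
      valid = rep(TRUE, nrow(t6)))
}

#' Canonical demonstration phantom
#'
#' A three-class study condition (background plus a left and a right
#' structure with mirrored fibre orientations) used by the command-line
#' \code{phantom} subcommand, the examples and the test-suite: structural
#' contrast 20 vs 80 intensity units (sd 5), DSW-beta FA ~ Beta(10,3) at
#' concentration 40 about mirrored axes (background Beta(2,8), kappa 5),
#' Wishart dof 15 (background 8) and log-Gaussian variance 0.05 analogues
#' with matched mean tensors.
#'
#' @param size cubic grid edge length in voxels.
#' @param family diffusion family.
#' @param seed RNG seed.
#' @param overlap if TRUE, the two structures' priors overlap heavily so
#'   that only diffusion separates them (the ablation condition).
#' @return list with \code{mesh}, \code{phantom} (from
#'   \code{\link{samplePhantom}}), \code{truth} (output-label ids),
#'   \code{coarse} (initial whole-structure labels), \code{spec} (the
#'   \linkS4class{MixtureSpec}) and \code{specYaml} (its YAML text).
#' @export
demoPhantom <- function(size = 16L, family = "dswbeta", seed = 1L,
                        overlap = FALSE) {
  g <- voxelGrid(rep(as.integer(size), 3))
  ctr <- (size - 1) / 2
  ## overlap: coincident priors, so the two structures differ in nothing
  ## but their diffusion signature
  off <- if (overlap) 0 else size * 0.2
  mesh <- makeBoxAtlas(g,
    centers = rbind(c(ctr - off, ctr, ctr), c(ctr + off, ctr, ctr)),
    width = size * 0.22, spacing = 4,
    classNames = c("background", "left", "right"))
  stp <- list(new("GaussianParams", mean = 20, cov = matrix(25, 1, 1)),
              new("GaussianParams", mean = 80, cov = matrix(25, 1, 1)),
              new("GaussianParams", mean = 80, cov = matrix(25, 1, 1)))
  md <- 0.7e-3
  dfp <- switch(family,
    ## contralateral axes are mirror images through the sagittal midplane
    dswbeta = list(dswBetaParams(2, 8, c(1, 0, 0), 5),
                   dswBetaParams(10, 3, c(0.6, 0.8, 0), 40),
                   dswBetaParams(10, 3, c(-0.6, 0.8, 0), 40)),
    wishart = list(wishartParams(8, diag(3) / md / 8),
                   wishartParams(15, diag(c(3, 0.6, 0.6)) / md / 15),
                   wishartParams(15, diag(c(0.6, 3, 0.6)) / md / 15)),
    loggauss = list(
      logGaussianParams(logTensorVectorize(diag(3) * md), 0.05),
      logGaussianParams(logTensorVectorize(diag(c(2, 0.3, 0.3)) * md), 0.05),
      logGaussianParams(logTensorVectorize(diag(c(0.3, 2, 0.3)) * md), 0.05)))
  psp <- phantomSpec(g, stp, dfp, family = family, seed = seed)
  ph <- samplePhantom(mesh, psp)
  spec <- mixtureSpec(c("background", "left", "right"),
    sSupport = rbind(c(1, 0), c(0, 1), c(0, 1)),
    dSupport = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    dFamily = family,
    pairs = if (family == "dswbeta") matrix(c(2L, 3L), 1) else NULL,
    mergeMap = c(0L, 1L, 2L))
  truth <- c(0L, 1L, 2L)[ph$labels]
  specYaml <- c(
    "classes: [background, left, right]",
    "structural_components: 2",
    "diffusion_components: 3",
    paste0("family: ", family),
    "assignments:",
    "  background: {structural: [1], diffusion: [1]}",
    "  left: {structural: [2], diffusion: [2]}",
    "  right: {structural: [2], diffusion: [3]}",
    if (family == "dswbeta") c("pairs:", "  - [2, 3]") else NULL,
    "merge_map: [0, 1, 2]")
  list(mesh = mesh, phantom = ph, truth = truth, coarse = truth,
       spec = spec, specYaml = specYaml)
}
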