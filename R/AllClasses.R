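#' @import methods
#' @importFrom stats dbeta kmeans mad median optim optimize quantile rbeta
#'   rWishart rgamma rnorm runif setNames var weighted.mean
#' @importFrom utils head tail write.table read.table modifyList
NULL

## ---------------------------------------------------------------------------
## Voxel grids
## ---------------------------------------------------------------------------

#' Voxel grid geometry
#'
#' A \code{VoxelGrid} couples array dimensions with a 4x4 voxel-to-world
#' affine (RAS millimetres, 0-based voxel indices).  All spatial quantities in
#' the package (kernel widths, Hausdorff distances, volumes) are expressed in
#' world millimetres through this affine.
#'
#' @slot dim integer(3), array dimensions.
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @export
setClass("VoxelGrid",
  representation(dim = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 1L))
      msg <- c(msg, "dim must be 3 positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    else {
      if (abs(det(object@affine)) < 1e-12)
        msg <- c(msg, "affine must be invertible")
      if (any(abs(object@affine[4, ] - c(0, 0, 0, 1)) > 1e-9))
        msg <- c(msg, "affine last row must be (0,0,0,1)")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a voxel grid
#'
#' @param dim integer(3) array dimensions.
#' @param voxel_size numeric(3) voxel edge lengths in mm (used when
#'   \code{affine} is missing; an axis-aligned RAS affine is built).
#' @param origin world coordinates of voxel (0,0,0).
#' @param affine optional explicit 4x4 voxel-to-world affine.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- voxelGrid(c(10L, 10L, 10L), voxel_size = c(1, 1, 1))
#' voxelVolume(g)
#' @export
voxelGrid <- function(dim, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                      affine = NULL) {
  dim <- as.integer(dim)
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  new("VoxelGrid", dim = dim, affine = affine)
}

#' @describeIn voxelGrid voxel edge lengths (mm), the column norms of the
#'   affine's linear part.
#' @param grid a \code{VoxelGrid}.
#' @export
voxelSize <- function(grid) sqrt(colSums(grid@affine[1:3, 1:3]^2))

#' @describeIn voxelGrid volume of one voxel in mm^3.
#' @export
voxelVolume <- function(grid) abs(det(grid@affine[1:3, 1:3]))

#' @describeIn voxelGrid number of voxels.
#' @export
nVoxels <- function(grid) prod(grid@dim)

#' @describeIn voxelGrid grid dimensions.
#' @export
gridDim <- function(grid) grid@dim

#' @describeIn voxelGrid 4x4 voxel-to-world affine.
#' @export
gridAffine <- function(grid) grid@affine

## 0-based voxel index matrix for all voxels, x fastest (R array order)
voxelIndexGrid <- function(grid) {
  d <- grid@dim
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' World coordinates of all voxel centres
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return numeric matrix, \code{nVoxels(grid)} x 3, world mm.
#' @export
voxelCenters <- function(grid) {
  ijk <- voxelIndexGrid(grid)
  xyz <- cbind(ijk, 1) %*% t(grid@affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world coordinates to continuous 0-based voxel coordinates
#' @param grid a \linkS4class{VoxelGrid}.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
worldToVoxel <- function(grid, xyz) {
  v <- cbind(xyz, 1) %*% t(solve(grid@affine))
  v[, 1:3, drop = FALSE]
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dim, collapse = " x "),
      "voxels,", paste(signif(voxelSize(object), 4), collapse = " x "),
      "mm\n")
})

sameGrid <- function(a, b, tol = 1e-6) {
  all(a@dim == b@dim) && max(abs(a@affine - b@affine)) < tol
}

## ---------------------------------------------------------------------------
## Tensor fields
## ---------------------------------------------------------------------------

#' Diffusion tensor field
#'
#' Per-voxel symmetric 3x3 diffusion tensors (mm^2/s), stored as an
#' \code{nVoxels x 6} matrix of unique elements in diagonal-first order
#' \code{(xx, yy, zz, xy, xz, yz)}, plus a validity mask.  A voxel is valid
#' when its tensor is symmetric positive definite (so its fractional
#' anisotropy automatically lies in [0,1]).
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot tensors numeric V x 6 matrix of unique tensor elements.
#' @slot valid logical V vector.
#' @export
setClass("TensorField",
  representation(grid = "VoxelGrid", tensors = "matrix", valid = "logical"),
  validity = function(object) {
    v <- nVoxels(object@grid)
    if (nrow(object@tensors) != v || ncol(object@tensors) != 6L)
      return("tensors must be nVoxels x 6")
    if (length(object@valid) != v) return("valid mask length mismatch")
    TRUE
  })

#' Log-Euclidean tensor field
#'
#' Per-voxel 6-vectors \code{d_v} such that Euclidean distance between vectors
#' equals Frobenius distance between matrix logarithms of the tensors
#' (see \code{\link{logTensorVectorize}}).
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot logvecs numeric V x 6 matrix.
#' @slot valid logical V vector.
#' @export
setClass("LogTensorField",
  representation(grid = "VoxelGrid", logvecs = "matrix", valid = "logical"),
  validity = function(object) {
    v <- nVoxels(object@grid)
    if (nrow(object@logvecs) != v || ncol(object@logvecs) != 6L)
      return("logvecs must be nVoxels x 6")
    if (length(object@valid) != v) return("valid mask length mismatch")
    TRUE
  })

#' Scalar DTI summaries: FA and principal direction
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot fa numeric V, fractional anisotropy in [0,1].
#' @slot pdir numeric V x 3, unit principal eigenvectors (antipodal sign
#'   fixed so the first nonzero component is positive).
#' @slot valid logical V.
#' @export
setClass("DTISummaryField",
  representation(grid = "VoxelGrid", fa = "numeric", pdir = "matrix",
                 valid = "logical"),
  validity = function(object) {
    v <- nVoxels(object@grid)
    if (length(object@fa) != v) return("fa length mismatch")
    if (nrow(object@pdir) != v || ncol(object@pdir) != 3L)
      return("pdir must be nVoxels x 3")
    ok <- object@valid & is.finite(object@fa)
    if (any(object@fa[ok] < -1e-9 | object@fa[ok] > 1 + 1e-9))
      return("fa outside [0,1]")
    TRUE
  })

#' @rdname TensorField-class
#' @param x a field object.
#' @export
fieldGrid <- function(x) x@grid

#' @rdname TensorField-class
#' @export
validMask <- function(x) x@valid

#' @rdname TensorField-class
#' @export
tensorData <- function(x) x@tensors

#' @rdname LogTensorField-class
#' @param x a \code{LogTensorField}.
#' @export
logvecData <- function(x) x@logvecs

setMethod("show", "TensorField", function(object) {
  cat("TensorField on", paste(object@grid@dim, collapse = "x"), "grid;",
      sum(object@valid), "/", length(object@valid), "valid voxels\n")
})
setMethod("show", "LogTensorField", function(object) {
  cat("LogTensorField on", paste(object@grid@dim, collapse = "x"), "grid;",
      sum(object@valid), "valid voxels\n")
})
setMethod("show", "DTISummaryField", function(object) {
  cat("DTISummaryField on", paste(object@grid@dim, collapse = "x"),
      "grid; median FA", signif(median(object@fa[object@valid]), 3), "\n")
})

## ---------------------------------------------------------------------------
## Atlas
## ---------------------------------------------------------------------------

#' Deformable tetrahedral probabilistic atlas mesh
#'
#' Each vertex carries a vector of class probabilities; barycentric
#' interpolation inside each tetrahedron yields voxel-wise priors.  Vertex
#' displacements deform the atlas into subject space under a
#' topology-preserving penalty scaled by the mesh stiffness.
#'
#' @slot vertices N x 3 reference vertex positions (atlas mm).
#' @slot tetrahedra M x 4 integer matrix of 1-based vertex indices, each with
#'   positive signed volume in the reference configuration.
#' @slot probs N x C per-vertex class probabilities (rows sum to 1).
#' @slot classNames character C.
#' @slot stiffness positive scalar, deformation penalty scale.
#' @slot affineToSubject 4x4 matrix placing the reference mesh in subject
#'   world coordinates.
#' @export
setClass("AtlasMesh",
  representation(vertices = "matrix", tetrahedra = "matrix", probs = "matrix",
                 classNames = "character", stiffness = "numeric",
                 affineToSubject = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@vertices)
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be N x 3")
    if (ncol(object@tetrahedra) != 4L)
      msg <- c(msg, "tetrahedra must be M x 4")
    if (max(object@tetrahedra) > n || min(object@tetrahedra) < 1)
      msg <- c(msg, "tetrahedron vertex index out of range")
    if (nrow(object@probs) != n)
      msg <- c(msg, "probs must have one row per vertex")
    if (length(object@classNames) != ncol(object@probs))
      msg <- c(msg, "classNames length must match probs columns")
    if (any(object@probs < -1e-12))
      msg <- c(msg, "probs must be non-negative")
    if (max(abs(rowSums(object@probs) - 1)) > 1e-9)
      msg <- c(msg, "probs rows must sum to 1")
    if (length(object@stiffness) != 1L || object@stiffness <= 0)
      msg <- c(msg, "stiffness must be a positive scalar")
    vols <- tetVolumes(object@vertices, object@tetrahedra)
    if (any(vols <= 0))
      msg <- c(msg, "all tetrahedra must have positive signed volume")
    if (length(msg)) msg else TRUE
  })

#' @rdname AtlasMesh-class
#' @param mesh an \code{AtlasMesh}.
#' @export
atlasClassNames <- function(mesh) mesh@classNames

#' @rdname AtlasMesh-class
#' @export
atlasVertices <- function(mesh) mesh@vertices

#' @rdname AtlasMesh-class
#' @export
atlasProbs <- function(mesh) mesh@probs

setMethod("show", "AtlasMesh", function(object) {
  cat("AtlasMesh:", nrow(object@vertices), "vertices,",
      nrow(object@tetrahedra), "tetrahedra,",
      ncol(object@probs), "classes (",
      paste(head(object@classNames, 5), collapse = ", "),
      if (length(object@classNames) > 5) ", ..." else "", ")\n", sep = " ")
})

#' Voxel-wise class prior probabilities
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot priors V x C matrix, rows summing to 1.
#' @slot classNames character C.
#' @export
setClass("ClassPriorField",
  representation(grid = "VoxelGrid", priors = "matrix",
                 classNames = "character"),
  validity = function(object) {
    if (nrow(object@priors) != nVoxels(object@grid))
      return("priors must have one row per voxel")
    if (any(object@priors < -1e-12)) return("priors must be non-negative")
    if (max(abs(rowSums(object@priors) - 1)) > 1e-8)
      return("prior rows must sum to 1")
    TRUE
  })

#' @rdname ClassPriorField-class
#' @param x a \code{ClassPriorField}.
#' @export
priorData <- function(x) x@priors

setMethod("show", "ClassPriorField", function(object) {
  cat("ClassPriorField on", paste(object@grid@dim, collapse = "x"),
      "grid,", ncol(object@priors), "classes\n")
})

## ---------------------------------------------------------------------------
## Likelihood component parameters
## ---------------------------------------------------------------------------

#' Multivariate Gaussian structural component
#' @slot mean numeric S.
#' @slot cov S x S symmetric positive-definite matrix.
#' @export
setClass("GaussianParams",
  representation(mean = "numeric", cov = "matrix"),
  validity = function(object) {
    s <- length(object@mean)
    if (!all(dim(object@cov) == c(s, s))) return("cov dimension mismatch")
    ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return("cov must be positive definite")
    TRUE
  })

#' Normal-Inverse-Wishart hyperparameters for a Gaussian component
#'
#' With \code{Psi} and \code{nu} set to zero (the default here) the prior on
#' the covariance is non-informative and only the mean is shrunk towards the
#' hypermean with strength \code{n}.
#' @slot M numeric S hypermean.
#' @slot n non-negative scalar strength.
#' @slot Psi S x S positive semi-definite scale.
#' @slot nu scalar degrees of freedom.
#' @export
setClass("NIWHyper",
  representation(M = "numeric", n = "numeric", Psi = "matrix", nu = "numeric"),
  validity = function(object) {
    if (object@n < 0) return("n must be >= 0")
    TRUE
  })

#' Wishart diffusion component (on the inverse tensor)
#' @slot dof scalar > 2 degrees of freedom.
#' @slot scale 3 x 3 SPD scale matrix.
#' @slot gammaHyper numeric(2), (shape, rate) of the Gamma prior on (dof-2)/2.
#' @export
setClass("WishartParams",
  representation(dof = "numeric", scale = "matrix", gammaHyper = "numeric"),
  validity = function(object) {
    if (object@dof <= 2) return("dof must be > 2")
    ev <- eigen(object@scale, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return("scale must be SPD")
    TRUE
  })

#' Isotropic Gaussian on log-Euclidean tensor vectors
#' @slot mean numeric 6.
#' @slot var positive scalar variance.
#' @export
setClass("LogGaussianParams",
  representation(mean = "numeric", var = "numeric"),
  validity = function(object) {
    if (length(object@mean) != 6L) return("mean must be length 6")
    if (object@var <= 0) return("var must be > 0")
    TRUE
  })

#' Joint Beta / Dimroth-Scheidegger-Watson diffusion component
#'
#' FA follows Beta(shape1, shape2); the principal direction follows a Watson
#' axial distribution around \code{meanDir} with effective concentration
#' \code{kappa * FA} at each voxel.
#' @slot shape1,shape2 positive Beta parameters.
#' @slot meanDir unit 3-vector mean axis.
#' @slot kappa non-negative concentration.
#' @export
setClass("DSWBetaParams",
  representation(shape1 = "numeric", shape2 = "numeric", meanDir = "numeric",
                 kappa = "numeric"),
  validity = function(object) {
    if (object@shape1 <= 0 || object@shape2 <= 0)
      return("Beta shapes must be > 0")
    if (abs(sqrt(sum(object@meanDir^2)) - 1) > 1e-8)
      return("meanDir must be a unit vector")
    if (object@kappa < 0) return("kappa must be >= 0")
    TRUE
  })

setMethod("show", "GaussianParams", function(object) {
  cat("GaussianParams: mean", paste(signif(object@mean, 4), collapse = ", "),
      "\n")
})
setMethod("show", "WishartParams", function(object) {
  cat("WishartParams: dof", signif(object@dof, 4), "\n")
})
setMethod("show", "LogGaussianParams", function(object) {
  cat("LogGaussianParams: var", signif(object@var, 4), "\n")
})
setMethod("show", "DSWBetaParams", function(object) {
  cat("DSWBetaParams: Beta(", signif(object@shape1, 4), ",",
      signif(object@shape2, 4), "), kappa", signif(object@kappa, 4), "\n")
})

## ---------------------------------------------------------------------------
## Reflection plane
## ---------------------------------------------------------------------------

#' Reflective-symmetry plane
#'
#' The plane through the origin of centred coordinates with unit normal
#' \code{normal}; its Householder matrix \code{I - 2 r r'} reflects diffusion
#' component parameters between hemispheres.
#' @slot normal unit 3-vector.
#' @export
setClass("ReflectionPlane",
  representation(normal = "numeric"),
  validity = function(object) {
    if (length(object@normal) != 3L) return("normal must be length 3")
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
      return("normal must be a unit vector")
    TRUE
  })

#' @rdname ReflectionPlane-class
#' @param normal a 3-vector (normalised internally).
#' @export
reflectionPlane <- function(normal) {
  new("ReflectionPlane", normal = normal / sqrt(sum(normal^2)))
}

#' @rdname ReflectionPlane-class
#' @param plane a \code{ReflectionPlane}.
#' @return \code{householder}: the 3x3 reflection matrix.
#' @export
householder <- function(plane) {
  r <- plane@normal
  diag(3) - 2 * tcrossprod(r)
}

setMethod("show", "ReflectionPlane", function(object) {
  cat("ReflectionPlane: normal (",
      paste(signif(object@normal, 5), collapse = ", "), ")\n")
})

## ---------------------------------------------------------------------------
## Mixture specification
## ---------------------------------------------------------------------------

#' Mixture-model specification
#'
#' Bookkeeping for the structural mixture model (sMM) and diffusion mixture
#' model (dMM): which structural components i and diffusion components j are
#' allowed for each label class c, the mixture weights, the diffusion family,
#' the contralateral component pairing used by the reflective-symmetry
#' machinery, and the map from model classes to output labels.
#'
#' @slot classNames character C.
#' @slot G,W integer component counts.
#' @slot g C x G structural weights (rows sum to 1 over the support).
#' @slot w C x W diffusion weights.
#' @slot sSupport,dSupport logical support masks, C x G and C x W.
#' @slot dFamily one of \code{"dswbeta"}, \code{"wishart"}, \code{"loggauss"}.
#' @slot pairs P x 2 integer matrix of (left, right) diffusion component
#'   indices fitted jointly under reflection; may have zero rows.
#' @slot mergeMap integer C of output label ids (0 = background).
#' @export
setClass("MixtureSpec",
  representation(classNames = "character", G = "integer", W = "integer",
                 g = "matrix", w = "matrix",
                 sSupport = "matrix", dSupport = "matrix",
                 dFamily = "character", pairs = "matrix",
                 mergeMap = "integer"),
  validity = function(object) {
    msg <- character()
    C <- length(object@classNames)
    if (!all(dim(object@g) == c(C, object@G))) msg <- c(msg, "g must be C x G")
    if (!all(dim(object@w) == c(C, object@W))) msg <- c(msg, "w must be C x W")
    if (!object@dFamily %in% c("dswbeta", "wishart", "loggauss"))
      msg <- c(msg, "unknown diffusion family")
    if (length(object@mergeMap) != C)
      msg <- c(msg, "mergeMap must have one entry per class")
    if (any(rowSums(object@sSupport) < 1))
      msg <- c(msg, paste("class without structural component:",
        paste(object@classNames[rowSums(object@sSupport) < 1], collapse = ", ")))
    if (any(rowSums(object@dSupport) < 1))
      msg <- c(msg, paste("class without diffusion component:",
        paste(object@classNames[rowSums(object@dSupport) < 1], collapse = ", ")))
    if (any(object@g[!object@sSupport] != 0) || any(object@w[!object@dSupport] != 0))
      msg <- c(msg, "weights outside the support must be zero")
    if (max(abs(rowSums(object@g) - 1)) > 1e-8 ||
        max(abs(rowSums(object@w) - 1)) > 1e-8)
      msg <- c(msg, "weight rows must sum to 1")
    if (nrow(object@pairs) > 0) {
      idx <- as.vector(object@pairs)
      if (any(idx < 1 | idx > object@W)) msg <- c(msg, "pair index out of range")
      if (anyDuplicated(idx)) msg <- c(msg, "component in more than one pair")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "MixtureSpec", function(object) {
  cat("MixtureSpec:", length(object@classNames), "classes,",
      object@G, "structural /", object@W, "diffusion (", object@dFamily,
      ") components,", nrow(object@pairs), "symmetric pairs\n")
})

## ---------------------------------------------------------------------------
## Fit state and segmentation output
## ---------------------------------------------------------------------------

#' Full model state during/after fitting
#'
#' @slot deformation N x 3 vertex displacements (mm).
#' @slot structParams list of \linkS4class{GaussianParams}, length G.
#' @slot diffParams list of diffusion component parameters, length W.
#' @slot g,w current mixture weights.
#' @slot plane the \linkS4class{ReflectionPlane} (or NULL normal when
#'   symmetry is off).
#' @slot epsilon diffusion-likelihood tempering exponent in (0, 1].
#' @slot trace numeric objective trace (non-decreasing across GEM cycles).
#' @slot flags named list of diagnostic flags raised while fitting.
#' @export
setClass("FitState",
  representation(deformation = "matrix", structParams = "list",
                 diffParams = "list", g = "matrix", w = "matrix",
                 plane = "ReflectionPlane", epsilon = "numeric",
                 trace = "numeric", flags = "list"))

#' @rdname FitState-class
#' @param state a \code{FitState}.
#' @export
objectiveTrace <- function(state) state@trace

setMethod("show", "FitState", function(object) {
  cat("FitState: epsilon", signif(object@epsilon, 4), ";",
      length(object@trace), "objective evaluations",
      if (length(object@trace))
        paste0("(final ", signif(tail(object@trace, 1), 8), ")"), "\n")
})

#' Segmentation result
#'
#' @slot grid the structural \linkS4class{VoxelGrid}.
#' @slot labels integer vector of MAP output labels per voxel (0 background).
#' @slot posteriors V x L merged posterior probabilities per output label.
#' @slot labelIds integer L output label ids (columns of posteriors).
#' @slot labelNames character L.
#' @slot volumes numeric L posterior-weighted volumes in mm^3.
#' @export
setClass("Segmentation",
  representation(grid = "VoxelGrid", labels = "integer", posteriors = "matrix",
                 labelIds = "integer", labelNames = "character",
                 volumes = "numeric"))

#' @rdname Segmentation-class
#' @param x a \code{Segmentation}.
#' @export
labelMap <- function(x) array(x@labels, dim = x@grid@dim)

#' @rdname Segmentation-class
#' @export
posteriorProbs <- function(x) x@posteriors

#' @rdname Segmentation-class
#' @export
labelVolumes <- function(x) setNames(x@volumes, x@labelNames)

setMethod("show", "Segmentation", function(object) {
  cat("Segmentation on", paste(object@grid@dim, collapse = "x"), "grid,",
      length(object@labelIds), "output labels\n")
  v <- signif(object@volumes, 5)
  cat(paste0("  ", object@labelNames, ": ", v, " mm^3", collapse = "\n"), "\n")
})
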