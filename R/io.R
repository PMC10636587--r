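## File formats: NIfTI volumes (through RNifti), the 6-component symmetric
## tensor dialects, the JSON atlas container with its FreeSurfer-style LUT
## sidecar, YAML mixture-spec configs, TSV outputs and the JSON model dump.

#' @importFrom RNifti readNifti writeNifti xform
NULL

gridFromNifti <- function(img) {
  dm <- dim(img)[1:3]
  aff <- structure(RNifti::xform(img), class = NULL)
  voxelGrid(as.integer(dm), affine = matrix(as.numeric(aff), 4, 4))
}

niftiFromGrid <- function(data, grid) {
  img <- RNifti::asNifti(data)
  ## setting both forms in sequence loses the scale in RNifti; the sform
  ## alone (code 2) is authoritative for xform() on read
  RNifti::sform(img) <- structure(grid@affine, code = 2L)
  img
}

#' Read / write scalar or multi-channel NIfTI volumes
#'
#' @param path file path.
#' @return \code{readNiftiVolume}: list with \code{data} (array) and
#'   \code{grid} (a \linkS4class{VoxelGrid}).
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       grid = gridFromNifti(img))
}

#' @rdname readNiftiVolume
#' @param data array to write (first three dimensions on \code{grid}).
#' @param grid a \linkS4class{VoxelGrid}.
#' @export
writeNiftiVolume <- function(data, grid, path) {
  RNifti::writeNifti(niftiFromGrid(data, grid), path)
  invisible(path)
}

## column orders of the two supported 6-component dialects, mapped to the
## internal (xx, yy, zz, xy, xz, yz) order
tensorOrderMap <- function(order) {
  switch(order,
    ## lower-triangular row order: Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
    lower = c(1L, 3L, 6L, 2L, 4L, 5L),
    ## row-first order: Dxx, Dxy, Dxz, Dyy, Dyz, Dzz
    rowfirst = c(1L, 4L, 6L, 2L, 3L, 5L),
    stop("unknown tensor component order: ", order))
}

#' Read a diffusion-tensor NIfTI (6-component symmetric dialect)
#'
#' Accepts a 4-D volume whose fourth dimension holds the 6 unique tensor
#' elements, in lower-triangular row order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
#' or row-first order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).  With
#' \code{order = "auto"} the dialect is detected by counting which
#' interpretation yields more positive-definite voxels.
#'
#' @param path NIfTI path.
#' @param order \code{"auto"}, \code{"lower"} or \code{"rowfirst"}.
#' @return a \linkS4class{TensorField}.
#' @export
readTensorNifti <- function(path, order = c("auto", "lower", "rowfirst")) {
  order <- match.arg(order)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4 || dm[4] != 6)
    stop("tensor NIfTI must be 4-D with 6 components, got ",
         paste(dm, collapse = "x"))
  grid <- gridFromNifti(img)
  flat <- matrix(as.numeric(img), ncol = 6)
  if (order == "auto") {
    cand <- c(lower = "lower", rowfirst = "rowfirst")
    nspd <- vapply(cand, function(o) {
      t6 <- flat[, tensorOrderMap(o), drop = FALSE]
      idx <- round(seq(1, nrow(t6), length.out = min(200, nrow(t6))))
      sum(tensorsAreSPD(t6[idx, , drop = FALSE]))
    }, numeric(1))
    order <- names(nspd)[which.max(nspd)]
  }
  tensorField(grid, flat[, tensorOrderMap(order), drop = FALSE])
}

#' @rdname readTensorNifti
#' @param field a \linkS4class{TensorField}.
#' @export
writeTensorNifti <- function(field, path, order = c("lower", "rowfirst")) {
  ord <- match.arg(order)
  flat <- field@tensors[, base::order(tensorOrderMap(ord)), drop = FALSE]
  writeNiftiVolume(array(flat, dim = c(field@grid@dim, 6)), field@grid, path)
}

#' Write FA and direction-encoded-colour FA NIfTI volumes
#'
#' @param summary a \linkS4class{DTISummaryField}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFANifti <- function(summary, path) {
  fa <- summary@fa
  fa[!summary@valid] <- 0
  writeNiftiVolume(array(fa, dim = summary@grid@dim), summary@grid, path)
}

#' @rdname writeFANifti
#' @export
writeDecFANifti <- function(summary, path) {
  fa <- ifelse(summary@valid, summary@fa, 0)
  rgb <- abs(summary@pdir) * fa
  rgb[!summary@valid, ] <- 0
  writeNiftiVolume(array(rgb, dim = c(summary@grid@dim, 3)), summary@grid,
                   path)
}

## ---------------------------------------------------------------------------
## Atlas container (JSON) and LUT sidecar
## ---------------------------------------------------------------------------

#' Read / write the atlas container
#'
#' Single-file JSON container with named numeric arrays: \code{vertices}
#' (N x 3), \code{tetrahedra} (M x 4, 0-based), \code{probs} (N x C),
#' \code{class_names}, \code{stiffness} and \code{affine_to_subject}.
#'
#' @param mesh an \linkS4class{AtlasMesh}.
#' @param path file path.
#' @export
writeAtlas <- function(mesh, path) {
  jsonlite::write_json(list(
    vertices = mesh@vertices,
    tetrahedra = mesh@tetrahedra - 1L,
    probs = mesh@probs,
    class_names = mesh@classNames,
    stiffness = mesh@stiffness,
    affine_to_subject = mesh@affineToSubject), path,
    digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAtlas
#' @return \code{readAtlas}: the \linkS4class{AtlasMesh}.
#' @export
readAtlas <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlasMesh(as.matrix(j$vertices), as.matrix(j$tetrahedra) + 1L,
            as.matrix(j$probs), classNames = j$class_names,
            stiffness = j$stiffness,
            affineToSubject = as.matrix(j$affine_to_subject))
}

#' Read / write a FreeSurfer-style lookup table
#'
#' Text sidecar mapping output label integers to names and RGB colours:
#' whitespace-separated columns \code{id name R G B A}, \code{#} comments.
#'
#' @param ids integer label ids.
#' @param names character label names.
#' @param colors optional L x 3 integer RGB matrix.
#' @param path file path.
#' @export
writeLUT <- function(ids, names, path, colors = NULL) {
  if (is.null(colors)) {
    set.seed(7)
    colors <- matrix(sample(0:255, 3 * length(ids), replace = TRUE),
                     ncol = 3)
    colors[1, ] <- 0
  }
  lines <- c("# id name R G B A",
             sprintf("%d %s %d %d %d 0", ids, names,
                     colors[, 1], colors[, 2], colors[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeLUT
#' @return \code{readLUT}: data.frame with id, name, R, G, B.
#' @export
readLUT <- function(path) {
  tb <- read.table(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tb) <- c("id", "name", "R", "G", "B", "A")[seq_len(ncol(tb))]
  tb
}

## ---------------------------------------------------------------------------
## Mixture spec config (YAML)
## ---------------------------------------------------------------------------

#' Read a mixture specification from a YAML config
#'
#' Expected sections: \code{classes} (names), \code{structural_components}
#' and \code{diffusion_components} (counts or names), \code{assignments}
#' (per class: \code{structural} and \code{diffusion} component index
#' lists), \code{family}, optional \code{pairs} (list of two-element
#' left/right index pairs) and \code{merge_map} (per-class output ids).
#'
#' @param path YAML file path.
#' @return a \linkS4class{MixtureSpec}.
#' @export
readMixtureSpecConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cls <- unlist(y$classes)
  C <- length(cls)
  G <- if (is.numeric(y$structural_components)) y$structural_components
       else length(y$structural_components)
  W <- if (is.numeric(y$diffusion_components)) y$diffusion_components
       else length(y$diffusion_components)
  sS <- matrix(FALSE, C, G)
  dS <- matrix(FALSE, C, W)
  for (c. in seq_len(C)) {
    a <- y$assignments[[cls[c.]]]
    if (is.null(a)) stop("no assignment for class ", cls[c.])
    sS[c., unlist(a$structural)] <- TRUE
    dS[c., unlist(a$diffusion)] <- TRUE
  }
  pairs <- if (!is.null(y$pairs))
    do.call(rbind, lapply(y$pairs, unlist)) else NULL
  mergeMap <- if (!is.null(y$merge_map)) unlist(y$merge_map) else NULL
  mixtureSpec(cls, sS, dS, dFamily = y$family, pairs = pairs,
              mergeMap = mergeMap)
}

## ---------------------------------------------------------------------------
## Run outputs
## ---------------------------------------------------------------------------

#' Write posterior-weighted volumes as TSV
#'
#' Columns \code{label_id}, \code{label_name}, \code{volume_mm3},
#' tab-separated, UTF-8.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param path output path.
#' @export
writeVolumesTsv <- function(seg, path) {
  df <- data.frame(label_id = seg@labelIds, label_name = seg@labelNames,
                   volume_mm3 = seg@volumes)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

paramsToList <- function(p) {
  if (is(p, "GaussianParams")) list(family = "gaussian", mean = p@mean,
                                    cov = p@cov)
  else if (is(p, "WishartParams")) list(family = "wishart", dof = p@dof,
                                        scale = p@scale)
  else if (is(p, "LogGaussianParams")) list(family = "loggauss",
                                            mean = p@mean, var = p@var)
  else if (is(p, "DSWBetaParams")) list(family = "dswbeta",
    shape1 = p@shape1, shape2 = p@shape2, meanDir = p@meanDir,
    kappa = p@kappa)
  else stop("unknown parameter object")
}

#' Dump the fitted model state to JSON
#'
#' Serialises all component parameters, mixture weights, the reflection
#' normal, epsilon and the objective trace, so a run is reproducible and
#' auditable from its artefacts.
#'
#' @param state a \linkS4class{FitState}.
#' @param spec the \linkS4class{MixtureSpec}.
#' @param path output path.
#' @export
writeModelDump <- function(state, spec, path) {
  jsonlite::write_json(list(
    family = spec@dFamily,
    class_names = spec@classNames,
    structural = lapply(state@structParams, paramsToList),
    diffusion = lapply(state@diffParams, paramsToList),
    g = state@g, w = state@w,
    reflection_normal = state@plane@normal,
    epsilon = state@epsilon,
    objective_trace = state@trace,
    flags = state@flags), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
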