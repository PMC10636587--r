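## Mixture-model bookkeeping: which structural components (sMM) and
## diffusion components (dMM) may model each label class, initial weights,
## k-means initialisation of component parameters, and merging of model
## classes into output labels.

#' Construct a mixture-model specification
#'
#' Support masks define the allowed class-to-component assignments
#' (many-to-many is allowed, e.g. one component shared between classes, or a
#' class with two components for a bimodal appearance).  Non-zero initial
#' weights are equal across each class's allowed components.
#'
#' @param classNames character C.
#' @param sSupport C x G logical (or 0/1) structural support mask.
#' @param dSupport C x W logical diffusion support mask.
#' @param dFamily \code{"dswbeta"}, \code{"wishart"} or \code{"loggauss"}.
#' @param pairs optional P x 2 matrix of (left, right) diffusion component
#'   indices fitted jointly under reflection.
#' @param mergeMap integer C of output label ids (0 = merged into
#'   background); defaults to \code{0, 1, ..., C-1} with class 1 treated as
#'   background.
#' @return a \linkS4class{MixtureSpec}.
#' @export
mixtureSpec <- function(classNames, sSupport, dSupport,
                        dFamily = c("dswbeta", "wishart", "loggauss"),
                        pairs = NULL, mergeMap = NULL) {
  dFamily <- match.arg(dFamily)
  sSupport <- as.matrix(sSupport) > 0
  dSupport <- as.matrix(dSupport) > 0
  C <- length(classNames)
  if (is.null(mergeMap)) mergeMap <- c(0L, seq_len(C - 1L))
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  g <- sSupport / pmax(rowSums(sSupport), 1)
  w <- dSupport / pmax(rowSums(dSupport), 1)
  new("MixtureSpec", classNames = classNames, G = ncol(sSupport),
      W = ncol(dSupport), g = g, w = w, sSupport = sSupport,
      dSupport = dSupport, dFamily = dFamily,
      pairs = matrix(as.integer(pairs), ncol = 2),
      mergeMap = as.integer(mergeMap))
}

#' Validate a mixture specification
#'
#' Re-runs all invariant checks (support coverage, weight normalisation,
#' pairing uniqueness, total merge map) and returns a diagnostics list;
#' violations raise errors naming the offending class.
#'
#' @param spec a \linkS4class{MixtureSpec}.
#' @return invisibly, a list with per-class component counts and the
#'   pairing summary.
#' @export
validateSpec <- function(spec) {
  v <- validObject(spec)  # errors with the offending message
  if (anyNA(spec@mergeMap))
    stop("unmapped class in mergeMap: ",
         paste(spec@classNames[is.na(spec@mergeMap)], collapse = ", "))
  bad <- abs(rowSums(spec@g) - 1) > 1e-8 | abs(rowSums(spec@w) - 1) > 1e-8
  if (any(bad))
    stop("weight rows not normalised for class: ",
         paste(spec@classNames[bad], collapse = ", "))
  invisible(list(
    n_struct = rowSums(spec@sSupport),
    n_diff = rowSums(spec@dSupport),
    n_pairs = nrow(spec@pairs),
    family = spec@dFamily))
}

#' Seeded k-means initialisation of component parameters
#'
#' Clusters the voxels whose prior mass for the component's class group
#' exceeds a threshold, using a family-appropriate feature space (intensity
#' vectors; log-Euclidean 6-vectors; or sign-fixed principal axes with FA
#' appended for DSW-beta), then fits each component on its cluster with the
#' family fitter.  Deterministic given \code{seed}.
#'
#' @param data family data: V x S intensities for \code{"gaussian"},
#'   otherwise a diffusion statistics list (internal representation from
#'   log-tensor fields).
#' @param priorWeights numeric V voxel weights (e.g. class prior mass).
#' @param K number of components.
#' @param family \code{"gaussian"}, \code{"dswbeta"}, \code{"wishart"} or
#'   \code{"loggauss"}.
#' @param seed integer seed.
#' @param threshold prior-mass threshold for inclusion (default 0.5).
#' @param opts fitter options.
#' @return list of K parameter objects (cluster order is by first feature
#'   mean, for reproducibility).
#' @export
kmeansInit <- function(data, priorWeights, K, family = "gaussian",
                       seed = 1L, threshold = 0.5, opts = list()) {
  stopifnot(K >= 1)
  feats <- switch(family,
    gaussian = as.matrix(data),
    loggauss = data$logvecs,
    wishart = data$logvecs,
    dswbeta = cbind(t(apply(data$pdir, 1, fixSign)) * data$fa, data$fa))
  sel <- which(priorWeights > threshold &
                 rowSums(!is.finite(feats)) == 0)
  if (length(sel) < K)
    sel <- order(priorWeights, decreasing = TRUE)[seq_len(min(
      length(priorWeights), max(K * 10, 50)))]
  sel <- sel[rowSums(!is.finite(feats[sel, , drop = FALSE])) == 0]
  X <- feats[sel, , drop = FALSE]
  if (nrow(unique(X)) < K)
    stop("fewer distinct data points than components")
  if (K == 1L) {
    cl <- rep(1L, nrow(X))
  } else {
    if (!exists(".Random.seed", envir = .GlobalEnv)) set.seed(NULL)
    old <- get(".Random.seed", envir = .GlobalEnv)
    set.seed(seed)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    km <- kmeans(X, centers = K, nstart = 5, iter.max = 50)
    ## impose a reproducible component order
    ord <- order(km$centers[, 1])
    cl <- match(km$cluster, ord)
  }
  lapply(seq_len(K), function(k) {
    wts <- numeric(length(priorWeights))
    wts[sel[cl == k]] <- 1
    if (family == "gaussian")
      fitGaussianMap(as.matrix(data), wts)$params
    else
      fitDiffComponent(data, wts, family, opts)$params
  })
}

#' Merge model-class posteriors into output-label posteriors
#'
#' Output posteriors are sums of member-class posteriors under the merge
#' map; per-voxel normalisation (total posterior mass) is conserved exactly.
#'
#' @param posteriors V x C matrix of per-class posteriors.
#' @param mergeMap integer C of output label ids; every class must be
#'   mapped.
#' @return list with \code{posteriors} (V x L), \code{labelIds} (sorted
#'   unique output ids).
#' @export
mergeOutputs <- function(posteriors, mergeMap) {
  if (anyNA(mergeMap) || length(mergeMap) != ncol(posteriors))
    stop("mergeMap must map every class")
  ids <- sort(unique(mergeMap))
  out <- vapply(ids, function(id)
    rowSums(posteriors[, mergeMap == id, drop = FALSE]),
    numeric(nrow(posteriors)))
  out <- matrix(out, nrow = nrow(posteriors))
  list(posteriors = out, labelIds = as.integer(ids))
}
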