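## Generalised EM engine: E step, generalised M step, coordinate ascent with
## atlas deformation and reflective symmetry, resolution-aware tempering of
## the diffusion likelihood, MAP labelling and posterior-weighted volumes.
##
## The mixture support is enumerated once as a table of (class c, structural
## component i, diffusion component j) tuples; the soft segmentation q is a
## dense V x K matrix over those tuples.  All products are computed in log
## space with per-voxel max subtraction.

## enumerate the allowed (c, i, j) tuples of a MixtureSpec
supportTuples <- function(spec) {
  out <- list()
  n <- 0L
  for (c. in seq_along(spec@classNames)) {
    is <- which(spec@sSupport[c., ])
    js <- which(spec@dSupport[c., ])
    for (i in is) for (j in js) {
      n <- n + 1L
      out[[n]] <- c(c., i, j)
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("c", "i", "j")
  m
}

#' Resolution-aware diffusion likelihood exponent
#'
#' After resampling the diffusion data to the structural grid, more voxels
#' enter the likelihood than were actually measured; tempering the diffusion
#' likelihood by the voxel-volume ratio makes the effective sample size
#' match the source acquisition.  Returns
#' \code{min(1, structural voxel volume / diffusion voxel volume)} unless
#' overridden.
#'
#' @param s_grid structural \linkS4class{VoxelGrid}.
#' @param d_grid diffusion \linkS4class{VoxelGrid}.
#' @param override optional explicit value in (0, 1].
#' @return epsilon in (0, 1].
#' @examples
#' chooseEpsilon(voxelGrid(c(4L,4L,4L), c(1,1,1)),
#'               voxelGrid(c(2L,2L,2L), c(2,2,2)))  # 1/8
#' @export
chooseEpsilon <- function(s_grid, d_grid, override = NULL) {
  if (!is.null(override)) {
    if (override <= 0 || override > 1)
      stop("epsilon override must be in (0, 1]")
    return(override)
  }
  min(1, voxelVolume(s_grid) / voxelVolume(d_grid))
}

## V x G structural log-likelihood matrix
structuralLogLik <- function(structural, structParams) {
  vapply(structParams, function(p) gaussianLogpdf(structural, p),
         numeric(nrow(structural)))
}

## V x W diffusion log-likelihood matrix; invalid voxels contribute 0
## (excluded from the diffusion likelihood, structural-only evidence there)
diffusionLogLik <- function(stats, diffParams, family) {
  V <- length(stats$valid)
  out <- matrix(0, V, length(diffParams))
  ok <- stats$valid
  if (!any(ok)) return(out)
  sub <- lapply(stats, function(x)
    if (is.matrix(x)) x[ok, , drop = FALSE] else x[ok])
  for (j in seq_along(diffParams))
    out[ok, j] <- diffLogpdfStats(sub, diffParams[[j]], family)
  out
}

#' E step: soft segmentation over (class, structural, diffusion) tuples
#'
#' Computes \code{q} proportional to
#' \code{g[c,i] * w[c,j] * prior[v,c] * p(s_v | i) * p(d_v | j)^epsilon},
#' normalised per voxel, in log space.  Voxels where every tuple underflows
#' get a uniform posterior over the support and are flagged.
#'
#' @param logPrior V x C log prior probabilities.
#' @param Ls V x G structural log-likelihoods.
#' @param Ld V x W diffusion log-likelihoods.
#' @param spec the \linkS4class{MixtureSpec}.
#' @param epsilon diffusion tempering exponent.
#' @param tuples optional precomputed \code{supportTuples(spec)}.
#' @return list with \code{q} (V x K), \code{logNorm} (per-voxel log
#'   normaliser, the voxel contributions to the objective), \code{tuples},
#'   and \code{flags}.
#' @export
eStep <- function(logPrior, Ls, Ld, spec, epsilon = 1, tuples = NULL) {
  if (is.null(tuples)) tuples <- supportTuples(spec)
  K <- nrow(tuples)
  V <- nrow(logPrior)
  logq <- matrix(0, V, K)
  for (k in seq_len(K)) {
    c. <- tuples[k, 1]; i <- tuples[k, 2]; j <- tuples[k, 3]
    logq[, k] <- log(spec@g[c., i]) + log(spec@w[c., j]) +
      logPrior[, c.] + Ls[, i] + epsilon * Ld[, j]
  }
  mx <- do.call(pmax, c(as.data.frame(logq), na.rm = FALSE))
  flags <- character()
  dead <- !is.finite(mx)
  if (any(dead)) flags <- "underflow_voxels"
  mxs <- ifelse(dead, 0, mx)
  eq <- exp(logq - mxs)
  eq[dead, ] <- 1
  s <- rowSums(eq)
  list(q = eq / s, logNorm = ifelse(dead, -7e2, mx + log(s)),
       tuples = tuples, flags = flags)
}

## marginal posterior per class (V x C) from a tuple posterior
classPosteriors <- function(q, tuples, C) {
  out <- matrix(0, nrow(q), C)
  for (c. in seq_len(C)) {
    ks <- which(tuples[, 1] == c.)
    if (length(ks)) out[, c.] <- rowSums(q[, ks, drop = FALSE])
  }
  out
}

## log prior-parameter density terms of the objective
paramPriorTerms <- function(structParams, diffParams, hyper, family) {
  val <- 0
  for (i in seq_along(structParams)) {
    h <- hyper[[i]]
    if (!is.null(h) && h@n > 0)
      val <- val + gaussianLogpdf(matrix(structParams[[i]]@mean, 1),
        new("GaussianParams", mean = h@M, cov = structParams[[i]]@cov / h@n))
  }
  if (family == "wishart") {
    for (p in diffParams) {
      gh <- p@gammaHyper
      if (!anyNA(gh))
        val <- val + (gh[1] - 1) * log((p@dof - 2) / 2) -
          gh[2] * (p@dof - 2) / 2
    }
  }
  val
}

#' Model objective (log posterior of the parameters, up to constants)
#'
#' Deformation-penalty and parameter-prior terms plus the voxel sum of
#' \code{log sum_c prior[v,c] * (sum_i g p(s|i)) * (sum_j w p(d|j)^eps)}.
#' Voxels with zero total likelihood are floored at a configurable log
#' minimum and flagged.
#'
#' @param logPrior,Ls,Ld,spec,epsilon,tuples as in \code{\link{eStep}}.
#' @param penalty deformation penalty value (subtracted).
#' @param priorTerms parameter-prior log-density value (added).
#' @return scalar objective.
#' @export
gemObjective <- function(logPrior, Ls, Ld, spec, epsilon = 1,
                         penalty = 0, priorTerms = 0, tuples = NULL) {
  es <- eStep(logPrior, Ls, Ld, spec, epsilon, tuples)
  sum(es$logNorm) - penalty + priorTerms
}

#' Generalised M step
#'
#' Updates each structural component by the NIW-MAP Gaussian fitter on its
#' marginal posterior weights, each diffusion component by its family fitter
#' on epsilon-scaled marginal weights (paired components jointly through the
#' reflection plane), and the mixture weights by their closed-form update.
#' Every component update is safeguarded: if a numerical fitter fails to
#' increase its own bound contribution the previous parameters are kept, so
#' the generalised M step never decreases the bound.
#'
#' @param es E-step result (from \code{\link{eStep}}).
#' @param structural V x S intensity matrix.
#' @param stats diffusion statistics list.
#' @param spec the \linkS4class{MixtureSpec}.
#' @param state list with \code{structParams}, \code{diffParams},
#'   \code{plane}.
#' @param hyper list of G \linkS4class{NIWHyper} (or NULL entries).
#' @param epsilon tempering exponent.
#' @param symmetry logical: fit pairs jointly under the plane.
#' @param opts fitter options.
#' @return updated \code{state} with new \code{g}, \code{w} and
#'   \code{flags}.
#' @export
mStep <- function(es, structural, stats, spec, state, hyper,
                  epsilon = 1, symmetry = nrow(spec@pairs) > 0,
                  opts = list()) {
  q <- es$q
  tuples <- es$tuples
  flags <- character()
  G <- spec@G; W <- spec@W; C <- length(spec@classNames)

  ## structural components
  for (i in seq_len(G)) {
    ks <- which(tuples[, 2] == i)
    wts <- rowSums(q[, ks, drop = FALSE])
    if (sum(wts) <= 1e-12) { flags <- c(flags, "empty_struct_comp"); next }
    fit <- fitGaussianMap(structural, wts, hyper[[i]])
    newQ <- sum(wts * gaussianLogpdf(structural, fit$params))
    oldQ <- sum(wts * gaussianLogpdf(structural, state$structParams[[i]]))
    h <- hyper[[i]]
    if (!is.null(h) && h@n > 0) {
      newQ <- newQ + gaussianLogpdf(matrix(fit$params@mean, 1),
        new("GaussianParams", mean = h@M, cov = fit$params@cov / h@n))
      oldQ <- oldQ + gaussianLogpdf(matrix(state$structParams[[i]]@mean, 1),
        new("GaussianParams", mean = h@M,
            cov = state$structParams[[i]]@cov / h@n))
    }
    if (newQ >= oldQ) state$structParams[[i]] <- fit$params
    flags <- c(flags, fit$flags)
  }

  ## diffusion components: marginal weights, epsilon-scaled, invalid zeroed
  wmat <- matrix(0, nrow(q), W)
  for (j in seq_len(W)) {
    ks <- which(tuples[, 3] == j)
    wmat[, j] <- epsilon * rowSums(q[, ks, drop = FALSE])
  }
  wmat[!stats$valid, ] <- 0
  mstats <- maskInvalid(stats, NULL)
  family <- spec@dFamily

  diffQ <- function(paramsList, j, wts) {
    sum(wts * diffLogpdfStats(mstats, paramsList[[j]], family)) +
      paramPriorTerms(list(), paramsList[j], NULL, family)
  }

  paired <- if (symmetry && nrow(spec@pairs) > 0) spec@pairs else
    matrix(integer(), 0, 2)
  inPair <- as.vector(paired)
  for (p in seq_len(nrow(paired))) {
    jL <- paired[p, 1]; jR <- paired[p, 2]
    if (sum(wmat[, jL]) + sum(wmat[, jR]) <= 1e-12) next
    fit <- fitPairSymmetric(stats, wmat[, jL], wmat[, jR], state$plane,
                            family, opts)
    old <- diffQ(state$diffParams, jL, wmat[, jL]) +
      diffQ(state$diffParams, jR, wmat[, jR])
    cand <- state$diffParams
    cand[[jL]] <- fit$left; cand[[jR]] <- fit$right
    newv <- diffQ(cand, jL, wmat[, jL]) + diffQ(cand, jR, wmat[, jR])
    if (newv >= old) {
      state$diffParams[[jL]] <- fit$left
      state$diffParams[[jR]] <- fit$right
    }
    flags <- c(flags, fit$flags)
  }
  for (j in setdiff(seq_len(W), inPair)) {
    if (sum(wmat[, j]) <= 1e-12) { flags <- c(flags, "empty_diff_comp"); next }
    fit <- fitDiffComponent(mstats, wmat[, j], family, opts)
    old <- diffQ(state$diffParams, j, wmat[, j])
    cand <- state$diffParams; cand[[j]] <- fit$params
    if (diffQ(cand, j, wmat[, j]) >= old)
      state$diffParams[[j]] <- fit$params
    flags <- c(flags, fit$flags)
  }

  ## closed-form mixture weight update
  gNew <- spec@g; wNew <- spec@w
  for (c. in seq_len(C)) {
    ks <- which(tuples[, 1] == c.)
    tot <- sum(q[, ks])
    if (tot <= 1e-12) next
    for (i in which(spec@sSupport[c., ]))
      gNew[c., i] <- sum(q[, ks[tuples[ks, 2] == i], drop = FALSE]) / tot
    for (j in which(spec@dSupport[c., ]))
      wNew[c., j] <- sum(q[, ks[tuples[ks, 3] == j], drop = FALSE]) / tot
  }
  state$g <- gNew
  state$w <- wNew
  state$flags <- unique(c(state$flags, flags))
  state
}

#' Posterior-weighted volumes
#'
#' Per label, the sum across voxels of its posterior probability times the
#' voxel volume; robust for structures whose posterior mass is spread over
#' partial-volume voxels.  Volumes over all labels sum to the grid volume.
#'
#' @param posteriors V x L posterior matrix (rows sum to 1).
#' @param grid the \linkS4class{VoxelGrid}.
#' @return numeric L volumes in mm^3.
#' @export
posteriorVolumes <- function(posteriors, grid) {
  colSums(posteriors) * voxelVolume(grid)
}

#' Joint structural + diffusion Bayesian segmentation
#'
#' Runs the full pipeline: tensor cleaning, log-domain resampling to the
#' structural grid, FA/principal-direction extraction, optional atlas
#' placement and structural hyperprior estimation from a coarse initial
#' segmentation, seeded k-means component initialisation, then coordinate
#' ascent cycles of atlas deformation, reflection-plane estimation and
#' generalised EM until the objective converges.  Deterministic given the
#' seed.
#'
#' @param structural 3-D array (or V x S matrix) of bias-corrected
#'   intensities on the structural grid.
#' @param s_grid structural \linkS4class{VoxelGrid}.
#' @param tensors a \linkS4class{TensorField} on the (possibly coarser)
#'   diffusion grid, co-registered in world space.
#' @param mesh the \linkS4class{AtlasMesh}.
#' @param spec the \linkS4class{MixtureSpec}.
#' @param coarse optional integer V vector of initial coarse labels (in
#'   output-label ids) used for hyperprior estimation.
#' @param config named list of options; see Details.
#' @details Config entries (defaults): \code{epsilon} ("auto" or value),
#'   \code{symmetry} (TRUE when pairs exist), \code{max_cycles} (10),
#'   \code{outer_tol} (1e-5), \code{max_inner} (25), \code{inner_tol}
#'   (1e-6), \code{deform_iter} (8), \code{deform} (TRUE),
#'   \code{use_diffusion} (TRUE; FALSE gives a structural-only run),
#'   \code{kernel_sigma_mm} (2), \code{seed} (1),
#'   \code{hyper_strength_frac} (0.1), \code{background} (class 1),
#'   \code{align_atlas} (FALSE; TRUE applies
#'   \code{\link{alignAtlasToCoarse}} before fitting, for atlases not
#'   already placed in subject space).
#' @return list with \code{segmentation} (a \linkS4class{Segmentation}),
#'   \code{state} (a \linkS4class{FitState}), and \code{prior} (final
#'   rasterised \linkS4class{ClassPriorField}).
#' @export
segmentJoint <- function(structural, s_grid, tensors, mesh, spec,
                         coarse = NULL, config = list()) {
  cf <- modifyList(list(
    epsilon = "auto", symmetry = nrow(spec@pairs) > 0, max_cycles = 10,
    outer_tol = 1e-5, max_inner = 25, inner_tol = 1e-6, deform_iter = 8,
    deform = TRUE, use_diffusion = TRUE, kernel_sigma_mm = 2, seed = 1L,
    hyper_strength_frac = 0.1, background = 1L, align_atlas = FALSE,
    opts = list()), config)
  set.seed(cf$seed)
  validateSpec(spec)
  if (cf$align_atlas && !is.null(coarse))
    mesh <- alignAtlasToCoarse(mesh, coarse, s_grid, cf$background)
  if (is.array(structural) && length(dim(structural)) == 3)
    structural <- matrix(as.numeric(structural), ncol = 1)
  structural <- as.matrix(structural)
  stopifnot(nrow(structural) == nVoxels(s_grid))

  ## diffusion preprocessing: clean, log, resample, summarise
  cleaned <- cleanTensorField(tensors, cf$kernel_sigma_mm)
  logf <- logTensorField(cleaned)
  logs <- resampleLogTensors(logf, s_grid)
  stats <- computeDiffStats(logs)
  epsilon <- chooseEpsilon(s_grid, tensors@grid,
    if (identical(cf$epsilon, "auto")) NULL else cf$epsilon)

  C <- length(spec@classNames)
  deform <- zeroDeformation(mesh)
  prior <- rasterisePriors(mesh, deform, s_grid, cf$background)
  tuples <- supportTuples(spec)

  ## structural hyperpriors from the coarse segmentation
  hyper <- vector("list", spec@G)
  if (!is.null(coarse)) {
    for (i in seq_len(spec@G)) {
      ids <- spec@mergeMap[spec@sSupport[, i]]
      vv <- which(coarse %in% ids)
      if (length(vv) >= 2) {
        hyper[[i]] <- niwHyper(apply(structural[vv, , drop = FALSE], 2,
                                     median),
                               n = cf$hyper_strength_frac * length(vv))
      }
    }
  }

  ## component initialisation: per class, k-means over its unassigned comps
  structParams <- vector("list", spec@G)
  diffParams <- vector("list", spec@W)
  for (c. in seq_len(C)) {
    pri_c <- prior@priors[, c.]
    is <- which(spec@sSupport[c., ] &
                  vapply(structParams, is.null, logical(1)))
    if (length(is)) {
      ini <- kmeansInit(structural, pri_c, length(is), "gaussian",
                        seed = cf$seed + c.)
      structParams[is] <- ini
    }
    js <- which(spec@dSupport[c., ] &
                  vapply(diffParams, is.null, logical(1)))
    if (length(js)) {
      pw <- pri_c
      pw[!stats$valid] <- 0
      ini <- kmeansInit(stats, pw, length(js), spec@dFamily,
                        seed = cf$seed + 100 + c., opts = cf$opts)
      diffParams[js] <- ini
    }
  }
  plane0 <- reflectionPlane(s_grid@affine[1:3, 1] /
                              sqrt(sum(s_grid@affine[1:3, 1]^2)))
  state <- list(structParams = structParams, diffParams = diffParams,
                plane = plane0, flags = character())
  specCur <- spec
  ## enforce the symmetry constraint from the start
  if (cf$symmetry && nrow(spec@pairs) > 0)
    for (p in seq_len(nrow(spec@pairs)))
      state$diffParams[[spec@pairs[p, 2]]] <-
        reflectParams(state$diffParams[[spec@pairs[p, 1]]], state$plane)

  logPrior <- log(pmax(prior@priors, 1e-12))
  trace <- numeric()
  evalObj <- function() {
    Ls <- structuralLogLik(structural, state$structParams)
    Ld <- if (cf$use_diffusion)
      diffusionLogLik(stats, state$diffParams, spec@dFamily)
      else matrix(0, nrow(structural), spec@W)
    pen <- deformationPenalty(mesh, deform)
    pt <- paramPriorTerms(state$structParams, state$diffParams, hyper,
                          spec@dFamily)
    list(Ls = Ls, Ld = Ld,
         value = gemObjective(logPrior, Ls, Ld, specCur, epsilon, pen, pt,
                              tuples))
  }

  ob <- evalObj()
  trace <- c(trace, ob$value)
  for (cycle in seq_len(cf$max_cycles)) {
    ## 1. atlas deformation on current class posteriors
    if (cf$deform) {
      es <- eStep(logPrior, ob$Ls, ob$Ld, specCur, epsilon, tuples)
      cp <- classPosteriors(es$q, tuples, C)
      dres <- optimiseDeformation(mesh, deform, cp, s_grid,
                                  max_iter = cf$deform_iter)
      deform <- dres$deform
      prior <- rasterisePriors(mesh, deform, s_grid, cf$background)
      logPrior <- log(pmax(prior@priors, 1e-12))
      ob <- evalObj()
      trace <- c(trace, ob$value)
    }
    ## 2. reflection plane, before the M steps
    if (cf$symmetry && nrow(spec@pairs) > 0 && cf$use_diffusion) {
      es <- eStep(logPrior, ob$Ls, ob$Ld, specCur, epsilon, tuples)
      wmat <- matrix(0, nrow(es$q), spec@W)
      for (j in seq_len(spec@W))
        wmat[, j] <- rowSums(es$q[, tuples[, 3] == j, drop = FALSE])
      wmat[!stats$valid, ] <- 0
      rres <- optimiseReflection(stats, wmat, state$diffParams, spec@pairs,
                                 state$plane, spec@dFamily)
      state$plane <- rres$plane
      for (p in seq_len(nrow(spec@pairs)))
        state$diffParams[[spec@pairs[p, 2]]] <-
          reflectParams(state$diffParams[[spec@pairs[p, 1]]], state$plane)
      ob <- evalObj()
      trace <- c(trace, ob$value)
    }
    ## 3. inner GEM to convergence
    for (inner in seq_len(cf$max_inner)) {
      es <- eStep(logPrior, ob$Ls, ob$Ld, specCur, epsilon, tuples)
      state <- mStep(es, structural, stats, specCur, state, hyper,
                     epsilon = if (cf$use_diffusion) epsilon else 0,
                     symmetry = cf$symmetry, opts = cf$opts)
      specCur@g <- state$g
      specCur@w <- state$w
      prev <- tail(trace, 1)
      ob <- evalObj()
      trace <- c(trace, ob$value)
      if (abs(ob$value - prev) <= cf$inner_tol * max(abs(prev), 1)) break
    }
    n <- length(trace)
    cycleStart <- trace[max(1, n - inner - 2)]
    if (abs(tail(trace, 1) - cycleStart) <=
          cf$outer_tol * max(abs(cycleStart), 1) && cycle > 1) break
  }

  ## final posteriors, merge, MAP labels, volumes
  es <- eStep(logPrior, ob$Ls, ob$Ld, specCur, epsilon, tuples)
  cp <- classPosteriors(es$q, tuples, C)
  mg <- mergeOutputs(cp, spec@mergeMap)
  labels <- mg$labelIds[max.col(mg$posteriors, ties.method = "first")]
  vols <- posteriorVolumes(mg$posteriors, s_grid)
  labelNames <- vapply(mg$labelIds, function(id) {
    nm <- spec@classNames[spec@mergeMap == id]
    paste(nm, collapse = "+")
  }, character(1))
  seg <- new("Segmentation", grid = s_grid, labels = as.integer(labels),
             posteriors = mg$posteriors, labelIds = mg$labelIds,
             labelNames = labelNames, volumes = vols)
  fs <- new("FitState", deformation = deform, structParams = state$structParams,
            diffParams = state$diffParams, g = state$g, w = state$w,
            plane = state$plane, epsilon = epsilon, trace = trace,
            flags = as.list(state$flags))
  list(segmentation = seg, state = fs, prior = prior)
}
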