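#' Fit gradient-forest turnover functions
#'
#' For every candidate locus, grows a regression forest (bootstrap
#' samples, \code{mtry} random predictors per split, variance-reduction
#' splitting) with the locus dosage as response and the climate variables
#' plus latent-factor confounder axes as predictors.  Each split's
#' impurity decrease is accrued to its predictor in the equal-width bin
#' containing the split threshold.  Per locus, binned importances are
#' normalized to sum to the locus's out-of-bag R-squared; loci with
#' R-squared <= 0 are dropped.  Summing over loci and accumulating along
#' each predictor yields the cumulative-importance turnover function
#' \eqn{F_p}: nondecreasing, 0 below the training range, total importance
#' above it.
#'
#' Confounder axes (named \code{U1..UK}) take part in training so that
#' population structure cannot masquerade as climate importance, but they
#' are excluded from offset distances — structure does not change between
#' climate periods.
#'
#' @param g a \linkS4class{GenotypeExperiment} or dosage matrix
#'   (individuals x loci)
#' @param predictors data.frame, individuals x predictors: the scaled
#'   climate variables and optionally confounder axes
#' @param candidates optional locus ids restricting the response set
#' @param confounders names of the confounder columns in
#'   \code{predictors} (default: those matching \code{"^U[0-9]+$"})
#' @param ntree regression trees per locus (default 500)
#' @param mtry predictors per split (default \code{ceiling(P / 3)})
#' @param minLeaf minimum samples per leaf (default 5)
#' @param nbins equal-width importance bins per predictor (default 201)
#' @param seed integer seed (forest randomness is R-RNG driven)
#' @return a \linkS4class{TurnoverModel}
#' @export
fitTurnover <- function(g, predictors, candidates = NULL,
                        confounders = NULL, ntree = 500, mtry = NULL,
                        minLeaf = 5, nbins = 201, seed = 1) {
  Y <- if (is(g, "GenotypeExperiment")) t(dosage(g)) else as.matrix(g)
  if (!is.null(candidates)) {
    idx <- match(candidates, colnames(Y))
    if (anyNA(idx))
      stop("candidate locus id(s) absent: ",
           paste(head(candidates[is.na(idx)], 5), collapse = ", "))
    Y <- Y[, idx, drop = FALSE]
  }
  Y <- imputeDosage(Y, center = FALSE)
  X <- as.matrix(predictors)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) < 2 * minLeaf)
    stop("fewer than ", 2 * minLeaf, " samples; cannot grow trees")
  pnames <- colnames(X)
  if (is.null(confounders))
    confounders <- grep("^U[0-9]+$", pnames, value = TRUE)
  climateP <- setdiff(pnames, confounders)
  P <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(P / 3)

  rng <- apply(X, 2, range)
  edges <- t(vapply(seq_len(P), function(p)
    seq(rng[1, p], rng[2, p], length.out = nbins + 1), numeric(nbins + 1)))

  L <- ncol(Y)
  acc <- matrix(0, nbins, P, dimnames = list(NULL, pnames))
  r2 <- setNames(numeric(L), colnames(Y))
  withSeed(seed, {
    for (l in seq_len(L)) {
      fit <- .snpForest(Y[, l], X, as.integer(ntree), as.integer(mtry),
                        as.integer(minLeaf), as.integer(nbins), edges)
      r2[l] <- fit$r2
      if (is.finite(fit$r2) && fit$r2 > 0) {
        tot <- sum(fit$importance)
        if (tot > 0)
          acc <- acc + fit$importance * (fit$r2 / tot)
      }
    }
  })

  binEdges <- lapply(seq_len(P), function(p) edges[p, ])
  cumImp <- lapply(seq_len(P), function(p) cumsum(acc[, p]))
  names(binEdges) <- names(cumImp) <- pnames
  new("TurnoverModel", predictors = pnames,
      climatePredictors = climateP, binEdges = binEdges,
      cumImportance = cumImp, r2 = r2,
      hyperparams = list(ntree = ntree, mtry = mtry, minLeaf = minLeaf,
                         nbins = nbins, seed = seed))
}

setMethod("show", "TurnoverModel", function(object) {
  tot <- vapply(object@cumImportance, function(x) x[length(x)], numeric(1))
  cat(sprintf("TurnoverModel: %d predictor(s) (%d climate), %d SNP(s), %d with R2 > 0\n",
              length(object@predictors), length(object@climatePredictors),
              length(object@r2), sum(object@r2 > 0, na.rm = TRUE)))
  cat("  total importance:",
      paste(sprintf("%s=%.3g", names(tot), tot), collapse = ", "), "\n")
})

#' Total importance per predictor
#'
#' The plateau value of each cumulative-importance curve: the summed
#' R-squared-weighted split importance carried by the predictor.
#'
#' @param model a \linkS4class{TurnoverModel}
#' @return named numeric vector
#' @export
totalImportance <- function(model) {
  vapply(model@cumImportance, function(x) x[length(x)], numeric(1))
}

## Evaluate F_p at values: cumulative importance of fully-passed bins.
## Below the training range -> 0; at/above the maximum -> total.
evalTurnover <- function(model, p, values) {
  edges <- model@binEdges[[p]]
  if (is.null(edges)) stop("unknown predictor '", p, "'")
  ci <- model@cumImportance[[p]]
  i <- findInterval(values, edges)
  i <- pmin(pmax(i - 1L, 0L), length(ci))
  c(0, ci)[i + 1L]
}

#' @rdname transformEnv
#' @export
setMethod("transformEnv", signature("TurnoverModel", "data.frame"),
  function(model, env, predictors = NULL) {
    if (is.null(predictors)) predictors <- model@climatePredictors
    unknown <- setdiff(predictors, model@predictors)
    if (length(unknown))
      stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
    miss <- setdiff(predictors, colnames(env))
    if (length(miss))
      stop("env lacks predictor(s): ", paste(miss, collapse = ", "))
    out <- vapply(predictors, function(p) evalTurnover(model, p, env[[p]]),
                  numeric(nrow(env)))
    if (nrow(env) == 1L) out <- matrix(out, 1,
                                       dimnames = list(NULL, predictors))
    out
  })

#' @rdname transformEnv
#' @export
setMethod("transformEnv", signature("TurnoverModel", "ClimateRasterSet"),
  function(model, env, predictors = NULL) {
    if (is.null(predictors)) predictors <- model@climatePredictors
    tab <- as.data.frame(lapply(predictors, function(p)
      as.vector(env[[p]]@values)))
    colnames(tab) <- predictors
    transformEnv(model, tab, predictors)
  })

#' Gradient-forest genomic offset
#'
#' Euclidean distance between current and future climate in turnover
#' space, over the climate predictors only: confounder coordinates are
#' excluded because population structure does not change between periods.
#'
#' @param model a \linkS4class{TurnoverModel}
#' @param eCur,eFut scaled climate data.frames (units x variables) or
#'   single-unit vectors with named entries
#' @return numeric vector of offsets
#' @export
gfOffset <- function(model, eCur, eFut) {
  asDf <- function(e) {
    if (is.data.frame(e)) e
    else as.data.frame(as.list(e))
  }
  tc <- transformEnv(model, asDf(eCur))
  tf <- transformEnv(model, asDf(eFut))
  if (!identical(dim(tc), dim(tf)))
    stop("current and future climate have mismatched dimensions")
  sqrt(rowSums((tc - tf)^2))
}

#' Serialize / restore a turnover model
#'
#' Versioned JSON carrying bin edges, cumulative-importance curves, the
#' per-SNP R-squared table and hyperparameters; round-trips exactly.
#'
#' @param model a \linkS4class{TurnoverModel}
#' @param path file path (".json")
#' @return \code{readTurnoverModel} returns a \linkS4class{TurnoverModel}
#' @export
writeTurnoverModel <- function(model, path) {
  jsonlite::write_json(list(
    format = "turnover-model", version = 1L,
    predictors = model@predictors,
    climatePredictors = model@climatePredictors,
    binEdges = model@binEdges, cumImportance = model@cumImportance,
    r2 = as.list(model@r2), hyperparams = model@hyperparams),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTurnoverModel
#' @export
readTurnoverModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "turnover-model"))
    stop("not a turnover model file")
  new("TurnoverModel", predictors = x$predictors,
      climatePredictors = x$climatePredictors,
      binEdges = as.list(x$binEdges),
      cumImportance = as.list(x$cumImportance),
      r2 = unlist(x$r2),
      hyperparams = as.list(x$hyperparams))
}

#' Export cumulative-importance curves as a table
#'
#' One row per (predictor, bin upper edge) with the cumulative importance
#' there — the content of a turnover-function plot.
#'
#' @param model a \linkS4class{TurnoverModel}
#' @return data.frame: \code{predictor}, \code{value},
#'   \code{cumulative_importance}
#' @export
turnoverCurves <- function(model) {
  do.call(rbind, lapply(model@predictors, function(p) {
    e <- model@binEdges[[p]]
    data.frame(predictor = p, value = e[-1],
               cumulative_importance = model@cumImportance[[p]],
               stringsAsFactors = FALSE)
  }))
}
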