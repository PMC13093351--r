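#' Genetic-gap genomic offset
#'
#' The latent-factor offset statistic: for a climate-change vector
#' \eqn{\Delta e = e_{fut} - e_{cur}} (in scaled units) and the matrix B of
#' environmental effect sizes over the candidate loci,
#' \deqn{G = \Delta e^T C_b \Delta e, \qquad C_b = B B^T / L,}
#' the mean over loci of the squared predicted genotypic change.  G is
#' nonnegative, zero iff the predicted genotypic change is zero, symmetric
#' in (current, future), and quadratic in the magnitude of climate change.
#'
#' A prose-literal variant (\code{form = "weighted_mean"}) is also
#' available: the mean over predictors of \eqn{w_j |\Delta e_j|} with
#' weights \eqn{w_j} the mean squared effect size of predictor j — a
#' reading of "each predictor individually weighted by effect size, then
#' averaged".  The quadratic form is the default and the one used
#' throughout the pipeline.
#'
#' @param model a \linkS4class{LatentFactorModel}, or a variables x loci
#'   effect-size matrix B
#' @param eCur,eFut scaled climate: vectors (one unit) or matrices
#'   (units x variables)
#' @param candidates optional locus ids (or column indices) restricting B
#'   to the candidate set
#' @param form \code{"quadratic"} (default) or \code{"weighted_mean"}
#' @return numeric vector of offsets, one per unit
#' @examples
#' B <- matrix(0.5, 1, 1)                 # one variable, one locus
#' geneticGap(B, eCur = 0, eFut = 2)      # (0.5 * 2)^2 / 1 = 1
#' @export
geneticGap <- function(model, eCur, eFut, candidates = NULL,
                       form = c("quadratic", "weighted_mean")) {
  form <- match.arg(form)
  B <- if (is(model, "LatentFactorModel")) model@B else as.matrix(model)
  if (!is.null(candidates)) {
    if (is.character(candidates)) {
      if (is(model, "LatentFactorModel")) {
        idx <- match(candidates, model@loci)
        if (anyNA(idx))
          stop("candidate locus id(s) absent from model: ",
               paste(head(candidates[is.na(idx)], 5), collapse = ", "))
      } else {
        idx <- match(candidates, colnames(B))
        if (anyNA(idx)) stop("candidate locus id(s) absent from B")
      }
      B <- B[, idx, drop = FALSE]
    } else B <- B[, candidates, drop = FALSE]
  }
  if (is.null(dim(eCur))) eCur <- matrix(eCur, nrow = 1)
  if (is.null(dim(eFut))) eFut <- matrix(eFut, nrow = 1)
  eCur <- as.matrix(eCur); eFut <- as.matrix(eFut)
  if (!identical(dim(eCur), dim(eFut)))
    stop("current and future climate have mismatched dimensions")
  if (ncol(eCur) != nrow(B))
    stop("climate has ", ncol(eCur), " variable(s) but B has ", nrow(B))
  de <- eFut - eCur
  L <- ncol(B)
  if (form == "quadratic") {
    Cb <- tcrossprod(B) / L
    rowSums((de %*% Cb) * de)
  } else {
    w <- rowMeans(B^2)
    as.numeric(abs(de) %*% w) / length(w)
  }
}

#' Per-site mean offsets
#'
#' Arithmetic mean of per-tree offsets within each sampling site.  Trees
#' whose climate extraction was error-flagged are excluded from the mean
#' and counted in \code{n_excluded}.
#'
#' @param offsets an \linkS4class{OffsetResult}, or a data.frame with
#'   columns \code{site_id} and \code{offset} (optionally \code{flag};
#'   rows with flag != "ok" are excluded)
#' @return data.frame: \code{site_id}, \code{offset} (site mean),
#'   \code{n}, \code{n_excluded}
#' @export
siteMeanOffsets <- function(offsets) {
  v <- if (is(offsets, "OffsetResult")) offsets@values else offsets
  stopifnot(all(c("site_id", "offset") %in% colnames(v)))
  flag <- if ("flag" %in% colnames(v)) v$flag else rep("ok", nrow(v))
  sites <- sort(unique(v$site_id))
  out <- do.call(rbind, lapply(sites, function(s) {
    rows <- v$site_id == s
    ok <- rows & flag == "ok"
    if (!any(ok)) stop("site ", s, " has no usable trees")
    data.frame(site_id = s, offset = mean(v$offset[ok]),
               n = sum(ok), n_excluded = sum(rows) - sum(ok))
  }))
  rownames(out) <- NULL
  out
}

#' Bundle per-tree offsets into an OffsetResult
#'
#' @param offset numeric vector of offsets
#' @param id unit ids
#' @param site_id site of each unit (NA for raster cells)
#' @param method \code{"lfmm"} or \code{"gf"}
#' @param scenario,period scenario tags
#' @return an \linkS4class{OffsetResult}
#' @export
OffsetResult <- function(offset, id, site_id = NA, method, scenario,
                         period = "") {
  new("OffsetResult",
      values = data.frame(id = id, site_id = site_id, offset = offset,
                          stringsAsFactors = FALSE),
      method = method, scenario = scenario, period = period)
}

#' @rdname OffsetResult-class
#' @export
setMethod("offsetValues", "OffsetResult", function(object) object@values)

#' @rdname OffsetResult-class
#' @export
setMethod("offsetMethod", "OffsetResult", function(object) object@method)

setMethod("show", "OffsetResult", function(object) {
  v <- object@values$offset
  cat(sprintf("OffsetResult [%s | %s %s]: %d unit(s), offset in [%.4g, %.4g]\n",
              object@method, object@scenario, object@period, length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})
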