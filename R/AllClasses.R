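#' @import methods
#' @importFrom stats complete.cases cor lm median pchisq pnorm pt qchisq qnorm
#'   quantile rbeta rbinom rnorm runif sd setNames var p.adjust coef predict
#'   rgamma
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib GenomicOffset, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Single-band georeferenced climate raster
#'
#' An in-memory single-band raster: a numeric matrix with an affine
#' georeference in geographic (lon/lat, WGS84) coordinates.  Row 1 is the
#' northernmost row, column 1 the westernmost column, and registration is
#' cell-center: the center of cell \code{[r, c]} lies at
#' \code{x = xmin + (c - 0.5) * xres}, \code{y = ymax - (r - 0.5) * yres}.
#' Missing cells are \code{NA} (the nodata value); nodata is propagated by
#' every operation, never imputed.
#'
#' @slot values numeric matrix of cell values, \code{NA} = nodata.
#' @slot extent numeric length-4 vector \code{(xmin, xmax, ymin, ymax)} of
#'   the outer cell edges, in degrees.
#' @slot crs character CRS identifier (default \code{"EPSG:4326"}).
#' @slot name character, the variable name carried by the band.
#' @export
setClass("ClimateRaster",
  representation(values = "matrix", extent = "numeric",
                 crs = "character", name = "character"),
  prototype(crs = "EPSG:4326", name = ""))

setValidity("ClimateRaster", function(object) {
  e <- object@extent
  if (length(e) != 4L) return("extent must be (xmin, xmax, ymin, ymax)")
  if (e[2] <= e[1] || e[4] <= e[3]) return("extent must have positive span")
  if (!is.numeric(object@values)) return("values must be numeric")
  TRUE
})

#' Set of aligned climate rasters for one scenario
#'
#' A named list of \linkS4class{ClimateRaster} objects (one per climate
#' variable) sharing grid shape, extent and CRS, tagged with the scenario
#' they describe (\code{"current"} or an SSP x period label).
#'
#' @slot rasters named list of \linkS4class{ClimateRaster}.
#' @slot scenario character scenario tag.
#' @export
setClass("ClimateRasterSet",
  representation(rasters = "list", scenario = "character"),
  prototype(scenario = "current"))

setValidity("ClimateRasterSet", function(object) {
  rs <- object@rasters
  if (length(rs) == 0L) return("empty raster set")
  if (is.null(names(rs)) || any(!nzchar(names(rs))))
    return("rasters must be named by variable")
  if (!all(vapply(rs, is, logical(1), "ClimateRaster")))
    return("all elements must be ClimateRaster")
  d0 <- dim(rs[[1]]@values); e0 <- rs[[1]]@extent; c0 <- rs[[1]]@crs
  for (nm in names(rs)) {
    r <- rs[[nm]]
    if (!identical(dim(r@values), d0))
      return(sprintf("raster '%s' has mismatched grid shape", nm))
    if (max(abs(r@extent - e0)) > 1e-9)
      return(sprintf("raster '%s' has mismatched extent", nm))
    if (!identical(r@crs, c0))
      return(sprintf("raster '%s' has mismatched CRS", nm))
  }
  TRUE
})

#' Train-time climate scaler
#'
#' Per-variable center (mean) and scale (standard deviation) estimated from
#' the sampled-tree climate values.  The same scaler is applied to future
#' climates and raster grids: downstream data are always expressed in units
#' of training standard deviations.
#'
#' @slot center named numeric vector of training means.
#' @slot scale named numeric vector of training standard deviations
#'   (all strictly positive).
#' @export
setClass("ClimateScaler",
  representation(center = "numeric", scale = "numeric"))

setValidity("ClimateScaler", function(object) {
  if (!identical(names(object@center), names(object@scale)))
    return("center and scale must share variable names")
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    return("scale must be finite and > 0 for every variable")
  TRUE
})

#' Genotype matrix with sampling metadata
#'
#' A \linkS4class{SummarizedExperiment} holding a loci x individuals dosage
#' assay (counts of the ALT allele, in \{0, 1, 2, NA\}).  \code{colData}
#' carries the per-individual sampling metadata (\code{site_id},
#' \code{pair_id}, \code{area_id}, \code{latitude}, \code{longitude},
#' \code{elevation}, \code{elevation_class}); \code{rowData} carries locus
#' ids and, for synthetic data, the simulation truth table
#' (\code{is_adaptive}, \code{driver}, \code{beta}, \code{p_ancestral}).
#'
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  if (!"dosage" %in% assayNames(object)) return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (nrow(d) == 0L) return("at least one locus is required")
  ok <- is.na(d) | d == 0 | d == 1 | d == 2
  if (!all(ok)) return("dosages must be in {0, 1, 2, NA}")
  need <- c("site_id", "area_id")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    return(paste("colData lacks required column(s):",
                 paste(miss, collapse = ", ")))
  if (anyNA(colData(object)$site_id) || anyNA(colData(object)$area_id))
    return("every individual must map to exactly one site and area")
  if (any(rowSums(is.na(d)) == ncol(d)))
    return("loci with 100% missingness are not allowed")
  TRUE
})

#' Ridge latent-factor model of genotypes on climate
#'
#' Fit of the decomposition \eqn{Y \approx E B + U V^T} where \eqn{Y} is the
#' centered dosage matrix (individuals x loci), \eqn{E} the scaled climate
#' matrix (individuals x variables), \eqn{U} the latent factor scores
#' absorbing population structure, and \eqn{B} the environmental effect
#' sizes, estimated under a ridge penalty on \eqn{B}.
#'
#' @slot K integer, number of latent factors.
#' @slot U numeric matrix, individuals x K factor scores.
#' @slot V numeric matrix, loci x K loadings.
#' @slot B numeric matrix, variables x loci effect sizes on the scaled
#'   predictors.
#' @slot lambda numeric ridge penalty.
#' @slot variables character climate-variable names (rows of B).
#' @slot loci character locus ids (columns of B).
#' @export
setClass("LatentFactorModel",
  representation(K = "integer", U = "matrix", V = "matrix", B = "matrix",
                 lambda = "numeric", variables = "character",
                 loci = "character"))

setValidity("LatentFactorModel", function(object) {
  if (object@K > 0 &&
      (ncol(object@U) != object@K || ncol(object@V) != object@K))
    return("U and V must have K columns")
  if (any(!is.finite(object@B))) return("B must be finite")
  if (nrow(object@B) != length(object@variables))
    return("B rows must match variable names")
  if (ncol(object@B) != length(object@loci))
    return("B columns must match locus ids")
  TRUE
})

#' Gradient-forest turnover model
#'
#' Per-predictor cumulative-importance step functions built from per-SNP
#' regression forests.  For each predictor \eqn{p}, split-impurity decreases
#' are accrued into equal-width bins over the training range, normalized per
#' SNP to sum to that SNP's positive out-of-bag \eqn{R^2}, summed over SNPs,
#' and accumulated into a nondecreasing step function \eqn{F_p}. Latent
#' factor axes may be included as confounding predictors during training;
#' they are excluded from offset distances.
#'
#' @slot predictors character, all predictors (climate variables then
#'   confounder axes).
#' @slot climatePredictors character, the subset used in offset distances.
#' @slot binEdges named list; per predictor, the \code{nbins + 1} bin edges
#'   spanning the training range.
#' @slot cumImportance named list; per predictor, the cumulative importance
#'   at each bin's upper edge (length \code{nbins}).
#' @slot r2 numeric, per-SNP out-of-bag R-squared (negatives truncated to 0
#'   at accumulation time, stored raw here).
#' @slot hyperparams list: \code{ntree}, \code{mtry}, \code{minNode},
#'   \code{nbins}, \code{seed}.
#' @export
setClass("TurnoverModel",
  representation(predictors = "character", climatePredictors = "character",
                 binEdges = "list", cumImportance = "list", r2 = "numeric",
                 hyperparams = "list"))

setValidity("TurnoverModel", function(object) {
  for (p in object@predictors) {
    ci <- object@cumImportance[[p]]
    if (is.null(ci)) return(sprintf("no cumulative importance for '%s'", p))
    if (any(diff(ci) < -1e-12))
      return(sprintf("cumulative importance for '%s' must be nondecreasing", p))
    if (length(object@binEdges[[p]]) != length(ci) + 1L)
      return(sprintf("bin edges for '%s' must be one longer than curve", p))
  }
  if (!all(object@climatePredictors %in% object@predictors))
    return("climatePredictors must be a subset of predictors")
  TRUE
})

#' Per-unit genomic offset values
#'
#' Offsets for one method under one scenario, per individual tree (or per
#' raster cell).  Offsets from different methods live on different scales
#' and are never compared directly; the method tag is mandatory.
#'
#' @slot values data.frame with columns \code{id}, \code{site_id} (NA for
#'   cells) and \code{offset}.
#' @slot method character, \code{"lfmm"} or \code{"gf"}.
#' @slot scenario character scenario name (SSP label).
#' @slot period character, \code{"mid"} or \code{"late"}.
#' @export
setClass("OffsetResult",
  representation(values = "data.frame", method = "character",
                 scenario = "character", period = "character"))

setValidity("OffsetResult", function(object) {
  v <- object@values
  if (!all(c("id", "site_id", "offset") %in% colnames(v)))
    return("values needs columns id, site_id, offset")
  off <- v$offset[!is.na(v$offset)]
  if (any(off < -1e-12)) return("offsets must be nonnegative")
  if (!object@method %in% c("lfmm", "gf"))
    return("method must be 'lfmm' or 'gf'")
  TRUE
})
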