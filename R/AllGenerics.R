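#' @rdname ClimateRaster-class
#' @param object a \linkS4class{ClimateRaster}
#' @export
setGeneric("rasterValues", function(object) standardGeneric("rasterValues"))

#' @rdname ClimateRaster-class
#' @export
setGeneric("rasterExtent", function(object) standardGeneric("rasterExtent"))

#' @rdname ClimateRasterSet-class
#' @param object a \linkS4class{ClimateRasterSet}
#' @export
setGeneric("scenarioTag", function(object) standardGeneric("scenarioTag"))

#' Apply a train-time scaler
#'
#' Centers and scales climate data with the \emph{training} means and
#' standard deviations held by a \linkS4class{ClimateScaler} — never with
#' the statistics of the data being scaled.  Methods exist for per-tree
#' climate tables (data.frame) and whole \linkS4class{ClimateRasterSet}s.
#'
#' @param scaler a \linkS4class{ClimateScaler}
#' @param x a data.frame of climate columns, or a ClimateRasterSet
#' @return object of the same shape with scaled values
#' @seealso \code{\link{fitScaler}}
#' @export
setGeneric("applyScaler", function(scaler, x) standardGeneric("applyScaler"))

#' @rdname GenotypeExperiment-class
#' @param object a \linkS4class{GenotypeExperiment}
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' Map environment into turnover space
#'
#' Evaluates a \linkS4class{TurnoverModel}'s cumulative-importance step
#' functions at new (scaled) predictor values.  Values beyond the training
#' range clamp to the endpoint plateau: the model never extrapolates past
#' the conditions it was trained on.
#'
#' @param model a \linkS4class{TurnoverModel}
#' @param env a data.frame of scaled predictor columns, or a scaled
#'   \linkS4class{ClimateRasterSet}
#' @param predictors which predictors to transform (default: all climate
#'   predictors in the model)
#' @return matrix (rows = rows/cells of \code{env}) of turnover coordinates
#' @export
setGeneric("transformEnv",
           function(model, env, predictors = NULL)
             standardGeneric("transformEnv"))

#' @rdname OffsetResult-class
#' @param object an \linkS4class{OffsetResult}
#' @export
setGeneric("offsetValues", function(object) standardGeneric("offsetValues"))

#' @rdname OffsetResult-class
#' @export
setGeneric("offsetMethod", function(object) standardGeneric("offsetMethod"))
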