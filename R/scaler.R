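#' Fit the train-time climate scaler
#'
#' Estimates per-variable means and standard deviations from the
#' current-period sampled-tree climate table.  All later data — future
#' climates at the trees and every raster grid, current or future — are
#' scaled with \emph{these} statistics, so that climate-change vectors are
#' expressed in units of the training standard deviation and offsets remain
#' comparable across periods.
#'
#' @param table data.frame of per-tree climate values (one column per
#'   variable; non-numeric columns are ignored)
#' @param variables which columns to use (default: all numeric columns)
#' @return a \linkS4class{ClimateScaler}
#' @examples
#' sc <- fitScaler(data.frame(gst = c(7, 8, 9), bio12 = c(600, 800, 1000)))
#' applyScaler(sc, data.frame(gst = 8, bio12 = 800))
#' @export
fitScaler <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- colnames(table)[vapply(table, is.numeric, logical(1))]
  ctr <- vapply(variables, function(v) mean(table[[v]], na.rm = TRUE),
                numeric(1))
  scl <- vapply(variables, function(v) sd(table[[v]], na.rm = TRUE),
                numeric(1))
  bad <- variables[!is.finite(scl) | scl <= 0]
  if (length(bad))
    stop("zero-variance variable(s): ", paste(bad, collapse = ", "))
  new("ClimateScaler", center = ctr, scale = scl)
}

#' @rdname applyScaler
#' @export
setMethod("applyScaler", signature("ClimateScaler", "data.frame"),
  function(scaler, x) {
    for (v in names(scaler@center)) {
      if (!v %in% colnames(x))
        stop("variable '", v, "' absent from table")
      x[[v]] <- (x[[v]] - scaler@center[[v]]) / scaler@scale[[v]]
    }
    x
  })

#' @rdname applyScaler
#' @export
setMethod("applyScaler", signature("ClimateScaler", "ClimateRasterSet"),
  function(scaler, x) {
    rs <- x@rasters
    for (v in names(rs)) {
      if (!v %in% names(scaler@center))
        stop("no training statistics for raster variable '", v, "'")
      rs[[v]]@values <- (rs[[v]]@values - scaler@center[[v]]) /
        scaler@scale[[v]]
    }
    new("ClimateRasterSet", rasters = rs, scenario = x@scenario)
  })

setMethod("show", "ClimateScaler", function(object) {
  cat("ClimateScaler over", length(object@center), "variable(s):\n")
  print(round(rbind(center = object@center, scale = object@scale), 4))
})

#' Serialize / restore a scaler
#'
#' JSON sidecar holding the training means and standard deviations, so a
#' projection run months later can reuse the exact training contract.
#'
#' @param scaler a \linkS4class{ClimateScaler}
#' @param path file path (".json")
#' @return \code{readScaler} returns a \linkS4class{ClimateScaler}
#' @export
writeScaler <- function(scaler, path) {
  jsonlite::write_json(
    list(center = as.list(scaler@center), scale = as.list(scaler@scale)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScaler
#' @export
readScaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ClimateScaler", center = unlist(x$center), scale = unlist(x$scale))
}
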