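#' Construct a ClimateRaster
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param extent numeric \code{(xmin, xmax, ymin, ymax)} outer edges, degrees.
#' @param crs CRS identifier.
#' @param name variable name of the band.
#' @return a \linkS4class{ClimateRaster}
#' @examples
#' r <- ClimateRaster(matrix(1:12, 3, 4), extent = c(0, 4, 0, 3))
#' bilinearExtract(r, data.frame(lon = 2, lat = 1.5))
#' @export
ClimateRaster <- function(values, extent, crs = "EPSG:4326", name = "") {
  new("ClimateRaster", values = as.matrix(values),
      extent = as.numeric(extent), crs = crs, name = name)
}

#' @rdname ClimateRaster-class
#' @export
setMethod("rasterValues", "ClimateRaster", function(object) object@values)

#' @rdname ClimateRaster-class
#' @export
setMethod("rasterExtent", "ClimateRaster", function(object) {
  setNames(object@extent, c("xmin", "xmax", "ymin", "ymax"))
})

#' @rdname ClimateRaster-class
#' @export
setMethod("dim", "ClimateRaster", function(x) dim(x@values))

setMethod("show", "ClimateRaster", function(object) {
  d <- dim(object@values); e <- object@extent
  cat("ClimateRaster", if (nzchar(object@name)) sQuote(object@name), "\n")
  cat(sprintf("  %d rows x %d cols | extent lon [%.4f, %.4f] lat [%.4f, %.4f] | %s\n",
              d[1], d[2], e[1], e[2], e[3], e[4], object@crs))
  v <- object@values
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cell(s)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

#' Construct a ClimateRasterSet
#'
#' @param rasters named list of aligned \linkS4class{ClimateRaster}s.
#' @param scenario scenario tag (\code{"current"} or an SSP x period label).
#' @return a \linkS4class{ClimateRasterSet}
#' @export
ClimateRasterSet <- function(rasters, scenario = "current") {
  new("ClimateRasterSet", rasters = rasters, scenario = scenario)
}

#' @rdname ClimateRasterSet-class
#' @export
setMethod("scenarioTag", "ClimateRasterSet", function(object) object@scenario)

#' @rdname ClimateRasterSet-class
#' @param x a ClimateRasterSet
#' @export
setMethod("names", "ClimateRasterSet", function(x) names(x@rasters))

#' @rdname ClimateRasterSet-class
#' @param i variable name or index
#' @export
setMethod("[[", "ClimateRasterSet", function(x, i) x@rasters[[i]])

#' @rdname ClimateRasterSet-class
#' @export
setMethod("length", "ClimateRasterSet", function(x) length(x@rasters))

setMethod("show", "ClimateRasterSet", function(object) {
  d <- dim(object@rasters[[1]]@values)
  cat(sprintf("ClimateRasterSet: %d variable(s) [%s] | scenario '%s' | %d x %d grid\n",
              length(object@rasters),
              paste(names(object@rasters), collapse = ", "),
              object@scenario, d[1], d[2]))
})

rasterRes <- function(r) {
  e <- r@extent; d <- dim(r@values)
  c(x = (e[2] - e[1]) / d[2], y = (e[4] - e[3]) / d[1])
}

## Cell-center coordinates for column c / row r (row 1 northernmost).
cellCenterX <- function(r, col) r@extent[1] + (col - 0.5) * rasterRes(r)["x"]
cellCenterY <- function(r, row) r@extent[4] - (row - 0.5) * rasterRes(r)["y"]

#' Bilinear point extraction from a raster
#'
#' Interpolates raster values at point coordinates from the four nearest
#' cell centers (bilinear blend), reproducing the stored cell value exactly
#' when a point sits on a cell center.  Points near the outer half-cell rim
#' (inside the extent but beyond the outermost cell centers) are clamped to
#' the edge centers, so extraction degrades to linear/nearest there rather
#' than extrapolating.
#'
#' @param raster a \linkS4class{ClimateRaster}
#' @param points data.frame with columns \code{lon}, \code{lat}
#' @return data.frame with columns \code{value} and \code{flag}; flag is
#'   \code{"ok"}, \code{"outside"} (point beyond raster bounds; value NA) or
#'   \code{"nodata"} (a contributing neighbor is nodata; value NA).  No
#'   silent NaN: every failed point carries its reason.
#' @export
bilinearExtract <- function(raster, points) {
  stopifnot(is(raster, "ClimateRaster"),
            all(c("lon", "lat") %in% colnames(points)))
  v <- raster@values
  e <- raster@extent
  res <- rasterRes(raster)
  nr <- nrow(v); nc <- ncol(v)
  n <- nrow(points)
  out <- data.frame(value = rep(NA_real_, n),
                    flag = rep("ok", n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- points$lon[i]; y <- points$lat[i]
    if (!is.finite(x) || !is.finite(y) ||
        x < e[1] || x > e[2] || y < e[3] || y > e[4]) {
      out$flag[i] <- "outside"
      next
    }
    ## fractional cell-center index: u = 1 at the first center, nc at the last
    u <- (x - e[1]) / res["x"] + 0.5
    w2 <- (e[4] - y) / res["y"] + 0.5
    cL <- min(max(floor(u), 1), nc - if (nc > 1) 1 else 0)
    rT <- min(max(floor(w2), 1), nr - if (nr > 1) 1 else 0)
    cR <- min(cL + 1, nc); rB <- min(rT + 1, nr)
    wx <- min(max(u - cL, 0), 1)   # clamp: edge rim degrades to edge center
    wy <- min(max(w2 - rT, 0), 1)
    q <- c(v[rT, cL], v[rT, cR], v[rB, cL], v[rB, cR])
    w <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
    if (any(is.na(q[w > 0]))) {
      out$flag[i] <- "nodata"
      next
    }
    q[is.na(q)] <- 0
    out$value[i] <- sum(w * q)
  }
  out
}

#' Extract all variables of a raster set at points
#'
#' @param rasterSet a \linkS4class{ClimateRasterSet}
#' @param points data.frame with \code{lon}, \code{lat}
#' @return data.frame: one column per variable plus a \code{flag} column
#'   ("ok" only when every variable extracted cleanly)
#' @export
extractClimate <- function(rasterSet, points) {
  vals <- lapply(names(rasterSet), function(nm)
    bilinearExtract(rasterSet[[nm]], points))
  out <- as.data.frame(lapply(vals, `[[`, "value"))
  colnames(out) <- names(rasterSet)
  flags <- vapply(seq_len(nrow(points)), function(i) {
    f <- vapply(vals, function(v) v$flag[i], character(1))
    if (all(f == "ok")) "ok" else f[f != "ok"][1]
  }, character(1))
  out$flag <- flags
  out
}

#' Cell-wise ensemble mean of aligned rasters
#'
#' Arithmetic mean across ensemble members (e.g., global circulation
#' models), cell by cell.  A nodata cell in any member yields nodata in the
#' mean: missingness is propagated, never imputed.
#'
#' @param rasters list of at least two aligned \linkS4class{ClimateRaster}s
#' @return a \linkS4class{ClimateRaster}
#' @export
ensembleMean <- function(rasters) {
  stopifnot(length(rasters) >= 2)
  r0 <- rasters[[1]]
  for (i in seq_along(rasters)) {
    r <- rasters[[i]]
    if (!identical(dim(r@values), dim(r0@values)) ||
        max(abs(r@extent - r0@extent)) > 1e-9)
      stop("ensembleMean: raster ", i, " ('", r@name,
           "') is not aligned with raster 1")
  }
  arr <- vapply(rasters, function(r) r@values,
                matrix(0, nrow(r0@values), ncol(r0@values)))
  m <- apply(arr, c(1, 2), function(z) if (anyNA(z)) NA_real_ else mean(z))
  ClimateRaster(m, r0@extent, crs = r0@crs, name = r0@name)
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster interchange (".asc": header of ncols,
#' nrows, corner, cellsize, nodata, then rows north to south).  Only square
#' cells can be represented; \code{writeAsciiGrid} refuses rasters whose x
#' and y resolutions differ by more than 1e-6 degrees.
#'
#' @param path file path
#' @param raster a \linkS4class{ClimateRaster}
#' @param name variable name to attach on read
#' @return \code{readAsciiGrid} returns a \linkS4class{ClimateRaster};
#'   \code{writeAsciiGrid} returns \code{path} invisibly.
#' @export
writeAsciiGrid <- function(raster, path) {
  res <- rasterRes(raster)
  if (abs(res["x"] - res["y"]) > 1e-6)
    stop("ASCII grid requires square cells")
  v <- raster@values
  nodata <- -9999
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", raster@extent[1]),
    sprintf("yllcorner %.10f", raster@extent[3]),
    sprintf("cellsize %.10f", res["x"]),
    sprintf("NODATA_value %d", nodata)), con)
  write.table(format(v, trim = TRUE, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path, name = "") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA
  cs <- h[["cellsize"]]
  ext <- c(h[["xllcorner"]], h[["xllcorner"]] + h[["ncols"]] * cs,
           h[["yllcorner"]], h[["yllcorner"]] + h[["nrows"]] * cs)
  ClimateRaster(v, ext, name = name)
}

#' Write every raster of a set as ASCII grids
#'
#' Files are named \code{<prefix><variable>.asc}.
#' @param rasterSet a \linkS4class{ClimateRasterSet}
#' @param dir output directory
#' @param prefix filename prefix (default the scenario tag + "_")
#' @return character vector of paths, invisibly
#' @export
writeRasterSet <- function(rasterSet, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- paste0(gsub("[^A-Za-z0-9._-]", "_",
                                             scenarioTag(rasterSet)), "_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(rasterSet), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".asc"))
    writeAsciiGrid(rasterSet[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
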