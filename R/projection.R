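#' Project genomic offsets across a raster range
#'
#' Computes a per-cell offset raster for one scenario from aligned current
#' and future climate raster sets, masked to the species range.  Cells
#' outside the mask are nodata.  A companion novelty raster flags cells
#' (1/0) whose scaled climate lies outside the training envelope
#' (\code{[min, max]} of any training variable, current or future value)
#' — the model is least trustworthy there.
#'
#' @param model a \linkS4class{LatentFactorModel} (genetic-gap offset) or
#'   \linkS4class{TurnoverModel} (gradient-forest offset)
#' @param current,future \linkS4class{ClimateRasterSet}s in scaled units
#'   (apply the training \linkS4class{ClimateScaler} first)
#' @param mask optional \linkS4class{ClimateRaster}; cells that are NA or
#'   0 are outside the range
#' @param trainEnv scaled training climate table (for the novelty
#'   envelope); without it the novelty raster is all-nodata
#' @param candidates optional candidate locus ids (LFMM model only)
#' @return list: \code{offset} and \code{novelty}
#'   \linkS4class{ClimateRaster}s
#' @export
projectOffsets <- function(model, current, future, mask = NULL,
                           trainEnv = NULL, candidates = NULL) {
  vars <- if (is(model, "LatentFactorModel")) model@variables
          else model@climatePredictors
  miss <- setdiff(vars, names(current))
  if (length(miss))
    stop("current raster set lacks variable(s): ",
         paste(miss, collapse = ", "))
  r0 <- current[[vars[1]]]
  checkAligned <- function(r, what) {
    if (!identical(dim(r@values), dim(r0@values)) ||
        max(abs(r@extent - r0@extent)) > 1e-9)
      stop("misaligned grid: ", what)
  }
  for (v in vars) {
    checkAligned(current[[v]], paste("current", v))
    checkAligned(future[[v]], paste("future", v))
  }
  if (!is.null(mask)) checkAligned(mask, "mask")

  nr <- nrow(r0@values); nc <- ncol(r0@values)
  eCur <- vapply(vars, function(v) as.vector(current[[v]]@values),
                 numeric(nr * nc))
  eFut <- vapply(vars, function(v) as.vector(future[[v]]@values),
                 numeric(nr * nc))
  inMask <- if (is.null(mask)) rep(TRUE, nr * nc)
            else {
              mv <- as.vector(mask@values)
              !is.na(mv) & mv != 0
            }
  ok <- inMask & complete.cases(eCur) & complete.cases(eFut)
  off <- rep(NA_real_, nr * nc)
  if (any(ok)) {
    if (is(model, "LatentFactorModel")) {
      off[ok] <- geneticGap(model, eCur[ok, , drop = FALSE],
                            eFut[ok, , drop = FALSE],
                            candidates = candidates)
    } else {
      dfc <- as.data.frame(eCur[ok, , drop = FALSE])
      dff <- as.data.frame(eFut[ok, , drop = FALSE])
      off[ok] <- gfOffset(model, dfc, dff)
    }
  } else warning("no unmasked cells with complete climate")

  nov <- rep(NA_real_, nr * nc)
  if (!is.null(trainEnv)) {
    env <- as.matrix(trainEnv[, vars, drop = FALSE])
    lo <- apply(env, 2, min); hi <- apply(env, 2, max)
    novCell <- rep(FALSE, sum(ok))
    for (j in seq_along(vars)) {
      novCell <- novCell |
        eCur[ok, j] < lo[j] | eCur[ok, j] > hi[j] |
        eFut[ok, j] < lo[j] | eFut[ok, j] > hi[j]
    }
    nov[ok] <- as.numeric(novCell)
  }
  list(offset = ClimateRaster(matrix(off, nr, nc), r0@extent,
                              crs = r0@crs, name = "offset"),
       novelty = ClimateRaster(matrix(nov, nr, nc), r0@extent,
                               crs = r0@crs, name = "novelty"))
}

#' Regress site-mean offsets on latitude
#'
#' Ordinary least squares of site-mean offset on latitude in degrees
#' south (positive southward, so a negative slope means larger offsets in
#' the north), overall or per elevation class.  Each summary carries a
#' significance tier: \code{"solid"} (p <= 0.05), \code{"dashed"}
#' (0.05 < p <= 0.1), \code{"none"} (p > 0.1).
#'
#' @param siteMeans data.frame from \code{\link{siteMeanOffsets}}
#' @param design the \code{\link{generateDesign}} design (site latitudes
#'   and elevation classes)
#' @param groupBy \code{"none"} (all sites together) or
#'   \code{"elevation_class"}
#' @return data.frame: \code{group}, \code{slope_per_degS},
#'   \code{intercept}, \code{r2}, \code{p}, \code{tier}, \code{n}
#' @export
regressOffsetLatitude <- function(siteMeans, design,
                                  groupBy = c("none", "elevation_class")) {
  groupBy <- match.arg(groupBy)
  m <- merge(siteMeans, design[, c("site_id", "latitude",
                                   "elevation_class")], by = "site_id")
  groups <- if (groupBy == "none") list(all = m)
            else split(m, m$elevation_class)
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    gm <- groups[[gname]]
    if (nrow(gm) < 3)
      stop("group '", gname, "' has fewer than 3 sites")
    degS <- -gm$latitude
    if (diff(range(degS)) < 1e-9)
      stop("degenerate regression: constant latitude in group '",
           gname, "'")
    fit <- lm(offset ~ degS, data = data.frame(offset = gm$offset,
                                               degS = degS))
    sm <- summary(fit)
    pv <- sm$coefficients["degS", "Pr(>|t|)"]
    data.frame(group = gname,
               slope_per_degS = sm$coefficients["degS", "Estimate"],
               intercept = sm$coefficients["(Intercept)", "Estimate"],
               r2 = sm$r.squared, p = pv,
               tier = if (pv <= 0.05) "solid"
                      else if (pv <= 0.1) "dashed" else "none",
               n = nrow(gm), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bin an offset raster into classes
#'
#' Monotone classification for display: higher offsets never map to a
#' lower class.  Quantile bins equalize cell counts; equal bins split the
#' value range evenly.  A constant raster yields a single class with a
#' warning under the quantile scheme.
#'
#' @param raster a \linkS4class{ClimateRaster}
#' @param nBins number of classes (>= 2; default 8)
#' @param scheme \code{"quantile"} or \code{"equal"}
#' @return list: \code{classified} (\linkS4class{ClimateRaster} of class
#'   indices) and \code{legend} (data.frame of class bounds)
#' @export
binOffsets <- function(raster, nBins = 8, scheme = c("quantile", "equal")) {
  scheme <- match.arg(scheme)
  stopifnot(nBins >= 2)
  v <- as.vector(raster@values)
  fin <- v[is.finite(v)]
  if (length(fin) == 0) stop("raster has no finite cells")
  if (diff(range(fin)) < 1e-12) {
    if (scheme == "quantile")
      warning("constant raster: single class")
    edges <- c(fin[1] - 1e-9, fin[1] + 1e-9)
  } else if (scheme == "quantile") {
    edges <- unique(quantile(fin, probs = seq(0, 1, length.out = nBins + 1)))
  } else {
    edges <- seq(min(fin), max(fin), length.out = nBins + 1)
  }
  cls <- findInterval(v, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cls[!is.finite(v)] <- NA
  legend <- data.frame(class = seq_len(length(edges) - 1),
                       lower = edges[-length(edges)], upper = edges[-1])
  list(classified = ClimateRaster(matrix(cls, nrow(raster@values),
                                         ncol(raster@values)),
                                  raster@extent, crs = raster@crs,
                                  name = paste0(raster@name, "_class")),
       legend = legend)
}
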