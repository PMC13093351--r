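#' Synthetic climate configuration
#'
#' Defines how the five climate variables — temperature isothermality
#' (\code{bio3}, \%), mean growing-season temperature (\code{gst}, deg C),
#' snow cover days (\code{scd}, days), total annual precipitation
#' (\code{bio12}, mm) and precipitation seasonality (\code{bio15}, \%) —
#' are generated over the landscape, and what the future emission
#' scenarios do to them.
#'
#' Each variable is an analytic field
#' \deqn{v(lon, lat, elev) = base + b_{lat}\,(lat - \bar{lat}) +
#'   b_{elev}\,(elev - 800) + b_{dry}\,\delta(lon, lat) + noise}
#' where \eqn{\delta} is the eastward distance from the Andes crest in
#' units of its typical site spread (the rain-shadow axis, quasi-orthogonal
#' to latitude) and the noise is a smooth random field (sum of long-wave
#' sinusoids), identical for trees and raster cells.  Temperature-type
#' variables decline southward and with elevation; precipitation-type
#' variables follow the rain-shadow axis.  The generator enforces the
#' study prerequisite that the variables be only weakly mutually
#' correlated: noise fields are redrawn (deterministically in the seed)
#' until the maximum pairwise |Pearson r| at the trees is below the
#' configured bound (0.75, inside the printed 0.77).
#'
#' Temperature scenario shifts are additive in raw units; snow-cover and
#' precipitation shifts are fractional (proportional to the local current
#' value), giving the anomaly field spatial texture.  \code{edw} adds
#' elevation-dependent warming on \code{gst}, centered on the 800 m
#' reference elevation (high elevations warm faster, low ones slower, the
#' domain mean is untouched); \code{latWarm} tilts warming toward the
#' north end of the gradient.  Severity is monotone: a more pessimistic
#' pathway warms more than a more optimistic one everywhere.
#'
#' @param variables data.frame of per-variable field coefficients; the
#'   default is described above
#' @param scenarios data.frame of per-(scenario, period) shifts; defaults
#'   define SSP 1-2.6 (optimistic), SSP 3-7.0 (moderate) and SSP 5-8.5
#'   (pessimistic) for mid-century and late-century periods
#' @param gridNrow raster rows; the grid spans the design bounding box
#'   plus a margin with square cells, so the cell size and column count
#'   are derived from the latitude span
#' @return list of class \code{"ClimateConfig"}
#' @export
climateConfig <- function(variables = NULL, scenarios = NULL,
                          gridNrow = 120) {
  if (is.null(variables)) {
    variables <- data.frame(
      variable = c("bio3", "gst", "scd", "bio12", "bio15"),
      base    = c(45,   7.5,  95,   1050,  38),
      bLat    = c(0.35, 0.85, -0.9, 8,     0.4),     # per degree northward
      bElev   = c(-0.002, -0.0045, 0.055, 0.05, 0),  # per meter above 800
      bDry    = c(0.6,  0.25, -3,   -480,  3.5),     # per crest-offset unit
      noiseSd = c(2.0,  0.5,  10,   130,   6),
      stringsAsFactors = FALSE)
  }
  if (is.null(scenarios)) {
    scenarios <- expand.grid(scenario = c("ssp126", "ssp370", "ssp585"),
                             period = c("mid", "late"),
                             stringsAsFactors = FALSE)
    sev <- match(scenarios$scenario, c("ssp126", "ssp370", "ssp585"))
    late <- scenarios$period == "late"
    ## additive shifts (raw units) for the temperature variables ...
    scenarios$d_gst   <- c(1.0, 1.7, 2.1)[sev] + ifelse(late, c(0.2, 0.9, 1.3)[sev], 0)
    scenarios$d_bio3  <- c(0.5, 0.8, 1.0)[sev] + ifelse(late, c(0.1, 0.5, 0.6)[sev], 0)
    scenarios$d_scd   <- 0
    scenarios$d_bio12 <- 0
    scenarios$d_bio15 <- 0
    ## ... and fractional anomalies for snow/precipitation regimes, so the
    ## raw change scales with the local current value (snow-day loss where
    ## there is snow, drying proportional to rainfall)
    scenarios$f_bio3  <- 0
    scenarios$f_gst   <- 0
    scenarios$f_scd   <- -(c(0.10, 0.18, 0.24)[sev] +
                             ifelse(late, c(0.04, 0.10, 0.14)[sev], 0))
    scenarios$f_bio12 <- -(c(0.03, 0.06, 0.08)[sev] +
                             ifelse(late, c(0.01, 0.03, 0.04)[sev], 0))
    scenarios$f_bio15 <- c(0.04, 0.07, 0.09)[sev] +
      ifelse(late, c(0.02, 0.04, 0.05)[sev], 0)
    scenarios$edw     <- c(4e-4, 6e-4, 8e-4)[sev]   # deg C per m, on gst
    scenarios$latWarm <- c(0.02, 0.03, 0.04)[sev]   # extra deg C per deg north
  }
  stopifnot(all(c("variable", "base", "bLat", "bElev", "bDry", "noiseSd")
                %in% colnames(variables)))
  structure(list(variables = variables, scenarios = scenarios,
                 gridNrow = gridNrow,
                 drySpread = 0.35, refElev = 800, maxAbsCor = 0.75),
            class = "ClimateConfig")
}

#' Place individual trees at sampling sites
#'
#' Trees are jittered around their site coordinates by up to ~100 m; each
#' tree inherits its site's elevation and metadata.  If \code{nTotal} is
#' given (e.g., 493 over 20 sites), trees are dropped one at a time from
#' sites in rotation so per-site counts stay near-balanced.
#'
#' @param design a \code{\link{generateDesign}} design
#' @param nPerSite trees per site (default 25)
#' @param nTotal optional total tree count (<= nPerSite * sites)
#' @param seed integer seed
#' @return data.frame: \code{tree_id}, \code{site_id}, \code{pair_id},
#'   \code{area_id}, \code{lon}, \code{lat}, \code{elevation},
#'   \code{elevation_class}
#' @export
generateTrees <- function(design, nPerSite = 25, nTotal = NULL, seed = 1) {
  withSeed(seed, {
    trees <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      s <- design[i, ]
      data.frame(site_id = s$site_id, pair_id = s$pair_id,
                 area_id = s$area_id,
                 lon = s$longitude + runif(nPerSite, -9e-4, 9e-4),
                 lat = s$latitude + runif(nPerSite, -9e-4, 9e-4),
                 elevation = s$elevation + runif(nPerSite, -15, 15),
                 elevation_class = s$elevation_class,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(nTotal)) {
      stopifnot(nTotal <= nrow(trees), nTotal >= nrow(design))
      drop <- nrow(trees) - nTotal
      if (drop > 0) {
        ## drop the last tree of successive sites in rotation
        sites <- unique(trees$site_id)
        dropIdx <- integer(0)
        r <- 1L
        while (length(dropIdx) < drop) {
          for (s in sites) {
            if (length(dropIdx) >= drop) break
            cand <- setdiff(rev(which(trees$site_id == s)), dropIdx)
            if (length(cand) > 1) dropIdx <- c(dropIdx, cand[r])
          }
          r <- r + 1L
        }
        trees <- trees[-dropIdx, ]
      }
    }
    trees$tree_id <- sprintf("tree%03d", seq_len(nrow(trees)))
    rownames(trees) <- NULL
    trees[, c("tree_id", "site_id", "pair_id", "area_id", "lon", "lat",
              "elevation", "elevation_class")]
  })
}

## Smooth random field: sum of nWaves long-wavelength sinusoids over
## (lon, lat).  Returned as a closure so trees and raster cells see the
## identical surface.
smoothField <- function(sdTarget, nWaves = 4) {
  amp <- sdTarget / sqrt(nWaves / 2)
  wl <- runif(nWaves, 1.5, 4)          # wavelength, degrees
  th <- runif(nWaves, 0, pi)           # orientation
  ph <- runif(nWaves, 0, 2 * pi)
  fx <- cos(th) / wl; fy <- sin(th) / wl
  function(lon, lat) {
    z <- 0
    for (w in seq_len(nWaves))
      z <- z + amp * sin(2 * pi * (fx[w] * lon + fy[w] * lat) + ph[w])
    z
  }
}

## Analytic elevation surface: the design's latitudinal base-elevation
## trend plus an Andes ridge in longitude and smooth bumps.  Site pairs sit
## below raster resolution, so their elevation contrast is deliberately
## not resolvable in this surface.
elevationSurface <- function(design, seed) {
  withSeed(seed + 7L, {
    bump <- smoothField(120)
    latMid <- mean(range(design$latitude))
    slope <- if (nrow(design) > 1)
      coef(lm(elevation ~ latitude, design))[2] else 0
    base <- mean(design$elevation)
    function(lon, lat) {
      ridge <- 900 * exp(-((lon - crestLongitude(lat)) / 0.9)^2)
      pmax(base + slope * (lat - latMid) - 350 + ridge + bump(lon, lat), 0)
    }
  })
}

#' Generate current climate at trees and on a raster grid
#'
#' Evaluates the configured climate fields (i) at each tree position using
#' the tree's true elevation and (ii) on a raster grid over the design
#' bounding box using a smooth analytic elevation surface.  Because site
#' pairs lie below raster resolution, raster cells carry the smoothed
#' landscape elevation while trees carry their real one — emulating the
#' topographic mismatch of coarse climate grids.
#'
#' @param design a \code{\link{generateDesign}} design
#' @param trees a \code{\link{generateTrees}} table
#' @param cfg a \code{\link{climateConfig}}
#' @param seed integer seed (controls the smooth noise fields)
#' @return list: \code{trees} (per-tree climate data.frame, one column per
#'   variable plus tree metadata), \code{rasters} (current
#'   \linkS4class{ClimateRasterSet}), \code{elevation} (the
#'   \linkS4class{ClimateRaster} elevation surface used by the grid)
#' @export
generateClimate <- function(design, trees, cfg = climateConfig(),
                            seed = 1) {
  stopifnot(inherits(cfg, "ClimateConfig"))
  latMid <- mean(range(design$latitude))
  elevFun <- elevationSurface(design, seed)
  ## rain-shadow axis in units of the realized site spread, so the dry
  ## gradient's variance at sampled positions is stable across designs
  dryScale <- sd(design$longitude - crestLongitude(design$latitude))
  if (!is.finite(dryScale) || dryScale < 1e-6) dryScale <- cfg$drySpread
  vars <- cfg$variables$variable

  mkValueAt <- function(fields) function(v, lon, lat, elev) {
    p <- cfg$variables[cfg$variables$variable == v, ]
    dry <- (lon - crestLongitude(lat)) / dryScale
    p$base + p$bLat * (lat - latMid) + p$bElev * (elev - cfg$refElev) +
      p$bDry * dry + fields[[v]](lon, lat)
  }

  ## The study's variable set was chosen subject to a low mutual
  ## correlation prerequisite; the generator enforces the same config
  ## invariant.  With only ~20 distinct site positions, two smooth noise
  ## fields can correlate strongly by chance, so noise fields are redrawn
  ## (deterministically in the seed) until the bound holds at the trees.
  ## with very few sites a sample correlation over site positions is
  ## meaningless, so the prerequisite is only enforced for designs of the
  ## study's order (>= 10 sites)
  maxAttempt <- if (nrow(design) >= 10 &&
                    any(cfg$variables$noiseSd > 0)) 24L else 0L
  valueAt <- NULL
  treeClim <- trees
  for (attempt in 0:maxAttempt) {
    fields <- withSeed(seed + 7919L * attempt, {
      f <- lapply(seq_len(nrow(cfg$variables)), function(i)
        smoothField(cfg$variables$noiseSd[i]))
      names(f) <- vars
      f
    })
    valueAt <- mkValueAt(fields)
    for (v in vars)
      treeClim[[v]] <- valueAt(v, trees$lon, trees$lat, trees$elevation)
    if (maxAttempt == 0L) break
    C <- suppressWarnings(cor(as.matrix(treeClim[, vars])))
    mc <- max(abs(C[upper.tri(C)]))
    if (!is.finite(mc) || mc < cfg$maxAbsCor) break
    if (attempt == maxAttempt)
      stop("could not satisfy the pairwise climate-correlation bound ",
           cfg$maxAbsCor, " for this design; adjust the configuration")
  }

  ## raster grid: design bbox + half-degree margin; square cells sized
  ## by the latitude span / gridNrow, column count derived
  mx <- 0.5
  ext <- c(min(design$longitude) - mx, max(design$longitude) + mx,
           min(design$latitude) - mx, max(design$latitude) + mx)
  nr <- cfg$gridNrow
  cell <- (ext[4] - ext[3]) / nr
  nc <- max(2L, ceiling((ext[2] - ext[1]) / cell))
  ext[2] <- ext[1] + nc * cell
  cx <- ext[1] + (seq_len(nc) - 0.5) * (ext[2] - ext[1]) / nc
  cy <- ext[4] - (seq_len(nr) - 0.5) * (ext[4] - ext[3]) / nr
  lonG <- matrix(cx, nr, nc, byrow = TRUE)
  latG <- matrix(cy, nr, nc)
  elevG <- elevFun(lonG, latG)
  rasters <- lapply(vars, function(v)
    ClimateRaster(valueAt(v, lonG, latG, elevG), ext, name = v))
  names(rasters) <- vars
  list(trees = treeClim,
       rasters = ClimateRasterSet(rasters, scenario = "current"),
       elevation = ClimateRaster(elevG, ext, name = "elevation"))
}

#' Shift current climate to a future scenario
#'
#' Applies the configured additive per-variable shifts for one
#' (scenario, period) cell of the SSP x period grid, plus
#' elevation-dependent warming (\code{edw * elevation} added to the
#' \code{gst} shift) and a latitudinal warming gradient.  Works on a
#' per-tree climate table (uses its \code{elevation}/\code{lat} columns)
#' or on a \linkS4class{ClimateRasterSet} (requires the \code{elevation}
#' raster).  An all-zero scenario row returns the input unchanged.
#'
#' @param x per-tree climate data.frame or a current
#'   \linkS4class{ClimateRasterSet}
#' @param scenario scenario name, e.g. \code{"ssp370"}
#' @param period \code{"mid"} or \code{"late"}
#' @param cfg a \code{\link{climateConfig}}
#' @param elevation the elevation \linkS4class{ClimateRaster} (raster-set
#'   input only)
#' @return object of the same type, scenario-tagged
#' @export
generateFuture <- function(x, scenario, period = "mid",
                           cfg = climateConfig(), elevation = NULL) {
  sc <- cfg$scenarios
  row <- sc[sc$scenario == scenario & sc$period == period, ]
  if (nrow(row) != 1L)
    stop("unknown scenario '", scenario, "' / period '", period,
         "'; defined: ",
         paste(unique(paste(sc$scenario, sc$period, sep = ":")),
               collapse = ", "))
  vars <- cfg$variables$variable
  pick <- function(prefix)
    setNames(vapply(vars, function(v) {
      cn <- paste0(prefix, v)
      if (cn %in% colnames(row)) as.numeric(row[[cn]]) else 0
    }, numeric(1)), vars)
  shift <- pick("d_")
  frac <- pick("f_")
  if (is.null(row$edw)) row$edw <- 0
  if (is.null(row$latWarm)) row$latWarm <- 0

  if (is.data.frame(x)) {
    stopifnot(all(c("elevation", "lat") %in% colnames(x)))
    latMid <- mean(range(x$lat))
    for (v in vars) {
      dv <- shift[[v]] + frac[[v]] * x[[v]]
      if (v == "gst")
        dv <- dv + row$edw * (x$elevation - cfg$refElev) +
          row$latWarm * (x$lat - latMid)
      x[[v]] <- x[[v]] + dv
    }
    attr(x, "scenario") <- paste(scenario, period, sep = "_")
    x
  } else if (is(x, "ClimateRasterSet")) {
    if (is.null(elevation))
      stop("raster-set input requires the elevation raster")
    rs <- x@rasters
    e0 <- rs[[1]]@extent
    nrg <- nrow(rs[[1]]@values); ncg <- ncol(rs[[1]]@values)
    latG <- matrix(e0[4] - (seq_len(nrg) - 0.5) * (e0[4] - e0[3]) / nrg,
                   nrg, ncg)
    latMid <- mean(range(latG))
    for (v in vars) {
      dv <- shift[[v]] + frac[[v]] * rs[[v]]@values
      if (v == "gst")
        dv <- dv + row$edw * (elevation@values - cfg$refElev) +
          row$latWarm * (latG - latMid)
      rs[[v]]@values <- rs[[v]]@values + dv
    }
    new("ClimateRasterSet", rasters = rs,
        scenario = paste(scenario, period, sep = "_"))
  } else stop("unsupported input type")
}
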