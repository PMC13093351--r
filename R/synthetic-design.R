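#' Generate a paired elevation-site sampling design
#'
#' Emulates a paired-site design along a southern-Andes latitudinal
#' gradient: pairs of sites a short linear distance apart but separated in
#' elevation, so that climatic distance is maximized while neutral genetic
#' distance is minimized.  Within-pair linear distance is drawn from a
#' scaled Beta distribution on [0.6, 2.2] km with mean 1.1 km, and the
#' within-pair elevation difference from a scaled Beta on [150, 320] m with
#' mean 230 m.  Sites are numbered north to south (site 1 northernmost) and
#' pair base elevations decline southward (northern populations grow at
#' higher elevations), reproducing the elevation-latitude autocorrelation
#' of the study region; set \code{elevLatSlope = 0} to switch that
#' confounding off.
#'
#' Sampling areas group sites geographically: each pair forms one area,
#' except the southernmost pair whose two sites fall in distinct areas, so
#' the default 10-pair design yields 11 areas over 20 sites.  Ungrouped
#' sites each form their own area.
#'
#' @param nPairs number of site pairs (>= 1)
#' @param nUngrouped number of additional unpaired sites
#' @param latitudeRange length-2 numeric, northern and southern limits in
#'   signed degrees (negative = south), within [-56, -36]
#' @param elevLatSlope meters of pair base elevation gained per degree of
#'   latitude northward (default 70; 0 disables the autocorrelation)
#' @param seed integer seed; the design is a pure function of the
#'   arguments and the seed
#' @return a \code{data.frame} of class \code{"SamplingDesign"} with
#'   columns \code{site_id}, \code{pair_id} (NA for ungrouped),
#'   \code{area_id}, \code{latitude}, \code{longitude}, \code{elevation},
#'   \code{elevation_class} (\code{"high"}/\code{"low"} within pairs,
#'   \code{"ungrouped"} otherwise)
#' @examples
#' d <- generateDesign(nPairs = 10, seed = 42)
#' nrow(d)   # 20 sites
#' @export
generateDesign <- function(nPairs = 10, nUngrouped = 0,
                           latitudeRange = c(-40, -55),
                           elevLatSlope = 70, seed = 1) {
  stopifnot(nPairs >= 1, nUngrouped >= 0)
  lr <- sort(as.numeric(latitudeRange), decreasing = TRUE)  # north first
  if (lr[1] > -36 || lr[2] < -56)
    stop("latitudeRange must lie within [-56, -36] degrees")
  span <- lr[1] - lr[2]
  ## pair centers must be far enough apart that a 2.2 km member offset
  ## (~0.02 degrees) can never break the strict north-to-south ordering
  nLoc <- nPairs + nUngrouped
  if (span / max(nLoc, 1) < 0.06)
    stop("infeasible geometry: latitude range too narrow for ", nLoc,
         " locations with 2.2 km pair separations")

  withSeed(seed, {
    ## location centers, jittered around an even north-to-south spread
    latc <- seq(lr[1], lr[2], length.out = nLoc + 2)[-c(1, nLoc + 2)]
    gap <- span / (nLoc + 1)
    latc <- sort(latc + runif(nLoc, -0.2, 0.2) * gap, decreasing = TRUE)
    ## Andes crest drifts east as it runs south
    crest <- crestLongitude(latc)
    lonc <- crest + rnorm(nLoc, 0, 0.35)
    pairIdx <- seq_len(nPairs)
    rows <- list()
    sid <- 0L
    for (i in seq_len(nLoc)) {
      paired <- i <= nPairs
      baseElev <- pmax(150, 650 + elevLatSlope * (latc[i] - mean(lr)) +
                         rnorm(1, 0, 90))
      if (paired) {
        distKm <- 0.6 + 1.6 * rbeta(1, 2, 4.4)      # mean 1.1 km
        dElev <- 150 + 170 * rbeta(1, 2, 2.25)      # mean 230 m
        bearing <- runif(1, 0, 360)
        p1 <- geosphere::destPoint(c(lonc[i], latc[i]), bearing,
                                   distKm * 500)
        p2 <- geosphere::destPoint(c(lonc[i], latc[i]), bearing - 180,
                                   distKm * 500)
        highFirst <- runif(1) < 0.5
        mem <- list(
          list(lon = p1[1], lat = p1[2],
               elev = baseElev + if (highFirst) dElev / 2 else -dElev / 2,
               class = if (highFirst) "high" else "low"),
          list(lon = p2[1], lat = p2[2],
               elev = baseElev + if (highFirst) -dElev / 2 else dElev / 2,
               class = if (highFirst) "low" else "high"))
        ## site ids run north to south, also within the pair
        ord <- order(vapply(mem, `[[`, numeric(1), "lat"),
                     decreasing = TRUE)
        for (m in mem[ord]) {
          sid <- sid + 1L
          rows[[sid]] <- data.frame(
            site_id = sid, pair_id = i, area_id = NA_integer_,
            latitude = m$lat, longitude = m$lon, elevation = m$elev,
            elevation_class = m$class, stringsAsFactors = FALSE)
        }
      } else {
        sid <- sid + 1L
        rows[[sid]] <- data.frame(
          site_id = sid, pair_id = NA_integer_, area_id = NA_integer_,
          latitude = latc[i], longitude = lonc[i], elevation = baseElev,
          elevation_class = "ungrouped", stringsAsFactors = FALSE)
      }
    }
    design <- do.call(rbind, rows)
    design$area_id <- assignAreas(design, nPairs)
    rownames(design) <- NULL
    validateDesign(design)
    class(design) <- c("SamplingDesign", "data.frame")
    design
  })
}

## Longitude of the Andes crest as a function of latitude: ~ -71.4 at 40S
## drifting east to ~ -68.4 at 55S.
crestLongitude <- function(lat) -71.4 + 0.2 * (-lat - 40)

assignAreas <- function(design, nPairs) {
  area <- integer(nrow(design))
  nextArea <- 0L
  for (p in seq_len(nPairs)) {
    idx <- which(design$pair_id == p)
    if (p == nPairs && nPairs > 1) {
      ## southernmost pair splits into two areas (11 areas for 20 sites)
      for (j in idx) { nextArea <- nextArea + 1L; area[j] <- nextArea }
    } else {
      nextArea <- nextArea + 1L
      area[idx] <- nextArea
    }
  }
  for (j in which(is.na(design$pair_id))) {
    nextArea <- nextArea + 1L
    area[j] <- nextArea
  }
  area
}

validateDesign <- function(design) {
  if (any(diff(design$latitude) >= 0))
    stop("infeasible geometry: site latitudes not strictly ordered ",
         "north to south")
  for (p in unique(stats::na.omit(design$pair_id))) {
    m <- design[!is.na(design$pair_id) & design$pair_id == p, ]
    if (nrow(m) != 2L || !setequal(m$elevation_class, c("high", "low")))
      stop("infeasible geometry: pair ", p,
           " lacks exactly one high and one low site")
    d <- greatCircleKm(m$longitude[1], m$latitude[1],
                       m$longitude[2], m$latitude[2])
    if (d < 0.6 - 1e-6 || d > 2.2 + 1e-6)
      stop("infeasible geometry: pair ", p, " distance ", round(d, 3),
           " km outside [0.6, 2.2]")
    dz <- abs(diff(m$elevation))
    if (dz < 150 - 1e-6 || dz > 320 + 1e-6)
      stop("infeasible geometry: pair ", p, " elevation difference ",
           round(dz, 1), " m outside [150, 320]")
  }
  invisible(design)
}

#' Summarize within-pair geometry of a design
#'
#' @param design a design from \code{\link{generateDesign}}
#' @return data.frame with one row per pair: \code{pair_id},
#'   \code{distance_km} (great-circle) and \code{delta_elevation_m}
#' @export
pairGeometry <- function(design) {
  pid <- sort(unique(stats::na.omit(design$pair_id)))
  do.call(rbind, lapply(pid, function(p) {
    m <- design[!is.na(design$pair_id) & design$pair_id == p, ]
    data.frame(pair_id = p,
               distance_km = greatCircleKm(m$longitude[1], m$latitude[1],
                                           m$longitude[2], m$latitude[2]),
               delta_elevation_m = abs(diff(m$elevation)))
  }))
}
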