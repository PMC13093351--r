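mkRaster <- function(f, ext = c(-72, -68, -50, -44), nr = 24, nc = 16) {
  cx <- ext[1] + (seq_len(nc) - 0.5) * (ext[2] - ext[1]) / nc
  cy <- ext[4] - (seq_len(nr) - 0.5) * (ext[4] - ext[3]) / nr
  ClimateRaster(outer(cy, cx, function(y, x) f(x, y) + 0 * x + 0 * y), ext)
}

test_that("bilinear extraction obeys its defining identities", {
  ## constant field
  rc <- mkRaster(function(x, y) 7)
  expect_equal(bilinearExtract(rc, data.frame(lon = -70.3, lat = -47.1))$value, 7)
  ## 2x2 neighborhood (0,0 / 2,2), point equidistant from all four centers
  r2 <- ClimateRaster(matrix(c(0, 2, 0, 2), 2, 2), c(0, 2, 0, 2))
  expect_equal(bilinearExtract(r2, data.frame(lon = 1, lat = 1))$value, 1)
  ## cell-center identity
  ra <- mkRaster(function(x, y) sin(x) + y^2)
  ext <- rasterExtent(ra)
  cx <- ext[1] + (5 - 0.5) * (ext[2] - ext[1]) / ncol(rasterValues(ra))
  cy <- ext[4] - (3 - 0.5) * (ext[4] - ext[3]) / nrow(rasterValues(ra))
  expect_equal(bilinearExtract(ra, data.frame(lon = cx, lat = cy))$value,
               rasterValues(ra)[3, 5])
})

test_that("bilinear extraction is exact for affine surfaces and matches the oracle", {
  f <- function(x, y) 2 + 3 * x - 1.5 * y
  r <- mkRaster(f)
  ext <- r@extent
  set.seed(42)
  pts <- data.frame(lon = runif(100, ext[1] + 0.2, ext[2] - 0.2),
                    lat = runif(100, ext[3] + 0.2, ext[4] - 0.2))
  got <- bilinearExtract(r, pts)
  expect_true(all(got$flag == "ok"))
  expect_lt(max(abs(got$value - f(pts$lon, pts$lat))), 1e-9)
  ## non-affine surface against the brute-force four-neighbor oracle
  rb <- mkRaster(function(x, y) cos(2 * x) * y)
  want <- vapply(seq_len(nrow(pts)), function(i)
    oracleBilinear(rasterValues(rb), rb@extent, pts$lon[i], pts$lat[i]),
    numeric(1))
  expect_equal(bilinearExtract(rb, pts)$value, want, tolerance = 1e-12)
})

test_that("failed points carry error records, not silent NaN", {
  r <- mkRaster(function(x, y) 1)
  out <- bilinearExtract(r, data.frame(lon = c(-70, 10), lat = c(-47, -47)))
  expect_equal(out$flag, c("ok", "outside"))
  expect_true(is.na(out$value[2]))
  v <- rasterValues(r)
  v[10, 8] <- NA
  rn <- ClimateRaster(v, r@extent)
  ext <- r@extent
  px <- ext[1] + (8 - 0.3) * (ext[2] - ext[1]) / ncol(v)
  py <- ext[4] - (10 - 0.3) * (ext[4] - ext[3]) / nrow(v)
  out2 <- bilinearExtract(rn, data.frame(lon = px, lat = py))
  expect_equal(out2$flag, "nodata")
  expect_true(is.na(out2$value))
})

test_that("ensemble mean is the cell-wise mean with nodata propagation", {
  base <- mkRaster(function(x, y) x + y)
  members <- lapply(1:5, function(i) {
    r <- base
    r@values <- r@values + i    # cell values v+1 .. v+5 -> mean v+3
    r
  })
  m <- ensembleMean(members)
  expect_equal(rasterValues(m), rasterValues(base) + 3)
  ## idempotence on identical members
  same <- ensembleMean(list(base, base, base, base, base))
  expect_equal(rasterValues(same), rasterValues(base))
  ## nodata in one member poisons the cell
  members[[2]]@values[4, 4] <- NA
  m2 <- ensembleMean(members)
  expect_true(is.na(rasterValues(m2)[4, 4]))
  expect_equal(sum(is.na(rasterValues(m2))), 1)
  ## misaligned grids are refused
  off <- ClimateRaster(rasterValues(base), base@extent + c(0, 0, 1, 1))
  expect_error(ensembleMean(list(base, off)), "not aligned")
})

test_that("ensemble mean commutes with extraction", {
  set.seed(7)
  members <- lapply(1:5, function(i)
    mkRaster(function(x, y) sin(i * x) + cos(y) + i))
  pts <- data.frame(lon = runif(20, -71.8, -68.2),
                    lat = runif(20, -49.8, -44.2))
  direct <- bilinearExtract(ensembleMean(members), pts)$value
  averaged <- rowMeans(vapply(members, function(r)
    bilinearExtract(r, pts)$value, numeric(20)))
  expect_equal(direct, averaged, tolerance = 1e-12)
})

test_that("the training scaler enforces the train-time contract", {
  set.seed(1)
  tab <- data.frame(gst = rnorm(50, 8, 2), bio12 = rnorm(50, 900, 200))
  sc <- fitScaler(tab)
  scaled <- applyScaler(sc, tab)
  expect_lt(max(abs(colMeans(scaled))), 1e-10)
  expect_lt(max(abs(apply(scaled, 2, sd) - 1)), 1e-10)
  ## a future table shifted +2 training-sd has scaled mean exactly 2
  fut <- tab
  fut$gst <- fut$gst + 2 * sd(tab$gst)
  expect_equal(mean(applyScaler(sc, fut)$gst), 2, tolerance = 1e-10)
  ## zero variance is an error
  expect_error(fitScaler(data.frame(gst = rep(1, 5))), "zero-variance")
})

test_that("the scaler round-trips through its JSON sidecar", {
  sc <- fitScaler(data.frame(a = rnorm(20), b = runif(20, 5, 9)))
  p <- tempfile(fileext = ".json")
  writeScaler(sc, p)
  sc2 <- readScaler(p)
  expect_equal(sc@center, sc2@center)
  expect_equal(sc@scale, sc2@scale)
})

test_that("raster sets scale with training statistics and round-trip .asc", {
  s <- defaultSynth()
  scaled <- applyScaler(s$scaler, s$clim$rasters)
  v <- "gst"
  want <- (rasterValues(s$clim$rasters[[v]]) - s$scaler@center[[v]]) /
    s$scaler@scale[[v]]
  expect_equal(rasterValues(scaled[[v]]), want)
  p <- tempfile(fileext = ".asc")
  r <- s$clim$rasters[[v]]
  writeAsciiGrid(r, p)
  r2 <- readAsciiGrid(p, name = v)
  expect_equal(rasterValues(r2), rasterValues(r), tolerance = 1e-7)
  expect_equal(r2@extent, r@extent, tolerance = 1e-9)
})
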