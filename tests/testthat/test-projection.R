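scaledScenario <- function(scenario = "ssp370", period = "mid") {
  s <- defaultSynth()
  cur <- applyScaler(s$scaler, s$clim$rasters)
  futR <- generateFuture(s$clim$rasters, scenario, period,
                         elevation = s$clim$elevation)
  list(cur = cur, fut = applyScaler(s$scaler, futR),
       mask = rangeMask(s$clim$elevation), elev = s$clim$elevation)
}

test_that("projection of an unchanged climate is a zero raster in the mask", {
  s <- defaultSynth()
  f <- defaultFit()
  cur <- applyScaler(s$scaler, s$clim$rasters)
  proj <- projectOffsets(f$model, cur, cur, mask = rangeMask(s$clim$elevation),
                         trainEnv = s$E, candidates = f$candidates)
  v <- rasterValues(proj$offset)
  mk <- rasterValues(rangeMask(s$clim$elevation)) == 1
  expect_lt(max(v[mk]), 1e-20)
  expect_true(all(is.na(v[!mk])))
})

test_that("raster projection equals the direct per-vector computation", {
  s <- defaultSynth()
  f <- defaultFit()
  sc <- scaledScenario()
  pred <- cbind(s$E, setNames(as.data.frame(f$model@U), paste0("U", 1:3)))
  tv <- fitTurnover(f$g, pred, candidates = f$candidates[1:25],
                    ntree = 30, seed = 5)
  for (model in list(f$model, tv)) {
    proj <- projectOffsets(model, sc$cur, sc$fut, mask = sc$mask,
                           trainEnv = s$E,
                           candidates = if (is(model, "LatentFactorModel"))
                             f$candidates else NULL)
    vars <- if (is(model, "LatentFactorModel")) model@variables
            else model@climatePredictors
    ## check a handful of in-mask cells cell-by-cell
    mk <- which(rasterValues(sc$mask) == 1 &
                  !is.na(rasterValues(proj$offset)))[c(1, 50, 200)]
    for (i in mk) {
      eC <- vapply(vars, function(v) rasterValues(sc$cur[[v]])[i],
                   numeric(1))
      eF <- vapply(vars, function(v) rasterValues(sc$fut[[v]])[i],
                   numeric(1))
      want <- if (is(model, "LatentFactorModel"))
        geneticGap(model, eC, eF, candidates = f$candidates)
      else gfOffset(model, setNames(as.data.frame(as.list(eC)), vars),
                    setNames(as.data.frame(as.list(eF)), vars))
      expect_equal(rasterValues(proj$offset)[i], want, tolerance = 1e-12)
    }
    ## novelty flags exist and are 0/1 inside the mask
    nv <- rasterValues(proj$novelty)
    expect_true(all(nv[!is.na(nv)] %in% c(0, 1)))
  }
})

test_that("degenerate projection inputs are refused or warned about", {
  s <- defaultSynth()
  f <- defaultFit()
  sc <- scaledScenario()
  empty <- ClimateRaster(matrix(0, nrow(rasterValues(sc$mask)),
                                ncol(rasterValues(sc$mask))),
                         sc$mask@extent)
  expect_warning(projectOffsets(f$model, sc$cur, sc$fut, mask = empty,
                                candidates = f$candidates),
                 "no unmasked")
  small <- ClimateRasterSet(list(bio3 = ClimateRaster(matrix(0, 2, 2),
                                                      c(0, 1, 0, 1))))
  expect_error(projectOffsets(f$model, sc$cur,
                              ClimateRasterSet(sapply(climVars, function(v)
                                ClimateRaster(matrix(0, 2, 2), c(0, 1, 0, 1)),
                                simplify = FALSE)),
                              candidates = f$candidates),
               "misaligned")
})

test_that("elevation-dependent warming concentrates offsets at high elevation", {
  s <- defaultSynth()
  f <- defaultFit()
  sc <- scaledScenario("ssp585", "late")
  proj <- projectOffsets(f$model, sc$cur, sc$fut, mask = sc$mask,
                         trainEnv = s$E, candidates = f$candidates)
  off <- rasterValues(proj$offset)
  elev <- rasterValues(s$clim$elevation)
  ok <- !is.na(off)
  qs <- quantile(elev[ok], c(0.25, 0.75))
  expect_gt(mean(off[ok & elev >= qs[2]]), mean(off[ok & elev <= qs[1]]))
})

test_that("latitude regressions match the closed-form OLS oracle", {
  d <- generateDesign(nPairs = 10, seed = 1)
  ## perfectly collinear fixture
  smPerfect <- data.frame(site_id = d$site_id,
                          offset = 3 - 0.2 * d$latitude)
  reg <- suppressWarnings(regressOffsetLatitude(smPerfect, d, "none"))
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  expect_equal(reg$slope_per_degS, 0.2, tolerance = 1e-9)
  ## 5-point fixture vs normal equations
  d5 <- d[1:5, ]
  set.seed(20)
  sm5 <- data.frame(site_id = d5$site_id, offset = rnorm(5, 2, 0.5))
  reg5 <- regressOffsetLatitude(sm5, d5, "none")
  x <- -d5$latitude; y <- sm5$offset
  Sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / Sxx
  alpha <- mean(y) - beta * mean(x)
  res <- y - alpha - beta * x
  se <- sqrt(sum(res^2) / 3 / Sxx)
  tstat <- beta / se
  expect_lt(abs(reg5$slope_per_degS - beta), 1e-10)
  expect_lt(abs(reg5$intercept - alpha), 1e-10)
  expect_lt(abs(reg5$r2 - cor(x, y)^2), 1e-10)
  expect_lt(abs(reg5$p - 2 * pt(-abs(tstat), 3)), 1e-12)
})

test_that("significance tiers follow the plotting convention", {
  d <- generateDesign(nPairs = 10, seed = 1)
  set.seed(30)
  tiers <- character(0); ps <- numeric(0)
  for (noise in c(0.05, 0.6, 3, 10, 40)) {
    sm <- data.frame(site_id = d$site_id,
                     offset = 5 - 0.3 * d$latitude + rnorm(20, 0, noise))
    reg <- regressOffsetLatitude(sm, d, "none")
    tiers <- c(tiers, reg$tier); ps <- c(ps, reg$p)
  }
  want <- ifelse(ps <= 0.05, "solid", ifelse(ps <= 0.1, "dashed", "none"))
  expect_equal(tiers, want)
  expect_true(all(c("solid", "none") %in% tiers))
  ## grouped regression and degenerate input
  sm <- data.frame(site_id = d$site_id, offset = seq_len(20))
  regs <- regressOffsetLatitude(sm, d, "elevation_class")
  expect_setequal(regs$group, c("high", "low"))
  dConst <- d; dConst$latitude <- -45
  expect_error(regressOffsetLatitude(sm, dConst, "none"), "degenerate")
})

test_that("offset binning is monotone with faithful legends", {
  r <- ClimateRaster(matrix(1:8, 2, 4), c(0, 4, 0, 2))
  got <- binOffsets(r, nBins = 4, scheme = "equal")
  expect_equal(sort(as.vector(rasterValues(got$classified))),
               rep(1:4, each = 2))
  v <- as.vector(rasterValues(r))
  cls <- as.vector(rasterValues(got$classified))
  expect_true(all(diff(cls[order(v)]) >= 0))
  expect_equal(nrow(got$legend), 4)
  ## constant raster: single class with warning
  rc <- ClimateRaster(matrix(2, 3, 3), c(0, 3, 0, 3))
  expect_warning(gotc <- binOffsets(rc, 4, "quantile"), "single class")
  expect_equal(unique(as.vector(rasterValues(gotc$classified))), 1)
  ## quantile scheme balances counts
  set.seed(2)
  rq <- ClimateRaster(matrix(runif(64), 8, 8), c(0, 8, 0, 8))
  gq <- binOffsets(rq, 8, "quantile")
  expect_true(all(table(rasterValues(gq$classified)) == 8))
})
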