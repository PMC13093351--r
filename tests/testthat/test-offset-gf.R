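## Hand-made turnover model: two climate predictors with known curves.
handModel <- function() {
  new("TurnoverModel",
      predictors = c("a", "b", "U1"),
      climatePredictors = c("a", "b"),
      binEdges = list(a = seq(0, 10, length.out = 6),
                      b = seq(0, 10, length.out = 6),
                      U1 = seq(-1, 1, length.out = 6)),
      cumImportance = list(a = c(1, 2, 3, 4, 5),
                           b = c(2, 4, 6, 8, 10),
                           U1 = c(0.1, 0.2, 0.3, 0.4, 0.5)),
      r2 = c(snpA = 0.5),
      hyperparams = list(ntree = 1, mtry = 1, minLeaf = 5, nbins = 5,
                         seed = 1))
}

gfPredictors <- function() {
  s <- defaultSynth()
  f <- defaultFit()
  cbind(s$E, setNames(as.data.frame(f$model@U), paste0("U", 1:3)))
}

test_that("turnover functions are nondecreasing from zero to total importance", {
  s <- defaultSynth()
  f <- defaultFit()
  pred <- gfPredictors()
  tv <- fitTurnover(f$g, pred, candidates = f$candidates[1:30],
                    ntree = 50, seed = 5)
  tot <- totalImportance(tv)
  for (p in tv@predictors) {
    grid <- seq(tv@binEdges[[p]][1] - 1,
                tv@binEdges[[p]][length(tv@binEdges[[p]])] + 1,
                length.out = 300)
    Fp <- transformEnv(tv, setNames(data.frame(grid), p), predictors = p)
    expect_true(all(diff(Fp[, 1]) >= -1e-12))
    expect_equal(unname(Fp[1, 1]), 0)
    expect_equal(unname(Fp[300, 1]), unname(tot[p]))
  }
})

test_that("pure-noise responses carry almost no climate importance", {
  s <- defaultSynth()
  pred <- gfPredictors()
  n <- nrow(pred)
  set.seed(8)
  noise <- matrix(rbinom(n * 25, 2, 0.5), n)
  colnames(noise) <- sprintf("noise%02d", 1:25)
  signal <- vapply(1:25, function(i)
    rbinom(n, 2, plogis(3 * pred$gst)), numeric(n))
  colnames(signal) <- sprintf("sig%02d", 1:25)
  tn <- fitTurnover(noise, pred, ntree = 100, seed = 1)
  ts <- fitTurnover(signal, pred, ntree = 100, seed = 1)
  cn <- sum(totalImportance(tn)[climVars])
  cs <- sum(totalImportance(ts)[climVars])
  expect_lt(cn, 0.05 * cs)
  ## signal attribution: the driver carries the largest climate importance
  expect_equal(names(which.max(totalImportance(ts)[climVars])), "gst")
})

test_that("fitting is deterministic and the model serializes losslessly", {
  s <- defaultSynth()
  f <- defaultFit()
  pred <- gfPredictors()
  a <- fitTurnover(f$g, pred, candidates = f$candidates[1:10],
                   ntree = 30, seed = 7)
  b <- fitTurnover(f$g, pred, candidates = f$candidates[1:10],
                   ntree = 30, seed = 7)
  expect_identical(a@cumImportance, b@cumImportance)
  expect_identical(a@r2, b@r2)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  writeTurnoverModel(a, p1)
  writeTurnoverModel(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  a2 <- readTurnoverModel(p1)
  expect_equal(a2@cumImportance, a@cumImportance)
  expect_equal(a2@binEdges, a@binEdges)
  expect_equal(unname(a2@r2), unname(a@r2))
})

test_that("turnover transforms clamp to the training plateau", {
  m <- handModel()
  ## at the training minimum every coordinate is 0
  lo <- transformEnv(m, data.frame(a = 0, b = 0))
  expect_equal(unname(lo[1, ]), c(0, 0))
  ## beyond the maximum: the plateau (total importance)
  hi <- transformEnv(m, data.frame(a = 99, b = 99))
  expect_equal(unname(hi[1, ]), c(5, 10))
  ## 50 random points against direct step-function evaluation
  set.seed(9)
  x <- data.frame(a = runif(50, -2, 12), b = runif(50, -2, 12))
  got <- transformEnv(m, x)
  stepEval <- function(edges, ci, v) {
    i <- findInterval(v, edges)
    i <- pmin(pmax(i - 1L, 0L), length(ci))
    c(0, ci)[i + 1L]
  }
  expect_equal(got[, "a"], stepEval(m@binEdges$a, m@cumImportance$a, x$a))
  expect_equal(got[, "b"], stepEval(m@binEdges$b, m@cumImportance$b, x$b))
  expect_error(transformEnv(m, x, predictors = "zz"), "unknown predictor")
})

test_that("gf offset is a Euclidean distance over climate coordinates only", {
  m <- handModel()
  e0 <- data.frame(a = 0, b = 0, U1 = 0)
  expect_equal(gfOffset(m, e0, e0), 0)
  ## coordinate differences (3, 4) -> distance 5
  eC <- data.frame(a = 0, b = 0)
  eF <- data.frame(a = 7, b = 5)   # F_a: 0 -> 3, F_b: 0 -> 4
  expect_equal(unname(transformEnv(m, eF)[1, ] - transformEnv(m, eC)[1, ]),
               c(3, 4))
  expect_equal(gfOffset(m, eC, eF), 5)
  ## perturbing only the confounder leaves the offset unchanged
  eFU <- cbind(eF, U1 = 0.9)
  eCU <- cbind(eC, U1 = -0.9)
  expect_equal(gfOffset(m, eCU, eFU), 5)
})

test_that("the turnover distance behaves like a metric", {
  m <- handModel()
  set.seed(10)
  for (rep in 1:25) {
    x <- data.frame(a = runif(3, -1, 11), b = runif(3, -1, 11))
    dxy <- gfOffset(m, x[1, ], x[2, ])
    dyz <- gfOffset(m, x[2, ], x[3, ])
    dxz <- gfOffset(m, x[1, ], x[3, ])
    expect_gte(dxy, 0)
    expect_equal(dxy, gfOffset(m, x[2, ], x[1, ]))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
})
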