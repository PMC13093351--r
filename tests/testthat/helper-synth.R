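## Shared synthetic dataset (the generator's default study conditions),
## built once per test run.  Chain of seeds 1..4 is the package's
## documented default dataset.

climVars <- c("bio3", "gst", "scd", "bio12", "bio15")

.synthCache <- new.env(parent = emptyenv())

defaultSynth <- function() {
  if (is.null(.synthCache$base)) {
    d <- generateDesign(nPairs = 10, seed = 1)
    tr <- generateTrees(d, nPerSite = 25, seed = 2)
    cl <- generateClimate(d, tr, seed = 3)
    scl <- fitScaler(cl$trees, variables = climVars)
    E <- applyScaler(scl, cl$trees)[, climVars]
    .synthCache$base <- list(design = d, trees = tr, clim = cl,
                             scaler = scl, E = E)
  }
  .synthCache$base
}

## Default genotypes plus fitted GEA objects, cached for reuse.
defaultFit <- function() {
  if (is.null(.synthCache$fit)) {
    s <- defaultSynth()
    g <- generateGenotypes(s$design, s$clim$trees, seed = 4)
    model <- fitLatentModel(g, s$E, K = 3)
    assoc <- associationTest(g, s$E, model@U)
    hits <- bhSelect(apply(assoc@pCalibrated, 1, min), q = 0.01)
    cand <- rownames(assoc@z)[hits]
    .synthCache$fit <- list(g = g, model = model, assoc = assoc,
                            candidates = cand)
  }
  .synthCache$fit
}

## Independent oracles -----------------------------------------------------

## Four-neighbor bilinear blend written directly from the definition.
oracleBilinear <- function(values, extent, lon, lat) {
  nr <- nrow(values); nc <- ncol(values)
  rx <- (extent[2] - extent[1]) / nc
  ry <- (extent[4] - extent[3]) / nr
  cx <- extent[1] + (seq_len(nc) - 0.5) * rx
  cy <- extent[4] - (seq_len(nr) - 0.5) * ry
  cL <- findInterval(lon, cx); cL <- min(max(cL, 1), nc - 1)
  rT <- findInterval(-lat, -cy); rT <- min(max(rT, 1), nr - 1)
  wx <- min(max((lon - cx[cL]) / rx, 0), 1)
  wy <- min(max((cy[rT] - lat) / ry, 0), 1)
  (1 - wx) * (1 - wy) * values[rT, cL] +
    wx * (1 - wy) * values[rT, cL + 1] +
    (1 - wx) * wy * values[rT + 1, cL] +
    wx * wy * values[rT + 1, cL + 1]
}

## Exhaustive Benjamini-Hochberg step-up.
oracleBH <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= q * seq_len(n) / n)
  if (length(pass) == 0) return(integer(0))
  kmax <- max(pass)
  thr <- ps[kmax]
  which(p <= thr)
}

## Genetic gap as the literal per-locus sum.
oracleGap <- function(B, de) {
  mean(vapply(seq_len(ncol(B)), function(l) sum(B[, l] * de)^2,
              numeric(1)))
}

## Per-area allele enumeration for locally-common / private counts.
oracleAlleleCounts <- function(dos, area, threshold = 0.05) {
  areas <- sort(unique(area))
  lc <- setNames(integer(length(areas)), areas)
  pr <- lc
  for (l in seq_len(nrow(dos))) {
    for (allele in c("alt", "ref")) {
      f <- vapply(areas, function(a) {
        x <- dos[l, area == a]
        x <- x[!is.na(x)]
        if (allele == "alt") sum(x) / (2 * length(x))
        else 1 - sum(x) / (2 * length(x))
      }, numeric(1))
      hot <- f >= threshold
      if (sum(hot) == 1) lc[hot] <- lc[hot] + 1L
      seen <- f > 0
      if (sum(seen) == 1) pr[seen] <- pr[seen] + 1L
    }
  }
  list(locally_common = lc, private = pr)
}
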