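#' Generate structured genotypes with planted climate-adaptive loci
#'
#' Simulates biallelic dosages (ALT-allele counts, 0/1/2) for the trees of
#' a synthetic design.  Neutral loci follow a Balding-Nichols
#' differentiation model: each of \code{kPops} ancestral pools draws its
#' allele frequency from \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} around an
#' ancestral frequency \code{p}, and each tree's expected frequency is an
#' admixture of the pools with proportions that vary smoothly along
#' latitude (Gaussian gates centered north / center / south for the
#' default \code{kPops = 3}).  This reproduces the predominantly
#' latitude-oriented population structure — and hence its collinearity
#' with latitudinal climate gradients — that the association machinery
#' must confound-correct.
#'
#' Adaptive loci ignore demography: a tree's allele frequency is
#' logit-linear in one standardized driver climate variable,
#' \code{plogis(qlogis(p) + beta * z_driver)}, with slope \code{beta}
#' drawn from \code{betaRange} (random sign) and the driver drawn from the
#' climate variables.  The generating truth (driver, beta, ancestral and
#' per-pool frequencies) is stored in \code{rowData} for parameter
#' recovery.
#'
#' @param design a \code{\link{generateDesign}} design
#' @param treeClimate per-tree climate table from
#'   \code{\link{generateClimate}}
#' @param nNeutral,nAdaptive locus counts
#' @param betaRange length-2 range of |beta| on the logit scale per
#'   training-sd unit of the driver
#' @param fst Balding-Nichols differentiation parameter of the pools
#' @param kPops number of ancestral pools (>= 1)
#' @param missingRate uniform missingness proportion (default 0)
#' @param seed integer seed
#' @return a \linkS4class{GenotypeExperiment}; \code{rowData} holds the
#'   truth table, \code{colData} the tree metadata plus the generating
#'   admixture proportions (\code{admix1..admixK})
#' @examples
#' d <- generateDesign(nPairs = 2, seed = 1)
#' tr <- generateTrees(d, nPerSite = 5, seed = 1)
#' cl <- generateClimate(d, tr, seed = 1)
#' g <- generateGenotypes(d, cl$trees, nNeutral = 50, nAdaptive = 5,
#'                        seed = 1)
#' dim(dosage(g))
#' @export
generateGenotypes <- function(design, treeClimate, nNeutral = 1900,
                              nAdaptive = 100, betaRange = c(1, 2.5),
                              fst = 0.1, kPops = 3, missingRate = 0,
                              seed = 1) {
  stopifnot(kPops >= 1, nNeutral >= 0, nAdaptive >= 0)
  L <- nNeutral + nAdaptive
  if (L == 0) stop("at least one locus is required")
  if (nAdaptive > L) stop("n_adaptive exceeds total loci")
  climVars <- intersect(c("bio3", "gst", "scd", "bio12", "bio15"),
                        colnames(treeClimate))
  if (nAdaptive > 0 && length(climVars) == 0)
    stop("treeClimate has no climate variable columns")
  n <- nrow(treeClimate)

  withSeed(seed, {
    ## latitude-dependent admixture over kPops pools
    lat <- treeClimate$lat
    Q <- admixtureGates(lat, kPops)

    p0 <- runif(L, 0.1, 0.9)
    isAdaptive <- rep(FALSE, L)
    if (nAdaptive > 0)
      isAdaptive[sample.int(L, nAdaptive)] <- TRUE
    driver <- rep(NA_character_, L)
    beta <- rep(0, L)
    if (nAdaptive > 0) {
      driver[isAdaptive] <- sample(climVars, nAdaptive, replace = TRUE)
      beta[isAdaptive] <- runif(nAdaptive, betaRange[1], betaRange[2]) *
        sample(c(-1, 1), nAdaptive, replace = TRUE)
    }

    ## per-pool frequencies for neutral loci (adaptive loci get NA)
    shape <- (1 - fst) / fst
    popFreq <- matrix(NA_real_, L, kPops)
    idxN <- which(!isAdaptive)
    for (k in seq_len(kPops))
      popFreq[idxN, k] <- rbeta(length(idxN), p0[idxN] * shape,
                                (1 - p0[idxN]) * shape)

    ## standardized drivers (z-scored over trees, the training population)
    Z <- scale(as.matrix(treeClimate[, climVars, drop = FALSE]))

    G <- matrix(NA_integer_, n, L)
    if (length(idxN))
      G[, idxN] <- rbinom(n * length(idxN), 2L,
                          pmin(pmax(tcrossprod(Q, popFreq[idxN, ,
                                                          drop = FALSE]),
                                    1e-4), 1 - 1e-4))
    for (l in which(isAdaptive)) {
      f <- stats::plogis(stats::qlogis(p0[l]) + beta[l] * Z[, driver[l]])
      G[, l] <- rbinom(n, 2L, f)
    }
    if (missingRate > 0)
      G[runif(length(G)) < missingRate] <- NA_integer_

    lociIds <- sprintf("snp%05d", seq_len(L))
    truth <- DataFrame(locus_id = lociIds, is_adaptive = isAdaptive,
                       driver = driver, beta = beta, p_ancestral = p0)
    for (k in seq_len(kPops))
      truth[[paste0("pool_freq", k)]] <- popFreq[, k]
    cd <- DataFrame(treeClimate[, c("tree_id", "site_id", "pair_id",
                                    "area_id", "lon", "lat", "elevation",
                                    "elevation_class")])
    for (k in seq_len(kPops))
      cd[[paste0("admix", k)]] <- Q[, k]
    rownames(cd) <- treeClimate$tree_id
    GenotypeExperiment(t(G), sampleInfo = cd, rowData = truth)
  })
}

## Smooth latitude-dependent admixture proportions: Gaussian gates with
## centers spread along the latitude range.  Rows sum to 1.
admixtureGates <- function(lat, kPops) {
  if (kPops == 1L) return(matrix(1, length(lat), 1))
  rng <- range(lat)
  centers <- seq(rng[1], rng[2], length.out = kPops)
  h <- diff(rng) / (kPops + 0.5)
  W <- vapply(centers, function(m) exp(-((lat - m) / h)^2),
              numeric(length(lat)))
  sweep(W, 1, rowSums(W), "/")
}

#' Construct a GenotypeExperiment
#'
#' @param dosage loci x individuals integer matrix in \{0, 1, 2, NA\}
#' @param sampleInfo per-individual metadata (needs \code{site_id},
#'   \code{area_id}); rownames or a \code{tree_id} column identify trees
#' @param rowData optional per-locus metadata (e.g. the truth table)
#' @return a \linkS4class{GenotypeExperiment}
#' @export
GenotypeExperiment <- function(dosage, sampleInfo, rowData = NULL) {
  dosage <- as.matrix(dosage)
  sampleInfo <- as(sampleInfo, "DataFrame")
  if (is.null(rownames(sampleInfo)) ||
      all(rownames(sampleInfo) == as.character(seq_len(nrow(sampleInfo))))) {
    if ("tree_id" %in% colnames(sampleInfo))
      rownames(sampleInfo) <- sampleInfo$tree_id
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- rownames(sampleInfo)
  if (is.null(rowData)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(nrow(dosage)))
    rowData <- DataFrame(locus_id = ids)
  }
  if (is.null(rownames(dosage))) rownames(dosage) <- rowData$locus_id
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             colData = sampleInfo, rowData = rowData)
  new("GenotypeExperiment", se)
}

#' @rdname GenotypeExperiment-class
#' @export
setMethod("dosage", "GenotypeExperiment",
          function(object) assay(object, "dosage"))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("sampleInfo", "GenotypeExperiment",
          function(object) colData(object))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("truthTable", "GenotypeExperiment", function(object) {
  rd <- rowData(object)
  if (!"is_adaptive" %in% colnames(rd))
    stop("no truth table: this object does not carry simulation truth")
  rd
})

setMethod("show", "GenotypeExperiment", function(object) {
  d <- dosage(object)
  cat(sprintf("GenotypeExperiment: %d loci x %d individuals\n",
              nrow(d), ncol(d)))
  cat(sprintf("  sites: %d | areas: %d | missing: %.2f%%\n",
              length(unique(colData(object)$site_id)),
              length(unique(colData(object)$area_id)),
              100 * mean(is.na(d))))
  if ("is_adaptive" %in% colnames(rowData(object)))
    cat(sprintf("  truth table: %d adaptive locus/loci\n",
                sum(rowData(object)$is_adaptive)))
})
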