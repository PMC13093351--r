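#' Default end-to-end pipeline configuration
#'
#' Study-condition defaults for the fully synthetic run: a 10-pair design
#' (20 sites), ~25 trees per site, 2000 loci of which 100 are planted
#' climate-adaptive, K = 3 latent factors, FDR 1\% candidate selection,
#' and both offset methods across the 3 SSP x 2 period scenario grid.
#'
#' @param outDir output directory
#' @param seed integer master seed
#' @return named list understood by \code{\link{runPipeline}}
#' @export
defaultPipelineConfig <- function(outDir = tempfile("genoffset_"),
                                  seed = 1) {
  list(out = outDir, seed = seed,
       design = list(nPairs = 10, nUngrouped = 0),
       trees = list(nPerSite = 25),
       genotypes = list(nNeutral = 1900, nAdaptive = 100,
                        betaRange = c(1, 2.5), fst = 0.1, kPops = 3),
       gea = list(K = 3, lambda = 1e-5, fdr = 0.01, maf = 0.05),
       gf = list(ntree = 500, minLeaf = 5, nbins = 201),
       scenarios = c("ssp126", "ssp370", "ssp585"),
       periods = c("mid", "late"))
}

checkConfig <- function(config) {
  need <- c("out", "seed", "design", "trees", "genotypes", "gea", "gf",
            "scenarios", "periods")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config validation: missing field(s): ",
         paste(miss, collapse = ", "))
  cfgScen <- climateConfig()$scenarios
  for (s in config$scenarios)
    for (p in config$periods)
      if (!any(cfgScen$scenario == s & cfgScen$period == p))
        stop("config validation: scenario '", s, "' / period '", p,
             "' is not defined")
  invisible(config)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic genomic-offset pipeline
#'
#' Simulate (design, trees, climate, genotypes) -> MAF filter -> latent
#' factor fit -> association tests -> FDR candidates -> both offset
#' statistics per tree and per scenario -> site means and latitude
#' regressions -> range-wide raster projections, writing all tables,
#' rasters and a checksummed manifest under \code{config$out}.  A rerun
#' with the same config and seed reproduces identical outputs.
#'
#' @param config list from \code{\link{defaultPipelineConfig}} (or a YAML
#'   file path with the same structure)
#' @return the manifest, invisibly (list: versions, seed, outputs with
#'   md5 checksums, candidate/site summaries)
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  checkConfig(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  ccfg <- climateConfig()

  design <- stage("design", do.call(generateDesign,
    c(config$design, list(seed = seed))))
  trees <- stage("trees", do.call(generateTrees,
    c(list(design = design), config$trees, list(seed = seed + 1))))
  clim <- stage("climate",
    generateClimate(design, trees, ccfg, seed = seed + 2))
  g <- stage("genotypes", do.call(generateGenotypes,
    c(list(design = design, treeClimate = clim$trees),
      config$genotypes, list(seed = seed + 3))))
  g <- stage("maf_filter", mafFilter(g, config$gea$maf))

  scaler <- stage("scaler", fitScaler(clim$trees,
    variables = ccfg$variables$variable))
  eCur <- applyScaler(scaler, clim$trees)[, ccfg$variables$variable]

  model <- stage("latent_model",
    fitLatentModel(g, eCur, K = config$gea$K,
                   lambda = config$gea$lambda))
  assoc <- stage("association", associationTest(g, eCur, model@U))
  pMin <- apply(assoc@pCalibrated, 1, min)
  hits <- stage("fdr", bhSelect(pMin, q = config$gea$fdr))
  candidates <- stage("candidates",
    mergeCandidates(character(0), rownames(assoc@z)[hits],
                    validLoci = model@loci))
  if (nrow(candidates) == 0)
    stop("pipeline stage 'candidates' failed: no candidate loci at FDR ",
         config$gea$fdr)

  predictors <- cbind(eCur, setNames(as.data.frame(model@U),
                                     paste0("U", seq_len(model@K))))
  turnover <- stage("turnover",
    fitTurnover(g, predictors, candidates = candidates$locus,
                ntree = config$gf$ntree, minLeaf = config$gf$minLeaf,
                nbins = config$gf$nbins, seed = seed + 4))

  rastersCur <- applyScaler(scaler, clim$rasters)
  mask <- rangeMask(clim$elevation)
  outputs <- character(0)
  siteTabs <- list()
  regTabs <- list()
  for (sc in config$scenarios) for (pd in config$periods) {
    tag <- paste(sc, pd, sep = "_")
    futTrees <- generateFuture(clim$trees, sc, pd, ccfg)
    eFut <- applyScaler(scaler, futTrees)[, ccfg$variables$variable]
    for (method in c("lfmm", "gf")) {
      off <- if (method == "lfmm")
        geneticGap(model, as.matrix(eCur), as.matrix(eFut),
                   candidates = candidates$locus)
      else gfOffset(turnover, eCur, eFut)
      res <- OffsetResult(off, id = clim$trees$tree_id,
                          site_id = clim$trees$site_id,
                          method = method, scenario = sc, period = pd)
      sm <- siteMeanOffsets(res)
      sm$method <- method; sm$scenario <- sc; sm$period <- pd
      siteTabs[[paste(method, tag)]] <- sm
      reg <- regressOffsetLatitude(sm, design, "elevation_class")
      reg$method <- method; reg$scenario <- sc; reg$period <- pd
      regTabs[[paste(method, tag)]] <- reg

      futR <- generateFuture(clim$rasters, sc, pd, ccfg,
                             elevation = clim$elevation)
      proj <- projectOffsets(
        if (method == "lfmm") model else turnover,
        rastersCur, applyScaler(scaler, futR), mask = mask,
        trainEnv = eCur,
        candidates = if (method == "lfmm") candidates$locus else NULL)
      for (nm in c("offset", "novelty")) {
        p <- file.path(config$out,
                       sprintf("%s_%s_%s.asc", method, tag, nm))
        writeAsciiGrid(proj[[nm]], p)
        outputs <- c(outputs, p)
      }
    }
  }

  writeTab <- function(x, name) {
    p <- file.path(config$out, name)
    write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  outputs <- c(outputs,
    writeTab(do.call(rbind, siteTabs), "site_mean_offsets.tsv"),
    writeTab(do.call(rbind, regTabs), "latitude_regressions.tsv"),
    writeTab(candidates, "candidates.tsv"),
    writeTab(design, "design.tsv"))
  writeScaler(scaler, file.path(config$out, "scaler.json"))
  writeTurnoverModel(turnover, file.path(config$out, "turnover.json"))
  outputs <- c(outputs, file.path(config$out, "scaler.json"),
               file.path(config$out, "turnover.json"))

  manifest <- list(
    package = as.character(utils::packageVersion("GenomicOffset")),
    seed = seed,
    n_sites = nrow(design), n_trees = nrow(clim$trees),
    n_loci = nrow(dosage(g)), n_candidates = nrow(candidates),
    scenarios = vapply(config$scenarios, function(s)
      paste(s, collapse = ","), character(1)),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Species-range mask from the elevation surface
#'
#' A simple montane-range operationalization for the synthetic landscape:
#' cells between 150 and 2000 m elevation are in range.
#'
#' @param elevation the elevation \linkS4class{ClimateRaster}
#' @param lo,hi elevation bounds in meters
#' @return a 0/1 \linkS4class{ClimateRaster}
#' @export
rangeMask <- function(elevation, lo = 150, hi = 2000) {
  v <- elevation@values
  ClimateRaster((v >= lo & v <= hi) * 1, elevation@extent,
                crs = elevation@crs, name = "range_mask")
}
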