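# GenomicOffset

Predicting climate-change maladaptation risk ("genomic offset") for
locally adapted populations sampled along climate gradients — built for
landscape-genomics studies of montane trees with paired elevation-site
designs, and fully exercisable on synthetic data that mirrors such a
study system.

## What it computes

Given individual genotypes (0/1/2 dosages), per-individual climate and
future-scenario climates, the package runs the whole chain:

1. **GEA candidate selection.** A ridge latent-factor mixed model
   `Y ≈ E B + U Vᵀ` relates centered dosages `Y` (n individuals × L
   loci) to scaled climate `E` while K latent factors `U` absorb
   population structure — including the part collinear with climate,
   via the shrink–reinflate SVD solution.  Per-locus tests are
   recalibrated with the genomic inflation factor
   `GIF = median(z²)/χ²₀.₅(1)` and selected by Benjamini–Hochberg at
   FDR 1 %.
2. **Genetic-gap offset.**  For a climate-change vector
   `Δe = e_fut − e_cur` in training-SD units and candidate effect sizes
   `B`,

       G = Δeᵀ (B Bᵀ / L) Δe

   — the mean squared predicted genotypic change.
3. **Gradient-forest offset.**  Per-SNP regression forests (500 trees
   per SNP; compiled implementation) accrue split-impurity decreases at
   their thresholds into R²-weighted cumulative-importance turnover
   functions `F_p`; latent factor axes take part in training as
   confounders but are excluded from the offset, which is the Euclidean
   distance between current and future climate in turnover space.
   Predictions beyond the training range clamp to the plateau.
4. **Aggregation and projection.**  Per-site offset means, OLS of site
   means on latitude (degrees south) by elevation class with
   significance tiers, and range-wide masked raster projection for
   every SSP × period scenario, with companion novelty rasters flagging
   cells outside the training climate envelope.

A synthetic-data module generates the study conditions end to end:
paired sites (within-pair distance 0.6–2.2 km, mean 1.1 km; elevation
difference 150–320 m, mean 230 m) numbered north to south, five climate
variables on two quasi-orthogonal gradients with all pairwise |r| kept
below 0.77, genotypes from a 3-pool Balding–Nichols demography with
latitudinal admixture plus planted climate-adaptive loci, and
scenario-shifted future climates with elevation-dependent warming.

## Worked example

```r
library(GenomicOffset)

design <- generateDesign(nPairs = 10, seed = 1)       # 20 sites, 11 areas
trees  <- generateTrees(design, nPerSite = 25, seed = 2)
clim   <- generateClimate(design, trees, seed = 3)
geno   <- generateGenotypes(design, clim$trees, seed = 4)
geno
#> GenotypeExperiment: 2000 loci x 500 individuals
#>   sites: 20 | areas: 11 | missing: 0.00%
#>   truth table: 100 adaptive locus/loci

vars   <- c("bio3", "gst", "scd", "bio12", "bio15")
scaler <- fitScaler(clim$trees, variables = vars)
E      <- applyScaler(scaler, clim$trees)[, vars]
model  <- fitLatentModel(geno, E, K = 3)
assoc  <- associationTest(geno, E, model@U)
assoc
#> AssociationResult: 2000 loci x 5 variable(s)
#>   GIF: bio3=1.199, gst=2.391, scd=1.416, bio12=1.186, bio15=1.239

candidates <- rownames(assoc@z)[bhSelect(apply(assoc@pCalibrated, 1, min), q = 0.01)]
length(candidates)
#> [1] 101

futr <- generateFuture(clim$trees, "ssp370", period = "mid")
eFut <- applyScaler(scaler, futr)[, vars]
gap  <- geneticGap(model, as.matrix(E), as.matrix(eFut), candidates = candidates)
siteGap <- siteMeanOffsets(data.frame(site_id = clim$trees$site_id, offset = gap))
head(siteGap, 3)
#>   site_id    offset  n n_excluded
#> 1       1 0.1900619 25          0
#> 2       2 0.1521150 25          0
#> 3       3 0.1926530 25          0

regressOffsetLatitude(siteGap, design, "elevation_class")
#>   group slope_per_degS intercept        r2           p  tier  n
#> 1  high   -0.007135401 0.4772847 0.6893035 0.002944163 solid 10
#> 2   low   -0.005809826 0.3868085 0.6819925 0.003244194 solid 10
```

The 101 selected candidates recover nearly all 100 planted adaptive loci
(their identities are in `truthTable(geno)`).  The GIF values near 1–2
show the latent factors controlling the latitude-collinear structure.
The negative slopes against degrees south mean the genetic gap under the
moderate mid-century scenario is largest at the northern end of the
gradient — the per-site offsets of each elevation class decline
significantly ("solid", p ≤ 0.05) toward the south.

`runPipeline(defaultPipelineConfig())` chains the same steps for all
3 SSPs × 2 periods and both offset methods, adds the gradient-forest
engine and raster projections, and writes tables, ASCII-grid rasters and
a checksummed manifest.

See `vignettes/genomic-offset-methods.Rmd` for the models, their
assumptions, parameter defaults and design decisions.

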