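---
title: "Genomic offset from latent-factor models and gradient forests: methods and design"
author: "GenomicOffset package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic offset methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Locally adapted tree populations carry allele frequencies matched to their
current climate.  As climate shifts, the genetic composition a location
*will* require diverges from the composition its population *has* — a
mismatch called the **genomic offset**, read as a forecast of
maladaptation risk.  This package implements the full analysis chain for a
montane tree sampled in a paired elevation-site design along a long
latitudinal gradient: genotype–environment association (GEA) to select
putatively climate-adaptive loci, two offset statistics computed per tree
and aggregated per site, regressions of offset against latitude by
elevation class, and range-wide raster projection under a grid of emission
scenarios (SSP 1-2.6 / 3-7.0 / 5-8.5, mid- and late-century).

No individual-level SNP data ship with the package.  Instead, a
first-class synthetic-data module generates genotypes, climate and
geography that statistically mirror the study system, so every stage is
testable end to end and every reported number is recomputable from code.

## The sampling design generator

`generateDesign()` builds paired sites: locations spread north to south,
each with a locally high and a locally low site.  Within a pair, the
linear separation is drawn from a scaled Beta distribution on
[0.6, 2.2] km with mean 1.1 km, and the elevation difference from a scaled
Beta on [150, 320] m with mean 230 m — both distributions are pinned to
the emulated study system's mean *and* range, which is why Beta
rather than uniform draws are used (a uniform on the same range would have mean
1.4 km).  Sites are numbered north to south; pair base elevations decline
southward (70 m per degree by default), reproducing the
elevation–latitude autocorrelation of the region.  The default 10-pair
design groups its 20 sites into 11 sampling areas (each pair one area,
the southernmost pair split in two).  Infeasible requests (e.g., a
latitude range too narrow to keep pairs apart) fail loudly; the generator
never clips silently.

## The climate fields

Five variables are simulated — temperature isothermality (`bio3`, %),
mean growing-season temperature (`gst`, °C), snow cover days (`scd`,
days), annual precipitation (`bio12`, mm) and precipitation seasonality
(`bio15`, %) — each as an analytic field in longitude, latitude and
elevation plus a smooth random surface (sums of long-wavelength
sinusoids).  Two quasi-orthogonal gradients structure the landscape: the
north–south temperature gradient and the west–east rain shadow, expressed
as distance from the mountain crest normalized by the realized site
spread.  Trees are evaluated with their true (design) elevations; raster
cells with a smooth analytic elevation surface that cannot resolve
sub-cell pair topography — deliberately emulating the topographic
mismatch between point observations and ~km-scale climate grids.

The emulated system's variable set was chosen subject to a low mutual
correlation prerequisite (all pairwise |r| below 0.77).  With only 20
distinct site positions, two smooth random surfaces can correlate
strongly by pure chance, so the generator enforces the same prerequisite
structurally: noise surfaces are redrawn — deterministically, from
sub-seeds derived from the main seed — until the maximum pairwise |r| at
the trees is below 0.75.  For miniature designs (fewer than 10 sites) or
noise-free configurations the check is skipped, because a sample
correlation over a handful of positions is not meaningful.

**Scenarios.** Future climates apply additive shifts to the temperature
variables and *fractional* anomalies to snow and precipitation variables
(snow-day loss proportional to snow days, drying proportional to
rainfall), which gives the anomaly field the spatial texture real
ensemble projections have.  Elevation-dependent warming adds
`edw * (elevation − 800 m)` to the `gst` shift — centered so it
redistributes warming across elevation rather than inflating the mean —
and a small latitudinal tilt makes the north warm slightly faster.
Severity is monotone by construction: the pessimistic pathway warms more
than the optimistic one at every position, and an all-zero scenario row
returns the input bit-for-bit.

## The genotype generator

Neutral loci follow a Balding–Nichols model: `kPops = 3` ancestral pools
(the number of genetic clusters the emulated system exhibits) draw allele
frequencies `Beta(p(1−F)/F, (1−p)(1−F)/F)` around an ancestral frequency
`p ~ U(0.1, 0.9)` with `F = 0.1`, and each tree mixes the pools with
smooth latitude-dependent Gaussian gates.  This makes the leading
principal component of neutral genotypes track latitude (|r| > 0.9 at
defaults) — precisely the structure–climate collinearity the inference
machinery must correct for.  Planted adaptive loci bypass demography:
allele frequency is logit-linear in one standardized driver variable,
`plogis(qlogis(p) + β z)`, with |β| drawn from [1, 2.5] and a random
sign.  The generating truth (driver, β, ancestral and pool frequencies,
admixture proportions) is stored in the object for parameter-recovery
tests.

Defaults are 2000 loci with 100 planted adaptive ones and ~25 trees per
site (500 trees; `nTotal = 493` reproduces the emulated system's tree count).  One
hundred planted loci was chosen because the turnover-function stage needs
a candidate set of a few hundred loci (the emulated system's has 490 SNPs) to produce stable
cumulative-importance curves; at desk scale the candidate *count*, not
the genome-wide fraction, is what that stage consumes.  The generator
deliberately omits linkage disequilibrium, coalescent noise, genotyping
error and missingness structure (missingness is optional and uniform), so
passing tests demonstrate correctness of the estimators under the model's
assumptions, not robustness to everything real data can do.

## Climate I/O and the train-time scaling contract

Rasters are minimal in-memory single-band objects (matrix plus extent,
WGS84 lon/lat, row 1 north, cell-center registration) with plain-text
ESRI ASCII grid I/O.  `bilinearExtract()` blends the four nearest cell
centers, reproduces stored values exactly at cell centers, is exact for
affine surfaces, and returns an explicit per-point flag (`"outside"`,
`"nodata"`) instead of silent `NaN`; nodata is always propagated, never
imputed.  `ensembleMean()` is the unweighted cell-wise mean across
aligned members (no member weights are defined anywhere in the pipeline),
with nodata poisoning the cell.

All scaling flows through one `ClimateScaler` fitted on the sampled
trees' current climate.  Future tables and every raster grid are scaled
with the *training* means and standard deviations — never their own — so
climate-change vectors are expressed in training-SD units and offsets are
comparable across periods.  Published offset pipelines differ on whether environmental
inputs are scaled for the turnover stage as well as the association
stage; this package applies the training scaler uniformly in both
offset engines and in spatial projection for internal consistency.  Because both engines are invariant to any fixed monotone
rescaling applied consistently to training and prediction inputs, this
choice affects units, not substance.

## The latent-factor association model

`fitLatentModel()` estimates `Y ≈ E B + U Vᵀ` for the mean-imputed,
column-centered dosage matrix `Y` (individuals × loci), scaled climate
`E`, `K` latent factors and a ridge penalty `λ = 1e-5` on `B` (numerical
stabilization with negligible shrinkage).
The factors use the shrink–reinflate SVD solution: sample directions
spanned by `E` are shrunk by `sqrt(λ/(λ+σᵢ²))`, the top-K SVD of the
shrunk matrix is taken, and the truncated reconstruction is re-inflated.
This subtlety matters: if the climate directions were simply projected
out, the structure that is collinear with climate would be absorbed into
`B` and the factors could not recover it — on the default synthetic data
that variant recovers the generating admixture axes with mean |r| ≈ 0.4
and leaves null tests inflated, while the shrink–reinflate solution
recovers them with |r| ≈ 0.93 and calibrates the nulls.  A fixed sign
convention (largest-magnitude score positive per factor) makes fits
bitwise reproducible, and `K = 0` degenerates to multivariate ridge
regression.

`associationTest()` regresses each locus on `E` with `U` as covariates
(one shared normal-equation solve across loci), converts t to z, computes
the per-variable genomic inflation factor `GIF = median(z²)/χ²₀.₅(1)` and
calibrates `p = P(χ²₁ > z²/GIF)`.  Candidates are selected per locus at
FDR 1% by Benjamini–Hochberg over the minimum calibrated p across the
five variables (`stats::p.adjust` does the step-up; ties at the boundary
p are all included).  On the default latitude-collinear demography the
calibrated null false-positive rate is within 2× nominal while omitting
`U` inflates it ~30-fold, and on planted architectures (500 loci of 5000,
β = 1.5, 493 trees) realized FDR averages ≈ 0.03 at nominal 1% with
power ≈ 0.99.

`selectK()` chooses `K` by masking 5% of dosage entries and scoring, for
each candidate `K`, a rank-K truncated-SVD imputation (a few EM passes)
on held-out RMSE, ties to the smallest `K`.  It runs on the *uncentered*
matrix, so one factor is spent on the overall allele-frequency profile
and the expected dosage matrix of a `kPops`-pool demography has rank
`kPops`: the selector recovers the generating pool count (modal choice 3
over replicate draws at defaults).  Two caveats are documented rather
than hidden: (i) planted adaptive loci are genuine extra structure — with
many of them the selector correctly counts their climate-driven
dimensions, so demographic `K` is estimated on genotypes without a
selection layer; (ii) an `E`-conditioned variant was evaluated and
rejected, because climate spans the latitudinal structure axis and
absorbs one demographic dimension (the selector then returns K − 1).

## The genetic-gap offset

For effect sizes `B` over the candidate loci and scaled climate-change
vector `Δe`, the offset is the quadratic form

&nbsp;&nbsp;&nbsp;&nbsp;`G = Δeᵀ (B Bᵀ / L) Δe`,

the mean over loci of the squared predicted genotypic change.  It is
nonnegative, zero when climate does not change, symmetric in
(current, future) and quadratic in the magnitude of change; the
implementation is tested against the brute-force per-locus sum
`Σₗ(Σⱼ bₗⱼ Δeⱼ)²/L` at 1e-10 on random instances.  The same form serves
the sampled trees and the raster projection.  The method description for
the spatial path can also be read prose-literally as "weight each
predictor by its effect sizes, then average", so a weighted-mean variant
(`form = "weighted_mean"`, mean over predictors of `wⱼ|Δeⱼ|` with
`wⱼ` the mean squared effect size) is available for comparison; the
quadratic form is the default everywhere because it is the statistic's standard definition.

## The gradient-forest offset

The turnover machinery is implemented from first principles (compiled
per-SNP regression forests) because the offset needs each split's
impurity decrease *at its threshold value*, which off-the-shelf forest
packages do not expose.  Per candidate SNP a forest of 500 regression
trees is grown (bootstrap resampling, `mtry = ⌈P/3⌉` predictors per
split, variance-reduction splitting, minimum leaf 5).  Each accepted
split accrues its impurity decrease to its predictor in one of 201
equal-width bins spanning the training range — a binned approximation of
the reference implementation's split-density standardization, documented
as a simplification; parity with the reference is at the level of
invariants and rank agreement, not decimals.  Per SNP the binned
importances are normalized to sum to the SNP's out-of-bag R², SNPs with
R² ≤ 0 are dropped, and summing over SNPs and accumulating along each
predictor yields the nondecreasing cumulative-importance function `F_p`
(0 below the training range, total importance above — the model never
extrapolates beyond training conditions; predictions beyond the range
clamp to the plateau).

Population structure enters as the latent factor axes `U1..UK` included
among the training predictors, following the established confounder treatment for turnover models: structure can claim importance during training, but confounder
coordinates are excluded from the offset distance, because structure does
not change between climate periods.  The offset is the Euclidean distance
between current and future positions in climate turnover space.  Forest
randomness runs on R's RNG, so a seed fixes the model exactly and its
JSON serialization is byte-identical across runs.

**Hyperparameters.** Only the 500-trees-per-SNP setting is taken
from the emulated analysis design; `mtry`, leaf size and bin count are declared package defaults
chosen from regression-forest conventions and declared as such.
Tests run at 100 trees per SNP (rank-level results are stable between 100
and 500; 500 remains the default for analysis runs).

## Validity of the offsets on synthetic truth

Because the generator knows each adaptive locus's response curve, the
*true* adaptive mismatch of a tree under a scenario is computable exactly
as the mean squared allele-frequency displacement
`mean((p(z_fut) − p(z_cur))²)` over planted loci, using the generating
logistic response.  The logistic — not its linearization — is the truth
here; the linearized mismatch `(βΔz)²` is unbounded at the warm range
edge, exactly where turnover functions plateau by design, which would
build a spurious disagreement into the comparison.  At default study
conditions (moderate scenario, mid-century), site-mean offsets of both
engines rank-correlate with this truth at Spearman ≈ 0.8–0.9, and with
each other at ≈ 0.6 — the level of qualitative agreement between the
two methods that motivates reporting them side by side.  Both offsets are verified to be
zero under an identity scenario and per-tree monotone from the optimistic
to the pessimistic pathway.

## Projection, novelty and reporting

`projectOffsets()` computes per-cell offsets over aligned scaled raster
sets, masked to a species range (for the synthetic landscape: cells
between 150 and 2000 m on the analytic elevation surface).  A companion
novelty raster flags cells whose scaled climate — current or future —
falls outside the [min, max] training envelope of any variable, the
simplest operationalization of the caution that projections into novel
conditions are less trustworthy.  Raster offsets agree with the direct
per-vector computation cell-for-cell, and under elevation-dependent
warming the top elevation quartile carries higher mean projected offset
than the bottom quartile (the treeline-hotspot mechanism).

`siteMeanOffsets()` averages per-tree offsets within sites, excluding and
counting error-flagged trees.  `regressOffsetLatitude()` runs unweighted
OLS of site means on latitude in **degrees south** (positive southward;
output headers carry the convention to avoid sign ambiguity), overall or
per elevation class, attaching the plotting significance tier (solid
p ≤ 0.05, dashed 0.05 < p ≤ 0.1, none p > 0.1).  Site means are regressed unweighted — each site counts
once regardless of tree count — matching the site as the unit of
analysis.
`binOffsets()` classifies a raster into display bins (quantile or
equal-width; 8 by default) with a legend of edges.

`runPipeline()` chains everything — simulate, filter at MAF 5%, fit,
test, select candidates, both offsets for all 3 SSPs × 2 periods, site
means, regressions, projections — writing tables, ASCII-grid rasters and
a checksummed JSON manifest; identical seeds give identical checksums.

## Numerical choices and degenerate inputs

* Missing dosages are mean-imputed per locus before model fitting
  (association and turnover stages); descriptive allele statistics use
  called alleles only.
* MAF filtering retains a locus iff its minor-allele frequency over
  called alleles is ≥ the threshold (boundary included).
* Locally common alleles: frequency ≥ 5% in exactly one area, < 5%
  elsewhere; private alleles: observed in exactly one area with no
  frequency floor (presence/absence).  Both REF and ALT alleles are
  eligible; counts are invariant to individual and locus ordering.
* FDR selection is at adjusted p ≤ the nominal level, boundary
  included; tied boundary p-values are all selected together.
* Degenerate inputs error loudly: zero-variance climate variables,
  rank-deficient association designs (collinear columns are named),
  empty sites, constant-latitude regressions, misaligned grids, unknown
  scenarios (valid names are listed).
* The raster grid spans the design bounding box plus a 0.5° margin with
  120 rows of square cells (~0.13° for the default domain); a fixed
  120 × 60 grid of ~0.025° cells cannot tile a 16°-tall domain, so the
  row count is kept and the cell size derived.

## Problem sizes used by the test suite

The suite regenerates everything from seeds at sizes chosen to exercise
the statistics meaningfully while keeping a full run at a few minutes:
the default 20-site / 500-tree / 2000-locus dataset for recovery and
validity checks; 10 replicate draws for K selection; 10 replicates of the
4500 + 500 planted-locus design (493 trees) for FDR and power; 20
replicates of 1000-locus null panels for calibration; 100 random
instances for each algebraic oracle; forests at 30–100 trees per SNP.

## Known limitations

* The genotype model has no linkage disequilibrium, so candidate sets
  cannot contain the redundant hitchhiking loci real GEA scans produce.
* Binomial sampling per tree understates the overdispersion of real
  sequencing-derived dosages.
* The turnover binning (201 equal-width bins) quantizes split positions;
  offsets are insensitive to this at the tested resolutions, but exact
  parity with the reference implementation is out of scope.
* Offset magnitudes are method-specific and carry no absolute fitness
  units; all cross-method statements are rank-level, and the offset
  containers carry a mandatory method tag for that reason.
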