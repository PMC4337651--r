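# sectorFISH

Statistical machinery for quantifying rare, transient losses of
heterochromatic gene silencing that are captured as permanent
fluorescent-reporter switches.

In budding yeast, the silent mating-type loci *HML* and *HMR* are so well
repressed that no bulk assay detects their expression. A Cre/lox reporter
strategy converts each transient failure of silencing into an
irreversible RFP-to-GFP switch, heritable by all descendants of the cell
in which it happened. Two quantitative readouts follow, and this package
implements both ends of each — the generative model and the estimator:

1. **Colony sectoring.** A switch in the mother or daughter cell of the
   first division on a plate yields a half red / half green colony, so
   the per-division rate of silencing loss is estimated by

   ```
   p̂ = (# half-sectored colonies) / (# total colonies − # fully green colonies)
   ```

   Fully green colonies (founder switched before plating) contribute no
   countable first division and are excluded from the denominator.
   Wild-type rates are of order 10⁻³ per division; mutants of the
   silencing machinery raise them up to ~5 × 10⁻².

2. **Single-molecule RNA FISH.** Per-cell transcript counts of the
   silenced gene and a constitutive control, obtained by 3D
   Laplacian-of-Gaussian (LoG) spot calling in anisotropic z-stacks
   (0.2 µm steps), summarized as mean spots/cell, variance, % cells with
   >0 and >1 spots, and the dispersion index σ²/µ (≈1 for the Poisson-like
   control, ≫1 for the derepressed reporter).

The package provides, for audiences working on epigenetic stability,
reporter-switch assays or smFISH pipeline validation:

* a branching-process colony simulator with irreversible switching
  (`simulateColony()`, `simulatePopulation()`), exact O(generations)
  binomial thinning for population scale, an explicit-tree mode for
  cross-checks, and a cell-cycle-resolved mode that classifies switches
  into the live-imaging bud-stage × progeny pattern taxonomy
  (`classifySwitchPattern()`);
* the half-sector estimator and replicate statistics
  (`halfSectorFrequency()`, `summarizeReplicates()`, `foldChange()`,
  `twoSampleT()`, `bootstrapRateCI()`, `recoverRate()`);
* a synthetic smFISH generator with full ground truth
  (`CountModel()`, `sampleCounts()`, `StackSpec()`, `generateStack()`,
  `makeTwoChannelFixture()`), writing multi-page TIFF stacks and 16-bit
  label masks;
* the 3D LoG spot caller (`logFilter3d()`, `detectSpots()`,
  `assignSpotsToCells()`, `summarizeCounts()`, `scoreDetection()`);
* an idealized plate renderer and threshold/connected-component colony
  counter (`renderPlate()`, `countColonies()`);
* seeded experiment orchestration from YAML configs
  (`runSectorExperiment()`, `runFishExperiment()`) and a thin CLI at
  `inst/scripts/sectorfish`.

## Worked example

Estimate a wild-type-like rate from a simulated plating, compare a
mutant against it, and run the FISH pipeline on synthetic stacks:

```r
library(sectorFISH)

## the printed estimator on one plate's tallies
halfSectorFrequency(SectorCounts(1267, halfSectored = 2, fullyGreen = 3))
#> [1] 0.001582278

## simulation + estimation round trip at a wild-type-like rate
wt <- recoverRate(SwitchParams(pDiv = 0.00158),
                  nColonies = 2e5, nReplicates = 3, seed = 1)
wt
#> RateEstimate: 0.001467 +/- 2.5e-05 (n = 3)

## a silencing-maintenance mutant, 0.055 losses per division
mut <- recoverRate(SwitchParams(pDiv = 0.055),
                   nColonies = 2e5, nReplicates = 3, seed = 4)
foldChange(mut, wt)$fold
#> [1] 37.6   # generative ratio 34.8; Monte-Carlo SE ~1.2
twoSampleT(rateReplicates(mut), rateReplicates(wt))$p.value
#> [1] 1.5e-11

## synthetic FISH: overdispersed reporter counts through the 3D LoG caller
spec <- StackSpec(dim = c(24, 360, 360), nCells = 30, minSeparation = 6)
cellCounts <- sampleCounts(CountModel("negbin", mean = 12, variance = 53),
                           30, seed = 2)
fx <- generateStack(spec, cellCounts, seed = 3)
filt <- logFilter3d(fx$stack)
spots <- detectSpots(filt, proposeThreshold(filt))
summarizeCounts(assignSpotsToCells(spots, fx$mask)$counts$count)
#> FISHSummary over 30 cells
#>   mean 11.4, variance 45 (dispersion 3.96)
#>   %>0 spots: 100  %>1 spot: 100
scoreDetection(spots, fx$truth$spots)[c("precision", "recall")]
#> $precision [1] 1   $recall [1] 1
```

The recovered mean of 11.4 spots/cell sits within sampling error of the
generative mean 12 (SE √(53/30) ≈ 1.3 at 30 cells), and detection is
exact at peak SNR 10 with spots ≥ 6 voxels apart. The fold-change of
37.6 brackets the generative ratio 0.055/0.00158 ≈ 34.8 within
Monte-Carlo error.

Example YAML configurations for multi-strain experiments are installed
under `inst/extdata/` (`example_sector_config.yaml`,
`example_fish_config.yaml`), alongside the reference strain rate and
FISH summary tables used as generative parameters.

## Methods

The methods vignette
(`vignettes/quantifying-silencing-loss.Rmd`) documents the generative
models, the exactness of the binomial-thinning reduction, the estimator
and its invariances, every tunable parameter with units and defaults,
the numerical choices in the LoG caller, and known limitations.
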