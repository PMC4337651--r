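---
title: "Quantifying transient losses of heterochromatic silencing: models and methods"
author: "sectorFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transient losses of heterochromatic silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectorFISH)
```

## The measurement problem

Heterochromatin at the silent mating-type loci of budding yeast represses
transcription so effectively that no population-level assay detects
expression above background. Yet heterochromatin structure is dynamic, so
repression might fail rarely and transiently. A genetic strategy converts
each transient failure into a permanent, heritable mark: the Cre
recombinase, silenced inside heterochromatin, excises a loxP-flanked RFP
cassette upon any burst of expression, irreversibly switching the cell and
all of its descendants from red to green fluorescence. Two readouts follow:

* **Colony sectors.** A switch during colony growth produces a green sector
  whose size records when the switch happened. A switch in the mother or
  daughter cell of the *first* division on the plate yields a colony that
  is half red and half green, so the frequency of half-sectored colonies
  estimates the per-division rate of silencing loss.
* **Single-molecule RNA FISH.** Per-cell transcript counts of the silenced
  gene and of a constitutive control gene, measured by 3D spot calling in
  image stacks, characterize how much transcription occurs when silencing
  is lost.

This package implements the quantitative machinery of both readouts as
reusable, seeded, tested components: a branching-process colony simulator,
the half-sector estimator and its replicate statistics, a synthetic FISH
generator with full ground truth, the 3D Laplacian-of-Gaussian (LoG) spot
caller, and an idealized plate renderer and counter.

## The branching-process colony model

A colony grows from one founder by synchronous divisions for
`generations` generations (default 14, about the size at which plates are
scored). At each division of an *unswitched* cell, a loss-of-silencing
event occurs independently with probability $p_{\mathrm{div}}$ and
permanently recombines the reporter. The switched state is heritable and
irreversible: a switched cell never draws further events and all its
descendants are switched. The founder may already be switched at plating
with probability $q_{\mathrm{pre}}$ (escape from red-cell pre-selection);
such colonies are entirely green.

Two timing models are available:

* `simple` (default): an event switches exactly one progeny of the
  division, mother or daughter with probability 1/2 each. Live imaging of
  switches shows no obvious mother--daughter bias, which motivates the
  symmetric choice.
* `cell_cycle`: the event time is drawn within the cycle. With
  probability `fPreReplication` the recombination acts before DNA
  replication, on the single cassette copy, and **both** progeny inherit a
  recombined cassette; otherwise it acts after replication on one of the
  two copies and exactly one progeny switches.

### Colony classes and the visible horizon

Colony classes are assigned from the event record, not from rendered
pixels:

* `full_green`: pre-switched founder, or a first-division
  pre-replication event (both progeny switched).
* `half_sector`: a first-division event that switches exactly one
  progeny. Later events add smaller green sectors *within the red half*;
  they do not destroy the half-sector morphology, so they do not change
  the class. This choice makes the expected half-sector frequency equal
  $p_{\mathrm{div}}$ exactly in simple mode, which is precisely the
  relationship the assay is built on; demoting such colonies to "partial"
  would multiply the expectation by $(1-p)^{31}$ (the number of divisions
  inside the visible horizon) and break the frequency-equals-rate
  identity badly at high rates (a 0.055-per-division mutant would read
  out 6.8-fold, not 35-fold, above wild type).
* `red`: no event within the visible horizon.
* `partial_sector`: anything else (first visible event after the first
  division).

The *visible horizon* (default generation 6, configurable) models the
fact that sectors founded after a few generations are too small to score;
events beyond it leave the class unchanged. A fraction-based classifier
(`classifyByFraction()`, half sector at green fraction $0.5 \pm 0.05$) is
provided for rendered or measured images.

### Exact thinning

`simulatePopulation()` does not build trees. Because events are iid
across unswitched dividing cells and a switched subtree can never host an
event, the number of events in generation $g$ is
$\mathrm{Binomial}(u_{g-1}, p_{\mathrm{div}})$ where $u_{g-1}$ counts
unswitched cells, and the colony class is a function of the
per-generation event counts alone. The generation-wise binomial thinning
is therefore an *exact* reduction of the explicit tree, not an
approximation, at cost $O(\mathrm{generations})$ per colony. The explicit
tree (`method = "tree"`) remains available and the suite checks that the
two agree in distribution. Population green fractions follow from
$u_G$: a single-progeny event at generation $g$ contributes exactly
$2^{-g}$ of the final cells, a both-progeny event $2^{-(g-1)}$.

### Cell-cycle patterns

Live imaging categorizes switches by bud morphology at first detectable
green signal crossed with which progeny stay green.
`classifySwitchPattern()` reproduces that taxonomy: the detection phase is
the event time plus the reporter maturation delay (`gfpDelay`, default
0.5 cycles), modulo one cycle, with bud emergence at 0.25 and the
large-bud stage from 0.6 of a cycle (package constants; the underlying
study reports no landmark values, and these place bud emergence at the
start of S phase). Numbered patterns are unbudded
mother/daughter/both = 1/2/3, small-budded = 4/5/6, large-budded
mother/daughter = 7/8. Two invariants are enforced and tested: both
progeny stay green only after a pre-replication event, and exactly one
progeny stays green only after a post-replication event. A large-budded
division in which both progeny remain green has no number in the printed
taxonomy and is returned with `pattern = NA`; pattern 3 is labelled but
deliberately assigned no mechanism. With the default `gfpDelay` of 0.5,
pattern 3 cannot arise (pre-replication events are detected at least half
a cycle after the cycle start); delays above ~0.75 populate it.
`fPreReplication` defaults to 0.25 so that both event families are well
represented; it is a free parameter, not a measured one.

## The half-sector estimator and replicate statistics

The estimator is the printed formula

$$\hat p = \frac{\#\text{half-sectored}}{\#\text{total} - \#\text{fully green}}$$

Fully green colonies were founded by cells that switched *before* their
first division on the plate, so they contribute no countable first
division; partially sectored colonies are tallied but never enter the
estimator. Adding fully green colonies to a plate leaves the estimate
unchanged (a tested invariant), and in simple mode
$E[\hat p] = p_{\mathrm{div}}$ exactly.

Replicate summaries report the arithmetic mean and the sample ($n-1$)
standard deviation over independent platings, matching how the study
tabulates three experiments per genotype. `twoSampleT()` is the classical
equal-variance, two-sided Student's t test (the natural reading of
"Student's t test", and Welch is ill-behaved at $n = 3$ per group),
delegated to `stats::t.test(var.equal = TRUE)` with an explicit degenerate
branch for zero pooled variance. `foldChange()` is the ratio of replicate
means with a delta-method standard error reported as supporting plumbing.
`bootstrapRateCI()` adds a percentile bootstrap (multinomial resampling of
colonies within replicates, 2000 resamples by default); the study itself
reports only mean ± SD, so intervals are an extra, not a reproduction.
No multiple-testing correction is applied: comparisons report raw p
values, as the study does.

## The synthetic FISH generator

`sampleCounts()` draws per-cell transcript counts from three families:

* `poisson` — constitutive transcription (the control gene is close to
  Poisson; its dispersion index is ~1).
* `negbin` — overdispersed transcription parameterized directly by
  (mean, variance), e.g. mean 12 and variance 53 for the fully
  derepressed reporter. The study reports exactly these two moments and
  no distributional form, so the negative binomial is used as the minimal
  two-moment overdispersed family; this is an assumption, flagged here.
  A variance at or below the mean falls back to Poisson with a warning.
* `mixture` — a zero-heavy two-state mixture for bistable silencing: a
  fraction `piExpressed` of cells draws from a nested expressed-component
  model, the rest have exactly zero transcripts. By default the expressed
  component is Poisson with mean `mean / piExpressed`, so the overall
  mean is preserved; only the overall mean and the expressing fraction
  are reported for the bistable mutant, so the within-component shape is
  a free choice.

`generateStack()` renders counts into an anisotropic 3D stack: cells are
non-overlapping ellipses (semi-axes 1.9 × 1.4 um, ±15% size jitter,
random orientation) in a 2D label mask; each transcript is an anisotropic
3D Gaussian at a uniform random sub-voxel position inside its cell
footprint (inset one pixel so rounded centroids always land on the owning
label) and uniform in z away from the axial margins. Defaults emulate a
60x widefield acquisition: 0.13 um lateral voxels, 0.2 um z step (the
standard smFISH step size), PSF sigma 0.12 um lateral and 0.24 um axial —
the diffraction scale for far-red dyes at NA ≈ 1.4, with the typical ~2x
axial anisotropy — amplitude 200 over background 100 with Gaussian read
noise of sd 20 (peak SNR 10). A `minSeparation` option enforces a minimum
distance between true spots by rejection sampling (bounded retries, then
the farthest candidate found); an optional `falseSpotRate` adds
background autofluorescence spots, rendered but excluded from the truth
counts, to emulate the apparent signal seen in probe-only controls.
Ground truth (per-cell counts, sub-voxel centroids, owning cells) is
returned in full so detection can be scored exactly. The generator does
not model aberrations, photobleaching or spectral bleed-through, and the
cell masks are synthetic stand-ins for hand-drawn boundaries — passing
tests demonstrate correctness of the calling machinery on
Gaussian-spot images, not performance on real micrographs.

## The 3D LoG spot caller

`logFilter3d()` applies a three-dimensional Laplacian-of-Gaussian filter
with physical sigmas converted to voxel units per axis, honouring the
lateral/axial anisotropy. The kernel is sampled analytically over ±4
sigma, negated so bright blobs give positive extrema, and shifted to zero
sum so constant images map to zero response (to numerical precision;
tested at 1e-10 of the input scale). Convolution is FFT-based with
replicate padding — boundary voxels see an extended constant, so flat
regions stay exactly flat — and is verified in the suite against an
independent direct shift-and-add convolution.

`detectSpots()` thresholds the response, groups voxels by 3D
26-connectivity (the standard for blob components; the study does not
state its choice), and discards components outside an admissible size
range (default 4–200 voxels, derived from the default PSF at the default
voxel size — the study states only "an expected range of sizes").
Components holding several local maxima are split into one call per
maximum when a maximum reaches 30% of the component peak and maxima are
at least 2 voxels apart; this is what resolves transcripts that overlap
in a 2D projection but are separated along z (two spots 4 z-slices apart
are called separately at SNR 10 with the defaults). Centroids are
response-weighted over the component voxels, in voxel coordinates
(z, y, x), 1-based, origin at the stack corner.

The detection threshold is explicit user input, stored per channel in the
experiment configuration and reused across every sample of an experiment
— mirroring the cross-sample threshold discipline of the original
analysis. `proposeThreshold()` offers a starting value at
median + 8 × MAD of the filtered response (background response is
centred near zero and spots are sparse); the study's actual threshold
values are unpublished, so defaults here are calibrated on synthetic data
only. `assignSpotsToCells()` takes the mask label at the rounded lateral
centroid; spots over background stay in the table but not in the counts.
`summarizeCounts()` reports mean spots per cell, the sample variance
(the study does not say whether its variances are sample or population;
sample is assumed), the percentage of cells with more than zero and more
than one spot, and the dispersion index. `scoreDetection()` matches
calls to truth greedily, nearest first, one-to-one within a radius
(default 3 voxels); the suite checks the greedy matching against an
exhaustive maximum-cardinality oracle.

## Plate rendering and counting

`renderPlate()` draws colonies as non-overlapping disks with sectors as
ideal wedges (half sector = 180 degrees) — spatially explicit colony
morphogenesis is out of scope. The GFP channel leaves red colonies at
background; the composite channel renders every colony bright.
`countColonies()` reproduces the threshold → binary image → connected
components counting used for totals: 8-connectivity, with a minimum-area
filter (default 20 px, an addition for robustness against single-pixel
noise). Touching colonies merge — a documented limitation of component
counting. Half-sector *scoring* from images is deliberately not
automated: the original analysis counted half and fully green colonies by
eye and only the total by thresholding, and the package follows that
division of labour.

## Numerical and design choices

* **Seeds.** Every stochastic function requires an explicit seed and
  restores the caller's RNG state; there is no hidden global state, and
  identical configurations give byte-identical outputs.
* **Estimator denominators.** Degenerate plates (total = fully green)
  raise an error rather than returning 0/0.
* **Degenerate t tests.** Zero pooled variance with equal means returns
  t = 0, p = 1; with different means, an infinite statistic with p = 0
  and a degeneracy flag.
* **Open estimator question.** Whether a first-division pre-replication
  event (which yields a fully green colony and is excluded by the
  denominator) should count toward the per-division rate is not specified
  by the printed formula. Simple mode sidesteps the question — no event
  produces a fully green colony; `cell_cycle` mode exposes it through
  `fPreReplication`, and users comparing modes should expect the
  estimator to recover $(1 - f_{\mathrm{pre}}) \, p_{\mathrm{div}}$.
* **Problem sizes.** The suite and the acceptance script use 3 replicates
  of 2×10^5 colonies for rate recovery (Monte-Carlo SE ≈ 5×10^-5 at the
  wild-type rate) and 10 stacks × 30 cells (≈ 3,600 spots) for the FISH
  round trip; both finish in well under a minute each on a laptop-class
  core and scale linearly for users who want tighter error bars.

## What the tests do and do not establish

The generator and simulator encode the study's stated conditions
(per-division rates of 10^-4–10^-1, Poisson-like control counts,
overdispersed reporter counts, 0.2 um z steps, diffraction-limited
anisotropic spots). Passing the suite shows the estimator, simulator,
caller and statistics are internally correct and mutually consistent at
those conditions. It does not validate performance on real microscopy
(aberrated PSFs, autofluorescent debris, imperfect masks), nor does it
test the biological model beyond the branching-process idealization
(synchronous divisions, constant rate per division, no death or drift
beyond the visible-horizon truncation).
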