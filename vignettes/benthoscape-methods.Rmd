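---
title: "Methods: predicting benthic diversity from full-waveform LiDAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting benthic diversity from full-waveform LiDAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthoscape)
```

## The scientific problem and the model

Epi-macrobenthic communities — the sessile and slow-moving macrofauna and
macroalgae living on the seabed surface — respond to two indirect
environmental gradients that green-laser bathymetric LiDAR can measure over
whole nearshore areas: water depth and the structural complexity of the
bottom. Depth integrates light, temperature and hydrodynamics; structural
complexity governs the supply of microhabitats and refuges. The working
hypothesis implemented here is that the *shape* of the benthic portion of
the LiDAR return waveform encodes that complexity: over flat simple bottoms
photons return in a short burst followed by a long low-intensity trail
(a right-skewed, temporally spread return), whereas structurally complex
covers reflect and absorb photons across a stack of surfaces before the
main peak, shortening the trail (a left-skewed, compact return). Diversity
indices computed from station photo-quadrats are therefore modelled as
functions of LiDAR-derived predictors, with classifiers benchmarked across
class discretizations and the selected model projected over the full grid.

The pipeline stages are: (1) a synthetic survey generator, (2) waveform
segmentation and 16 shape statistics, (3) quadrat diversity indices,
(4) quadratic-surface terrain morphometry, (5) supervised substratum
mapping with kernel beta-diversity rasters, (6) a 7-learner x 4-evaluator
benchmark over k = 2..10 equal-width classes, and (7) Moran's I plus the
predicted diversity map. `run_pipeline()` chains them under one seed.

## The synthetic survey generator

No survey of this kind is publicly deposited, so the generator is a
first-class, tested module that emulates the statistical structure the
analysis assumes — it defines the study conditions for every property test
in the package.

**Physical template.** The depth model is a shore-normal gradient over a
2-m cell grid (row 1 = shore), spanning 2–16 m (the upper bound mirrors the
practical bottom-detection limit of green LiDAR in moderately turbid
water), multiplied by a smooth shallowing bump anchored on the shore edge —
a sheltered embayment shallower than the 6.25-m threshold that also serves
as the ecological boundary in the depth model — plus a smoothed Gaussian
noise field, linearly rescaled to the configured range. The multiplicative
embayment keeps every column strictly increasing seaward, which the tests
exploit. Structural complexity is a [0, 1] field rising with depth (soft
nourished sands inshore, hard complex bottoms offshore) plus smooth noise;
substratum truth coarsens with complexity through fixed thresholds
(0.3 / 0.5 / 0.65) over a four-class grain-size legend.

**Waveforms.** Each sounding is a sum of: a Gaussian surface peak (sigma
2.5 ns) at 15 ns; an exponential water-column decay (rate 0.08 per ns); an
asymmetric Gaussian benthic pulse whose maximum sits exactly at
`t_surface + 8.9 ns/m * depth` — 8.9 ns/m is a design constant (two-way
travel at ~0.225 m/ns), used identically by the simulator and the feature
stage, so any consistent value would do; a gamma-shaped low-intensity
afterglow trailing the peak; and a constant 8-count dark baseline with
optional Gaussian noise (default SD 2 counts), clipped at zero. Complexity
drives the pulse asymmetry (rise width 1.2 + 1.8c ns, fall width
5.0 − 3.0c ns) and the afterglow (amplitude fraction 0.15(1 − c) of the
pulse, decay time 2 + 10(1 − c) ns). The afterglow is what gives
low-complexity returns their long positive tail; the gamma shape (zero
value and slope at the peak) keeps the pulse maximum at the travel-time
position. These constants were chosen while constructing the generator so
that the stated qualitative scenario holds — extracted benthic skewness
strictly decreasing in complexity at zero noise, time range shrinking with
complexity, temporal third moment changing sign from c = 0 to c = 1 — and
are not exposed as tuning knobs.

**Communities.** Station placement is uniform over cells, without
substratum stratification. Per station, a community linear predictor
`eta = depth_effect * scaled_depth + complexity_effect * scaled_complexity
+ noise` (defaults 1.6, 1.6, SD 0.4 on the logit scale) drives: occurrence
of each of the 12 biotic variables through logistic responses with
staggered baselines (so richness runs from ~0–1 inshore to ~8–10 offshore,
giving a realistic spread of quadrat richness); cover proportions of the
present taxa through a Dirichlet draw whose concentration `exp(0.8 +
0.8*eta)` makes communities more even along the gradient; and total biotic
cover `100 * plogis(-0.3 + 0.9*eta)` percent. Covers are quantized to the
100-square grid (integer percents), substratum classes fill the residual
image area weighted toward the station's true substratum, and summed
biotic cover stays at or below 100 % unless `layered_cover = TRUE` enables
overlapping canopies (overall abundance can then exceed 100 %, as real
layered vegetation does; the default keeps the simple non-overlapping
protocol). With these defaults the Simpson index spans the [0, 1] tercile
classes with all three populated and correlates strongly with depth —
deliberately a *strong-signal* configuration: its purpose is parameter and
relationship recovery, not effect-size realism.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real surveys: instrument noise spectra and flight-line
geometry; water-column inhomogeneity (the column decay is a single
exponential); species identities and interactions (taxa are exchangeable
labels); observation error in quadrat scoring; and the weak, noisy
biotic-abiotic coupling of real data (the paper-scale correlations of ~0.1
are far below the synthetic ones). Headline real-data numbers are therefore
not reproduction targets; the tests assert protocol constants, oracle
equivalence and qualitative structure instead.

## Waveform segmentation and statistics

Peaks are detected on a 3-sample moving average as local maxima whose
height and prominence exceed the noise floor (median of the first five
pre-surface samples) by three noise SDs; a relative floor of 0.001 of the
trace amplitude replaces the SD on noiseless traces. First prominent peak =
surface, last = benthic; fewer than two peaks raises the "bottom signal
lost" condition that mirrors the seaward detection limit. The benthic
interval runs from the last return to the noise floor before the benthic
peak (falling back to the inter-peak trough when the return rides on an
elevated column — the pure trough rule mis-segments deep soundings whose
column reaches the floor long before the bottom return) to the return to
the noise floor after it, widened to at least 10 samples so deciles are
always defined. The water column between surface end and benthic start is
fitted by a straight line; a persistent (two-sample) excursion of the
residuals above three residual SDs marks the column end, and the
transition interval spans column end to benthic start, kept at three or
more samples.

Statistics treat the intensity samples of an interval as an empirical
distribution (population moments; skewness and kurtosis as standardized
third/fourth central moments, kurtosis non-excess, both 0 by convention on
constant segments). Time range uses the global extrema of the interval —
with first-occurrence tie-breaking — and AUC is trapezoidal. The decile
Shannon index normalizes the 10th–100th percentiles (linear interpolation
between order statistics) to proportions and returns their entropy, ln 10
when all deciles are equal. Depth normalization regresses each feature on a
second-degree polynomial of depth and keeps standardized residuals
(all-zero when the residual variance vanishes); PCA retains the smallest
leading component set reaching 95 % of variance.

## Diversity indices

The Shannon index is computed on *image fractions* (cover %/100 of the
present biotic variables), read literally from its definition: it is not
scale-free, and the test suite asserts the literal form rather than the
abundance-normalized one. Log transforms are base 10 (consistent with
reported magnitudes of log-abundance for covers far above 100 %).
Zero-abundance quadrats set D, H′ and mJ′ to 0, and log transforms of
non-positive values are reported as 0 — documented conventions rather than
NaNs, so survey tables stay rectangular. Dead shells count among the 12
biotic variables, as listed in the scoring protocol.

## Morphometry

All surface fitting happens on heights z = −depth, so a shoal is a peak and
aspect (degrees clockwise from north, NA on flats) points downslope. Window
sizes follow the cell grid: a 6-m scale on 2-m cells is 3x3; 12 m would be
6 cells, an even count, so the nearest odd 7x7 is used. Curvatures are
−a−b ∓ sqrt((a−b)² + c²) from the quadratic coefficients; convexities use
the standard slope-normal/aspect-plane quadratic forms (pinned by in-repo
oracles; other GIS packages use different variants, which is an accepted
source of disagreement). The slope tolerance defaults to 1 degree and the
curvature tolerance to 0.005 per unit — small enough to label gentle
synthetic relief, large enough to absorb fit noise. Edge cells use
nearest-valid padding; windows containing missing values propagate no-data.

## Substratum mapping and kernel diversity

Ground truth is sampled as labelled pixels (2/3 training, 1/3 validation,
disjoint). The classifier is a radial-kernel SVM on standardized inputs
with a small grid search (cost 1/10/100, three kernel widths around 1/p)
under stratified 3-fold cross-validation; no post-classification smoothing
is applied. The kernel Bray-Curtis raster compares the class composition of
a disc kernel against a surrounding annulus grown until its cell count
reaches the disc's (locally equal-area); comparing against the map-wide
composition is available behind `reference = "global"`. Evenness divides
kernel entropy by ln of the number of classes *present*, matching the 0
(single class) and 1 (all classes equal) anchors. The default kernel radius
of 6 m matches the smaller terrain scale; it is a documented choice, not a
printed value.

## Benchmark protocol

Equal-width discretization uses the observed response range by default; the
bounded Simpson index D uses its theoretical [0, 1] interval (for k = 3
this produces the tercile cuts 1/3 and 2/3). The test split is a fixed
count of 100 stations (the "34 % of 300" protocol; the count takes
precedence if the survey size changes). The four evaluators: CA by argmax
(ties toward the lower class); AUC macro-averaged one-vs-rest with rank
ties at 0.5 (the binary rank definition generalized to multi-class);
the information score credits, per sample, the probability assigned beyond
the training prior, in bits, with priors clamped to [1e-6, 1 − 1e-6] so
classes unseen in training stay finite; the Brier score is halved so the
multi-class quadratic score respects the printed [0, 1] bounds (confident
misclassification of every sample scores exactly 1). Learner settings
default to the printed values (see `learner_settings()`). Where a backend
cannot express a setting exactly, the nearest expressible form is used and
noted: rpart has no m-estimate post-pruning (its default complexity pruning
stands in), and randomForest's minimum-10-to-split is expressed as
`nodesize = 9`. The regression tree predicts a numeric class code that is
rounded and clamped to a class (one-hot probabilities). The gain-ratio tree
and the covering-rule inducer are implemented in the package: the former
with binary threshold splits, minimum 10 samples to split, and pessimistic
subtree-replacement pruning at the 25 % upper binomial confidence bound;
the latter with decile candidate thresholds per predictor, a beam of 5,
Laplace rule evaluation, likelihood-ratio significance 0.05 with stopping
significance 0.2, exclusive covering, and a Laplace default rule.

Model selection excludes binary discretizations (they oversimplify the
ecology), maximizes CA, breaks ties by lower Brier score, then by the fixed
learner order — fully deterministic. Trend fits regress an evaluator series
on 1/k by OLS with R²adj = 1 − (1 − R²)(n − 1)/(n − 2) and define R² = 0
for constant series. Binned trends sort stations along a predictor and
average consecutive blocks of 20 before fitting polynomial or logarithmic
models.

## Spatial statistics

Moran's I uses row-standardized 8-nearest-neighbour weights by default (the
original exploratory tool's scheme is unprinted; distance-band and
rook/queen schemes are provided), the closed-form expectation −1/(n − 1),
and a one-sided (positive autocorrelation) permutation p-value with 999
seeded permutations. Significance by permutation may well disagree with
informal "not significant" judgements of moderate I values; the p-value is
reported, not calibrated. The predicted map retains per-class probability
layers so users can re-threshold.

## Problem sizes and numerical choices

Package defaults: a 60 x 80-cell grid (4800 soundings), 300 stations, and
the full 8-response x 7-learner x 9-k sweep. The test suite exercises the
full learner sweep at one seed for the Simpson response and the
random-forest recovery at ten seeds on the default survey; module tests use
15 x 20 to 30 x 40 grids — sizes chosen so the suite gives stable
statistical answers while remaining comfortable to run interactively. All
randomness flows from explicit integer seeds; helper draws save and restore
the RNG state, and reruns are bit-identical. Interval bins are right-open
except the last; cell indices are 0-based in discretized labels and 1-based
in raster row/col, with cell-centre coordinates and row 1 at the north
edge throughout.

## Known limitations

Raster I/O is plain-text ESRI ASCII grid (no GeoTIFF, no CRS metadata);
ground truth is pixel-based rather than polygonal. The C4.5- and CN2-style
learners are faithful to the printed settings but are reimplementations,
not the original software, so their exact trees/rules can differ from
historical runs. The regression-tree probability model is degenerate
(one-hot), which penalizes its Brier and information scores. Waveform
segmentation assumes a single benthic return; overlapping surface and
benthic peaks shallower than ~1 m, or multiple bottom echoes, are out of
scope. The synthetic generator's strong, monotone gradients make recovery
tests meaningful but flatter than nature; conclusions about real surveys
require real ground truth.
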