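---
title: "Quantifying multi-neuron phenotypes: methods and design notes"
author: "neuroHCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-neuron phenotypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroHCS)
```

## The problem

High-content screens of neuronal cultures produce micrographs in which
hundreds of neurons overlap. Tracing single cells in such images is
impractical, so the unit of analysis here is the *whole image*: every
drug dose (the benchmark compound is nocodazole, a microtubule
depolymerizer that retracts neurites) is characterized by the collective
morphology of the population in each frame. The package covers the full
workflow: segmentation and morphometry, generic image descriptors,
dose-response statistics, and discriminative feature selection around an
SVM classifier — plus a synthetic-scene generator that provides exact
geometric ground truth so that every stage is testable without original
screen images.

## Segmentation and the 13-feature neuromorphology descriptor

Four parameters drive preprocessing, with defaults `contrast = 13`,
`somaIntensity = 288`, `neuriteWidth = 5`, `particleCleanup = 15`
(16-bit gray levels and pixels; the absolute soma threshold of 288 only
makes sense above 8-bit depth, which is why the synthetic renderer works
on a 16-bit scale). The stages are re-derived from the feature
definitions rather than copied from any particular tool:

* **Background**: grayscale opening with a large disk (radius 25 px by
  default; it must exceed the largest soma) estimates the smooth
  background; after subtraction, pixels below `contrast` are zeroed.
* **Somata**: an opening with a disk of radius `neuriteWidth` erases
  thin processes; thresholding at `somaIntensity` and removing
  components below `particleCleanup` yields the soma mask. Touching
  cell bodies merge into one component — a real phenomenon at high
  dose (soma clustering), so it is deliberately not undone.
* **Neurites**: a white top-hat with the same disk keeps structures
  thinner than roughly `2 * neuriteWidth`; the soma mask (dilated by
  2 px to suppress boundary ribbing) is removed and small particles
  cleaned up.
* **Skeleton**: Zhang-Suen parallel thinning, followed by a sequential
  pass that dissolves any remaining 2 x 2 foreground block while
  preserving local connectivity, and by spur pruning (terminal twigs of
  at most 4 px that end in a junction are thinning artifacts, not
  arms).
* **Landmarks**: an ending point is a skeleton pixel with exactly one
  8-neighbor. A branch point matches a 3 x 3 branch pattern,
  formalized as: at least three skeleton neighbors falling in at least
  three circular runs around the pixel; adjacent hits of one junction
  are clustered (1-px bridge) and reported once. An attachment point
  is a run of skeleton pixels inside a 7-px dilation ring of the soma
  mask — the ring must bridge the 2-px soma exclusion border plus the
  terminal retraction of thinning (about half a stroke width).
  Skeleton termini inside that ring are contacts, not free ends, and
  are excluded from the ending-point count.

The descriptor is the vector of seven cumulative features — soma count,
soma area, neurite length (skeleton pixel count), neurite area, and the
attachment/ending/branch point counts — plus the six per-neuron averages
obtained by dividing each cumulative feature except the count itself by
the soma count. With no detected soma the averages are undefined and
reported as `NA` with a warning; classification drops such rows.

Neurite length is a *pixel count*, not a diagonal-weighted path length:
that matches the ImageJ-lineage convention the descriptor extends, and
it undercounts Euclidean length by up to about 10 % for isotropic
orientations (a 45-degree segment counts cos 45 of its length in
pixels). The ground-truth tolerance of +/-15 % absorbs this bias; on the
separated test scenes the observed error stays within about -12 % to 0.

## Generic descriptor bank

Seven descriptor families with fixed feature counts; shape families use
the binary foreground, texture families the grayscale image:

| family | count | notes |
|---|---|---|
| Zernike moments | 4/9/25/81 (orders 2/4/8/16) | magnitudes on the centroid-anchored unit disk |
| Legendre moments | 9/25/81/289 | `[-1, 1]^2` mapping, `(2p+1)(2q+1)/(NM)` normalization |
| Tchebichef moments | 9/25/81/289 | orthonormal discrete Chebyshev recurrence |
| generic Fourier | 60 | 5 angular x 12 radial frequencies, DC-normalized |
| Haralick | 180 | see below |
| Gabor | 60 | 6 orientations x 5 octave-spaced scales, mean and SD of response magnitude |
| Daubechies-4 | 30 | 10-level 2-D DWT, mean energy of the three detail bands per level |

**The Haralick layout.** Distances 1..5 and angles 0/45/90/135 degrees
give 20 symmetric, normalized 8-bin co-occurrence matrices. Computing 18
statistics per matrix would give 360 raw values; the package follows the
classic aggregation — the mean and the range over the four angles per
(statistic, distance) — which yields exactly 18 x 2 x 5 = 180 features.
The 18 statistics are Haralick's 13 classic measures (angular second
moment, contrast, correlation, variance, inverse difference moment,
sum average/variance/entropy, entropy, difference variance/entropy, and
the two information measures of correlation) plus five common
extensions: autocorrelation, dissimilarity, cluster shade, cluster
prominence and maximum probability. Degenerate single-bin images follow
limit conventions (contrast 0, ASM 1, correlation and IMC1 reported
as 0).

**Other numerical choices.** Gabor statistics are computed on the
response *magnitude* of the complex filter (the natural
phase-invariant choice); the bank is octave-spaced from 0.25 cycles/px
with one-octave bandwidth. The wavelet transform uses the 4-tap
Daubechies filter with periodic boundary handling — that makes the
energy-conservation (Parseval) identity exact, which the tests exploit —
after reflect-padding the image to the smallest size divisible by
2^levels. The quantization for co-occurrence matrices is uniform over
the per-image min-max range.

## Dose-response statistics

Doses enter regressions as `x = log10(concentration)`, with the 0-dose
control mapped to `x = 0`. The convention is deliberate: applied to the
published per-dose group means it reproduces the published regression
coefficients (e.g. soma count `-35.5 x^2 + 81.2 x + 218.8` against the
printed `-35.3 x^2 + 80.4 x + 219.3`, within the 3-significant-figure
rounding of the means), which pins down both the base-10 logarithm and
the control mapping.

Per feature the chain is: Shapiro-Wilk normality (reported, not
gating), a Bartlett homoscedasticity gate at alpha = 0.05, then the
standard pooled ANOVA when the gate passes or Welch's variance-weighted
ANOVA when it fails, followed by Tukey HSD letters (Tukey-Kramer with
the pooled within-group variance in both branches) and the log-dose
regression. The ANOVA `R^2` is always the between-group share of total
variation. Null simulations of the full gate-then-test chain (6 groups
x 36, same normal) hold the nominal 5 % type-I rate within +/-1.5
points over 2,000 replicates.

**Model selection.** Both a linear and a quadratic model are fit by
ordinary least squares; the quadratic is chosen when its R-squared gain
exceeds 5 % of the variation the linear model leaves unexplained. The
rule operates on the *total-variance* scale. This matters: on the
between-group scale the rule would pick the quadratic for total neurite
length, contradicting the published choice, because dividing by the
(large) within-group variation shrinks both R-squared values and the
5 % margin proportionally. With per-image data the total-scale values
are direct; when only group means are available the feature's ANOVA
R-squared rescales the between-group shares (the `anovaR2` argument).
In a balanced design the fitted coefficients from per-image values and
from group means coincide, which is what lets the packaged group means
stand in for raw data. The share of between-group variation captured by
the selected model is the *variance explained* column; a fit is
"successful" when it exceeds 90 %. Regressions are computed from
per-image values when available, so standard errors are per-image-based;
a third-order polynomial is intentionally not part of the automated
ladder.

## Classification and inheritable bi-objective selection

Images are split 2/3 : 1/3 stratified by dose (round-half-up per
class; 216 images become 144 + 72 with 24/12 per class). The classifier
is a radial-basis soft-margin SVM (libsvm's one-vs-one multi-class);
C and gamma come from the 16-value grid 2^-7 .. 2^8, tuned either by an
exhaustive 256-point grid search or by the genetic algorithm's two
4-bit parameter genes. Features are z-scored with statistics fit on the
training side of every split or fold — never on held-out data. The
fitness folds are fixed within a run (re-randomizing them per
evaluation would make fitness values incomparable across a
generation).

The selection chromosome carries one bit per feature plus the two
parameter genes. At stage r every individual has exactly r feature
bits set; swap mutation exchanges a set and an unset bit, and
orthogonal-array crossover evaluates the differing genes on the
smallest two-level orthogonal array, returning the best evaluated row
and the main-effect composition (children are repaired back to r by
flipping the bits with the weakest main effects). For additive fitness
the main-effect child provably attains the exhaustive optimum over the
differing bits, which the tests verify against full enumeration. Stages
sweep r from 13 down to 1; on inheritance each individual drops one
randomly chosen selected feature. The printed description of the
inheritance step flips a bit "from 0 to 1", which cannot decrease r and
is impossible at r = n; the package treats that as a typo and flips
1 -> 0, consistent with the stated sweep direction. Population size,
tournament size and per-gene mutation rate are not prescribed anywhere;
the defaults are 50, 2 and 0.05, all configurable. The final solution
is the best 10-fold cross-validation accuracy over all stages, ties
resolved toward fewer features (the second objective); repeated runs
are aggregated into per-feature selection frequencies.

## What the synthetic generator emulates — and what it does not

`generateDoseSeries()` renders the six-dose design (0, 10, 50, 100,
200, 1000 ng/mL; 36 images per dose; doses are labeled in ng/mL
throughout, following the benchmark's tables over its inconsistent
in-text unit). Per-class trends are piecewise-linear interpolations (on
log dose) of the published group-mean patterns, scaled to a renderable
population: mean soma count 14.0 -> 8.6 per 256 x 256 frame (published
counts divided by 16), per-soma neurite abundance falling 2.4 -> 0.6,
per-neurite length falling 45 -> 8 px (the published per-soma length
column scaled by 0.12), and soma clustering probability rising 0 ->
0.5. Scene noise has two dials: a coefficient of variation (default
0.15) on the per-image parameter draws, and additive clipped Gaussian
pixel noise (default SD 3 gray levels — low enough that the standard
contrast step of 13 separates foreground from the noise floor, as it
does on the camera data the parameter set presumes). Rendering uses
Bresenham polylines dilated to the stroke width — reproducible integer
geometry — and ground truth comes from the specifications (Euclidean
arc lengths, spec-level landmark counts), never from the rendering.

`sampleScene()` builds the *landmark-exact* fixtures used by the
recovery tests: up to four neurons on a tile grid, neurites in
disjoint angular sectors, and a stroke-separation test that rejects
branches curling back onto their parent. On such noiseless scenes
extraction recovers every landmark count exactly on 50 seeded scenes
and skeleton length within the 15 % tolerance.

What the generator does *not* emulate: point-spread blur, uneven
illumination, autofluorescence texture, intensity falloff along
neurites, and truly interwoven arbors crossing many cells. Passing
tests on synthetic data therefore validate the *mechanics* of the
pipeline (geometry, counts, statistics, selection), not its robustness
to real acquisition artifacts; the published real-data accuracies are
not reproducible without the original images and are not targets of
the test suite.

## Problem sizes used by the tests

The test and acceptance runs use sizes chosen to keep the full suite
comfortably interactive while preserving every contract: 256 x 256
frames; 50 seeded scenes for ground-truth recovery; 2,000 null
replicates for the type-I check; the planted-selection study runs the
full 13 -> 1 stage sweep with population 12, 4 generations per stage,
3-fold fitness and 10 runs (the production defaults remain 50
individuals, 20 generations, 10-fold and 30 runs); the end-to-end
screen uses the complete 216-image design. The planted table gives the
three informative features complementary monotone step signals so that
all three are needed to separate the six classes — redundant planted
signals would legitimately let the bi-objective criterion drop one, as
happens with collinear real features.

## Known limitations

* The exact 3 x 3 pattern list of the original branch operator is not
  published; the circular-run formalization used here is validated
  against exhaustive neighborhood enumeration, not against the original
  implementation.
* Whether the original 180-feature texture layout used mean+range
  aggregation is unverifiable; the choice is frozen and documented
  above.
* Skeleton length underestimates Euclidean length for diagonal
  geometry by construction (pixel-count convention).
* Welch-gated features still receive pooled-variance Tukey letters,
  mirroring the benchmark's own workflow rather than a
  heteroscedasticity-consistent post hoc.
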