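---
title: "Multi-resolution classification of whole-slide images: models, parameters, and design choices"
author: "panoptes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution classification of whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panoptes)
```

# The problem

Digital pathology slides are gigapixel image pyramids carrying only weak,
slide-level labels: a patient's histological or molecular subtype is known,
but no pathologist has outlined which regions express it. The standard
recipe — cut the slide into small tiles, train a convolutional classifier on
tiles inheriting the slide label, and average tile scores per patient —
discards an essential aspect of how pathologists read slides: architecture
at low power and cytology at high power are judged *together*. This package
implements a complete, desk-scale version of that recipe with a
multi-resolution twist: each training sample is a *tile set* — three
co-registered 299 px tiles of one region at 10x, 5x and 2.5x equivalent
magnification, each higher power covering one fourth of the area of the
next lower power — and the Panoptes model family consumes all three at
once through parallel convolutional branches.

# Pipeline stages and their parameters

## Tiling and filtering

A slide is partitioned into non-overlapping 299 px cells at 2.5x
equivalent magnification (stride = tile size; overlap would silently
inflate per-patient tile counts). Each cell holds a 4x4 lattice of 10x
tiles and a 2x2 lattice of 5x tiles, so a fully usable cell yields 16
matched tile sets. Edge cells are dropped rather than padded — padding
would fabricate tissue.

A pixel is background or contaminant when all three RGB channels fall
below 50 (dark debris) or all three exceed 200 (white glass), on the 0-255
scale; a tile is discarded when strictly more than 40% of its pixels are
background, so a tile at exactly 40% is retained. A tile set is kept only
when **all three** member tiles pass: every branch of the model then sees
informative pixels. Filtering happens on raw pixels, before stain
normalization, because normalization remaps near-white background and
would corrupt the background fraction.

Coordinates are 0-based, half-open rectangles, always expressed in the
level-0 frame. Magnification equivalence follows the usual calibration
(0.25 um/px is called 40x, 0.5 um/px 20x, nearest match); when no pyramid
level matches a requested factor, the nearest finer level is read and
resampled — box (area) averaging for integer residual factors, bilinear
interpolation otherwise, chosen because box filtering is antialiased,
cheap and order-independent. When tiles are *shrunk* (to a storage or
model-input size), the package uses a box-prefiltered resize
(`resizeBox`): plain point-sampling at a 4x shrink would alias
high-frequency texture into the output and bury smooth low-frequency
signal under noise.

## Stain normalization

H&E color variation is removed by structure-preserving (Vahadane-style)
normalization: the tile's optical densities (`OD = -log((I+1)/256)`) are
factorized as `OD ~ C S` with a 2x3 nonnegative unit-row stain basis `S`
and nonnegative concentrations `C` under an L1 penalty (weight 0.10, OD
background threshold 0.15, both the published defaults of the method);
concentrations are rescaled so their tissue 99th percentiles match a
reference profile and recombined with the reference basis. Estimation
alternates L1-penalized coordinate descent for `C` with an exact projected
least-squares update for `S`; after the sparse phase pins the basis
orientation, the basis is refit with unpenalized concentrations — the L1
step biases `C` additively and the refit removes the resulting tilt. A
tile whose optical densities are already explained by the reference basis
(relative residual below 0.02, the 8-bit quantization floor) keeps the
basis unchanged, making normalization a fixed point on already-normalized
tiles. The default reference basis is the conventional H&E
optical-density matrix; the normalization target is convention-dependent
(the underlying method never fixes a reference image), so only invariance
properties — idempotence, cancellation of global stain-intensity scaling —
are meaningful tests. `tileSlide` estimates stains per tile by default
(no slide-level intensity residue can survive into the records); a
per-slide mode (one basis fit on a thumbnail) is offered for speed at
full tile size. Note one interaction worth knowing: per-tile
99th-percentile rescaling equalizes within-tile contrast across tiles,
so class signal carried purely by within-tile contrast amplitude is
attenuated by normalization — the synthetic learning study therefore
runs on unnormalized records (see below).

## Cohorts, splits, records

Labels live in a per-patient table (patient, slide, cohort, 0/1 task
labels, age, BMI). Splits are drawn at patient level — 8:1:1
train/validation/test in mixed mode, stratified by label within one
patient of exact proportions; cohort-independent mode holds out one whole
cohort as test and splits the rest 9:1 — and re-drawn (bounded retries)
until every partition holds at least one positive and one negative slide.
Class weights equalize training composition: `w_c = N / (2 N_c)` over
training tile sets. Tile sets stream into sharded, length-prefixed binary
records with md5-checksummed JSON manifests; pixels are stored at 8-bit
depth (the acquisition depth), so write/read round trips are lossless.
Missing age/BMI are imputed with the training median and flagged.

## Models

Panoptes1-4 are three-branch networks (branch plans follow the
Inception-ResNet v1 topology for Panoptes1/3 and v2 for Panoptes2/4);
baselines are the same branch fed only the 10x tile, in five flavors
(Inception v1/v2/v3, Inception-ResNet v1/v2). Each branch is a compact
Inception-style extractor — two strided stem convolutions, one or two
inception blocks with parallel 1x1/3x3 paths (residual connection in the
ResNet families), a strided reduction carrying an auxiliary classifier
head, and a 1x1 tail. Every convolution is followed by batch
normalization (non-affine; the next convolution absorbs scale), as in the
Inception lineage these branches abbreviate — without it, training
networks this small from scratch is an initialization lottery: gradients
reach the early layers at wildly varying scales and most runs sit at
chance loss for hundreds of iterations. Running mean/variance buffers
travel with the weights and are used in evaluation mode. Branch feature maps are concatenated on the channel
axis (equal input sizes guarantee equal spatial grids), optionally passed
through a 1x1 feature-pooling convolution (Panoptes3/4, 1024 channels at
full width), then global average pooling, optional concatenation of a
clinical embedding (age and BMI standardized on the training partition,
with missingness flags, through a 4-16-16 perceptron), dropout, and the
final fully connected layer. Inputs are scaled to [-1, 1], the
preprocessing convention of the Inception lineage.

The concatenate-then-pool-then-classify reading of "merging at the
third-to-last layer" is deliberate: pooling after concatenation lets the
final layer weigh branches against each other per channel. The clinical
embedding joins after pooling and is kept small (16 units) so two scalars
cannot swamp hundreds of image channels. A `widthMultiplier` scales every
channel count uniformly (parameter counts are monotone in it) and
`inputPx` may shrink to 75 px — affordances for CPU-scale runs that leave
the full-scale defaults untouched. Dropout keep rate 0.3 means keeping
30% of units: an unusually aggressive setting, implemented literally.
The auxiliary loss weight is 0.4, the long-standing default of the
Inception lineage.

## Training schedule

The loss is class-weighted softmax cross-entropy on the main logits plus
0.4 times the mean of the branch auxiliary cross-entropies, optimized
with Adam (framework-default moments). Full-scale constants: learning
rate 1e-4, batch 24 for Panoptes and 64 for baselines, validation of 100
batches every 1000 iterations *and* whenever the training loss sets a new
minimum after iteration 30000; a checkpoint on every new validation
minimum; stop after 10000 iterations without a validation minimum,
enforced only from iteration 100000. The policy is implemented as a state
machine (`runTrainingLoop`) that takes step/validate/checkpoint callbacks,
so it is testable against a simulation oracle with scripted losses.

Desk-scale runs (`deskSchedule`) keep the structure and shrink the
counters (validate 8 batches every 50 iterations, loss-minimum window
from 150, patience 200 enforced from 400, 600-iteration cap) and raise
the learning rate to 3e-3: width-0.1 networks carry much smaller
gradients than the full-width models the 1e-4 default serves, and at
1e-4 they sit at chance loss for the whole desk budget while 1e-2
destabilizes. The 100000-iteration stopping floor is a policy constant,
not a correctness requirement, and is exercised only in scaled form.
Desk-scale training also enables dihedral (rotation/flip) augmentation —
the same random square symmetry applied to the three co-registered
members of a sample, so the set stays aligned. With a few dozen training
slides, an unaugmented network memorizes tiles long before it finds
orientation-invariant tissue features; augmentation is off by default at
full scale, where data volumes of hundreds of slides make it unnecessary
for the properties tested here.

## Evaluation

One tile set counts as one tile. Per-patient scores are the arithmetic
mean of a patient's tile-set probabilities; patient-level metrics treat
each patient as one sample. (The alternative reading — average per-tile
*metrics* per patient — is ill-defined for AUROC and was not used.)
AUROC is the Mann-Whitney probability with ties counted one half,
verified against exhaustive pairwise comparison; AUPR is stepwise average
precision; hard calls use a strict `score > 0.5` rule, so exactly 0.5 is
negative. 95% CIs come from 1000 percentile-bootstrap resamples over
patients (patient level) or tile sets (tile level), single-class
resamples redrawn; 1000 is the conventional default, while the distinct
50-resample / 80%-rate scheme is reserved for architecture comparison
exactly as specified: 50 AUROCs per model from 80% subsamples without
replacement, compared by a one-sided unpaired t-test. The tile-level
class comparison uses the unpaired one-sided rank-sum test (positive and
negative tile groups have unequal sizes, so a paired test is mechanically
impossible); small tie-free samples are enumerated exactly, larger ones
use the normal approximation with tie correction.

## POLE composition

The POLE subtype is classified indirectly: the composed score is the mean
(optionally product) of the *complements* of the member models' positive
scores (CNV-H, CNV-L, MSI-high). Mean is the default because it is the
minimal reading of "aggregating"; the composed table flows through the
standard evaluation unchanged. Tile-level composition joins members by
tile-set id when they share a tiling; otherwise composition happens at
patient level.

## Visualization

Penultimate feature vectors (post-pooling, post-clinical-concat) are
subsampled (20000 by default), projected to 100 principal components, and
embedded by exact tSNE (perplexity 30, 1000 iterations, O(n^2) — adequate
for the few thousand points of desk-scale runs), colored by prediction
score on a fixed 0-1 diverging scale with midpoint 0.5. Heatmaps write
each tile-set score into the cell of its 10x anchor on a
`floor(extent10x / 299)` grid; unfilled (filtered) cells stay missing and
render transparent over the slide thumbnail.

# The synthetic study and what it shows

The generator renders tissue through the same two-dye optical-density
model the stain module assumes: an eosin-like concentration field (stroma
texture) plus a hematoxylin-like field (diffuse baseline and Poisson
nuclear dots, 300 per 299 px tile, Gaussian radius 2.2 px), white margins
and dark contaminant disks with a ground-truth mask, and pyramid levels
by area averaging. Slides are 1196 px at 10x equivalent by default (one
2.5x cell, 16 tile sets); cohorts draw age ~ N(64, 10) years and BMI ~
N(30, 6) kg/m^2, typical of an endometrial-carcinoma population.

The class signal is planted at a chosen scale. In macro mode the eosin
field is a rank-transformed mixture of two Gaussian random fields: a
micro texture (correlation length 8 px, amplitude 2.5) identical across
classes, and a macro field (correlation length 300 px for class 0, times
`1 + effect` for class 1, amplitude 1.0; the end-to-end study uses effect
3, its "large" setting). The rank transform fixes the
single-pixel marginal exactly (a Beta(2,2) shape over concentrations
0.35-1.0), so classes cannot be told apart by pixel histograms at any
scale; the micro amplitude dominates within-10x-tile variation, hiding
the residual macro slope there, while a 2.5x tile spans several macro
correlation lengths and exposes the class difference as within-tile
smoothness. Both lengths were sized so that each 2.5x tile is a stable
estimate of the macro scale: with macro lengths comparable to the slide,
each slide is a single macro realization and slide-to-slide chance swamps
the class effect, and with micro texture much coarser than the macro-band
averaging window its leakage floods the macro statistic (at these
constants, the slide-level macro-band gradient statistic separates 30
realizations per class perfectly). In micro mode the nuclear-dot density
scales by `1 + effect` for class 1 with identical macro arrangement.

The end-to-end study (40 patients, two slides each, macro signal, effect
3, a quarter of patients held out as the test cohort with the remainder
split 9:1) shows the property that motivates the architecture: a
width-0.1 Panoptes reaches per-patient test AUROC at or above 0.9 while
the 10x-only baseline's per-tile AUROC bootstrap CI covers 0.5. The
study's records skip stain normalization: every synthetic slide is
rendered in the same reference basis, so normalization is an identity
there up to estimation noise, and that noise is exactly the kind of
slide-level nuisance a small network will shortcut on; the
normalization's own properties are verified separately. The test-set
geometry is sized for the statistic being claimed: each patient's 2.5x
evidence is a handful of independent texture realizations, so a patient
is occasionally misread by realization chance, and with only four test
patients a single misreading destroys a 2-vs-2 AUROC — ten held-out
patients with two slides each make the patient-level AUROC an honest
estimate. The baseline's "covers 0.5" check is evaluated at tile level
(320 test tile sets) for the same reason. The null check (effect 0) uses
a 30-patient cohort with a 12-patient held-out test cohort so the
patient-level bootstrap interval is non-degenerate; it must cover 0.5.

What passing does and does not show: the synthetic texture exercises the
geometry, filtering, normalization, learning and evaluation machinery
under a controlled scale-specific signal, but it is not photorealistic —
real H&E slides carry nuclei morphology, staining artifacts, pen marks,
within-slide label heterogeneity and scanner variation that the generator
does not emulate. Desk-scale results demonstrate mechanism, not clinical
performance.

# Numerical choices and degenerate inputs

* Region reads validate bounds before touching pixels and fail with the
  offending rectangle; requests beyond the base magnification fail.
* Slides smaller than one 2.5x cell yield an empty plan, not an error;
  all-background slides tile to zero sets with an explicit summary.
* Unstainable tiles (fewer than 100 pixels above the OD threshold) raise
  a typed condition; `tileSlide` keeps such tiles unnormalized and counts
  them.
* Single-class prediction tables make AUROC/AUPR `NA` with a warning —
  never silently 0 — and bootstrap resamples that lose a class are
  redrawn.
* AUROC ties count one half, which matters on small synthetic tables
  where scores collide exactly.
* All randomness (splits, shuffles, dropout, initialization, bootstrap,
  tSNE) flows through seeds derived from a run seed by hashing, so every
  artifact is reproducible and sub-computations are decorrelated.
* Training is synchronous and single-stream; data-loading order is fixed
  by the seed, so worker parallelism cannot change batch composition.

# Problem sizes

Built-in studies run at deliberately small scale: 1196 px synthetic
slides (16 tile sets each), 75 px stored tiles, width-0.1 models, at
most 600 training iterations under the desk schedule, 30-40 patient
cohorts with one or two slides per patient, 100-1000 bootstrap
resamples. Full-scale constants (299 px inputs, width 1.0, the
1000/30000/10000/100000-iteration schedule) remain the defaults of the
corresponding classes.

# Known limitations

* No GPU path: the convolution engine is plain R linear algebra, fine at
  desk scale and deliberately not a training platform for full-width
  models.
* SVS/SCN vendor formats require external conversion to pyramidal TIFF;
  the reader handles multi-page TIFF plus a JSON metadata sidecar.
* Slide-level weak labels are inherited by every tile; within-slide
  heterogeneity is noise the pipeline does not correct.
* tSNE is exact O(n^2); embedding much beyond ~5000 points calls for a
  Barnes-Hut implementation instead.
* The stain model is strictly two-dye; a third chromogen would violate
  the rank-2 factorization.
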