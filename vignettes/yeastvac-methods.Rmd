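---
title: "Methods: quantifying vacuole fusion and lipophagy in yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vacuole fusion and lipophagy in yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(yeastvac)
```

# The biological question

During starvation, vesicles of the yeast vacuole (the lysosome
equivalent of *Saccharomyces cerevisiae*) fuse into one central
compartment, and lipid droplets (LDs) are ingested into the vacuole and
degraded — a selective autophagy called lipophagy. Both processes are
classically scored by eye: vacuoles stained with the lipophilic dye
FM 4-64 are classified as *fully fused* (one central vacuole) or
*partially fused* (a multi-vesicular cluster), and BODIPY 493/503-stained
droplets are counted inside and outside the vacuole. Manual scoring is
slow and hard to standardize, and wide-field fluorescence cannot resolve
whether a droplet sits inside the vacuole lumen. This package automates
both readouts: a classification network for two-channel fluorescence
fields, and a segmentation pipeline for cryo soft X-ray tomography (SXT)
reconstructions, where droplets appear as strongly absorbing spheres and
the water-filled vacuole lumen as the least absorbing compartment.

Everything is testable without microscope data: synthetic generators
produce two-channel fluorescence fields and 3D tomography phantoms with
complete ground truth, including a limited-angle filtered back
projection (FBP) simulator that reproduces missing-wedge artifacts.

# Fluorescence branch

## Cell detection and ROI extraction

`detect_cells()` finds single cells in the red (vacuole) channel:

1. Canny edge detection with percentile-based hysteresis thresholds
   (the thresholds adapt to exposure, so no absolute gradient values
   need tuning);
2. a circular Hough transform over a radius interval covering plausible
   cell radii (1 px steps), each radius voted by convolving the edge map
   with a normalized ring kernel;
3. a max projection of the accumulator over radii, blurred with a
   Gaussian of sigma 5 px;
4. greedy local peak finding with a minimum separation of one mean cell
   diameter. Equal peaks are taken in row-major order, so results are
   deterministic.

The channel choice (red) is ours: the membrane outline and vacuole rings
dominate that channel. `extract_rois()` crops a 100 x 100 px (or
50 x 50 px, depending on acquisition) square per peak from all channels,
pads at field borders with the channel median, rescales to 64 x 64 by
bicubic (Keys cubic-convolution, a = -0.5) interpolation, divides by the
camera saturation (2047 or 7500 counts for the two supported
acquisitions) and clips to [0, 1].

## The classification network

`dyfnet_build()` defines a compact CNN: three blocks of 3 x 3
convolution (16/32/64 filters), ReLU, local response normalization
(LRN) and 2 x 2 max pooling, then two dense ReLU layers of 64 units and
one sigmoid output — the probability of the *positive* class
("partially fused" for the fusion model; "usable" for the rejection
model). LRN hyper-parameters follow the classic ImageNet-era defaults
(radius 5, k = 1, alpha = 1e-4, beta = 0.75) and are configurable.
Training uses the Nadam optimizer under binary cross-entropy;
augmentation applies flips, 90-degree rotations and elastic
deformations with alpha = 60, sigma = 15 (displacement fields drawn
uniformly in [-1, 1] per pixel, Gaussian-smoothed, scaled, shared across
channels through a common seed).

`crossval_train()` performs stratified 8-fold cross-validation, pools
the out-of-fold predictions into one confusion matrix, and keeps all
fold models. Deployment (`classify_rois()`) is a two-stage ensemble:
the rejection ensemble filters unusable ROIs first; survivors get a
fusion label from the rounded mean of the 8 fold-model outputs
(label 1 iff mean >= 0.5). The rounded-mean rule makes the ensemble
invariant under permutation of its models.

## Error-corrected prevalence statistics

The fusion classifier's printed operating point (accuracy 86.02%,
sensitivity 71.24%, specificity 92.08%) determines everything else:
accuracy is the prevalence-weighted mean of sensitivity and
specificity, so `complete_metrics()` solves

$$\mathrm{acc} = \pi\,\mathrm{sens} + (1-\pi)\,\mathrm{spec}$$

for the prevalence $\pi$, assembles the rate-form confusion matrix and
reads off PPV, NPV and the Matthews correlation coefficient.

`correct_fractions()` inverts the classifier's error process with the
standard linear (Rogan-Gladen-style) estimator

$$\hat p = \frac{p_{\mathrm{obs}} + \mathrm{spec} - 1}
                {\mathrm{sens} + \mathrm{spec} - 1},$$

clipped to [0, 1], assuming the error rates are constant across
conditions. When rejection-stage metrics are supplied, the population
size is first rescaled by the same estimator applied to the accepted
fraction, then the fusion correction is applied; this sequential
composition is one of several defensible choices and is recorded in the
result's metadata.

`empirical_pvalue()` tests a difference in classified fractions against
the null that both conditions share one error process at the pooled
observed prevalence. Each of the (default 100,000) iterations draws two
predicted-label samples of size $m = \min(n_A, n_B)$ and records the
difference of means; the p-value is
$(\#\{|d| \ge |d_{\mathrm{obs}}|\} + 1)/(N + 1)$, two-sided by default,
never exactly zero. Because predicted labels are i.i.d. Bernoulli under
the null, the per-iteration count is drawn as a single binomial — exactly
equivalent to drawing $m$ labels, and fast enough that the full 100,000
iterations run in milliseconds. At the pooled observed prevalence the
predicted-positive probability equals the pooled observed fraction, which
is what the implementation uses.

# Tomography branch

## Normalization and slab assembly

`preprocess_stack()` rescales every z-slice to 512 x 512 (bicubic; the
original dimensions are kept so native pixel sizes can be recovered) and
quantile-normalizes the whole stack: every voxel is replaced by the
standard-normal reference value of equal rank, with ties broken by
stable order. The reference is the deterministic inverse-CDF grid
$\Phi^{-1}((i - 0.5)/n)$ rather than a random normal sample —
reproducibility without an RNG; a `sample_seed` mode provides the
sampled-reference variant. The network input is a slab of five
consecutive normalized slices centered on the target slice
(edge-replicated at stack boundaries), which gives the 2D network local
3D context against missing-wedge artifacts.

## The segmentation network

`unet_build()` is an encoder-decoder with skip connections by
concatenation: five encoders (doubling filters from a base of 32), a
bridge, five decoders, blocks of two (convolution, batch normalization,
ReLU) sets with the second set at half the filters, 2 x 2 max pooling
down, 2x nearest-neighbour up-sampling up (the up-sampling operator is
not dictated by the architecture description; nearest-neighbour is the
simpler choice and is configurable in principle via the code), zero
padding throughout, and a single 1 x 1 sigmoid convolution head. Each
channel — cell membrane, vacuole, droplet — is trained as its own model;
a trained channel can warm-start another (`init` argument), which the
warm-start test shows lowers the initial loss.

## Loss

Training uses the compound loss `(1 - soft Dice) + TopK-BCE`:

* `dice_coefficient()` is the standard overlap
  $2|A \cap B| / (|A| + |B|)$ (soft version with sums of products;
  1 when both masks are empty).
* `topk_bce()` averages the per-pixel binary cross-entropy over the K
  pixels with the largest loss (hard-pixel mining). K is a user
  parameter (default 10% of pixels). The sum is normalized by the total
  pixel count N by default, with a `norm = "k"` switch for the
  K-normalized variant.

Both weights of the compound loss are configurable. For the desk-scale
droplet experiment in the test suite (below) the TopK term's weight is
set to 0: at that scale the droplet class is roughly 0.3% of pixels and
the N-normalized TopK term, which mostly pushes the dominant background
class, measurably stalls convergence, while the Dice term alone reaches
a held-out Dice above 0.9 within 150 updates.

## Training loop

Training pairs are grouped by source tomogram; each "epoch" draws
exactly one (slab, label) pair per tomogram and performs one Adam
update, so heavily annotated tomograms do not dominate. Augmentation
applies one random rotation from {0, 90, 180, 270} degrees and, with
probability 1/2, one elastic deformation (alpha = 430, sigma = 20 at the
512-pixel scale) — the field is generated from a single seed so all
five slices and the label receive the same distortion, and labels are
resampled nearest-neighbour so they stay binary.

# Instance post-processing

`postprocess_channels()` applies a fixed, logged order: outlier removal
(cell channel) -> masking (other channels) -> Gaussian averaging ->
threshold -> watershed -> hole filling -> convex constraint (optional)
-> minimum-volume filter.

* *Outlier removal* thresholds the mean z-projection of the cell
  prediction (default threshold 0.1 — the projection dilutes per-slice
  probabilities), dilates it (default radius 10 voxels) and applies the
  resulting z-invariant mask to all slices.
* *Masking* zeroes other channels outside the post-processed cell
  segmentation, suppressing droplet-like fiducial gold beads.
* *Averaging* is a 3D Gaussian (default sigma 1 voxel) on probabilities.
* `watershed_instances()` computes the exact Euclidean distance
  transform of the thresholded mask (separable lower-envelope method),
  suppresses shallow maxima with an h-maxima transform (default h = 2
  distance units; prevents over-segmentation of noisy spheres), labels
  the regional maxima as seeds (26-connectivity) and priority-floods the
  inverted distance map within the mask (Meyer's algorithm, FIFO
  tie-break for determinism). Components too shallow to retain a seed
  become their own instances, so the labels always partition the mask.
  The seeding details are design choices, not constraints inherited from
  the architecture.
* `fill_holes()` fills background regions not 6-connected to the volume
  border, after instance segmentation so inter-object gaps are not
  wrongly filled.
* `convexify()` replaces objects by their voxelized 3D convex hull
  (quickhull over the per-column voxel extremes); the output always
  contains the input.
* Default minimum volumes (droplet 50, vacuole/cell 1000 voxels) are
  package choices.

# Meshes and morphometry

`labels_to_meshes()` extracts one closed triangle surface per instance
at isolevel 0.5 of the label indicator. The isosurface is computed by
marching tetrahedra on the conforming 6-tetrahedron (Kuhn) cube
decomposition — the same isosurface family as classic marching cubes,
chosen because it is watertight by construction and free of the
ambiguous cube cases; triangle orientation is fixed outward
numerically. Optional Laplacian smoothing (default 10 iterations,
relaxation 0.5) changes sphere volumes by under 2% at the default
settings. Vertices are scaled to micrometres (voxel index times voxel
size; internal axis order (z, y, x), exports use (x, y, z)).

Per-droplet analytics (`analyze_droplets()`):

* *volume*: divergence-theorem volume of the closed mesh, in um^3;
* *nearest vacuole*: by center-of-mass distance (the metric is our
  choice; the assignment is recorded per row);
* *distance to the vacuolar membrane*: a ray is cast from the droplet's
  center of mass toward the vacuole's; the distance is the gap between
  the droplet-surface exit point and the vacuole-surface entry point
  along that ray (0 if inside or overlapping). Surface-to-surface along
  the ray — not center-to-center — because the quantity reported per
  droplet is the distance to the membrane. If the ray misses the
  vacuole (pathological concavity), the nearest-vertex distance is used
  and flagged;
* *consumed*: the droplet's center of mass lies inside the nearest
  vacuole's closed surface (parity ray test) — the operational
  definition of a lipophagy event;
* *contact percent*: 100 for consumed droplets by definition; otherwise
  the area-weighted fraction of droplet faces whose centroid lies inside
  the vacuole or within epsilon of its surface. Epsilon defaults to two
  voxel lengths — "in contact" has no canonical geometric definition at
  finite resolution, and two voxels is the scale of the membrane shell.

`compare_droplet_volumes()` compares volume distributions between
conditions with the Mann-Whitney U and Kolmogorov-Smirnov tests.

# Synthetic data

`make_fluor_field()` renders stationary-phase-like cells: a faint
membrane ring at the cell radius, one bright vacuole ring (fully fused)
or 2-4 tangent smaller rings (partially fused) in the red channel, and
droplet puncta in the green channel, plus Poisson shot noise and
Gaussian read noise, clipped at the camera saturation. Defaults (512 x
512 fields, cell radii 18-26 px, saturation 2047, background 80,
read noise 15 counts) emulate an automated 100x wide-field acquisition
with a 12-bit camera. What it does *not* emulate: defocus, uneven
illumination, touching cells, intravacuolar FM 4-64 staining and debris
— so a high synthetic cross-validation accuracy shows the pipeline
recovers a recoverable signal, not that real-data accuracy would be
comparable.

`make_tomo_phantom()` renders ellipsoidal cells with 2-voxel membrane
shells, an interior vacuole (with its own shell), and spherical
droplets inside (center strictly inside the vacuole) or outside it, on
a gray scale ordered droplet > membrane > cytosol > lumen > background
("higher = more absorbing"; an `invert` flag in `read_stack()` adapts
real data recorded the other way). Additive Gaussian noise is applied
after level assignment; droplets are placed with a 2-voxel clearance so
generated instances are individually countable. Default voxel size is
19.6 nm (a twice-binned 9.8 nm acquisition pixel).

`simulate_missing_wedge()` degrades a phantom slice-by-slice through a
parallel-beam Radon transform and ramp-filtered back projection with
linear interpolation (single-tilt geometry, rotation axis along image
rows). A full angular range reconstructs a disk phantom with
correlation above 0.99; restricting to the typical cryo-holder range of
-65 to +65 degrees lowers the correlation and produces the directional
edge artifacts characteristic of the missing wedge (horizontal edges
degrade harder than vertical ones under this geometry).

# Numerical choices and degenerate inputs

* Probabilities are clipped at 1e-7 inside all cross-entropy terms.
* `complete_metrics()` refuses sensitivity = specificity (prevalence
  indeterminate) and accuracies outside the [sens, spec] interval.
* `correct_fractions()` refuses sensitivity + specificity <= 1
  (uninformative classifier); corrected fractions are clipped to [0, 1].
* Hough peak ties break in row-major order; a constant field yields no
  detections; border crops are median-padded.
* `dice_coefficient()` returns 1 when both masks are empty; an empty
  mask yields an empty instance labeling, not an error.
* Degenerate (flat) point clouds are returned unchanged by the convex
  constraint.
* Batch-norm inference uses running statistics (momentum 0.9), so
  repeated predictions are deterministic.

# Desk-scale validation experiments

The test suite validates the learning components on generated data at
sizes chosen to make the full suite fast enough for routine use:

* *Classifier*: 2,000 two-channel ROIs (from ~125 generated fields of
  16 cells, phenotype mix 0.5), stratified 8-fold cross-validation, one
  training epoch per fold, batch 64, no augmentation. The synthetic
  phenotypes are nearly linearly separable (single large ring vs several
  small rings), and a single epoch reaches a held-out accuracy of 1.0
  in development runs; the suite requires pooled accuracy >= 0.90.
* *Segmenter*: 50 slabs of 128 x 128 x 5 from 10 phantom tomograms
  (training slices chosen where the droplet annotation is most visible,
  as hand annotation would), a base-8, depth-5 network, 200 epochs (the
  default training length, one pair per tomogram per epoch) at learning
  rate 1e-2, Dice-term-only loss weights and a head bias of -2 (both
  motivated above); held-out Dice >= 0.8 is required, with ~0.95
  typical.
* *Correction recovery*: simulated classifications at sensitivity
  0.7124 / specificity 0.9208 on a true prevalence of 0.30 with
  n = 10,000; the corrected estimate must land within 2 percentage
  points of the truth in at least 95 of 100 seeds.

# Known limitations

* The networks run on CPU with double precision; they are sized for
  method validation and small studies, not for training on hundreds of
  full-resolution tomograms.
* The FBP simulator is 2D slice-wise parallel-beam; it reproduces
  missing-wedge artifacts but not zone-plate optics, photon statistics
  or alignment errors.
* The contact-percent epsilon and the nearest-vacuole metric are
  geometric conventions; absolute contact values depend on them, while
  comparisons across conditions analyzed with the same settings do not.
* The prevalence correction assumes error rates constant across
  conditions — the same assumption under which the corrected group
  differences are tested.
* Intravacuolar vesicles/tubules and extracellular vesicles are not
  segmented; their heterogeneous shape and weak contrast make automated
  identification unreliable.
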