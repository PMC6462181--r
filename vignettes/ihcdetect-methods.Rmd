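---
title: "Detecting and counting stained immune cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and counting stained immune cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Immunohistochemistry (IHC) marks cells expressing a target protein — CD3
for T-cells, CD8 for cytotoxic T-cells, CD20 for B-cells — with a brown
DAB chromogen over a blue-purple hematoxylin counterstain. Quantifying
the density of these positively stained immune cells in tumour tissue is
a building block for immuno-oncology biomarkers, but manual counting is
slow and subjective, and classical image-analysis pipelines struggle
with staining variability and with confounders such as anthracotic
pigment (inhaled carbon deposits, common in lung tissue), erythrocytes
and diffuse stain traces.

`ihcdetect` implements a detection-by-classification pipeline:

1. a small convolutional network classifies 46×46 px RGB patches
   (0.228 µm/px, i.e. roughly a 10 µm field around a nucleus) as
   *positive* (stained immune cell at the centre) or *negative*
   (anything else);
2. the trained network is applied densely, giving a per-pixel posterior
   **likelihood map** of "positive cell here";
3. a **fast radial symmetry transform** (FRST) converts the bright,
   roughly circular likelihood blobs into individual cell-centre
   detections;
4. evaluation operations score detections against point ground truth and
   compare cell counts across raters.

Because the original slide material is not publicly available, the
package ships a synthetic-image generator with known ground truth; all
quantitative claims made by the test suite are claims about this
synthetic world (see *What the synthetic world does and does not show*).

# The patch classifier

## Architecture

The network has six valid (unpadded) convolutional layers, two 2×2
max-pooling layers and two fully connected layers ending in a softmax
over the two classes. Defaults: 3×3 kernels, filter counts
16-16-32-32-64-64, pools after conv 2 and conv 4, a 128-unit hidden
layer — about 152k parameters. The spatial trace on a 46-px input is
46 → 44 → 42 → 21 → 19 → 17 → 8 → 6 → 4 → 1, so the receptive field fits
the patch exactly and the whole stack reduces a patch to a single
2-vector. `cnn_config()` validates any alternative choice against this
constraint. The filter counts were chosen so that training and dense
whole-image inference run comfortably on a single CPU core; doubling all
widths roughly quadruples the cost without changing any qualitative
behaviour on the synthetic classes.

Pixel intensities are divided by 255 before entering the network; no
other normalisation is applied (the approach deliberately avoids
stain-specific preprocessing).

## Training

Minibatch SGD on the softmax cross-entropy with learning rate 0.01 and
Nesterov momentum 0.9, in the update form

    v ← µ·v − η·∇L        θ ← θ + µ·v − η·∇L

with one pass over the training patches by default — on both the real
problem this recipe comes from and the synthetic classes here, further
passes do not improve validation accuracy. The default minibatch is 32
patches: with a 20,000-patch corpus and one epoch this yields ~625
gradient steps, enough for the optimiser to converge; large minibatches
(256) leave too few steps per epoch at this corpus size.

Weights are initialised Glorot-normal (variance `2/(fan_in + fan_out)`),
deterministically per seed. This is a numerical-stability choice: with
He initialisation the lr 0.01 + momentum 0.9 combination (effective step
size ≈ 0.1) reliably drives the ReLU stack into a dead, constant-output
state, while Glorot keeps it stable.

A second stability safeguard is per-batch global gradient-norm clipping
(default `clip_norm = 2`, `NA` to disable). With momentum 0.9 and only
one pass over the data there is no second epoch to recover in: a single
outlier batch late in training can otherwise throw the already-converged
parameters into a dead-ReLU state (observed as loss 0.001 → stuck at
ln 2 for particular initialisation seeds). Clipping rescales the whole
gradient, so the update direction and the published learning-rate and
momentum values are unchanged. Training is reproducible per
(platform, seed); bit-identical results across platforms are *not*
promised (floating-point summation order may differ across BLAS builds).

## Dense inference

`predict_likelihood_map()` assigns to pixel `(y, x)` the positive-class
probability of the 46×46 window centred there (window rows
`y−23 … y+22`; the 23-px border band where no full window fits is 0).
Rather than classifying every window separately, the network is run
fully convolutionally: with valid convolutions and stride-2 pools, one
pass over the whole image computes every window whose top-left corner is
a multiple of 4 (the cumulative pooling stride), and the 16 shifted
copies of the image fill in the remaining offsets ("shift and stitch").
This is *arithmetically identical* to per-window classification — the
test suite asserts equality against a literal sliding-window oracle to
1e-4 (observed agreement is at machine precision) — at a small fraction
of the cost.

Large images can be processed tile-wise (`tile_image()` /
`stitch_tiles()`): with a halo of at least 23 px every owned pixel sees
its full window inside its tile, so tiling changes no value. A fast mode
(`stride = 4`) computes only the unshifted coarse grid and bilinearly
upsamples; it is excluded from the exactness guarantees and off by
default.

# Cell-centre detection

The likelihood map is first thresholded at 0.3 (values below are set to
0), then transformed with FRST over every integer pixel radius from 1 px
to `ceiling(4 µm / pixel size)` — 1…18 px at 0.228 µm/px. A 0 µm minimum
radius maps to 1 px, since a 0-px radius would vote on the voting pixel
itself. For each radius *n*:

* the map gradient is taken with central differences (zero at borders);
* every pixel whose gradient magnitude exceeds β times the map's maximum
  gradient magnitude casts one vote at `p + round(n·ĝ)` — *bright*
  symmetry only, because cells are bright peaks on a likelihood map —
  incrementing an orientation image `O` and adding `|g|` to a magnitude
  image `M`;
* the radial response `F_n = (min(O, κ_n)/κ_n)^α · (M/κ_n)` is smoothed
  with an isotropic Gaussian of σ = n/4; the final response is the mean
  of `F_n` over radii.

Defaults: α (radial strictness) 0.5, β 0.25, κ = 8 for radius 1 px and
9.9 otherwise — the transform's published constants. β is interpreted as
a *fraction* of the maximum gradient magnitude: likelihood-map gradients
are far below 1, so an absolute threshold of 0.25 would discard
everything (an absolute mode exists behind `beta_absolute`). Rounding of
vote offsets is half-up (`floor(x + 0.5)`) in both the fast
implementation and the test oracle; Gaussian smoothing uses zero padding
at the borders, which only attenuates responses in the border band where
no detections live anyway.

The response is thresholded at a fraction (default 0.1) of its maximum —
the operating point fixes only the likelihood threshold, not a numeric
response threshold, so a scale-free relative cut is used and exposed as
a parameter. 8-connected components of the thresholded response become
detections: one per component at its response-weighted centroid
(sub-pixel stable on asymmetric components), scored by the component's
maximum response; components below 2 px are noise and dropped. Ordering
is by (y, x), so detection CSVs are reproducible.

Densely clustered cells merge into single likelihood blobs and are
counted as one — a known limitation of this detector family; no
declumping (watershed etc.) is attempted.

# Evaluation

`confusion_stats()` normalises per *actual* class: FNR = 100·fn/(tp+fn),
FPR = 100·fp/(fp+tn), so sensitivity = 100 − FNR and specificity =
100 − FPR by construction; rates for an absent class are `NA`, never 0.
Percentages are carried at full precision and rounded only for display.

`match_detections()` pairs detections with ground-truth centres
greedily, nearest first, one-to-one, within a tolerance of 4 µm (the
maximum nucleus radius), with deterministic tie-breaking by
(distance, y, x). Greedy rather than optimal assignment: at the cell
densities involved the two differ negligibly, and greedy is simple and
deterministic.

`relative_differences()` computes, per image and rater,
`(mean − count)/mean`, where the mean is taken over all observers *and*
the model; with that convention the per-image differences sum to zero
exactly, which the test suite verifies on 1,000 random count tables.
Over-counting raters get negative differences; a `flip_sign` flag and an
observers-only normalising mode cover the alternative conventions, since
published descriptions of this statistic differ between the defining
sentence and figure captions. Summaries report the mean, mean absolute
value, median and type-7 (linear interpolation) quartiles; the mean
absolute relative difference of the model column is the headline
agreement number. Both signed and absolute means are reported because
the two are easily conflated. Images with a zero mean count are excluded
with a warning rather than dividing by zero.

# The synthetic world

`generate_tissue_image()` renders, on a pale lavender
(hematoxylin-tinted) background with a slow sinusoidal tint: positively
stained cells as brown ellipses (per-cell darkness uniform in
[0.35, 0.9] between a light and a dark DAB reference colour, radius
uniform in [1.5, 3.5] µm, aspect ratio in [1, 1.6], random orientation);
negative nuclei as blue-purple ellipses; anthracotic pigment as
near-black irregular multi-lobed blobs whose colour satisfies R ≤ B, so
brown chroma (R−B > 0) never occurs inside pigment and the classes are
separable in principle; erythrocytes as red-orange disks with G < B
(red, not brown); and diffuse stain traces as faint elongated low-chroma
smears below the positive staining range. Objects get a soft ~1 px edge
(flat shading otherwise — no optical-density simulation), i.i.d.
Gaussian noise (σ = 4 grey levels) is added last, and everything is
deterministic given the seed.

Placement is rejection sampling with a 10,000-attempt budget per object
and a loud failure when infeasible — ground truth therefore always
matches the requested counts exactly. Positive cells keep a pairwise
minimum separation of 8 µm so that single-cell detection is well-posed;
confounders keep that clearance *to positive cells* but only ~0.7 cell
diameters among themselves (pigment and erythrocytes crowd freely in
real tissue, and full mutual separation would exceed the packing limit
of a 500×500 px tile). All object centres stay 30 px clear of the image
border so every cell has a full patch context; the dense-inference
border band is zero there by design.

Default object counts per 500×500 px tile (0.2 of the side length of a
standard 2,000×2,000 px validation image): 50 positive cells, 10 pigment
clumps, 10 erythrocytes, 30 negative nuclei, 4 smears.

`generate_patch_set()` extracts positive patches centred on rendered
cells and negative patches from images generated *without* positive
cells. Half of the negatives are centred on rendered confounders and
half drawn uniformly: the negative class of the original training corpus
was likewise deliberately curated to contain pigment, unspecific
staining and artifacts. This matters: with purely uniform negatives,
confounders are so rare at patch centres that the classifier generalises
"dark/red object = cell" and fires on erythrocytes and pigment.

**What passing tests do and do not show.** The synthetic classes are
colour-separable by construction and carry no intra-class texture,
focus, or staining-protocol variability; accuracy and F1 achieved here
are upper bounds of a sort — they validate the *machinery* (corpus
construction, optimisation, exact dense inference, FRST geometry,
statistics), not clinical performance. Claims that do transfer:
exactness of dense inference and tiling, FRST-oracle equivalence,
determinism per seed, the counting statistics' algebraic identities, and
the qualitative behaviour of hard-negative mining. Claims that do not:
absolute accuracy/sensitivity/specificity levels on real tissue.

# Hard-negative mining

`mine_hard_negatives()` runs likelihood inference on images known to be
free of positive cells, finds the peak of every 8-connected likelihood
component above 0.3, drops peaks within 4 µm of any supplied true
centre, and cuts negative patches (origin `mined_hard_negative`) at the
rest. The pipeline's default two-round schedule retrains from scratch on
the base corpus plus mined negatives. The test suite exercises the loop
with a deliberately colour-blind darkness-ramp model (`darkness_model()`)
that fires on everything dark: mining recovers the planted pigment
clumps, and a classifier retrained on a deliberately impoverished corpus
(uniform negatives only) plus the mined patches stops detecting pigment.

# Problem sizes and numerical choices

The acceptance-level experiments use: a 20,000-patch training corpus
(380 manually-extracted patches per class, 27-fold augmented, subsampled
to 10,000 per class), one epoch, and 500×500 px validation images with
40–60 planted cells each — 20 images in the test suite, 8 in the
acceptance script. These sizes were chosen so the full study runs in
minutes on one CPU core while keeping ≥ 900 planted cells behind the
detection statistics.

Other numerical choices collected in one place: patch-centre convention
for even windows puts the centre pixel at offset 23 (window
`c−23 … c+22`); fractional annotation coordinates round half-up to the
pixel grid; border-adjacent annotation centres are skipped with a
warning, never padded (padding would fabricate tissue); rotation
augmentation uses bilinear interpolation over a reflect-padded patch and
centre-crops back (no black corners that could leak label information),
while 0°/90° multiples and mirrors are exact permutations; "rotating by
40 degrees" is read as 40° *steps* over the full circle (9 angles × 3
mirrors = 27 transforms) — composed with mirrors, originals kept; the
augmentation multiplier is identical for both classes, so class balance
is exactly preserved.

# Known limitations

* Clustered cells are merged by design (single-blob, single-detection).
* The generator models neither tissue architecture nor scanner
  artifacts beyond additive noise; stain colocalisation, focus blur and
  compression artifacts are out of scope.
* Proprietary whole-slide formats are not read; images enter as
  PNG/TIFF tiles with a YAML metadata sidecar.
* Training reproducibility is per platform, not bit-portable.
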