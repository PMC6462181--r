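# ihcdetect

Detection and quantification of immunohistochemically stained immune
cells (CD3/CD8/CD20-positive lymphocytes and similar markers) in
digitised tissue images, for researchers quantifying the tumour immune
micro-environment.

The method is detection-by-classification:

1. **Patch classifier.** A convolutional network — six valid 3×3
   convolutions, two 2×2 max pools, two fully connected layers, softmax
   over {negative, positive} — classifies 46×46 px RGB patches
   (0.228 µm/px) as *stained immune cell at the centre* vs *anything
   else*. Training is one pass of minibatch SGD with learning rate
   η = 0.01 and Nesterov momentum µ = 0.9
   (`v ← µv − η∇L`, `θ ← θ + µv − η∇L`), with gradient-norm clipping as
   a stability safeguard.
2. **Likelihood map.** The trained network is applied at every pixel
   (fully convolutional shift-and-stitch inference, arithmetically
   identical to classifying every window), giving a per-pixel posterior
   `P(positive cell centred here)`.
3. **Fast radial symmetry transform (FRST).** After thresholding the
   map at 0.3, gradient voting over radii 0–4 µm (α = 0.5 radial
   strictness, β = 0.25 gradient threshold,
   `F_n = (min(O_n, κ)/κ)^α · M_n/κ` smoothed with σ = n/4, averaged
   over radii) turns likelihood blobs into a symmetry response;
   thresholded 8-connected components yield one detection per cell at
   the response-weighted centroid.
4. **Evaluation.** Per-class normalised confusion statistics
   (sensitivity = 100 − FNR, specificity = 100 − FPR), greedy one-to-one
   detection/truth matching within 4 µm, and per-image relative count
   differences `(mean − count)/mean` across raters with median/IQR
   summaries.

Because the original slide material is proprietary, the package includes
a synthetic IHC image generator with exact ground truth — DAB-brown
cells of varying intensity and shape on a hematoxylin-tinted background,
with anthracotic-pigment clumps, erythrocytes, negative nuclei and
diffuse stain smears as confounders — plus patch extraction with 27-fold
mirror/rotation augmentation and a hard-negative mining loop.

## Worked example

```r
library(ihcdetect)

## a synthetic 500x500 px tile (0.228 um/px) with 50 stained cells,
## pigment clumps, erythrocytes, nuclei and stain smears
cfg <- synth_config(seed = 42)
val <- generate_tissue_image(cfg, image_id = "demo")
val$image
#> <rgb_image> 500 x 500 px, id='demo', 0.228 um/px

## train the classifier on an augmented balanced patch corpus
base   <- generate_patch_set(cfg, n_per_class = 100)
corpus <- augment_patches(base)          # 100/class -> 2700/class
model  <- build_cnn(cnn_config(), seed = 7)
model  <- train_cnn(model, corpus, training_config(seed = 3))
model
#> <ihc_cnn> 46-px patches, trained, 203,538 parameters

## dense likelihood map and radial-symmetry detection
lmap <- predict_likelihood_map(model, val$image)
dets <- detect_cells(lmap, frst_params())
nrow(dets)
#> [1] 50

## score against the planted ground truth (4 um tolerance)
match_detections(dets, val$truth$positive_centers, val$image$metadata)
#> <match_result> matched=50, false positives=0, missed=0
```

All 50 planted cells are recovered with no false positive; in
particular, no detection lands on a pigment clump — the colour-aware
classifier separates near-black carbon deposits from brown DAB staining.

A runnable command-line front end with `synth`, `build-dataset`,
`train`, `predict`, `detect`, `evaluate` and `run-all` subcommands is
installed at `inst/cli/ihcdetect.R`; `run_pipeline(pipeline_config())`
is the equivalent in-R entry point.

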