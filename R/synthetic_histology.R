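## Synthetic IHC image generator: DAB-brown stained cells on a
## hematoxylin-tinted background, plus the confounders that make real
## stained lung tissue hard -- near-black anthracotic pigment clumps,
## red-orange erythrocytes, blue-purple negative nuclei and faint diffuse
## stain smears. Ground-truth cell centres are known by construction.

#' Configuration for the synthetic tissue image generator
#'
#' Defaults emulate a 500 x 500 px tile scanned at 0.228 um/px with about
#' fifty positively stained immune cells (nucleus radii 1.5--3.5 um,
#' staining intensity from light to dark brown) among pigment clumps,
#' erythrocytes and counterstained negative nuclei.
#'
#' @param image_size_px `(H, W)` in pixels.
#' @param pixel_size_um Physical pixel size (um/px).
#' @param n_positive_cells,n_pigment_clumps,n_negative_nuclei,n_erythrocytes
#'   Object counts (>= 0 each).
#' @param n_stain_smears Number of faint diffuse-stain smears (low-chroma
#'   brown, below the positive staining intensity range).
#' @param cell_radius_um_range `(lo, hi)` nucleus radius range in um,
#'   within `(0, 4]`.
#' @param dab_intensity_range `(lo, hi)` brown staining darkness in
#'   `[0, 1]` (0 = barely stained, 1 = saturated dark brown).
#' @param min_separation_um Minimum centre-to-centre distance between
#'   placed objects (um).
#' @param margin_px Placement margin: no object centre closer than this to
#'   any image border, so every cell has a full 46-px patch context.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise
#'   on the 8-bit scale.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_size_px = c(500L, 500L),
                         pixel_size_um = 0.228,
                         n_positive_cells = 50L,
                         n_pigment_clumps = 10L,
                         n_negative_nuclei = 30L,
                         n_erythrocytes = 10L,
                         n_stain_smears = 4L,
                         cell_radius_um_range = c(1.5, 3.5),
                         dab_intensity_range = c(0.35, 0.9),
                         min_separation_um = 8,
                         margin_px = 30L,
                         noise_sd = 4,
                         seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(rep(image_size_px, length.out = 2L)),
    pixel_size_um = pixel_size_um,
    n_positive_cells = as.integer(n_positive_cells),
    n_pigment_clumps = as.integer(n_pigment_clumps),
    n_negative_nuclei = as.integer(n_negative_nuclei),
    n_erythrocytes = as.integer(n_erythrocytes),
    n_stain_smears = as.integer(n_stain_smears),
    cell_radius_um_range = as.numeric(cell_radius_um_range),
    dab_intensity_range = as.numeric(dab_intensity_range),
    min_separation_um = as.numeric(min_separation_um),
    margin_px = as.integer(margin_px),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(pixel_size_um > 0, all(image_size_px >= 1L),
              n_positive_cells >= 0L, n_pigment_clumps >= 0L,
              n_negative_nuclei >= 0L, n_erythrocytes >= 0L,
              n_stain_smears >= 0L, min_separation_um >= 0, noise_sd >= 0)
    if (cell_radius_um_range[1] > cell_radius_um_range[2] ||
        cell_radius_um_range[1] <= 0 || cell_radius_um_range[2] > 4) {
      stop("cell_radius_um_range must satisfy 0 < lo <= hi <= 4", call. = FALSE)
    }
    if (dab_intensity_range[1] > dab_intensity_range[2]) {
      stop("dab_intensity_range must satisfy lo <= hi", call. = FALSE)
    }
  })
  structure(cfg, class = "synth_config")
}

## Reference colours (R, G, B on the 8-bit scale). Pigment is constructed
## with R - B < 0 so that brown chroma (R - B > 0) never appears inside a
## pigment clump: a colour-aware classifier can always separate the classes.
.synth_colors <- list(
  background   = c(232, 226, 238),   # pale lavender (hematoxylin-tinted)
  dab_dark     = c(96, 56, 18),      # saturated DAB brown
  dab_light    = c(205, 172, 132),   # barely stained brown
  nucleus      = c(108, 96, 168),    # blue-purple counterstained nucleus
  pigment      = c(18, 18, 26),      # anthracotic pigment, near black, R < B
  erythrocyte  = c(214, 62, 72),     # red-orange, G below B (not brown)
  smear        = c(222, 204, 182)    # faint diffuse stain trace
)

## Rejection-sample n centres within [margin, size - margin - 1]:
## pairwise separation >= sep_self among the sampled points, and
## >= sep_existing against previously accepted points.
.place_centers <- function(n, H, W, margin, sep_self, existing = NULL,
                           sep_existing = sep_self, attempts = 10000L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x", "y")))
  placed_n <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(attempts)) {
      x <- stats::runif(1, margin, W - 1 - margin)
      y <- stats::runif(1, margin, H - 1 - margin)
      ok_existing <- is.null(existing) || nrow(existing) == 0L ||
        all((existing[, 1] - x)^2 + (existing[, 2] - y)^2 >= sep_existing^2)
      ok_self <- placed_n == 0L ||
        all((out[seq_len(placed_n), 1] - x)^2 +
              (out[seq_len(placed_n), 2] - y)^2 >= sep_self^2)
      if (ok_existing && ok_self) {
        placed_n <- placed_n + 1L
        out[placed_n, ] <- c(x, y)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("object placement infeasible: could not place object ",
                          "%d of %d with min separation %.1f px within %d attempts"),
                   i, n, sep_self, attempts), call. = FALSE)
    }
  }
  out
}

## Paint a filled rotated ellipse onto the H x W x 3 canvas (in place value
## semantics: returns the modified canvas). Coordinates 0-based.
.paint_ellipse <- function(canvas, cx, cy, a, b, theta, color, feather = 0.8) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  r <- ceiling(max(a, b)) + 2L
  xs <- max(0L, floor(cx - r)):min(W - 1L, ceiling(cx + r))
  ys <- max(0L, floor(cy - r)):min(H - 1L, ceiling(cy + r))
  if (length(xs) == 0L || length(ys) == 0L) return(canvas)
  gx <- outer(rep(1, length(ys)), xs) - cx
  gy <- outer(ys, rep(1, length(xs))) - cy
  u <- (gx * cos(theta) + gy * sin(theta)) / a
  v <- (-gx * sin(theta) + gy * cos(theta)) / b
  d <- sqrt(u^2 + v^2)
  ## soft edge over ~feather px keeps gradients finite but stays "flat shading"
  w <- pmin(1, pmax(0, (1 - d) * max(a, b) / feather + 0))
  if (all(w == 0)) return(canvas)
  ridx <- ys + 1L; cidx <- xs + 1L
  for (ch in 1:3) {
    block <- canvas[ridx, cidx, ch]
    canvas[ridx, cidx, ch] <- block * (1 - w) + color[ch] * w
  }
  canvas
}

## Irregular blob: union of a few jittered ellipses around the centre.
.paint_blob <- function(canvas, cx, cy, r, color, n_lobes = 4L) {
  for (k in seq_len(n_lobes)) {
    dx <- stats::runif(1, -r / 2, r / 2); dy <- stats::runif(1, -r / 2, r / 2)
    a <- stats::runif(1, 0.5 * r, r); b <- stats::runif(1, 0.5 * r, r)
    canvas <- .paint_ellipse(canvas, cx + dx, cy + dy, a, b,
                             stats::runif(1, 0, pi), color, feather = 0.6)
  }
  canvas
}

#' Generate a synthetic stained-tissue image with known ground truth
#'
#' Renders positively stained cells as brown ellipses (per-cell staining
#' intensity drawn from `dab_intensity_range`, aspect ratio 1--1.6),
#' negative nuclei as blue-purple ellipses, anthracotic pigment as
#' near-black irregular blobs, erythrocytes as red-orange disks and
#' diffuse stain traces as faint low-chroma smears, over a pale lavender
#' background; i.i.d. Gaussian noise is added last. All object centres are
#' placed by rejection sampling with a minimum separation; if placement is
#' infeasible the generator fails loudly rather than silently dropping
#' objects.
#'
#' @param config A [synth_config()].
#' @param image_id Identifier stored in the image metadata.
#' @return A list with elements `image` (an [rgb_image()]) and `truth`
#'   (class `ground_truth`: data.frame `positive_centers` with columns
#'   `x`, `y`; data.frame `confounder_centers` with columns `x`, `y`,
#'   `kind`).
#' @examples
#' out <- generate_tissue_image(synth_config(image_size_px = c(120, 120),
#'   n_positive_cells = 3, n_pigment_clumps = 1, n_negative_nuclei = 2,
#'   n_erythrocytes = 1, seed = 7))
#' nrow(out$truth$positive_centers)
#' @export
generate_tissue_image <- function(config, image_id = "synth") {
  stopifnot(inherits(config, "synth_config"))
  H <- config$image_size_px[1]; W <- config$image_size_px[2]
  ps <- config$pixel_size_um
  min_sep_px <- config$min_separation_um / ps
  margin <- config$margin_px
  if (2 * margin >= min(H, W)) {
    stop("image too small for the placement margin", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  canvas <- array(0, c(H, W, 3))
  for (ch in 1:3) canvas[, , ch] <- .synth_colors$background[ch]

  ## background mottling: a large-scale tint so the background is not flat
  fx <- stats::runif(1, 1, 3); fy <- stats::runif(1, 1, 3)
  tint <- 6 * outer(sin(seq(0, fy * pi, length.out = H)),
                    cos(seq(0, fx * pi, length.out = W)))
  for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] + tint

  ## place everything with mutual separation, positives first
  n_conf <- config$n_pigment_clumps + config$n_erythrocytes +
    config$n_negative_nuclei + config$n_stain_smears
  ## positives keep the full pairwise separation (so single-cell detection
  ## is well-posed); confounders keep that clearance to positives but only
  ## a small clearance among themselves (real pigment and erythrocytes
  ## crowd freely)
  conf_sep <- min(min_sep_px, 2 * config$cell_radius_um_range[2] / ps * 0.7)
  pos <- .place_centers(config$n_positive_cells, H, W, margin, min_sep_px)
  conf <- .place_centers(n_conf, H, W, margin, conf_sep, existing = pos,
                         sep_existing = min_sep_px)
  kind <- rep(c("pigment", "erythrocyte", "nucleus", "smear"),
              times = c(config$n_pigment_clumps, config$n_erythrocytes,
                        config$n_negative_nuclei, config$n_stain_smears))

  r_lo <- config$cell_radius_um_range[1] / ps
  r_hi <- config$cell_radius_um_range[2] / ps

  ## confounders underneath, positives on top
  for (i in seq_len(nrow(conf))) {
    cx <- conf[i, "x"]; cy <- conf[i, "y"]
    canvas <- switch(kind[i],
      pigment = .paint_blob(canvas, cx, cy, stats::runif(1, r_lo, r_hi),
                            .synth_colors$pigment),
      erythrocyte = .paint_ellipse(canvas, cx, cy,
                                   a = stats::runif(1, r_lo, r_hi),
                                   b = stats::runif(1, r_lo, r_hi),
                                   theta = 0, color = .synth_colors$erythrocyte),
      nucleus = {
        a <- stats::runif(1, r_lo, r_hi); asp <- stats::runif(1, 1, 1.6)
        .paint_ellipse(canvas, cx, cy, a, a / asp, stats::runif(1, 0, pi),
                       .synth_colors$nucleus)
      },
      smear = {
        a <- stats::runif(1, 2 * r_hi, 4 * r_hi)
        .paint_ellipse(canvas, cx, cy, a, a / stats::runif(1, 2, 4),
                       stats::runif(1, 0, pi), .synth_colors$smear,
                       feather = 3)
      })
  }
  for (i in seq_len(nrow(pos))) {
    darkness <- stats::runif(1, config$dab_intensity_range[1],
                             config$dab_intensity_range[2])
    color <- .synth_colors$dab_light +
      darkness * (.synth_colors$dab_dark - .synth_colors$dab_light)
    a <- stats::runif(1, r_lo, r_hi)
    asp <- stats::runif(1, 1, 1.6)
    canvas <- .paint_ellipse(canvas, pos[i, "x"], pos[i, "y"],
                             a, a / asp, stats::runif(1, 0, pi), color)
  }

  if (config$noise_sd > 0) {
    canvas <- canvas + stats::rnorm(length(canvas), 0, config$noise_sd)
  }
  canvas <- round(pmin(pmax(canvas, 0), 255))

  meta <- image_metadata(ps, marker = "synthetic", image_id = image_id)
  truth <- structure(
    list(
      positive_centers = data.frame(x = pos[, "x"], y = pos[, "y"]),
      confounder_centers = data.frame(
        x = conf[, "x"], y = conf[, "y"],
        kind = if (nrow(conf)) kind else character(),
        stringsAsFactors = FALSE)
    ),
    class = "ground_truth"
  )
  list(image = rgb_image(canvas, meta), truth = truth)
}

#' Generate a balanced labelled patch set with known classes
#'
#' Positive 46 x 46 patches are extracted centred on rendered stained
#' cells. Negative patches come from images generated with zero positive
#' cells (so any confounder may appear in them, but never a stained
#' cell); a fraction `confounder_fraction` of them is centred on rendered
#' confounders (pigment clumps, erythrocytes, counterstained nuclei,
#' stain smears) -- the negative class is deliberately enriched with the
#' hard artifacts rather than sampled purely at random -- and the rest
#' are drawn uniformly. As many images as needed are generated, with
#' per-image seeds derived from `config$seed`.
#'
#' @param config A [synth_config()]; its `n_positive_cells` is used for the
#'   positive source images and set to zero for the negative ones.
#' @param n_per_class Number of patches per class (>= 1).
#' @param patch_px Patch edge length (default 46).
#' @param confounder_fraction Target fraction of negative patches centred
#'   on a confounder object (default 0.5).
#' @return A `patch_set` (see [patch_set()]) with `2 * n_per_class`
#'   patches, exactly balanced.
#' @export
generate_patch_set <- function(config, n_per_class, patch_px = 46L,
                               confounder_fraction = 0.5) {
  stopifnot(inherits(config, "synth_config"), n_per_class >= 1L)
  half <- patch_px %/% 2L
  pos_sets <- list(); n_pos <- 0L; img_idx <- 0L
  while (n_pos < n_per_class) {
    img_idx <- img_idx + 1L
    cfg_i <- config
    cfg_i$seed <- (config$seed * 1000L + img_idx) %% .Machine$integer.max
    out <- generate_tissue_image(cfg_i, image_id = sprintf("pos_%03d", img_idx))
    ann <- data.frame(image_id = out$image$metadata$image_id,
                      x = out$truth$positive_centers$x,
                      y = out$truth$positive_centers$y,
                      label = "positive")
    ps <- extract_positive_patches(out$image, ann, patch_px = patch_px)
    pos_sets[[img_idx]] <- ps
    n_pos <- n_pos + n_patches(ps)
    if (img_idx > 1000L) stop("could not collect enough positive patches", call. = FALSE)
  }
  pos <- do.call(combine_patches, pos_sets)
  pos <- subset_patches(pos, seq_len(n_per_class))

  neg_cfg <- config
  neg_cfg$n_positive_cells <- 0L
  neg_sets <- list(); n_neg <- 0L; img_idx <- 0L
  n_conf_target <- round(confounder_fraction * n_per_class)
  n_conf_got <- 0L
  per_img <- max(25L, ceiling(n_per_class / 4))
  while (n_neg < n_per_class) {
    img_idx <- img_idx + 1L
    cfg_i <- neg_cfg
    cfg_i$seed <- (config$seed * 1000L + 500L + img_idx) %% .Machine$integer.max
    out <- generate_tissue_image(cfg_i, image_id = sprintf("neg_%03d", img_idx))
    ## confounder-centred negatives first (suppress the border warning:
    ## placement margins already keep centres eligible)
    if (n_conf_got < n_conf_target) {
      cc <- out$truth$confounder_centers
      take_c <- min(nrow(cc), n_conf_target - n_conf_got,
                    n_per_class - n_neg)
      if (take_c > 0L) {
        ps_c <- suppressWarnings(
          extract_positive_patches(out$image, cc[seq_len(take_c), ],
                                   patch_px = patch_px))
        if (n_patches(ps_c) > 0L) {
          ps_c$label <- rep("negative", n_patches(ps_c))
          neg_sets[[length(neg_sets) + 1L]] <- ps_c
          n_neg <- n_neg + n_patches(ps_c)
          n_conf_got <- n_conf_got + n_patches(ps_c)
        }
      }
    }
    take <- min(per_img, n_per_class - n_neg)
    if (take > 0L) {
      ps <- sample_negative_patches(out$image, take,
                                    seed = cfg_i$seed + 1L, patch_px = patch_px)
      neg_sets[[length(neg_sets) + 1L]] <- ps
      n_neg <- n_neg + n_patches(ps)
    }
    if (img_idx > 1000L) stop("could not collect enough negative patches", call. = FALSE)
  }
  neg <- do.call(combine_patches, neg_sets)
  combine_patches(pos, neg)
}
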