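## Patch corpus construction: extraction of positive/negative 46x46
## patches, mirror/rotation augmentation, slide-level splits and the
## hard-negative mining loop.

#' Labelled patch sets
#'
#' A `patch_set` stores `N` square RGB patches in one `p x p x 3 x N`
#' numeric array (8-bit scale), with per-patch `label`
#' (`"positive"`/`"negative"`), `source_image_id` and `origin`
#' (`"manual"`, `"mined_hard_negative"` or `"augmented"`).
#'
#' @param pixels `p x p x 3 x N` numeric array in \[0, 255\].
#' @param label Character vector of length `N`.
#' @param source_image_id Character vector of length `N`.
#' @param origin Character vector of length `N`.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(pixels, label, source_image_id = rep("", n),
                      origin = rep("manual", n)) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4L, dim(pixels)[3] == 3L,
            dim(pixels)[1] == dim(pixels)[2])
  n <- dim(pixels)[4]
  stopifnot(length(label) == n)
  if (length(source_image_id) == 1L) source_image_id <- rep(source_image_id, n)
  if (length(origin) == 1L) origin <- rep(origin, n)
  stopifnot(length(source_image_id) == n, length(origin) == n,
            all(label %in% c("positive", "negative")),
            all(origin %in% c("manual", "mined_hard_negative", "augmented")))
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, label = as.character(label),
                 source_image_id = as.character(source_image_id),
                 origin = as.character(origin)),
            class = "patch_set")
}

#' @rdname patch_set
#' @param x A `patch_set`.
#' @export
n_patches <- function(x) {
  stopifnot(inherits(x, "patch_set"))
  dim(x$pixels)[4]
}

#' @export
print.patch_set <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<patch_set> %d patches (%d x %d px): %s\n",
              n_patches(x), dim(x$pixels)[1], dim(x$pixels)[2],
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @rdname patch_set
#' @param ... `patch_set` objects with equal patch sizes.
#' @export
combine_patches <- function(...) {
  sets <- list(...)
  sets <- Filter(function(s) n_patches(s) > 0L, sets)
  if (length(sets) == 0L) stop("nothing to combine", call. = FALSE)
  p <- dim(sets[[1]]$pixels)[1]
  stopifnot(all(vapply(sets, function(s) dim(s$pixels)[1] == p, logical(1))))
  n <- sum(vapply(sets, n_patches, integer(1)))
  px <- array(0, c(p, p, 3L, n))
  at <- 0L
  for (s in sets) {
    k <- n_patches(s)
    px[, , , at + seq_len(k)] <- s$pixels
    at <- at + k
  }
  patch_set(px,
            label = unlist(lapply(sets, `[[`, "label")),
            source_image_id = unlist(lapply(sets, `[[`, "source_image_id")),
            origin = unlist(lapply(sets, `[[`, "origin")))
}

#' @rdname patch_set
#' @param idx Integer indices of the patches to keep.
#' @export
subset_patches <- function(x, idx) {
  stopifnot(inherits(x, "patch_set"))
  patch_set(x$pixels[, , , idx, drop = FALSE], x$label[idx],
            x$source_image_id[idx], x$origin[idx])
}

#' Extract positive patches centred on annotated cell centres
#'
#' One `patch_px x patch_px` patch is cut out per centre; a centre whose
#' window would cross an image border (closer than `patch_px %/% 2` px to
#' any edge) is skipped with a warning rather than padded, since padding
#' would fabricate tissue.
#'
#' @param image An [rgb_image()].
#' @param centers Data.frame with 0-based columns `x`, `y` (fractional
#'   coordinates are rounded half-up to the nearest pixel).
#' @param patch_px Patch edge length (default 46).
#' @return A `patch_set` of positive patches with origin `"manual"`.
#' @export
extract_positive_patches <- function(image, centers, patch_px = 46L) {
  stopifnot(inherits(image, "rgb_image"))
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  half <- patch_px %/% 2L                      # 23 for 46-px patches
  cx <- floor(centers$x + 0.5); cy <- floor(centers$y + 0.5)
  ## window spans rows cy - half .. cy + patch_px - half - 1 (0-based)
  ok <- cy - half >= 0 & cy + (patch_px - half) - 1L <= H - 1L &
        cx - half >= 0 & cx + (patch_px - half) - 1L <= W - 1L
  if (any(!ok)) {
    warning(sprintf("skipped %d centre(s) closer than %d px to an image border",
                    sum(!ok), half), call. = FALSE)
  }
  cx <- cx[ok]; cy <- cy[ok]
  n <- length(cx)
  px <- array(0, c(patch_px, patch_px, 3L, n))
  for (i in seq_len(n)) {
    rows <- (cy[i] - half + 1L):(cy[i] + patch_px - half)  # 1-based
    cols <- (cx[i] - half + 1L):(cx[i] + patch_px - half)
    px[, , , i] <- image$pixels[rows, cols, ]
  }
  patch_set(px, label = rep("positive", n),
            source_image_id = rep(image$metadata$image_id, n),
            origin = rep("manual", n))
}

#' Randomly sample negative patches from a positive-free image
#'
#' Patch top-left corners are drawn uniformly so every window lies fully
#' inside the image; the draw is deterministic given `seed`. The image is
#' expected to contain no positively stained cells (negative regions are
#' taken from slides without positive staining), which the caller
#' guarantees.
#'
#' @param image An [rgb_image()] at least `patch_px` pixels in each
#'   dimension.
#' @param n Number of patches to sample (>= 0).
#' @param seed Integer seed for the sampling positions.
#' @param patch_px Patch edge length (default 46).
#' @return A `patch_set` of negative patches with origin `"manual"`.
#' @export
sample_negative_patches <- function(image, n, seed = 1L, patch_px = 46L) {
  stopifnot(inherits(image, "rgb_image"), n >= 0L)
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  if (H < patch_px || W < patch_px) {
    stop(sprintf("image (%d x %d) smaller than patch size %d", H, W, patch_px),
         call. = FALSE)
  }
  px <- array(0, c(patch_px, patch_px, 3L, n))
  if (n > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    y0 <- sample.int(H - patch_px + 1L, n, replace = TRUE)  # 1-based top-left
    x0 <- sample.int(W - patch_px + 1L, n, replace = TRUE)
    for (i in seq_len(n)) {
      px[, , , i] <- image$pixels[y0[i]:(y0[i] + patch_px - 1L),
                                  x0[i]:(x0[i] + patch_px - 1L), ]
    }
  }
  patch_set(px, label = rep("negative", n),
            source_image_id = rep(image$metadata$image_id, n),
            origin = rep("manual", n))
}

#' Augmentation configuration
#'
#' The default reproduces mirroring horizontally and vertically combined
#' with rotations in 40-degree steps over the full circle: 3 mirrors
#' (identity included) x 9 rotation angles = a 27-fold expansion.
#'
#' @param rotations_deg Set of rotation angles in degrees; must contain 0.
#' @param mirrors Subset of `c("identity", "horizontal", "vertical")`;
#'   must contain `"identity"`.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotations_deg = seq(0, 320, by = 40),
                                mirrors = c("identity", "horizontal", "vertical")) {
  rotations_deg <- as.numeric(rotations_deg)
  mirrors <- match.arg(mirrors, c("identity", "horizontal", "vertical"),
                       several.ok = TRUE)
  if (!0 %in% rotations_deg) stop("rotations_deg must contain 0", call. = FALSE)
  if (!"identity" %in% mirrors) stop("mirrors must contain 'identity'", call. = FALSE)
  structure(list(rotations_deg = rotations_deg, mirrors = mirrors),
            class = "augmentation_config")
}

## Bilinear sampling plan for one (mirror, angle) transform on a p x p
## patch: 4 source linear indices + weights per output pixel, with
## reflect padding resolved back into in-bounds indices. Angles that are
## multiples of 90 degrees reduce to exact permutations.
.transform_plan <- function(p, mirror, angle) {
  ## output pixel grid, 1-based
  g <- expand.grid(y = seq_len(p), x = seq_len(p))
  yy <- g$y; xx <- g$x
  ## apply the inverse mirror first (mirrors are involutions)
  if (mirror == "horizontal") xx <- p + 1L - xx
  if (mirror == "vertical") yy <- p + 1L - yy
  c0 <- (p + 1) / 2
  th <- angle * pi / 180
  ## inverse rotation of the output grid into source coordinates
  sy <- c0 + sin(-th) * (xx - c0) + cos(-th) * (yy - c0)
  sx <- c0 + cos(-th) * (xx - c0) - sin(-th) * (yy - c0)
  reflect <- function(i) {
    ## reflect (without edge repeat) into 1..p: pattern period 2(p-1)
    i <- (i - 1) %% (2 * (p - 1))
    ifelse(i >= p - 1, 2 * (p - 1) - i, i) + 1
  }
  if (isTRUE(all.equal(angle %% 90, 0)) || isTRUE(all.equal(angle %% 90, 90))) {
    iy <- reflect(round(sy)); ix <- reflect(round(sx))
    l1 <- (ix - 1L) * p + iy
    return(list(exact = TRUE, idx = as.integer(l1)))
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflect(y0); iy1 <- reflect(y0 + 1)
  ix0 <- reflect(x0); ix1 <- reflect(x0 + 1)
  lin <- function(iy, ix) as.integer((ix - 1L) * p + iy)
  list(exact = FALSE,
       i1 = lin(iy0, ix0), w1 = (1 - fy) * (1 - fx),
       i2 = lin(iy1, ix0), w2 = fy * (1 - fx),
       i3 = lin(iy0, ix1), w3 = (1 - fy) * fx,
       i4 = lin(iy1, ix1), w4 = fy * fx)
}

#' Augment a patch set by mirroring and rotation
#'
#' Every patch is transformed by every (mirror, rotation) combination in
#' the configuration, multiplying the patch count by
#' `length(mirrors) * length(rotations_deg)` (27 by default) for both
#' classes alike. Rotations by angles that are not multiples of 90 degrees
#' use bilinear interpolation over a reflect-padded patch, then a centre
#' crop back to the original size, so no black-corner artefacts leak label
#' information; multiples of 90 degrees (and mirrors) are exact pixel
#' permutations. The (identity, 0 degree) copy is bit-identical to the
#' input and keeps its origin; all other copies get origin `"augmented"`.
#'
#' @param patches A `patch_set`.
#' @param config An [augmentation_config()].
#' @return The augmented `patch_set`.
#' @export
augment_patches <- function(patches, config = augmentation_config()) {
  stopifnot(inherits(patches, "patch_set"), inherits(config, "augmentation_config"))
  p <- dim(patches$pixels)[1]
  n <- n_patches(patches)
  if (n == 0L) return(patches)
  npix <- p * p
  X <- matrix(patches$pixels, nrow = npix * 3L, ncol = n)
  n_tr <- length(config$mirrors) * length(config$rotations_deg)
  out <- array(0, c(p, p, 3L, n * n_tr))
  label <- character(n * n_tr); src <- character(n * n_tr); org <- character(n * n_tr)
  ch_off <- rep((0:2) * npix, each = npix)
  at <- 0L
  for (mirror in config$mirrors) {
    for (angle in config$rotations_deg) {
      plan <- .transform_plan(p, mirror, angle)
      if (plan$exact) {
        idx3 <- rep(plan$idx, times = 3L) + ch_off
        block <- X[idx3, , drop = FALSE]
      } else {
        i1 <- rep(plan$i1, 3L) + ch_off; i2 <- rep(plan$i2, 3L) + ch_off
        i3 <- rep(plan$i3, 3L) + ch_off; i4 <- rep(plan$i4, 3L) + ch_off
        w1 <- rep(plan$w1, 3L); w2 <- rep(plan$w2, 3L)
        w3 <- rep(plan$w3, 3L); w4 <- rep(plan$w4, 3L)
        block <- X[i1, , drop = FALSE] * w1 + X[i2, , drop = FALSE] * w2 +
                 X[i3, , drop = FALSE] * w3 + X[i4, , drop = FALSE] * w4
      }
      sel <- at + seq_len(n)
      out[, , , sel] <- array(block, c(p, p, 3L, n))
      label[sel] <- patches$label
      src[sel] <- patches$source_image_id
      org[sel] <- if (mirror == "identity" && angle == 0) patches$origin
                  else "augmented"
      at <- at + n
    }
  }
  patch_set(out, label, src, org)
}

#' Split image ids into disjoint train and test sets
#'
#' Patches from one source image (slide) must never appear on both sides
#' of a split; the split therefore operates on image ids, not patches.
#'
#' @param image_ids Character vector of distinct image/slide identifiers.
#' @param n_train Number of ids assigned to training.
#' @param seed Integer seed for the shuffle.
#' @return A list of class `dataset_split` with `train_image_ids` and
#'   `test_image_ids` (disjoint, union = `image_ids`).
#' @export
dataset_split <- function(image_ids, n_train, seed = 1L) {
  image_ids <- unique(as.character(image_ids))
  stopifnot(n_train >= 0L, n_train <= length(image_ids))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  sh <- sample(image_ids)
  structure(list(train_image_ids = sort(sh[seq_len(n_train)]),
                 test_image_ids = sort(sh[-seq_len(n_train)])),
            class = "dataset_split")
}

#' Mine hard negative patches from a model's false positives
#'
#' Runs likelihood inference on images known to contain no positive cells
#' (or with ground truth supplied so true positives can be excluded),
#' finds likelihood peaks above `likelihood_threshold` that do not match
#' any true centre within `match_radius_um`, and cuts a negative patch
#' centred on each. These "exceptionally challenging" negatives are then
#' added to the training corpus for a second training round.
#'
#' @param model A trained classifier accepted by
#'   [predict_likelihood_map()].
#' @param images List of [rgb_image()] objects.
#' @param likelihood_threshold Peaks below this posterior are ignored
#'   (default 0.3, the detection-stage likelihood threshold).
#' @param truth Optional list (parallel to `images`) of data.frames with
#'   0-based `x`, `y` columns of true positive centres; peaks within
#'   `match_radius_um` of a true centre are not mined.
#' @param match_radius_um Exclusion radius around true centres (um).
#' @param patch_px Patch edge length.
#' @return A `patch_set` of negative patches with origin
#'   `"mined_hard_negative"` (possibly empty). The 0-based peak
#'   coordinates the patches were cut at are attached as attribute
#'   `"centers"` (data.frame `image_id`, `x`, `y`).
#' @export
mine_hard_negatives <- function(model, images, likelihood_threshold = 0.3,
                                truth = NULL, match_radius_um = 4,
                                patch_px = 46L) {
  if (!is_trained(model)) {
    stop("cannot mine hard negatives with an untrained model", call. = FALSE)
  }
  if (inherits(images, "rgb_image")) images <- list(images)
  half <- patch_px %/% 2L
  sets <- list()
  centers <- list()
  for (k in seq_along(images)) {
    image <- images[[k]]
    H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
    lmap <- predict_likelihood_map(model, image)
    mask <- lmap$values >= likelihood_threshold
    if (!any(mask)) next
    lab <- cpp_label8(mask)
    ncomp <- max(lab)
    if (ncomp == 0L) next
    ## peak (argmax of the likelihood) per component, 0-based coords
    ord <- order(as.vector(lab))
    lin <- seq_len(H * W)[ord]; labv <- as.vector(lab)[ord]
    first <- match(seq_len(ncomp), labv)
    last <- c(first[-1L] - 1L, length(labv))
    px_r <- um_to_px(match_radius_um, image$metadata)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (comp in seq_len(ncomp)) {
      idx <- lin[first[comp]:last[comp]]
      peak <- idx[which.max(lmap$values[idx])]
      y <- (peak - 1L) %% H          # 0-based
      x <- (peak - 1L) %/% H
      if (!is.null(truth) && !is.null(truth[[k]]) && nrow(truth[[k]]) > 0L) {
        d2 <- (truth[[k]]$x - x)^2 + (truth[[k]]$y - y)^2
        if (any(d2 <= px_r^2)) next
      }
      if (y < half || y > H - 1L - (patch_px - half - 1L) ||
          x < half || x > W - 1L - (patch_px - half - 1L)) next
      keep_x <- c(keep_x, x); keep_y <- c(keep_y, y)
    }
    if (length(keep_x) == 0L) next
    n <- length(keep_x)
    px <- array(0, c(patch_px, patch_px, 3L, n))
    for (i in seq_len(n)) {
      rows <- (keep_y[i] - half + 1L):(keep_y[i] + patch_px - half)
      cols <- (keep_x[i] - half + 1L):(keep_x[i] + patch_px - half)
      px[, , , i] <- image$pixels[rows, cols, ]
    }
    sets[[length(sets) + 1L]] <-
      patch_set(px, rep("negative", n),
                rep(image$metadata$image_id, n),
                rep("mined_hard_negative", n))
    centers[[length(centers) + 1L]] <-
      data.frame(image_id = rep(image$metadata$image_id, n),
                 x = keep_x, y = keep_y, stringsAsFactors = FALSE)
  }
  if (length(sets) == 0L) {
    out <- patch_set(array(0, c(patch_px, patch_px, 3L, 0L)),
                     character(0), character(0), character(0))
    attr(out, "centers") <- data.frame(image_id = character(),
                                       x = numeric(), y = numeric())
    return(out)
  }
  out <- do.call(combine_patches, sets)
  attr(out, "centers") <- do.call(rbind, centers)
  out
}
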