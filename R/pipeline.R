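## End-to-end pipeline: synthesise images -> build the patch corpus ->
## train -> (mine hard negatives -> retrain) -> dense likelihood maps ->
## radial-symmetry detection -> evaluation against ground truth.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with a global seed that
#' propagates to every stochastic stage (image synthesis, patch
#' sampling, shuffling, network initialisation).
#'
#' @param out_dir Output directory for artifacts.
#' @param n_validation_images Number of held-out synthetic images the
#'   detector is evaluated on.
#' @param synth A [synth_config()] describing the synthetic tissue.
#' @param augmentation An [augmentation_config()].
#' @param cnn A [cnn_config()].
#' @param training A [training_config()].
#' @param frst An [frst_params()].
#' @param n_base_patches_per_class Manually-extracted patches per class
#'   before augmentation.
#' @param n_patches_per_class Corpus size per class after augmentation
#'   (subsampled deterministically; `NULL` keeps everything).
#' @param hard_negative_round Run the second training round on mined
#'   hard negatives (on by default -- the first-round model's false
#'   positives are fed back as additional negative patches)?
#' @param n_mining_images Negative-only images used for mining.
#' @param match_tol_um Detection-to-truth match tolerance (um).
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ihcdetect_run_"),
                            n_validation_images = 4L,
                            synth = synth_config(),
                            augmentation = augmentation_config(),
                            cnn = cnn_config(),
                            training = training_config(),
                            frst = frst_params(),
                            n_base_patches_per_class = 100L,
                            n_patches_per_class = NULL,
                            hard_negative_round = TRUE,
                            n_mining_images = 2L,
                            match_tol_um = 4,
                            seed = 1L) {
  structure(list(out_dir = out_dir,
                 n_validation_images = as.integer(n_validation_images),
                 synth = synth, augmentation = augmentation, cnn = cnn,
                 training = training, frst = frst,
                 n_base_patches_per_class = as.integer(n_base_patches_per_class),
                 n_patches_per_class = if (is.null(n_patches_per_class)) NULL
                                       else as.integer(n_patches_per_class),
                 hard_negative_round = isTRUE(hard_negative_round),
                 n_mining_images = as.integer(n_mining_images),
                 match_tol_um = match_tol_um,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ihcdetect] ", fmt), ...))
}

## deterministic sub-seed derivation, kept within the 32-bit integer range
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587)
}

#' Build the training corpus (base extraction + augmentation)
#'
#' @param config A [pipeline_config()].
#' @param extra_negatives Optional `patch_set` of additional negative
#'   patches (e.g. mined hard negatives) appended before augmentation.
#' @param verbose Log progress?
#' @return An augmented, optionally subsampled `patch_set`.
#' @export
build_training_corpus <- function(config, extra_negatives = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$synth
  sc$seed <- .sub_seed(config$seed, 1L)
  base <- generate_patch_set(sc, config$n_base_patches_per_class)
  if (!is.null(extra_negatives) && n_patches(extra_negatives) > 0L) {
    base <- combine_patches(base, extra_negatives)
  }
  corpus <- augment_patches(base, config$augmentation)
  .log_stage(verbose, "corpus: %d base -> %d augmented patches",
             n_patches(base), n_patches(corpus))
  if (!is.null(config$n_patches_per_class)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(.sub_seed(config$seed, 2L))
    idx <- unlist(lapply(c("positive", "negative"), function(cl) {
      i <- which(corpus$label == cl)
      if (length(i) > config$n_patches_per_class)
        sort(sample(i, config$n_patches_per_class)) else i
    }))
    corpus <- subset_patches(corpus, idx)
  }
  corpus
}

#' Run the full detection pipeline on synthetic data
#'
#' Stages: synthesise validation images; build the augmented patch
#' corpus; train the classifier; optionally mine hard negatives from
#' negative-only images with the first-round model and retrain; compute
#' dense likelihood maps; detect cells with the radial-symmetry
#' transform; evaluate detections and counts against the known ground
#' truth. All artifacts (images, ground truth, detections, count table,
#' checkpoint, config + checksums manifest) are written under
#' `config$out_dir`; a rerun with the same configuration and seed
#' reproduces the detection CSVs exactly on the same platform.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr?
#' @return A list of class `pipeline_result`: the trained `model`,
#'   per-image `detections` list, `counts` (truth vs model), `matches`
#'   (per image), aggregate `metrics` (precision, recall, F1, median
#'   relative count error), and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(config$out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  ## stage: synth -- held-out validation images with ground truth
  val <- run_stage("synth", {
    lapply(seq_len(config$n_validation_images), function(i) {
      sc <- config$synth
      sc$seed <- .sub_seed(config$seed, 100L + i)
      out <- generate_tissue_image(sc, image_id = sprintf("val_%02d", i))
      write_image(out$image, file.path(img_dir, sprintf("val_%02d.png", i)))
      write_annotations(
        data.frame(image_id = out$image$metadata$image_id,
                   x = out$truth$positive_centers$x,
                   y = out$truth$positive_centers$y,
                   label = "positive"),
        file.path(img_dir, sprintf("val_%02d_truth.csv", i)))
      out
    })
  })
  .log_stage(verbose, "synth: %d validation images", length(val))

  ## stage: build-dataset + train (round 1)
  corpus <- run_stage("build-dataset", build_training_corpus(config, verbose = verbose))
  tc <- config$training
  tc$seed <- .sub_seed(config$seed, 3L)
  model <- run_stage("train", {
    m <- build_cnn(config$cnn, seed = .sub_seed(config$seed, 4L))
    train_cnn(m, corpus, tc)
  })
  .log_stage(verbose, "train: %d patches, final loss %.4f",
             n_patches(corpus), utils::tail(model$history$loss, 1))

  ## stage: hard-negative mining + retrain (round 2)
  if (config$hard_negative_round) {
    mined <- run_stage("mine-hard-negatives", {
      mine_imgs <- lapply(seq_len(config$n_mining_images), function(i) {
        sc <- config$synth
        sc$n_positive_cells <- 0L
        sc$seed <- .sub_seed(config$seed, 200L + i)
        generate_tissue_image(sc, image_id = sprintf("mine_%02d", i))$image
      })
      mine_hard_negatives(model, mine_imgs,
                          likelihood_threshold = config$frst$likelihood_threshold)
    })
    .log_stage(verbose, "mining: %d hard negatives", n_patches(mined))
    if (n_patches(mined) > 0L) {
      corpus2 <- run_stage("build-dataset-2",
                           build_training_corpus(config, extra_negatives = mined,
                                                 verbose = verbose))
      model <- run_stage("retrain", {
        m <- build_cnn(config$cnn, seed = .sub_seed(config$seed, 4L))
        train_cnn(m, corpus2, tc)
      })
      .log_stage(verbose, "retrain: %d patches", n_patches(corpus2))
    }
  } else {
    .log_stage(verbose, "hard-negative round disabled; skipping retraining")
  }

  ## stage: predict + detect + evaluate
  dets <- list(); matches <- list()
  counts <- data.frame(image_id = character(), truth = numeric(),
                       model = numeric())
  for (i in seq_along(val)) {
    v <- val[[i]]
    id <- v$image$metadata$image_id
    lmap <- run_stage("predict", predict_likelihood_map(model, v$image))
    tiff::writeTIFF(lmap$values, file.path(img_dir, sprintf("%s_map.tif", id)),
                    bits.per.sample = 32L)
    d <- run_stage("detect", detect_cells(lmap, config$frst))
    d$image_id <- rep(id, nrow(d))
    dets[[id]] <- d
    matches[[id]] <- match_detections(d, v$truth$positive_centers,
                                      v$image$metadata, config$match_tol_um)
    counts <- rbind(counts,
                    data.frame(image_id = id,
                               truth = nrow(v$truth$positive_centers),
                               model = nrow(d)))
    .log_stage(verbose, "%s: %d detections / %d truth", id, nrow(d),
               nrow(v$truth$positive_centers))
  }
  det_path <- file.path(config$out_dir, "detections.csv")
  write_detections(do.call(rbind, dets), det_path)
  counts_path <- file.path(config$out_dir, "counts.csv")
  write_observer_counts(counts, counts_path)

  tp <- sum(vapply(matches, `[[`, integer(1), "n_matched"))
  fp <- sum(vapply(matches, `[[`, integer(1), "n_false_positive"))
  fn <- sum(vapply(matches, `[[`, integer(1), "n_missed"))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  rel_err <- abs(counts$model - counts$truth) / pmax(counts$truth, 1)
  metrics <- list(precision = precision, recall = recall, f1 = f1,
                  median_rel_count_error = stats::median(rel_err),
                  n_detections = sum(counts$model),
                  n_truth = sum(counts$truth))

  ## manifest: configuration hash + artifact checksums
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_path)
  manifest <- data.frame(
    file = c(basename(det_path), basename(counts_path)),
    md5 = unname(tools::md5sum(c(det_path, counts_path)))
  )
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)

  model_path <- file.path(config$out_dir, "model.rds")
  save_model(model, model_path)
  structure(list(model = model, detections = dets, matches = matches,
                 counts = counts, metrics = metrics,
                 paths = list(out_dir = config$out_dir, detections = det_path,
                              counts = counts_path, model = model_path,
                              config = cfg_path)),
            class = "pipeline_result")
}

.config_as_list <- function(config) {
  rapply(unclass(config), f = function(x) x, how = "list")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<pipeline_result> %d images: F1 %.3f (precision %.3f, ",
                     "recall %.3f), median relative count error %.3f\n"),
              nrow(x$counts), m$f1, m$precision, m$recall,
              m$median_rel_count_error))
  invisible(x)
}

#' Overlay detections on an image
#'
#' Marks detected cell centres with small magenta squares, the usual
#' presentation of radial-symmetry detections on stained tissue.
#'
#' @param image An [rgb_image()].
#' @param dets A [detections()] data.frame.
#' @param path Output PNG path.
#' @param marker_px Marker half-width in px.
#' @export
write_overlay <- function(image, dets, path, marker_px = 2L) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- image$pixels
  H <- dim(arr)[1]; W <- dim(arr)[2]
  for (i in seq_len(nrow(dets))) {
    ys <- max(1L, round(dets$y[i]) + 1L - marker_px):
          min(H, round(dets$y[i]) + 1L + marker_px)
    xs <- max(1L, round(dets$x[i]) + 1L - marker_px):
          min(W, round(dets$x[i]) + 1L + marker_px)
    arr[ys, xs, 1] <- 255; arr[ys, xs, 2] <- 0; arr[ys, xs, 3] <- 255
  }
  png::writePNG(arr / 255, path)
  invisible(path)
}
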