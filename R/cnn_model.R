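## The two-class patch classifier: a small convolutional network trained
## on 46x46 RGB patches with minibatch SGD + Nesterov momentum, and dense
## per-pixel likelihood-map inference over whole images.

#' CNN architecture configuration
#'
#' The network comprises six convolutional layers, two 2x2 max-pooling
#' layers and two fully connected layers ending in a softmax over
#' \{negative, positive\}. Kernel sizes, filter counts, pool positions and
#' fully-connected widths are configurable; the defaults (3x3 kernels,
#' filters 16-16-32-32-64-64, pools after conv 2 and conv 4, a
#' 128-unit hidden layer) keep the receptive field within the 46-px patch
#' while remaining fast enough for dense whole-image inference on a
#' single CPU.
#'
#' @param input_size Patch edge length in px (default 46).
#' @param conv_filters Integer vector of 6 filter counts.
#' @param conv_kernels Integer vector of 6 (square) kernel sizes.
#' @param pool_after Two indices into the conv sequence after which a 2x2
#'   stride-2 max pool is applied.
#' @param fc_sizes Two fully-connected widths; the last must be 2.
#' @return An object of class `cnn_config`. Errors if the configured
#'   stack does not reduce an `input_size` patch to a 1x1 output (i.e.
#'   the receptive field would exceed the patch).
#' @export
cnn_config <- function(input_size = 46L,
                       conv_filters = c(16L, 16L, 32L, 32L, 64L, 64L),
                       conv_kernels = rep(3L, 6L),
                       pool_after = c(2L, 4L),
                       fc_sizes = c(128L, 2L)) {
  conv_filters <- as.integer(conv_filters)
  conv_kernels <- as.integer(conv_kernels)
  pool_after <- as.integer(pool_after)
  fc_sizes <- as.integer(fc_sizes)
  if (length(conv_filters) != 6L || length(conv_kernels) != 6L) {
    stop("exactly six convolutional layers are required", call. = FALSE)
  }
  if (length(pool_after) != 2L || any(pool_after < 1L) || any(pool_after > 6L) ||
      anyDuplicated(pool_after)) {
    stop("exactly two distinct pooling positions in 1..6 are required", call. = FALSE)
  }
  if (length(fc_sizes) != 2L || fc_sizes[2] != 2L) {
    stop("exactly two fully connected layers are required, the last of width 2",
         call. = FALSE)
  }
  ## trace the spatial size through the stack
  s <- as.integer(input_size)
  for (l in 1:6) {
    if (s < conv_kernels[l]) {
      stop(sprintf("receptive field exceeds the input: only %d px left before conv %d (kernel %d)",
                   s, l, conv_kernels[l]), call. = FALSE)
    }
    s <- s - conv_kernels[l] + 1L
    if (l %in% pool_after) s <- s %/% 2L
    if (s < 1L) stop("receptive field exceeds the input", call. = FALSE)
  }
  structure(list(input_size = as.integer(input_size),
                 conv_filters = conv_filters, conv_kernels = conv_kernels,
                 pool_after = sort(pool_after), fc_sizes = fc_sizes,
                 fc_kernel = s),
            class = "cnn_config")
}

#' Training configuration
#'
#' Defaults follow plain stochastic gradient descent with a learning rate
#' of 0.01 and Nesterov momentum of 0.9, stopping after a single pass over
#' the training patches (further passes bring no validation improvement on
#' this problem).
#'
#' @param learning_rate SGD step size (> 0).
#' @param nesterov_momentum Momentum coefficient in \[0, 1).
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param clip_norm Global gradient-norm clip applied per batch (`NA`
#'   disables). With momentum 0.9 and a single pass over the data, one
#'   outlier batch can otherwise blow the parameters into a dead-ReLU
#'   state it never recovers from.
#' @param seed Integer seed controlling shuffling.
#' @param shuffle Shuffle the patch order each epoch?
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.01, nesterov_momentum = 0.9,
                            epochs = 1L, batch_size = 32L, clip_norm = 2,
                            seed = 1L, shuffle = TRUE) {
  stopifnot(learning_rate >= 0, nesterov_momentum >= 0, nesterov_momentum < 1,
            epochs >= 1L, batch_size >= 1L, is.na(clip_norm) || clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 nesterov_momentum = nesterov_momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 clip_norm = as.numeric(clip_norm),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "training_config")
}

## layer list in the internal format shared with the C++ core
.init_layers <- function(config) {
  layers <- list()
  cin <- 3L
  for (l in 1:6) {
    k <- config$conv_kernels[l]; cout <- config$conv_filters[l]
    fan_in <- cin * k * k
    layers[[l]] <- list(
      k = k, relu = TRUE, pool = l %in% config$pool_after,
      W = matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / (fan_in + cout))),
                 cout, fan_in),
      b = rep(0, cout)
    )
    cin <- cout
  }
  kfc <- config$fc_kernel
  fan_in <- cin * kfc * kfc
  layers[[7]] <- list(
    k = kfc, relu = TRUE, pool = FALSE,
    W = matrix(stats::rnorm(config$fc_sizes[1] * fan_in, 0,
                            sqrt(2 / (fan_in + config$fc_sizes[1]))),
               config$fc_sizes[1], fan_in),
    b = rep(0, config$fc_sizes[1])
  )
  layers[[8]] <- list(
    k = 1L, relu = FALSE, pool = FALSE,
    W = matrix(stats::rnorm(2L * config$fc_sizes[1], 0,
                            sqrt(2 / (config$fc_sizes[1] + 2L))),
               2L, config$fc_sizes[1]),
    b = rep(0, 2L)
  )
  layers
}

#' Build an untrained patch classifier
#'
#' Parameters are Glorot-initialised (normal, variance
#' `2/(fan_in + fan_out)`), which keeps the published SGD settings
#' (learning rate 0.01, Nesterov momentum 0.9) stable; initialisation is
#' deterministic given
#' `seed`.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `ihc_cnn`.
#' @examples
#' model <- build_cnn(cnn_config(), seed = 1)
#' model
#' @export
build_cnn <- function(config = cnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  structure(list(config = config, layers = .init_layers(config),
                 trained = FALSE, history = NULL, seed = as.integer(seed)),
            class = "ihc_cnn")
}

#' @export
print.ihc_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<ihc_cnn> %d-px patches, %s, %s parameters\n",
              x$config$input_size,
              if (x$trained) "trained" else "untrained",
              format(np, big.mark = ",")))
  invisible(x)
}

#' @export
summary.ihc_cnn <- function(object, ...) {
  cat(sprintf("Patch classifier (%d x %d RGB input)\n",
              object$config$input_size, object$config$input_size))
  for (l in seq_along(object$layers)) {
    L <- object$layers[[l]]
    kind <- if (l <= 6) "conv" else "fc"
    cat(sprintf("  %2d %s k=%d out=%d%s\n", l, kind, L$k, nrow(L$W),
                if (L$pool) " + 2x2 max pool" else ""))
  }
  if (!is.null(object$history)) {
    cat(sprintf("Training: %d SGD steps, final batch loss %.4f\n",
                length(object$history$loss),
                utils::tail(object$history$loss, 1)))
    if (length(object$history$val_accuracy) > 0) {
      cat(sprintf("Validation accuracy: %s\n",
                  paste(sprintf("%.4f", object$history$val_accuracy),
                        collapse = ", ")))
    }
  }
  invisible(object)
}

#' Number of trainable parameters
#' @param model An `ihc_cnn`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "ihc_cnn"))
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Is a classifier trained?
#' @param model A classifier object.
#' @return Logical.
#' @export
is_trained <- function(model) UseMethod("is_trained")

#' @export
is_trained.default <- function(model) TRUE

#' @export
is_trained.ihc_cnn <- function(model) isTRUE(model$trained)

#' Train the patch classifier
#'
#' Minibatch stochastic gradient descent on the softmax cross-entropy,
#' with the Nesterov momentum update
#' `v <- mu*v - eta*grad; theta <- theta + mu*v - eta*grad`. Exactly
#' `epochs` passes are made over the (optionally shuffled) patches; the
#' per-batch mean loss is recorded, and validation accuracy is logged
#' after each epoch when `val_patches` is supplied. Training data must
#' contain both classes; a non-finite loss aborts with diagnostics.
#'
#' @param model An [build_cnn()] model.
#' @param patches A `patch_set` whose patch size matches the model input.
#' @param tc A [training_config()].
#' @param val_patches Optional `patch_set` used only for accuracy logging.
#' @return The trained `ihc_cnn`, with `$history` holding the per-step
#'   loss and per-epoch validation accuracy.
#' @export
train_cnn <- function(model, patches, tc = training_config(),
                      val_patches = NULL) {
  stopifnot(inherits(model, "ihc_cnn"), inherits(patches, "patch_set"),
            inherits(tc, "training_config"))
  n <- n_patches(patches)
  if (n < 2L) stop("need at least two training patches", call. = FALSE)
  if (dim(patches$pixels)[1] != model$config$input_size) {
    stop(sprintf("patch size %d does not match model input size %d",
                 dim(patches$pixels)[1], model$config$input_size), call. = FALSE)
  }
  y <- as.integer(patches$label == "positive")
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; both classes are required",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(tc$seed)
  orders <- lapply(seq_len(tc$epochs), function(e) {
    if (tc$shuffle) sample.int(n) - 1L else seq_len(n) - 1L
  })
  Xval <- NULL; yval <- NULL
  if (!is.null(val_patches)) {
    stopifnot(inherits(val_patches, "patch_set"))
    Xval <- val_patches$pixels
    yval <- as.integer(val_patches$label == "positive")
  }
  clip <- if (is.na(tc$clip_norm)) -1 else tc$clip_norm
  fit <- cpp_cnn_train(model$layers, patches$pixels, y, orders,
                       tc$learning_rate, tc$nesterov_momentum, tc$batch_size,
                       clip, Xval, yval)
  ## bias vectors come back from the C++ core as n x 1 arrays
  model$layers <- lapply(fit$layers, function(l) {
    l$b <- as.vector(l$b)
    l
  })
  model$trained <- TRUE
  model$history <- list(loss = fit$loss, val_accuracy = fit$val_accuracy)
  model
}

#' Positive-class probabilities for a set of patches
#'
#' The forward pass is applied per patch, so results are independent of
#' any batching. Probabilities for the two classes sum to 1.
#'
#' @param model An `ihc_cnn`.
#' @param patches A `patch_set` with the model's input size.
#' @return Numeric vector of positive-class probabilities in \[0, 1\].
#' @export
classify_patches <- function(model, patches) {
  stopifnot(inherits(model, "ihc_cnn"), inherits(patches, "patch_set"))
  if (dim(patches$pixels)[1] != model$config$input_size) {
    stop(sprintf("patch size %d does not match model input size %d",
                 dim(patches$pixels)[1], model$config$input_size), call. = FALSE)
  }
  if (n_patches(patches) == 0L) return(numeric(0))
  pr <- cpp_cnn_forward(model$layers, patches$pixels)
  pr[, 2]
}

#' Likelihood map container
#'
#' Per-pixel posterior probability of "positive cell", same spatial size
#' as the source image, values in \[0, 1\].
#'
#' @param values `H x W` numeric matrix of probabilities.
#' @param metadata The source image's [image_metadata()].
#' @return An object of class `likelihood_map`.
#' @export
likelihood_map <- function(values, metadata) {
  stopifnot(is.matrix(values), inherits(metadata, "image_metadata"))
  if (any(values < -1e-9 | values > 1 + 1e-9)) {
    stop("likelihood values must lie in [0, 1]", call. = FALSE)
  }
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, metadata = metadata),
            class = "likelihood_map")
}

#' @export
print.likelihood_map <- function(x, ...) {
  cat(sprintf("<likelihood_map> %d x %d, range [%.3f, %.3f], id='%s'\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              x$metadata$image_id))
  invisible(x)
}

#' Dense per-pixel likelihood inference
#'
#' The value at pixel `(y, x)` is the positive-class probability of the
#' 46x46 window centred there (window rows `y-23 .. y+22`). The border
#' band where no full window fits is filled with 0. Inference is
#' fully convolutional with shift-and-stitch reassembly and is
#' arithmetically identical to classifying every window separately. Large
#' images can be processed tile-wise (`tile` with `halo >= 23`), which
#' does not change any value.
#'
#' @param model A classifier (method dispatch; `ihc_cnn` provided).
#' @param image An [rgb_image()] at least as large as the model input.
#' @param ... Method arguments.
#' @return A [likelihood_map()].
#' @export
predict_likelihood_map <- function(model, image, ...) {
  UseMethod("predict_likelihood_map")
}

#' @rdname predict_likelihood_map
#' @param tile Optional tile edge (px) for tile-wise processing.
#' @param halo Tile overlap half-width; must be at least half the patch
#'   size (default 23) so tiling is value-exact.
#' @param stride 1 for exact pixel-by-pixel inference (default); the
#'   model's pooling stride (4 for the default architecture) selects the
#'   fast mode, which evaluates a coarse grid and bilinearly upsamples.
#' @export
predict_likelihood_map.ihc_cnn <- function(model, image, tile = NULL,
                                           halo = 23L, stride = 1L, ...) {
  stopifnot(inherits(image, "rgb_image"))
  win <- model$config$input_size
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  if (H < win || W < win) {
    stop(sprintf("image (%d x %d) smaller than the %d-px patch", H, W, win),
         call. = FALSE)
  }
  if (!is.null(tile)) {
    if (halo < win %/% 2L) {
      stop(sprintf("tile-wise inference needs halo >= %d", win %/% 2L),
           call. = FALSE)
    }
    ts <- tile_image(image, tile, halo)
    for (k in seq_along(ts$tiles)) {
      arr <- ts$tiles[[k]]
      if (dim(arr)[1] >= win && dim(arr)[2] >= win) {
        sub <- rgb_image(arr, image$metadata)
        m <- predict_likelihood_map(model, sub, tile = NULL, stride = stride)
        ts$tiles[[k]] <- m$values
      } else {
        ts$tiles[[k]] <- matrix(0, dim(arr)[1], dim(arr)[2])
      }
    }
    ts$depth <- 1L
    return(likelihood_map(stitch_tiles(ts), image$metadata))
  }
  res <- cpp_cnn_dense(model$layers, image$pixels, win, isTRUE(stride == 1L))
  half <- win %/% 2L
  out <- matrix(0, H, W)
  rows <- (half + 1L):(H - (win - half) + 1L)   # 1-based centre rows
  cols <- (half + 1L):(W - (win - half) + 1L)
  if (!res$coarse) {
    out[rows, cols] <- res$P
  } else {
    ## coarse grid at window top-lefts 0, s, 2s, ...; upsample bilinearly
    s <- res$stride
    P <- res$P
    cg_y <- (seq_len(nrow(P)) - 1L) * s       # coarse top-lefts, 0-based
    cg_x <- (seq_len(ncol(P)) - 1L) * s
    fy <- 0:(length(rows) - 1L); fx <- 0:(length(cols) - 1L)
    tmp <- apply(P, 2, function(col)
      stats::approx(cg_y, col, xout = fy, rule = 2)$y)
    tmp <- matrix(tmp, nrow = length(fy))
    fine <- t(apply(tmp, 1, function(row)
      stats::approx(cg_x, row, xout = fx, rule = 2)$y))
    fine <- matrix(fine, nrow = length(fy))
    out[rows, cols] <- pmin(pmax(fine, 0), 1)
  }
  likelihood_map(out, image$metadata)
}

#' @export
predict.ihc_cnn <- function(object, newdata, type = c("prob", "class", "map"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "rgb_image") || type == "map") {
    return(predict_likelihood_map(object, newdata, ...))
  }
  p <- classify_patches(object, newdata)
  if (type == "class") ifelse(p >= 0.5, "positive", "negative") else p
}

#' Save and load a classifier checkpoint
#'
#' The checkpoint is a self-describing list (architecture configuration
#' plus parameter tensors) written with R serialisation.
#'
#' @param model An `ihc_cnn`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ihc_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ihc_cnn")) stop("not an ihc_cnn checkpoint", call. = FALSE)
  model
}

## ---- colour-blind toy model ------------------------------------------------

#' A deliberately colour-blind toy classifier
#'
#' Scores each pixel by its darkness (1 - mean intensity / 255) on a
#' clipped linear ramp, ignoring colour entirely. Dark stained cells and
#' anthracotic pigment both light up, making this model a controlled
#' source of false positives for exercising hard-negative mining.
#'
#' @param threshold Darkness at which the posterior starts to rise.
#' @param scale Darkness span over which the posterior ramps from 0 to 1
#'   (kept wide so the posterior keeps a gradient over near-black
#'   objects instead of saturating into a flat plateau).
#' @return An object of class `darkness_model`.
#' @export
darkness_model <- function(threshold = 0.45, scale = 0.5) {
  structure(list(threshold = threshold, scale = scale, trained = TRUE),
            class = "darkness_model")
}

#' @export
predict_likelihood_map.darkness_model <- function(model, image, ...) {
  stopifnot(inherits(image, "rgb_image"))
  dark <- 1 - (image$pixels[, , 1] + image$pixels[, , 2] +
                 image$pixels[, , 3]) / (3 * 255)
  p <- pmin(pmax((dark - model$threshold) / model$scale, 0), 1)
  likelihood_map(p, image$metadata)
}

#' @export
is_trained.darkness_model <- function(model) TRUE
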