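# Shared fixtures: tiny configurations that keep unit tests fast, plus
# independent brute-force oracles for the radial symmetry transform and
# for dense sliding-window inference.

tiny_cnn_config <- function() {
  cnn_config(conv_filters = c(4L, 4L, 8L, 8L, 8L, 8L), fc_sizes = c(16L, 2L))
}

small_synth_config <- function(seed = 1L, ...) {
  synth_config(image_size_px = c(300L, 300L), n_positive_cells = 8L,
               n_pigment_clumps = 3L, n_negative_nuclei = 5L,
               n_erythrocytes = 2L, n_stain_smears = 1L, seed = seed, ...)
}

random_rgb_image <- function(H, W, seed = 1L, pixel_size_um = 0.228,
                             image_id = "rand") {
  set.seed(seed)
  rgb_image(array(runif(H * W * 3, 0, 255), c(H, W, 3)),
            image_metadata(pixel_size_um, image_id = image_id))
}

# two trivially colour-separable classes: red-ish vs blue-ish patches
separable_patch_set <- function(n_per_class, seed = 1L, noise = 20) {
  set.seed(seed)
  n <- 2L * n_per_class
  px <- array(0, c(46L, 46L, 3L, n))
  for (i in seq_len(n_per_class)) {
    px[, , 1, i] <- 200; px[, , 2, i] <- 60; px[, , 3, i] <- 40
    px[, , 1, n_per_class + i] <- 40
    px[, , 2, n_per_class + i] <- 60
    px[, , 3, n_per_class + i] <- 200
  }
  px <- px + array(rnorm(length(px), 0, noise), dim(px))
  px <- pmin(pmax(px, 0), 255)
  patch_set(px, c(rep("positive", n_per_class), rep("negative", n_per_class)))
}

# brute-force FRST: explicit per-pixel, per-radius voting loops and a
# full 2-D Gaussian convolution (zero padding), entirely independent of
# the vectorised implementation under test
frst_oracle <- function(map, radii, alpha = 0.5, beta = 0.25,
                        kappa_small = 8, kappa_large = 9.9,
                        sigma_factor = 0.25) {
  H <- nrow(map); W <- ncol(map)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (x in 2:(W - 1)) {
    for (y in 2:(H - 1)) {
      gx[y, x] <- (map[y, x + 1] - map[y, x - 1]) / 2
      gy[y, x] <- (map[y + 1, x] - map[y - 1, x]) / 2
    }
  }
  gm <- sqrt(gx^2 + gy^2)
  if (max(gm) == 0) return(matrix(0, H, W))
  thr <- beta * max(gm)
  S <- matrix(0, H, W)
  round_half_up <- function(v) floor(v + 0.5)
  for (n in radii) {
    O <- matrix(0, H, W); M <- matrix(0, H, W)
    for (x in 1:W) {
      for (y in 1:H) {
        if (gm[y, x] <= thr) next
        qx <- x + round_half_up(n * gx[y, x] / gm[y, x])
        qy <- y + round_half_up(n * gy[y, x] / gm[y, x])
        if (qx < 1 || qx > W || qy < 1 || qy > H) next
        O[qy, qx] <- O[qy, qx] + 1
        M[qy, qx] <- M[qy, qx] + gm[y, x]
      }
    }
    kap <- if (n == 1) kappa_small else kappa_large
    Fn <- (pmin(abs(O), kap) / kap)^alpha * (M / kap)
    sigma <- sigma_factor * n
    r <- max(1, ceiling(3 * sigma))
    k1 <- exp(-0.5 * ((-r):r)^2 / sigma^2)
    k1 <- k1 / sum(k1)
    K <- outer(k1, k1)
    Fb <- matrix(0, H, W)
    for (dy in -r:r) {
      for (dx in -r:r) {
        w <- K[dy + r + 1, dx + r + 1]
        ys <- max(1, 1 + dy):min(H, H + dy)
        xs <- max(1, 1 + dx):min(W, W + dx)
        Fb[ys - dy, xs - dx] <- Fb[ys - dy, xs - dx] + w * Fn[ys, xs]
      }
    }
    S <- S + Fb
  }
  S / length(radii)
}

# a symmetric Gaussian blob likelihood map with peak `amp` at a 0-based
# centre
blob_map <- function(H, W, cx, cy, sigma = 3, amp = 1) {
  outer(0:(H - 1), 0:(W - 1), function(y, x)
    amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
}

# naive dense inference: classify every window separately
naive_window_map <- function(model, image) {
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  win <- model$config$input_size
  vals <- matrix(NA_real_, H - win + 1L, W - win + 1L)
  for (r in seq_len(nrow(vals))) {
    for (c in seq_len(ncol(vals))) {
      patch <- image$pixels[r:(r + win - 1L), c:(c + win - 1L), , drop = FALSE]
      vals[r, c] <- classify_patches(
        model, patch_set(array(patch, c(win, win, 3L, 1L)), "negative"))
    }
  }
  vals
}
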