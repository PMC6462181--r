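test_that("architecture validation enforces the six-conv/two-pool/two-fc shape", {
  cc <- cnn_config()
  expect_equal(length(cc$conv_filters), 6)
  expect_error(cnn_config(conv_filters = c(8, 8, 8)), "six")
  expect_error(cnn_config(pool_after = c(1, 2, 3)), "two")
  expect_error(cnn_config(fc_sizes = c(64, 3)), "width 2")
  # a receptive field larger than the patch is rejected
  expect_error(cnn_config(conv_kernels = rep(15, 6)), "receptive field")
})

test_that("initialisation is deterministic and the forward pass is a softmax", {
  cc <- tiny_cnn_config()
  m1 <- build_cnn(cc, seed = 5)
  m2 <- build_cnn(cc, seed = 5)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_cnn(cc, seed = 6)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))

  np <- n_parameters(m1)
  expect_true(np > 0 && is.finite(np))

  zeros <- patch_set(array(0, c(46, 46, 3, 1)), "negative")
  pr <- cpp_cnn_forward(m1$layers, zeros$pixels)
  expect_equal(pr[1, 1] + pr[1, 2], 1, tolerance = 1e-6)
  ones <- patch_set(array(255, c(46, 46, 3, 2)), c("negative", "negative"))
  p <- classify_patches(m1, ones)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[1], p[2])  # duplicated patch, identical probability
})

test_that("training separates two colour classes and is reproducible", {
  ps <- separable_patch_set(250, seed = 8)
  m <- build_cnn(tiny_cnn_config(), seed = 2)
  tc <- training_config(epochs = 1, batch_size = 16, seed = 4)
  fit1 <- train_cnn(m, ps, tc)
  acc <- mean((classify_patches(fit1, ps) >= 0.5) == (ps$label == "positive"))
  expect_gte(acc, 0.99)
  expect_true(is_trained(fit1))

  # same data + same seed: identical final parameters
  fit2 <- train_cnn(m, ps, tc)
  expect_identical(fit1$layers, fit2$layers)

  # the epoch-mean loss decreases across thirds of the pass
  l <- fit1$history$loss
  thirds <- split(l, cut(seq_along(l), 3, labels = FALSE))
  expect_lt(mean(thirds[[2]]), mean(thirds[[1]]))
  expect_lt(mean(thirds[[3]]), mean(thirds[[1]]))

  # zero learning rate leaves parameters untouched
  fit0 <- train_cnn(m, ps, training_config(learning_rate = 0, epochs = 1,
                                           seed = 4))
  expect_identical(fit0$layers, m$layers)

  # single-class data is an explicit error
  onecls <- subset_patches(ps, which(ps$label == "positive"))
  expect_error(train_cnn(m, onecls, tc), "single class")

  # validation accuracy is logged per epoch
  fitv <- train_cnn(m, ps, training_config(epochs = 2, batch_size = 16,
                                           seed = 4),
                    val_patches = subset_patches(ps, 1:20))
  expect_length(fitv$history$val_accuracy, 2)
})

test_that("patch classification is batch-independent and size-checked", {
  ps <- separable_patch_set(8, seed = 3)
  m <- train_cnn(build_cnn(tiny_cnn_config(), seed = 1), ps,
                 training_config(epochs = 1, batch_size = 4, seed = 2))
  p_all <- classify_patches(m, ps)
  p_one <- vapply(seq_len(n_patches(ps)), function(i)
    classify_patches(m, subset_patches(ps, i)), numeric(1))
  expect_equal(p_all, p_one, tolerance = 1e-10)

  wrong <- patch_set(array(0, c(32, 32, 3, 1)), "negative")
  expect_error(classify_patches(m, wrong), "size")
})

test_that("dense inference equals naive sliding-window classification", {
  m <- build_cnn(tiny_cnn_config(), seed = 2)
  img <- random_rgb_image(60, 60, seed = 4)
  lmap <- predict_likelihood_map(m, img)
  expect_s3_class(lmap, "likelihood_map")
  expect_equal(dim(lmap$values), c(60, 60))
  expect_true(all(lmap$values >= 0 & lmap$values <= 1))

  naive <- naive_window_map(m, img)            # 15 x 15 valid grid
  dense_interior <- lmap$values[24:38, 24:38]  # centres 23..37 (0-based)
  expect_equal(dense_interior, naive, tolerance = 1e-4)

  # the border band where no window fits is zero
  expect_true(all(lmap$values[1:23, ] == 0))
  expect_true(all(lmap$values[, 1:23] == 0))
  expect_true(all(lmap$values[39:60, ] == 0))

  expect_error(predict_likelihood_map(m, random_rgb_image(40, 40)), "smaller")
})

test_that("tile-wise inference does not change any likelihood value", {
  m <- build_cnn(tiny_cnn_config(), seed = 9)
  img <- random_rgb_image(120, 100, seed = 6)
  whole <- predict_likelihood_map(m, img)
  tiled <- predict_likelihood_map(m, img, tile = 70, halo = 23)
  expect_equal(tiled$values, whole$values, tolerance = 1e-6)
  expect_error(predict_likelihood_map(m, img, tile = 70, halo = 10), "halo")
})

test_that("fast strided inference approximates the exact map", {
  ps <- separable_patch_set(30, seed = 12)
  m <- train_cnn(build_cnn(tiny_cnn_config(), seed = 3), ps,
                 training_config(epochs = 1, batch_size = 8, seed = 1))
  img <- random_rgb_image(80, 80, seed = 5)
  exact <- predict_likelihood_map(m, img)
  fast <- predict_likelihood_map(m, img, stride = 4)
  expect_equal(dim(fast$values), dim(exact$values))
  # interpolation error stays small relative to the probability scale
  expect_lt(max(abs(fast$values - exact$values)), 0.5)
  expect_lt(mean(abs(fast$values - exact$values)), 0.05)
})

test_that("model checkpoints round-trip", {
  m <- train_cnn(build_cnn(tiny_cnn_config(), seed = 2),
                 separable_patch_set(10, seed = 1),
                 training_config(epochs = 1, batch_size = 4, seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$layers, m$layers)
  ps <- separable_patch_set(3, seed = 9)
  expect_identical(classify_patches(back, ps), classify_patches(m, ps))
})
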