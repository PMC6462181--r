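test_that("radius sets convert um to px with a 1-px floor", {
  p <- frst_params()
  expect_equal(frst_radii_px(p, image_metadata(0.228)), 1:18)  # ceil(4/0.228)
  expect_equal(frst_radii_px(p, image_metadata(1)), 1:4)
  expect_equal(frst_radii_px(frst_params(r_min_um = 2, r_max_um = 4),
                             image_metadata(1)), 2:4)
  expect_error(frst_params(r_min_um = 5, r_max_um = 4))
  expect_error(frst_params(alpha = 0))
})

test_that("an all-zero map produces an all-zero response", {
  S <- frst_transform(matrix(0, 32, 32), frst_params(),
                      meta = image_metadata(1))
  expect_true(all(S == 0))
})

test_that("the vectorised transform matches the brute-force voting oracle", {
  meta <- image_metadata(1)  # radii 1..4 px
  p <- frst_params()
  set.seed(23)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64), 64, 64)
    S <- frst_transform(m, p, meta = meta)
    S_oracle <- frst_oracle(m, 1:4)
    expect_lt(max(abs(S - S_oracle)), 1e-6)
  }
  # and on a single-blob map, with sub-pixel-accurate localisation
  g <- blob_map(64, 64, cx = 32, cy = 32, sigma = 3)
  S <- frst_transform(g, p, meta = meta)
  expect_lt(max(abs(S - frst_oracle(g, 1:4))), 1e-6)
  am <- which(S == max(S), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(am - c(33, 33))), 1)  # 1-based argmax near the centre
})

test_that("the response commutes with 90-degree rotation", {
  set.seed(7)
  m <- blob_map(48, 48, cx = 20, cy = 28, sigma = 2.5) +
    0.05 * matrix(runif(48 * 48), 48, 48)
  p <- frst_params()
  meta <- image_metadata(1)
  rot90 <- function(x) t(x)[, nrow(x):1, drop = FALSE]  # counter-clockwise
  S1 <- frst_transform(rot90(m), p, meta = meta)
  S2 <- rot90(frst_transform(m, p, meta = meta))
  expect_lt(max(abs(S1 - S2)), 1e-6)
})

test_that("detection thresholds, components and centroids behave per contract", {
  meta <- image_metadata(1)
  p <- frst_params()

  # a map entirely below the likelihood threshold yields no detections
  low <- likelihood_map(matrix(0.29, 40, 40), meta)
  expect_equal(nrow(detect_cells(low, p)), 0)

  # two well-separated blobs -> exactly two detections at their centres
  m <- blob_map(80, 80, cx = 20, cy = 20, sigma = 3) +
       blob_map(80, 80, cx = 60, cy = 55, sigma = 3)
  d <- detect_cells(likelihood_map(pmin(m, 1), meta), p)
  expect_equal(nrow(d), 2)
  expect_true(all(d$score > 0))
  expect_true(all(d$component_size >= 2))
  ord <- order(d$y)
  expect_lt(abs(d$x[ord[1]] - 20), 1); expect_lt(abs(d$y[ord[1]] - 20), 1)
  expect_lt(abs(d$x[ord[2]] - 60), 1); expect_lt(abs(d$y[ord[2]] - 55), 1)
  # deterministic (y, x) ordering
  expect_true(!is.unsorted(d$y))
})

test_that("planted well-separated blobs are each detected exactly once", {
  set.seed(15)
  meta <- image_metadata(1)
  H <- 220
  n <- 15
  # place on a jittered grid with > 2*r_max separation
  gx <- rep(seq(25, 195, length.out = 5), 3)
  gy <- rep(seq(30, 190, length.out = 3), each = 5)
  cx <- gx + runif(n, -4, 4); cy <- gy + runif(n, -4, 4)
  m <- matrix(0, H, H)
  for (i in seq_len(n)) m <- m + blob_map(H, H, cx[i], cy[i], sigma = 3)
  d <- detect_cells(likelihood_map(pmin(m, 1), meta), frst_params())
  expect_equal(nrow(d), n)
  mr <- match_detections(d, data.frame(x = cx, y = cy), meta, tol_um = 4)
  expect_equal(mr$n_matched, n)

  # monotone robustness: scaling down (peak still above 0.3) keeps count
  d2 <- detect_cells(likelihood_map(pmin(m, 1) * 0.5, meta), frst_params())
  expect_equal(nrow(d2), n)
})

test_that("detections are translation-equivariant", {
  meta <- image_metadata(1)
  m <- blob_map(90, 90, cx = 40, cy = 45, sigma = 3)
  d0 <- detect_cells(likelihood_map(m, meta), frst_params())
  shift <- function(mat, dy, dx) {
    out <- matrix(0, nrow(mat), ncol(mat))
    out[(1 + dy):nrow(mat), (1 + dx):ncol(mat)] <-
      mat[1:(nrow(mat) - dy), 1:(ncol(mat) - dx)]
    out
  }
  d1 <- detect_cells(likelihood_map(shift(m, 7, 11), meta), frst_params())
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(d1$x, d0$x + 11, tolerance = 1e-6)
  expect_equal(d1$y, d0$y + 7, tolerance = 1e-6)
})
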