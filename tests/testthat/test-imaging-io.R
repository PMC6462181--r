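test_that("micron/pixel conversions follow the scanner resolution", {
  meta <- image_metadata(0.228)
  expect_equal(um_to_px(4, meta), 4 / 0.228)
  expect_equal(um_to_px(0, meta), 0)
  expect_equal(um_to_px(0.228, meta), 1)
  # inverse pair
  for (v in c(0, 0.5, 1, 17.3, 4000)) {
    expect_equal(um_to_px(px_to_um(v, meta), meta), v)
  }
  expect_error(image_metadata(0), "pixel_size_um")
  expect_error(image_metadata(-1), "pixel_size_um")
})

test_that("image area matches the validation-image geometry", {
  meta <- image_metadata(0.228)
  a <- image_area_mm2(2000, 2000, meta)
  expect_equal(a, 2000 * 2000 * 0.228^2 / 1e6)
  expect_equal(round(a, 1), 0.2)
  expect_equal(image_area_mm2(1, 1, image_metadata(1000)), 1)
  # linear in pixel count
  expect_equal(image_area_mm2(1000, 2000, meta), a / 2)
  expect_equal(image_area_mm2(2000, 6000, meta), 3 * a)
})

test_that("annotation CSV round-trips and errors name the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  ann <- data.frame(image_id = c("a", "a", "b"), x = c(10, 20.5, 3),
                    y = c(5, 6, 7),
                    label = c("positive", "positive", "negative_region_sample"))
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$x, ann$x)
  expect_equal(back$label, ann$label)

  writeLines("image_id,x,y,label", f)
  expect_equal(nrow(read_annotations(f)), 0)

  writeLines(c("image_id,x,y,label", "a,1,2,positive", "a,abc,3,positive"), f)
  expect_error(read_annotations(f), "row 2")

  writeLines(c("image_id,x,y", "a,1,2"), f)
  expect_error(read_annotations(f), "label")
})

test_that("detection tables round-trip through CSV", {
  d <- detections(x = c(10.123456, 200.5, 3, 44, 7),
                  y = c(5, 6.25, 7, 8, 9),
                  score = c(0.5, 1.25, 0.125, 2, 0.75),
                  component_size = c(3L, 10L, 2L, 5L, 4L),
                  image_id = "img1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_detections(d, f)
  back <- read_detections(f)
  expect_equal(nrow(back), 5)
  expect_equal(back$x, signif(d$x, 6))
  expect_equal(back$score, signif(d$score, 6))
  expect_equal(back$component_size, d$component_size)
  expect_error(detections(x = 1, y = 1, score = 0, component_size = 1L,
                          image_id = "a"), "score")
})

test_that("observer count tables enforce completeness and uniqueness", {
  f <- withr::local_tempfile(fileext = ".csv")
  counts <- data.frame(image_id = sprintf("img%02d", 1:64),
                       A = rpois(64, 40), B = rpois(64, 40),
                       C = rpois(64, 40), D = rpois(64, 40))
  write_observer_counts(counts, f)
  back <- read_observer_counts(f)
  expect_equal(dim(back), c(64L, 5L))
  expect_equal(back$A, as.numeric(counts$A))

  writeLines(c("image_id,A,B", "a,1,2", "a,3,4"), f)
  expect_error(read_observer_counts(f), "duplicate")
  writeLines(c("image_id,A,B", "a,1,", "b,3,4"), f)
  expect_error(read_observer_counts(f), "missing")
})

test_that("PNG image write/read round-trips pixels and metadata sidecar", {
  img <- random_rgb_image(32, 40, seed = 2, image_id = "tile7")
  img$pixels <- round(img$pixels)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$metadata$pixel_size_um, 0.228)
  expect_equal(back$metadata$image_id, "tile7")
})

test_that("tiling with halo-trimmed stitching is an exact identity", {
  set.seed(31)
  cases <- list(c(100, 100, 60, 10), c(46, 46, 128, 23), c(97, 53, 50, 12),
                c(64, 200, 47, 23), c(30, 30, 7, 3))
  for (cs in cases) {
    arr <- array(runif(cs[1] * cs[2] * 3, 0, 255), c(cs[1], cs[2], 3))
    img <- rgb_image(arr, image_metadata(1, image_id = "t"))
    ts <- tile_image(img, tile = cs[3], halo = cs[4])
    expect_identical(stitch_tiles(ts), arr)
  }
  # a single tile when the tile covers the image
  ts <- tile_image(random_rgb_image(46, 46), tile = 128, halo = 23)
  expect_length(ts$tiles, 1L)
  # matrices (e.g. likelihood maps) tile too
  m <- matrix(rnorm(50 * 70), 50, 70)
  expect_identical(stitch_tiles(tile_image(m, tile = 30, halo = 5)), m)
  expect_error(tile_image(m, tile = 10, halo = 5), "halo")
})
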