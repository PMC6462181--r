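test_that("confusion statistics reproduce the per-class normalised rates", {
  # a confusion matrix with per-class error rates 1.19% / 1.30%
  cs <- confusion_stats(
    labels = c(rep(1, 10000), rep(0, 10000)),
    predictions = c(rep(1, 10000 - 119), rep(0, 119),
                    rep(1, 130), rep(0, 10000 - 130)))
  expect_equal(cs$fnr, 1.19)
  expect_equal(cs$fpr, 1.30)
  expect_equal(cs$sensitivity, 98.81)
  expect_equal(cs$specificity, 98.70)
  expect_equal(round(cs$sensitivity, 1), 98.8)
  expect_equal(round(cs$specificity, 1), 98.7)

  perfect <- confusion_stats(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$fnr, 0)
  expect_equal(perfect$fpr, 0)

  hand <- confusion_stats(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(hand$tp, 1); expect_equal(hand$fn, 1)
  expect_equal(hand$tn, 2); expect_equal(hand$fp, 0)
  expect_equal(hand$sensitivity, 50)
  expect_equal(hand$specificity, 100)
  expect_equal(hand$accuracy, 75)

  # single-class labels leave the absent class's rates undefined, not 0
  onecls <- confusion_stats(c(1, 1, 1), c(1, 0, 1))
  expect_true(is.na(onecls$specificity))
  expect_true(is.na(onecls$fpr))
  expect_false(is.na(onecls$sensitivity))
})

test_that("confusion identities hold for random matrices", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    preds <- ifelse(runif(n) < 0.3, 1 - labels, labels)
    cs <- confusion_stats(labels, preds)
    expect_equal(cs$sensitivity, 100 - cs$fnr, tolerance = 1e-9)
    expect_equal(cs$specificity, 100 - cs$fpr, tolerance = 1e-9)
    expect_equal(cs$accuracy,
                 100 * (cs$tp + cs$tn) / (cs$tp + cs$fp + cs$fn + cs$tn),
                 tolerance = 1e-9)
    expect_true(all(c(cs$sensitivity, cs$specificity, cs$accuracy,
                      cs$fnr, cs$fpr) >= 0))
    expect_true(all(c(cs$sensitivity, cs$specificity, cs$accuracy,
                      cs$fnr, cs$fpr) <= 100))
  }
})

test_that("greedy nearest-first matching is one-to-one and deterministic", {
  meta <- image_metadata(1)  # 1 um/px: tol in px == tol in um

  truth <- data.frame(x = c(10, 30, 50), y = c(10, 30, 50))
  d <- detections(x = c(10, 30, 50), y = c(10, 30, 50),
                  score = rep(1, 3), component_size = rep(3L, 3),
                  image_id = "a")
  mr <- match_detections(d, truth, meta, tol_um = 4)
  expect_equal(mr$n_matched, 3)
  expect_equal(mr$n_false_positive, 0)
  expect_equal(mr$n_missed, 0)

  mr0 <- match_detections(d[0, ], data.frame(x = 1:5, y = 1:5), meta, 4)
  expect_equal(mr0$n_matched, 0)
  expect_equal(mr0$n_missed, 5)
  expect_equal(mr0$n_false_positive, 0)

  # two detections near one truth point: the nearer wins, the other is FP
  d2 <- detections(x = c(11, 40), y = c(10, 10), score = c(1, 1),
                   component_size = c(2L, 2L), image_id = "a")
  mr2 <- match_detections(d2, data.frame(x = 10, y = 10), meta, tol_um = 18)
  expect_equal(mr2$n_matched, 1)
  expect_equal(mr2$pairing$detection, 1)
  expect_equal(mr2$n_false_positive, 1)
  expect_equal(mr2$n_missed, 0)

  # bookkeeping identities on random scatters
  set.seed(19)
  for (i in 1:25) {
    nd <- sample(0:30, 1); nt <- sample(0:30, 1)
    dd <- if (nd > 0) detections(x = runif(nd, 0, 100), y = runif(nd, 0, 100),
                                 score = rep(1, nd),
                                 component_size = rep(2L, nd), image_id = "r")
          else detections(image_id = character())
    tt <- data.frame(x = runif(nt, 0, 100), y = runif(nt, 0, 100))
    mr <- match_detections(dd, tt, meta, tol_um = 10)
    expect_equal(mr$n_matched + mr$n_missed, nt)
    expect_equal(mr$n_matched + mr$n_false_positive, nd)
    if (nrow(mr$pairing) > 0) {
      expect_false(anyDuplicated(mr$pairing$detection) > 0)
      expect_false(anyDuplicated(mr$pairing$truth) > 0)
      expect_true(all(mr$pairing$distance_px <= 10))
    }
  }
})

test_that("relative differences follow the mean-minus-count convention", {
  counts <- data.frame(image_id = "img1", A = 10, B = 12, C = 8, D = 10,
                       model = 10)
  rd <- relative_differences(counts)
  expect_equal(as.vector(rd$diffs), c(0, -0.2, 0.2, 0, 0))
  expect_equal(sum(rd$diffs), 0)
  expect_equal(rd$mean_counts[[1]], 10)

  # all raters equal on every image: all diffs zero, IQR [0, 0]
  eq <- data.frame(image_id = c("a", "b"), A = c(10, 20), B = c(10, 20),
                   model = c(10, 20))
  rde <- relative_differences(eq)
  expect_true(all(rde$diffs == 0))
  expect_equal(rde$summary$q25, rep(0, 3))
  expect_equal(rde$summary$q75, rep(0, 3))

  # sign flip
  rdf <- relative_differences(counts, flip_sign = TRUE)
  expect_equal(as.vector(rdf$diffs), c(0, 0.2, -0.2, 0, 0))

  # observers-only normalising mean
  rdo <- relative_differences(data.frame(image_id = "i", A = 10, B = 10,
                                         model = 13),
                              include = "observers")
  expect_equal(as.vector(rdo$diffs), c(0, 0, -0.3))

  # zero-mean images are excluded with a warning
  z <- data.frame(image_id = c("ok", "empty"), A = c(10, 0), B = c(10, 0))
  expect_warning(rdz <- relative_differences(z), "zero mean")
  expect_equal(nrow(rdz$diffs), 1)
  expect_equal(rdz$excluded, "empty")
})

test_that("relative differences sum to zero and are scale-invariant", {
  set.seed(77)
  for (i in 1:300) {
    n_img <- sample(1:8, 1); n_rat <- sample(2:6, 1)
    M <- matrix(rpois(n_img * n_rat, 30) + 1, n_img, n_rat)
    counts <- data.frame(image_id = sprintf("i%d", seq_len(n_img)))
    for (r in seq_len(n_rat)) counts[[sprintf("r%d", r)]] <- M[, r]
    rd <- relative_differences(counts)
    expect_lt(max(abs(rowSums(rd$diffs))), 1e-9)
    # scaling one image's counts by a common factor changes nothing
    counts2 <- counts
    counts2[1, -1] <- counts2[1, -1] * 7
    rd2 <- relative_differences(counts2)
    expect_equal(rd2$diffs, rd$diffs, tolerance = 1e-12)
  }
})
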