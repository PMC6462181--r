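## Evaluation: patch-level confusion statistics, detection-to-truth
## matching, and multi-observer relative count differences.

#' Per-class normalised confusion statistics
#'
#' Counts and percentages for a two-class problem. Rates are normalised
#' per actual class: the false negative rate is `100 * fn / (tp + fn)`
#' and the false positive rate `100 * fp / (fp + tn)`, so that
#' `sensitivity = 100 - fnr` and `specificity = 100 - fpr`. Percentages
#' are carried at full precision and rounded only for display. When a
#' class is absent from `labels`, the rates involving it are `NA`
#' (undefined), never silently 0.
#'
#' @param labels Binary vector (0/1, logical, or
#'   `"negative"`/`"positive"`) of true classes.
#' @param predictions Binary vector of predicted classes, same length.
#' @return An object of class `confusion_stats` with fields `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`, `accuracy`, `fnr`, `fpr`
#'   (percentages).
#' @examples
#' confusion_stats(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_stats <- function(labels, predictions) {
  to01 <- function(v) {
    if (is.character(v)) v <- v == "positive"
    as.integer(as.logical(v))
  }
  labels <- to01(labels)
  predictions <- to01(predictions)
  if (length(labels) != length(predictions) || length(labels) < 1L) {
    stop("labels and predictions must have equal length >= 1", call. = FALSE)
  }
  if (anyNA(labels) || anyNA(predictions)) stop("NA in inputs", call. = FALSE)
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  pos <- tp + fn
  neg <- fp + tn
  sens <- if (pos > 0) 100 * tp / pos else NA_real_
  spec <- if (neg > 0) 100 * tn / neg else NA_real_
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sens, specificity = spec,
         accuracy = 100 * (tp + tn) / (tp + fp + fn + tn),
         fnr = if (pos > 0) 100 * fn / pos else NA_real_,
         fpr = if (neg > 0) 100 * fp / neg else NA_real_),
    class = "confusion_stats"
  )
}

#' @export
print.confusion_stats <- function(x, digits = 1, ...) {
  cat("Confusion (per-class normalised):\n")
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf(paste0("%.", digits, "f%%"), v)
  cat(sprintf("  sensitivity %s, specificity %s, accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy)))
  cat(sprintf("  FNR %s, FPR %s\n",
              fmt(x$fnr), fmt(x$fpr)))
  invisible(x)
}

#' Match detections to ground-truth centres
#'
#' Greedy nearest-first one-to-one matching: all detection-truth pairs
#' within `tol_um` are sorted by (distance, truth y, truth x) and
#' accepted in order, each detection and each truth point at most once.
#' The default tolerance of 4 um equals the maximum nucleus radius.
#'
#' @param dets A [detections()] data.frame (or any data.frame with `x`,
#'   `y`).
#' @param truth Data.frame with 0-based `x`, `y` columns of true centres.
#' @param meta An [image_metadata()] used to convert `tol_um` to px.
#' @param tol_um Match tolerance in um (> 0).
#' @return A list of class `match_result`: `n_matched`,
#'   `n_false_positive`, `n_missed`, and `pairing` (data.frame of matched
#'   detection/truth indices and their distance in px).
#' @export
match_detections <- function(dets, truth, meta = image_metadata(),
                             tol_um = 4) {
  stopifnot(tol_um > 0, inherits(meta, "image_metadata"))
  nd <- nrow(dets)
  nt <- nrow(truth)
  tol_px <- um_to_px(tol_um, meta)
  if (nd == 0L || nt == 0L) {
    return(structure(list(n_matched = 0L, n_false_positive = nd,
                          n_missed = nt,
                          pairing = data.frame(detection = integer(),
                                               truth = integer(),
                                               distance_px = numeric())),
                     class = "match_result"))
  }
  dx <- outer(dets$x, truth$x, "-")
  dy <- outer(dets$y, truth$y, "-")
  dist <- sqrt(dx^2 + dy^2)
  cand <- which(dist <= tol_px, arr.ind = TRUE)
  ord <- order(dist[cand], truth$y[cand[, 2]], truth$x[cand[, 2]],
               cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  pair_d <- integer(); pair_t <- integer(); pair_dist <- numeric()
  for (i in seq_len(nrow(cand))) {
    d <- cand[i, 1]; t <- cand[i, 2]
    if (used_d[d] || used_t[t]) next
    used_d[d] <- TRUE; used_t[t] <- TRUE
    pair_d <- c(pair_d, d); pair_t <- c(pair_t, t)
    pair_dist <- c(pair_dist, dist[d, t])
  }
  structure(list(n_matched = length(pair_d),
                 n_false_positive = nd - length(pair_d),
                 n_missed = nt - length(pair_t),
                 pairing = data.frame(detection = pair_d, truth = pair_t,
                                      distance_px = pair_dist)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> matched=%d, false positives=%d, missed=%d\n",
              x$n_matched, x$n_false_positive, x$n_missed))
  invisible(x)
}

#' Relative count differences to the cross-rater mean
#'
#' For each image, the relative difference of a rater (observer or model)
#' is `(mean - count) / mean`, where the mean is over all observers and
#' the model (`include` controls the normalising set; an observers-only
#' mean matches the alternative convention for plots against the manual
#' consensus). Over-counting raters therefore get negative differences;
#' `flip_sign = TRUE` flips the convention. Images with a zero mean count
#' are excluded with a warning. Per-rater summaries report the mean,
#' mean absolute value, median and quartiles (linear-interpolation,
#' type-7 percentiles) of the per-image differences.
#'
#' @param counts Data.frame with `image_id` plus one numeric column per
#'   rater (see [read_observer_counts()]).
#' @param include `"all"` (observers and model define the mean) or
#'   `"observers"` (columns other than `model_col`).
#' @param model_col Name of the model's column, if present.
#' @param flip_sign Report `(count - mean)/mean` instead.
#' @return A list of class `relative_differences`: `diffs` (image x
#'   rater matrix), `mean_counts` (per image), `summary` (per-rater
#'   data.frame with `mean`, `mean_abs`, `median`, `q25`, `q75`),
#'   `excluded` (image ids with zero mean).
#' @examples
#' counts <- data.frame(image_id = "img1", A = 10, B = 12, C = 8,
#'                      D = 10, model = 10)
#' relative_differences(counts)$diffs
#' @export
relative_differences <- function(counts, include = c("all", "observers"),
                                 model_col = "model", flip_sign = FALSE) {
  include <- match.arg(include)
  stopifnot("image_id" %in% names(counts), nrow(counts) >= 1L)
  raters <- setdiff(names(counts), "image_id")
  if (length(raters) < 1L) stop("no rater columns", call. = FALSE)
  mean_cols <- if (include == "observers") setdiff(raters, model_col) else raters
  if (length(mean_cols) < 1L) stop("no columns left to define the mean", call. = FALSE)
  M <- as.matrix(counts[raters])
  if (any(M < 0)) stop("counts must be >= 0", call. = FALSE)
  mu <- rowMeans(as.matrix(counts[mean_cols]))
  zero <- mu == 0
  if (any(zero)) {
    warning(sprintf("excluded %d image(s) with zero mean count: %s",
                    sum(zero), paste(counts$image_id[zero], collapse = ", ")),
            call. = FALSE)
  }
  keep <- !zero
  if (!any(keep)) stop("all images have zero mean count", call. = FALSE)
  D <- (mu[keep] - M[keep, , drop = FALSE]) / mu[keep]
  if (flip_sign) D <- -D
  rownames(D) <- counts$image_id[keep]
  summ <- data.frame(
    rater = raters,
    mean = apply(D, 2, mean),
    mean_abs = apply(D, 2, function(v) mean(abs(v))),
    median = apply(D, 2, stats::median),
    q25 = apply(D, 2, stats::quantile, probs = 0.25, type = 7),
    q75 = apply(D, 2, stats::quantile, probs = 0.75, type = 7),
    row.names = NULL
  )
  structure(list(diffs = D, mean_counts = mu[keep], summary = summ,
                 excluded = counts$image_id[zero], include = include,
                 flip_sign = flip_sign),
            class = "relative_differences")
}

#' @export
print.relative_differences <- function(x, ...) {
  cat(sprintf("<relative_differences> %d images x %d raters (mean over %s)\n",
              nrow(x$diffs), ncol(x$diffs), x$include))
  print(x$summary, digits = 3)
  invisible(x)
}
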