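## Image, annotation and count-table I/O, physical-unit conversions, tiling.
##
## Conventions used throughout the package:
##  * pixel coordinates are 0-based, x = column, y = row, pixel-centre;
##  * pixel intensities are stored on the 8-bit scale [0, 255] as numerics;
##  * physical distances are micrometres (um), areas square millimetres.

#' Image metadata
#'
#' Holds the physical pixel size and identifying information for a scanned
#' tissue image. The default pixel size of 0.228 um/px corresponds to a
#' whole-slide scanner operating at 40x magnification.
#'
#' @param pixel_size_um Physical size of one pixel edge in micrometres.
#'   Must be a single positive number.
#' @param marker Stain label, e.g. `"CD3"`. Free text.
#' @param image_id Identifier of the image the metadata belongs to.
#' @return An object of class `image_metadata`.
#' @examples
#' meta <- image_metadata(0.228, marker = "CD3", image_id = "tile_01")
#' um_to_px(4, meta)
#' @export
image_metadata <- function(pixel_size_um = 0.228, marker = "", image_id = "") {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("invalid metadata: 'pixel_size_um' must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(pixel_size_um = as.numeric(pixel_size_um),
         marker = as.character(marker)[1L],
         image_id = as.character(image_id)[1L]),
    class = "image_metadata"
  )
}

#' @export
print.image_metadata <- function(x, ...) {
  cat(sprintf("<image_metadata> id='%s' marker='%s' pixel_size=%.4g um/px\n",
              x$image_id, x$marker, x$pixel_size_um))
  invisible(x)
}

#' RGB image container
#'
#' An RGB image is an `H x W x 3` numeric array of 8-bit intensities
#' (0--255, channel order R,G,B) together with its [image_metadata()].
#'
#' @param pixels `H x W x 3` numeric array with values in \[0, 255\].
#' @param metadata An [image_metadata()] object.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, metadata = image_metadata()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have H >= 1 and W >= 1", call. = FALSE)
  }
  if (!inherits(metadata, "image_metadata")) {
    stop("'metadata' must be an image_metadata object", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, metadata = metadata), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, id='%s', %.4g um/px\n",
              d[1], d[2], x$metadata$image_id, x$metadata$pixel_size_um))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Convert micrometres to pixels (and back)
#'
#' `um_to_px()` divides a physical distance by the pixel size; `px_to_um()`
#' is its inverse. No rounding is applied -- callers round according to
#' their own policy (e.g. the radial-symmetry detector takes the ceiling
#' of the maximum nucleus radius).
#'
#' @param distance_um,distance_px Non-negative distance in um / px.
#' @param meta An [image_metadata()] object (carries `pixel_size_um`).
#' @return Distance in pixels (respectively micrometres), a non-negative
#'   numeric.
#' @examples
#' um_to_px(4, image_metadata(0.228))   # ~17.54 px
#' @export
um_to_px <- function(distance_um, meta) {
  stopifnot(inherits(meta, "image_metadata"))
  if (any(distance_um < 0)) stop("distance must be >= 0", call. = FALSE)
  distance_um / meta$pixel_size_um
}

#' @rdname um_to_px
#' @export
px_to_um <- function(distance_px, meta) {
  stopifnot(inherits(meta, "image_metadata"))
  if (any(distance_px < 0)) stop("distance must be >= 0", call. = FALSE)
  distance_px * meta$pixel_size_um
}

#' Physical area of an image in square millimetres
#'
#' At 0.228 um/px a 2,000 x 2,000 px tile covers 0.208 mm^2 (commonly
#' reported rounded to 0.2 mm^2).
#'
#' @param width_px,height_px Image dimensions in pixels (>= 1).
#' @param meta An [image_metadata()] object.
#' @return Area in mm^2.
#' @examples
#' image_area_mm2(2000, 2000, image_metadata(0.228))
#' @export
image_area_mm2 <- function(width_px, height_px, meta) {
  stopifnot(inherits(meta, "image_metadata"))
  if (width_px < 1 || height_px < 1) stop("image dimensions must be >= 1", call. = FALSE)
  as.numeric(width_px) * as.numeric(height_px) * meta$pixel_size_um^2 / 1e6
}

## ---- point annotations -----------------------------------------------------

.annotation_labels <- c("positive", "negative_region_sample")

#' Read and write point annotations
#'
#' Annotations are cell-centre points stored as plain CSV with header
#' columns `image_id,x,y,label`; coordinates are 0-based pixel indices and
#' labels one of `"positive"` or `"negative_region_sample"`.
#'
#' @param path Path to a CSV file.
#' @return `read_annotations()` returns a data.frame with columns
#'   `image_id`, `x`, `y`, `label` (zero rows for a header-only file).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("image_id", "x", "y", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("annotation file '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) > 0L || anyNA(v)) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(v))[1L]
      stop(sprintf("non-numeric coordinate '%s' in column '%s' at data row %d of '%s'",
                   df[[col]][row], col, row, path), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_lab <- setdiff(unique(df$label), .annotation_labels)
  if (length(bad_lab) > 0L) {
    stop(sprintf("unknown annotation label(s): %s",
                 paste(bad_lab, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

#' @rdname read_annotations
#' @param annotations Data.frame with columns `image_id`, `x`, `y`, `label`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("image_id", "x", "y", "label") %in% names(annotations)))
  utils::write.csv(annotations[c("image_id", "x", "y", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- detections ------------------------------------------------------------

#' Construct a detection table
#'
#' Detections are cell-centre candidates with their radial-symmetry
#' response (`score`) and the size of the supporting connected component.
#'
#' @param x,y 0-based centre coordinates (pixel-centre convention).
#' @param score Positive response value at the detection.
#' @param component_size Number of pixels in the supporting component (>= 1).
#' @param image_id Image identifier (recycled).
#' @return A data.frame of class `detections`.
#' @export
detections <- function(x = numeric(), y = numeric(), score = numeric(),
                       component_size = integer(), image_id = character()) {
  n <- length(x)
  stopifnot(length(y) == n, length(score) == n, length(component_size) == n)
  if (n > 0L && length(image_id) == 1L) image_id <- rep(image_id, n)
  if (n == 0L) image_id <- character()
  if (any(score <= 0)) stop("detection scores must be > 0", call. = FALSE)
  if (any(component_size < 1)) stop("component_size must be >= 1", call. = FALSE)
  structure(
    data.frame(image_id = image_id, x = as.numeric(x), y = as.numeric(y),
               score = as.numeric(score),
               component_size = as.integer(component_size),
               stringsAsFactors = FALSE),
    class = c("detections", "data.frame")
  )
}

#' Read and write detection tables
#'
#' CSV with columns `image_id,x,y,score,component_size`; numeric values are
#' written with 6 significant digits so that a write/read round trip is
#' value-stable.
#'
#' @param dets A `detections` data.frame (see [detections()]).
#' @param path CSV path.
#' @export
write_detections <- function(dets, path) {
  stopifnot(all(c("image_id", "x", "y", "score", "component_size") %in% names(dets)))
  out <- data.frame(
    image_id = dets$image_id,
    x = signif(dets$x, 6), y = signif(dets$y, 6),
    score = signif(dets$score, 6),
    component_size = as.integer(dets$component_size)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "x", "y", "score", "component_size")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("detection file '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$image_id <- as.character(df$image_id)
  structure(df[required], class = c("detections", "data.frame"))
}

## ---- observer count tables -------------------------------------------------

#' Read and write observer count tables
#'
#' A count table records, per validation image, how many positive cells
#' each rater (human observer or the model) counted: CSV with an
#' `image_id` column plus one numeric column per rater.
#'
#' @param path CSV path.
#' @return A data.frame with `image_id` plus one integer-valued column per
#'   rater. Duplicate `image_id` rows or missing cells are format errors.
#' @export
read_observer_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"image_id" %in% names(df)) {
    stop(sprintf("count table '%s' has no 'image_id' column", path), call. = FALSE)
  }
  df$image_id <- as.character(df$image_id)
  if (anyDuplicated(df$image_id)) {
    stop(sprintf("count table '%s' has duplicate image_id rows: %s", path,
                 paste(unique(df$image_id[duplicated(df$image_id)]), collapse = ", ")),
         call. = FALSE)
  }
  raters <- setdiff(names(df), "image_id")
  if (length(raters) == 0L) stop("count table has no rater columns", call. = FALSE)
  for (r in raters) {
    v <- suppressWarnings(as.numeric(df[[r]]))
    if (anyNA(v)) {
      stop(sprintf("missing or non-numeric count for rater '%s' (image_id %s)",
                   r, df$image_id[which(is.na(v))[1L]]), call. = FALSE)
    }
    if (any(v < 0)) stop(sprintf("negative count for rater '%s'", r), call. = FALSE)
    df[[r]] <- v
  }
  df
}

#' @rdname read_observer_counts
#' @param counts Data.frame with `image_id` plus one column per rater.
#' @export
write_observer_counts <- function(counts, path) {
  stopifnot("image_id" %in% names(counts))
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- image files -----------------------------------------------------------

#' Read and write RGB images (PNG or TIFF)
#'
#' Format is chosen by file extension. An optional YAML sidecar
#' `<path>.meta.yaml` (keys `pixel_size_um`, `marker`, `image_id`) carries
#' the physical metadata; if absent, `meta` is used.
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @param meta Fallback [image_metadata()] when no sidecar file exists.
#' @return An [rgb_image()].
#' @export
read_image <- function(path, meta = image_metadata()) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  sidecar <- paste0(path, ".meta.yaml")
  if (file.exists(sidecar)) {
    y <- yaml::read_yaml(sidecar)
    meta <- image_metadata(
      pixel_size_um = y$pixel_size_um %||% meta$pixel_size_um,
      marker = y$marker %||% meta$marker,
      image_id = y$image_id %||% meta$image_id
    )
  }
  rgb_image(round(arr * 255), meta)
}

#' @rdname read_image
#' @param image An [rgb_image()].
#' @param sidecar Write the YAML metadata sidecar alongside the image?
#' @export
write_image <- function(image, path, sidecar = TRUE) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- pmin(pmax(image$pixels, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  if (isTRUE(sidecar)) {
    yaml::write_yaml(
      list(pixel_size_um = image$metadata$pixel_size_um,
           marker = image$metadata$marker,
           image_id = image$metadata$image_id),
      paste0(path, ".meta.yaml")
    )
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tiling / stitching ----------------------------------------------------

#' Split an image into overlapping tiles and stitch them back
#'
#' Tiles are `tile x tile` windows with a `halo`-pixel overlap on each
#' inner edge, so that dense per-pixel inference (which loses a border
#' band of half the patch size) can run tile-wise without changing any
#' value: the halo-trimmed tiles partition the image exactly, and
#' `stitch_tiles(tile_image(x))` reproduces `x` bit for bit. An image
#' smaller than the tile size yields a single tile.
#'
#' @param image An [rgb_image()] or a 2-D/3-D numeric array.
#' @param tile Tile edge length in px; must satisfy `tile >= 2 * halo + 1`.
#' @param halo Overlap half-width in px (e.g. 23 for a 46-px patch model).
#' @return A list of class `tile_set`: `tiles` (list of arrays), `offsets`
#'   (0-based `(y, x)` top-left corners), `core` (0-based row/col ranges
#'   each tile is responsible for), and the original image size.
#' @export
tile_image <- function(image, tile, halo = 0L) {
  arr <- if (inherits(image, "rgb_image")) image$pixels else image
  tile <- as.integer(tile); halo <- as.integer(halo)
  if (tile < 2L * halo + 1L) stop("need tile >= 2*halo + 1", call. = FALSE)
  d <- dim(arr); H <- d[1]; W <- d[2]
  step <- tile - 2L * halo
  ## core starts: each tile owns rows [s, s + step) clipped to the image
  starts <- function(n) if (n <= tile) 0L else seq.int(0L, n - 1L, by = step)
  ys <- starts(H); xs <- starts(W)
  ys <- ys[ys < H]; xs <- xs[xs < W]
  tiles <- list(); offsets <- list(); core <- list()
  k <- 0L
  for (y0 in ys) for (x0 in xs) {
    ## tile window: core plus halo on each side, clipped
    ty0 <- max(0L, y0 - halo); tx0 <- max(0L, x0 - halo)
    ty1 <- min(H, y0 + step + halo); tx1 <- min(W, x0 + step + halo)
    cy1 <- min(H, y0 + step); cx1 <- min(W, x0 + step)
    k <- k + 1L
    idx_y <- (ty0 + 1L):ty1; idx_x <- (tx0 + 1L):tx1
    tiles[[k]] <- if (length(d) == 3L) arr[idx_y, idx_x, , drop = FALSE]
                  else arr[idx_y, idx_x, drop = FALSE]
    offsets[[k]] <- c(y = ty0, x = tx0)
    core[[k]] <- c(y0 = y0, y1 = cy1 - 1L, x0 = x0, x1 = cx1 - 1L)
  }
  structure(list(tiles = tiles, offsets = offsets, core = core,
                 size = c(H = H, W = W), halo = halo,
                 depth = if (length(d) == 3L) d[3] else 1L),
            class = "tile_set")
}

#' @rdname tile_image
#' @param tileset A `tile_set` produced by `tile_image()` (tile contents may
#'   have been replaced by equally-sized processed arrays).
#' @export
stitch_tiles <- function(tileset) {
  stopifnot(inherits(tileset, "tile_set"))
  H <- unname(tileset$size["H"]); W <- unname(tileset$size["W"])
  depth <- tileset$depth
  out <- if (depth > 1L) array(0, c(H, W, depth)) else matrix(0, H, W)
  for (k in seq_along(tileset$tiles)) {
    tl <- tileset$tiles[[k]]; off <- tileset$offsets[[k]]; co <- tileset$core[[k]]
    ry <- (co["y0"]:co["y1"])        # 0-based image rows owned by this tile
    rx <- (co["x0"]:co["x1"])
    ly <- ry - off["y"] + 1L; lx <- rx - off["x"] + 1L  # 1-based tile rows
    if (depth > 1L) out[ry + 1L, rx + 1L, ] <- tl[ly, lx, , drop = FALSE]
    else out[ry + 1L, rx + 1L] <- tl[ly, lx, drop = FALSE]
  }
  out
}
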