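## Cell-centre detection on likelihood maps: fast radial symmetry
## transform (gradient voting for bright radial blobs) followed by
## thresholding and 8-connected component analysis.

#' Parameters of the radial-symmetry detector
#'
#' Defaults follow the published operating point for nucleus detection on
#' posterior likelihood maps: radial strictness `alpha = 0.5`, gradient
#' threshold fraction `beta = 0.25`, nucleus radii 0--4 um and a
#' likelihood-map threshold of 0.3. `beta` is interpreted as a fraction
#' of the maximum gradient magnitude of the map (so 0.25 is meaningful on
#' probability maps whose gradients are much smaller than 1);
#' `beta_absolute = TRUE` switches to an absolute threshold. The
#' normalisation constants `kappa` (8 for a 1-px radius, 9.9 for larger)
#' and the per-radius smoothing `sigma = gaussian_sigma_factor * radius`
#' follow the transform's published constants. The response threshold --
#' a fraction of the maximum response -- is not fixed by the operating
#' point above and defaults to 0.1.
#'
#' @param alpha Radial strictness exponent (> 0).
#' @param beta Gradient threshold, as a fraction of the maximum gradient
#'   magnitude (or absolute when `beta_absolute`).
#' @param beta_absolute Interpret `beta` as an absolute threshold?
#' @param r_min_um,r_max_um Nucleus radius range in um; every integer
#'   pixel radius from `max(1, ceiling(r_min_um/px))` to
#'   `ceiling(r_max_um/px)` is used (a 0-um minimum maps to 1 px, since a
#'   0-px radius votes onto the pixel itself and is degenerate).
#' @param likelihood_threshold Likelihood-map values below this are
#'   zeroed before the transform.
#' @param frst_response_threshold Detection threshold as a fraction of
#'   the maximum response.
#' @param gaussian_sigma_factor Per-radius smoothing sigma as a fraction
#'   of the radius.
#' @param kappa_small,kappa_large Vote normalisation for radius 1 px and
#'   for larger radii.
#' @param min_component_px Connected components smaller than this many
#'   pixels are discarded.
#' @return An object of class `frst_params`.
#' @export
frst_params <- function(alpha = 0.5, beta = 0.25, beta_absolute = FALSE,
                        r_min_um = 0, r_max_um = 4,
                        likelihood_threshold = 0.3,
                        frst_response_threshold = 0.1,
                        gaussian_sigma_factor = 0.25,
                        kappa_small = 8, kappa_large = 9.9,
                        min_component_px = 2L) {
  stopifnot(alpha > 0, beta >= 0, !beta_absolute || beta > 0,
            r_min_um >= 0, r_min_um <= r_max_um,
            likelihood_threshold >= 0, likelihood_threshold <= 1,
            frst_response_threshold >= 0, frst_response_threshold <= 1,
            gaussian_sigma_factor >= 0, kappa_small > 0, kappa_large > 0,
            min_component_px >= 1L)
  if (!beta_absolute && beta >= 1) {
    stop("relative gradient threshold 'beta' must be < 1", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, beta_absolute = beta_absolute,
                 r_min_um = r_min_um, r_max_um = r_max_um,
                 likelihood_threshold = likelihood_threshold,
                 frst_response_threshold = frst_response_threshold,
                 gaussian_sigma_factor = gaussian_sigma_factor,
                 kappa_small = kappa_small, kappa_large = kappa_large,
                 min_component_px = as.integer(min_component_px)),
            class = "frst_params")
}

#' Pixel radius set used by the transform
#' @param params An [frst_params()].
#' @param meta An [image_metadata()] (provides um/px).
#' @return Integer vector of radii in px (errors when empty).
#' @export
frst_radii_px <- function(params, meta) {
  stopifnot(inherits(params, "frst_params"), inherits(meta, "image_metadata"))
  lo <- max(1L, as.integer(ceiling(um_to_px(params$r_min_um, meta))))
  hi <- as.integer(ceiling(um_to_px(params$r_max_um, meta)))
  if (hi < lo) stop("empty radius set for this pixel size", call. = FALSE)
  lo:hi
}

#' Fast radial symmetry transform of a likelihood map
#'
#' For each radius `n`, the map gradient (central differences, zero at
#' the border) is computed; every pixel whose gradient magnitude exceeds
#' the gradient threshold casts one vote at the positively affected pixel
#' `p + round(n * ghat)` -- bright symmetry only, since cells are bright
#' peaks on the likelihood map -- incrementing an orientation image and
#' adding the gradient magnitude to a magnitude image. The radial
#' response `F_n = (min(O_n, kappa)/kappa)^alpha * (M_n/kappa)` is
#' smoothed with an isotropic Gaussian of `sigma = factor * n`; the final
#' response is the mean over radii. An all-zero map yields an all-zero
#' response.
#'
#' @param map A [likelihood_map()] (or a plain numeric matrix together
#'   with `meta`).
#' @param params An [frst_params()].
#' @param meta Metadata when `map` is a plain matrix.
#' @return `H x W` numeric matrix of non-negative responses.
#' @export
frst_transform <- function(map, params = frst_params(), meta = NULL) {
  if (inherits(map, "likelihood_map")) {
    meta <- map$metadata
    values <- map$values
  } else {
    stopifnot(is.matrix(map), inherits(meta, "image_metadata"))
    values <- map
  }
  radii <- frst_radii_px(params, meta)
  cpp_frst(values, radii, params$alpha, params$beta, params$beta_absolute,
           params$kappa_small, params$kappa_large,
           params$gaussian_sigma_factor)
}

#' Detect cell centres on a likelihood map
#'
#' Pipeline: (1) zero the likelihood map below `likelihood_threshold`;
#' (2) radial symmetry transform; (3) threshold the response at
#' `frst_response_threshold * max(response)`; (4) 8-connected component
#' labelling; (5) one detection per component at its response-weighted
#' centroid, with the component's maximum response as score. Components
#' smaller than `min_component_px` pixels are discarded; detections are
#' ordered by `(y, x)`.
#'
#' @param map A [likelihood_map()].
#' @param params An [frst_params()].
#' @return A [detections()] data.frame (0-based `x`, `y` coordinates).
#' @export
detect_cells <- function(map, params = frst_params()) {
  stopifnot(inherits(map, "likelihood_map"), inherits(params, "frst_params"))
  values <- map$values
  values[values < params$likelihood_threshold] <- 0
  if (all(values == 0)) {
    return(detections(image_id = character()))
  }
  S <- frst_transform(values, params, meta = map$metadata)
  smax <- max(S)
  if (smax <= 0) return(detections(image_id = character()))
  mask <- S >= params$frst_response_threshold * smax
  lab <- cpp_label8(mask)
  ncomp <- max(lab)
  if (ncomp == 0L) return(detections(image_id = character()))
  H <- nrow(S)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  w <- S[idx]
  y0 <- (idx - 1L) %% H            # 0-based
  x0 <- (idx - 1L) %/% H
  size <- tabulate(comp, nbins = ncomp)
  wsum <- as.vector(rowsum(w, comp))
  cx <- as.vector(rowsum(w * x0, comp)) / wsum
  cy <- as.vector(rowsum(w * y0, comp)) / wsum
  smax_c <- vapply(split(w, factor(comp, levels = seq_len(ncomp))),
                   max, numeric(1))
  keep <- size >= params$min_component_px
  d <- detections(x = cx[keep], y = cy[keep], score = smax_c[keep],
                  component_size = size[keep],
                  image_id = map$metadata$image_id)
  d <- d[order(d$y, d$x), , drop = FALSE]
  rownames(d) <- NULL
  d
}
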