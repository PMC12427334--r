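#' Morphometric features from binary dorsal masks
#'
#' The five-feature vector bridging segmentation masks and live-weight
#' estimation: relative projection area (RA), contour perimeter (CP), body
#' length and body width (BL, BW, from the minimum-area rotated rectangle)
#' and least-squares ellipse eccentricity (E). Masks are 0/1 matrices
#' indexed `[x, y]`; an optional `scale` (physical length per pixel)
#' converts CP/BL/BW to physical units while RA and E stay dimensionless.
#'
#' @name morphometrics
NULL

as_binary_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  abort_if(sum(m) == 0, "mask has no foreground pixels")
  m
}

#' Preprocess a segmentation mask
#'
#' Morphological closing with a disc-shaped structuring element, hole
#' filling (background regions not connected to the border), then retention
#' of the largest 8-connected foreground component only. This is the
#' standard clean-up applied to raw segmenter output before any feature is
#' measured; it is idempotent on already-clean masks.
#'
#' @param mask 0/1 matrix indexed `[x, y]`.
#' @param closing_radius Disc radius in pixels (default 3).
#' @return 0/1 integer matrix of the same size.
#' @export
preprocess_mask <- function(mask, closing_radius = 3) {
  m <- as_binary_mask(mask)
  img <- EBImage::Image(m)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    img <- EBImage::closing(img, brush)
  }
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  abort_if(length(tab) == 0 || max(tab) == 0,
           "mask has empty foreground after preprocessing")
  keep <- which.max(tab)
  out <- (EBImage::imageData(lab) == keep) * 1L
  matrix(out, nrow = nrow(m))
}

# Ordered outer contour (pixel-centre coordinates, 1-based [x, y]) of the
# single foreground component of a preprocessed mask.
outer_contour <- function(mask) {
  m <- as_binary_mask(mask)
  lab <- EBImage::bwlabel(EBImage::Image(m))
  n_comp <- max(EBImage::imageData(lab))
  abort_if(n_comp != 1,
           "expected a single connected component, found ", n_comp,
           " (run preprocess_mask first)")
  oc <- EBImage::ocontour(lab)[[1]]
  oc + 1  # ocontour returns 0-based indices
}

#' Relative projection area
#'
#' Fraction of the frame covered by foreground: the ratio of the
#' foreground pixel count to the total pixel count of the mask image.
#'
#' @param mask Preprocessed 0/1 matrix.
#' @return Fraction in (0, 1].
#' @export
relative_area <- function(mask) {
  m <- as_binary_mask(mask)
  sum(m) / length(m)
}

#' Contour perimeter
#'
#' Arc length of the closed outer contour polygon: Euclidean distances
#' between consecutive contour vertices, last joined to first, multiplied
#' by `scale`. Contour vertices sit at pixel centres on the 8-connected
#' boundary of the (single) foreground component; a circular moving
#' average over `smooth_window` vertices is applied first to remove the
#' systematic overestimate (about +5% on smooth convex shapes) that raw
#' pixel chains carry.
#'
#' @param mask Preprocessed 0/1 matrix with exactly one component.
#' @param scale Physical length per pixel (default 1 = pixels).
#' @param smooth_window Odd window of the contour smoother; 1 disables
#'   smoothing and returns the raw chain length.
#' @return Perimeter in `scale` units.
#' @export
contour_perimeter <- function(mask, scale = 1, smooth_window = 5) {
  pts <- outer_contour(mask)
  closed_polygon_length(smooth_closed_contour(pts, smooth_window)) * scale
}

#' Body length and width from the minimum-area rotated rectangle
#'
#' Computes the minimum-area rectangle enclosing the outer contour
#' (rotating calipers over the convex hull). Body length BL is the longer
#' side, body width BW the shorter, each a corner-to-corner Euclidean
#' distance times `scale`.
#'
#' @inheritParams contour_perimeter
#' @return Named numeric `c(BL = , BW = )`.
#' @export
min_rect_dims <- function(mask, scale = 1) {
  pts <- outer_contour(mask)
  rect <- min_area_rect(pts)
  # contour vertices sit at pixel centres; each boundary pixel's footprint
  # extends half a pixel beyond, so a w-pixel-wide rectangle spans
  # (w - 1) + 1 between opposite faces
  sides <- sort(c(rect$width, rect$height) + 1, decreasing = TRUE) * scale
  c(BL = sides[1], BW = sides[2])
}

#' Ellipse eccentricity of the outer contour
#'
#' Fits an ellipse to the outer contour by direct least squares and
#' returns, with semi-axes `a >= b`, the standard eccentricity
#' `sqrt(1 - (b/a)^2)` (`variant = "standard"`). The alternative
#' `variant = "squared"` returns `1 - (b/a)^2`, the non-radical form some
#' pipelines use.
#'
#' @inheritParams contour_perimeter
#' @param variant `"standard"` (default) or `"squared"`.
#' @return Eccentricity in `[0, 1)`.
#' @export
ellipse_eccentricity <- function(mask, variant = c("standard", "squared")) {
  variant <- match.arg(variant)
  pts <- outer_contour(mask)
  abort_if(nrow(pts) < 5, "need at least 5 contour points for a conic fit")
  fit <- fit_ellipse_lsq(pts)
  ratio2 <- (fit$b / fit$a)^2
  if (variant == "standard") sqrt(1 - ratio2) else 1 - ratio2
}

#' Extract the five-feature morphometric vector
#'
#' Runs [preprocess_mask()] then computes RA, CP, BL, BW and E, in that
#' fixed order (the weight model consumes positional vectors).
#'
#' @inheritParams preprocess_mask
#' @param scale Physical length per pixel applied to CP, BL, BW.
#' @param ecc_variant Passed to [ellipse_eccentricity()].
#' @param smooth_window Passed to [contour_perimeter()].
#' @return Named numeric vector `c(RA, CP, BL, BW, E)`.
#' @export
extract_features <- function(mask, closing_radius = 3, scale = 1,
                             ecc_variant = "standard", smooth_window = 5) {
  m <- preprocess_mask(mask, closing_radius = closing_radius)
  dims <- min_rect_dims(m, scale = scale)
  c(RA = relative_area(m),
    CP = contour_perimeter(m, scale = scale, smooth_window = smooth_window),
    BL = unname(dims["BL"]), BW = unname(dims["BW"]),
    E = ellipse_eccentricity(m, variant = ecc_variant))
}

#' Batch feature extraction over a directory of PNG masks
#'
#' Reads every `.png` in `dir` (any nonzero pixel = foreground) and writes
#' the interchange feature table consumed by the weight module.
#'
#' @param dir Directory of 8-bit PNG masks.
#' @param out_csv Optional path; when given the table is also written as
#'   CSV with columns `mask_id, RA, CP, BL, BW, E`.
#' @inheritParams extract_features
#' @return A data.frame with one row per mask.
#' @export
extract_features_dir <- function(dir, out_csv = NULL, closing_radius = 3,
                                 scale = 1, ecc_variant = "standard") {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  abort_if(length(files) == 0, "no .png masks found in ", dir)
  rows <- lapply(files, function(f) {
    fv <- extract_features(read_mask_png(f), closing_radius = closing_radius,
                           scale = scale, ecc_variant = ecc_variant)
    data.frame(mask_id = sub("\\.png$", "", basename(f)), t(fv))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
  }
  out
}
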