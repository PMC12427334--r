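#' Specify a synthetic dorsal silhouette
#'
#' A superellipse (Lamé curve) stands in for the dorsal outline of a pig:
#' `|u/a|^n + |v/b|^n <= 1` in the shape frame, optionally rotated and
#' perturbed by smooth periodic boundary noise. With `shape_exponent = 2`
#' this is an exact ellipse, for which closed-form area, axes and
#' eccentricity are available as ground truth; exponents above 2 give the
#' flatter-backed outline typical of a standing pig seen from above.
#'
#' @param semi_major_px,semi_minor_px Semi-axes in pixels; the major axis
#'   must be at least as long as the minor axis.
#' @param orientation_deg Rotation of the major axis from the x-axis,
#'   degrees.
#' @param center Length-2 numeric, pixel coordinates of the shape centre.
#'   Defaults to the canvas centre.
#' @param shape_exponent Lamé exponent; 2 = ellipse, larger = boxier.
#' @param boundary_noise_sd Standard deviation (pixels) of the smooth
#'   periodic radial perturbation applied to the boundary; 0 disables it.
#' @param canvas_w,canvas_h Canvas size in pixels.
#' @param seed Integer seed controlling the boundary noise.
#' @return An object of class `silhouette_spec`.
#' @export
silhouette_spec <- function(semi_major_px, semi_minor_px,
                            orientation_deg = 0,
                            center = c(canvas_w / 2, canvas_h / 2),
                            shape_exponent = 2,
                            boundary_noise_sd = 0,
                            canvas_w = 640, canvas_h = 640,
                            seed = 1L) {
  abort_if(!is.numeric(semi_major_px) || !is.numeric(semi_minor_px) ||
             semi_minor_px <= 0 || semi_major_px < semi_minor_px,
           "need semi_major_px >= semi_minor_px > 0")
  abort_if(shape_exponent < 1, "shape_exponent must be >= 1")
  abort_if(boundary_noise_sd < 0, "boundary_noise_sd must be >= 0")
  spec <- structure(
    list(semi_major_px = semi_major_px, semi_minor_px = semi_minor_px,
         orientation_deg = orientation_deg, center = as.numeric(center),
         shape_exponent = shape_exponent,
         boundary_noise_sd = boundary_noise_sd,
         canvas_w = as.integer(canvas_w), canvas_h = as.integer(canvas_h),
         seed = as.integer(seed)),
    class = "silhouette_spec")
  ext <- semi_major_px + 3 * boundary_noise_sd + 1
  if (spec$center[1] - ext < 1 || spec$center[1] + ext > canvas_w ||
      spec$center[2] - ext < 1 || spec$center[2] + ext > canvas_h) {
    stop("silhouette (extent ", round(ext, 1),
         " px around center) does not fit inside the ",
         canvas_w, "x", canvas_h, " canvas", call. = FALSE)
  }
  spec
}

# Polar radius of the Lamé curve at shape-frame angle phi.
superellipse_radius <- function(phi, a, b, n) {
  (abs(cos(phi) / a)^n + abs(sin(phi) / b)^n)^(-1 / n)
}

# Area of the Lamé curve |x/a|^n + |y/b|^n <= 1 (gamma-function closed form;
# reduces to pi*a*b at n = 2).
superellipse_area <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

# Boundary arc length by quadrature on the polar form (used as generator
# ground truth; for n = 2 it agrees with the Ramanujan approximation).
superellipse_perimeter <- function(a, b, n, m = 4096L) {
  phi <- seq(0, 2 * pi, length.out = m + 1L)
  r <- superellipse_radius(phi, a, b, n)
  pts <- cbind(r * cos(phi), r * sin(phi))[-(m + 1L), , drop = FALSE]
  closed_polygon_length(pts)
}

#' Ramanujan approximation to an ellipse perimeter
#'
#' @param a,b Semi-axes.
#' @return Approximate perimeter, same units as the axes.
#' @export
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Rasterize a synthetic silhouette into a binary mask
#'
#' Pixel centres at integer coordinates are tested against the (noise-
#' perturbed) analytic boundary. The analytic area, axes, eccentricity and
#' perimeter of the noise-free shape are returned alongside the raster as
#' ground truth for downstream oracle tests. Rendering is deterministic in
#' the spec's seed.
#'
#' @param spec A [silhouette_spec()].
#' @return A list of class `silhouette_render` with elements `mask`
#'   (integer 0/1 matrix, `canvas_w` columns x `canvas_h` rows indexed
#'   `[x, y]`), `spec`, and `truth` (list: `area_px`, `a`, `b`,
#'   `eccentricity`, `perimeter_px`, `orientation_deg`, `center`).
#' @export
render_mask <- function(spec) {
  stopifnot(inherits(spec, "silhouette_spec"))
  a <- spec$semi_major_px; b <- spec$semi_minor_px; n <- spec$shape_exponent
  th <- spec$orientation_deg * pi / 180
  # smooth periodic radial noise: harmonics k = 2..9 (k = 1 would shift the
  # centroid), total variance boundary_noise_sd^2
  noise_fun <- if (spec$boundary_noise_sd > 0) {
    K <- 8L
    co <- with_seed(spec$seed,
                    matrix(stats::rnorm(2 * K, sd = spec$boundary_noise_sd /
                                          sqrt(K)), ncol = 2))
    ks <- seq(2L, length.out = K)
    function(phi) {
      out <- numeric(length(phi))
      for (i in seq_len(K)) {
        out <- out + co[i, 1] * cos(ks[i] * phi) + co[i, 2] * sin(ks[i] * phi)
      }
      out
    }
  } else {
    function(phi) 0
  }
  xs <- matrix(seq_len(spec$canvas_w), nrow = spec$canvas_w,
               ncol = spec$canvas_h)
  ys <- matrix(seq_len(spec$canvas_h), nrow = spec$canvas_w,
               ncol = spec$canvas_h, byrow = TRUE)
  dx <- xs - spec$center[1]; dy <- ys - spec$center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  rr <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  rb <- superellipse_radius(phi, a, b, n) + noise_fun(phi)
  mask <- matrix(as.integer(rr <= rb), nrow = spec$canvas_w)
  truth <- list(
    area_px = superellipse_area(a, b, n),
    a = a, b = b,
    eccentricity = sqrt(1 - (b / a)^2),
    perimeter_px = if (n == 2) ramanujan_perimeter(a, b) else
      superellipse_perimeter(a, b, n),
    orientation_deg = spec$orientation_deg,
    center = spec$center)
  structure(list(mask = mask, spec = spec, truth = truth),
            class = "silhouette_render")
}

#' Write / read a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0; on reading, any nonzero
#' pixel is treated as foreground.
#'
#' @param mask Integer/numeric 0/1 matrix indexed `[x, y]`.
#' @param path File path ending in `.png`.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns a 0/1 integer matrix indexed `[x, y]`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  img <- t(mask != 0) * 1  # png wants [row = y, col = x]
  png::writePNG(img, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- t(img > 0)
  storage.mode(mask) <- "integer"
  mask
}
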