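test_that("preprocessing fills interior holes", {
  m <- rect_mask(40, 20)
  m[20:22, 15:17] <- 0L  # 3x3 interior hole
  before <- sum(m)
  out <- preprocess_mask(m, closing_radius = 0)
  expect_equal(sum(out), before + 9)
})

test_that("preprocessing is idempotent on clean masks", {
  m <- preprocess_mask(ellipse_mask(80, 50, canvas = 256))
  expect_identical(preprocess_mask(m), m)
})

test_that("only the largest component survives preprocessing", {
  m <- matrix(0L, 100, 100)
  m[10:34, 10:29] <- 1L   # 500 px blob
  m[60:69, 60:64] <- 1L   # 50 px blob
  out <- preprocess_mask(m, closing_radius = 0)
  expect_equal(sum(out), 500)
  expect_equal(sum(out[60:69, 60:64]), 0)
})

test_that("empty masks are rejected with a clear message", {
  expect_error(preprocess_mask(matrix(0L, 10, 10)), "foreground")
})

test_that("relative area matches closed forms", {
  expect_equal(relative_area(matrix(1L, 8, 8)), 1.0)
  m <- ellipse_mask(200, 100)
  expect_equal(relative_area(m), pi * 200 * 100 / 640^2, tolerance = 0.01)
})

test_that("contour perimeter matches rectangle and circle oracles", {
  # brute-force oracle: axis-aligned rectangle contour through pixel
  # centres has arc length 2 * ((w-1) + (h-1))
  m <- rect_mask(100, 50, canvas = c(120, 70))
  expect_equal(contour_perimeter(m), 2 * (99 + 49), tolerance = 0.02)
  circ <- ellipse_mask(100, 100, canvas = 256)
  expect_equal(contour_perimeter(circ), 2 * pi * 100, tolerance = 0.03)
})

test_that("perimeter is exactly linear in scale", {
  m <- ellipse_mask(80, 50, canvas = 256)
  expect_identical(contour_perimeter(m, scale = 0.5),
                   contour_perimeter(m) * 0.5)
})

test_that("masks with several components are rejected by contour ops", {
  m <- matrix(0L, 60, 60)
  m[5:15, 5:15] <- 1L
  m[40:50, 40:50] <- 1L
  expect_error(contour_perimeter(m), "single connected component")
})

test_that("minimum-area rectangle recovers constructed extents", {
  m <- rect_mask(120, 60, canvas = c(150, 90))
  d <- min_rect_dims(m)  # footprint-corrected: within 1 px of the extent
  expect_lte(abs(d[["BL"]] - 120), 1)
  expect_lte(abs(d[["BW"]] - 60), 1)
  expect_equal(d[["BL"]], 120)  # exact for axis-aligned rectangles
  expect_equal(d[["BW"]], 60)

  # rotation invariance: same rectangle rasterized at 30 degrees
  rot <- matrix(0L, 220, 220)
  th <- 30 * pi / 180
  xs <- row(rot) - 110.5; ys <- col(rot) - 110.5
  u <- xs * cos(th) + ys * sin(th); v <- -xs * sin(th) + ys * cos(th)
  rot[abs(u) <= 60 & abs(v) <= 30] <- 1L
  d2 <- min_rect_dims(rot)
  expect_equal(unname(d2["BL"]), 120, tolerance = 0.02)
  expect_equal(unname(d2["BW"]), 60, tolerance = 0.02)
})

test_that("a square mask gives BL equal to BW", {
  d <- min_rect_dims(rect_mask(40, 40))
  expect_equal(unname(d["BL"]), unname(d["BW"]))
})

test_that("degenerate (collinear) foreground is rejected", {
  m <- matrix(0L, 30, 30)
  m[5:25, 10] <- 1L
  expect_error(min_rect_dims(m), "collinear")
})

test_that("ellipse eccentricity matches closed forms", {
  expect_lt(ellipse_eccentricity(ellipse_mask(100, 100, canvas = 256)),
            0.02)
  expect_equal(ellipse_eccentricity(ellipse_mask(200, 100)),
               sqrt(1 - 0.25), tolerance = 0.02 / sqrt(1 - 0.25))
  expect_equal(ellipse_eccentricity(ellipse_mask(200, 180, canvas = 512)),
               sqrt(1 - 0.81), tolerance = 0.02 / sqrt(1 - 0.81))
})

test_that("the squared-eccentricity variant is the square of the default", {
  m <- ellipse_mask(200, 100)
  expect_equal(ellipse_eccentricity(m, "squared"),
               ellipse_eccentricity(m, "standard")^2, tolerance = 1e-10)
})

test_that("feature vector keeps the fixed RA, CP, BL, BW, E order", {
  fv <- extract_features(ellipse_mask(120, 60, canvas = 320))
  expect_identical(names(fv), c("RA", "CP", "BL", "BW", "E"))
  expect_identical(fv, extract_features(ellipse_mask(120, 60, canvas = 320)))
  expect_true(fv["BL"] >= fv["BW"])
})

test_that("scale equivariance: lengths scale by k, RA and E do not", {
  m <- ellipse_mask(150, 90, canvas = 400)
  f1 <- extract_features(m, scale = 1)
  f2 <- extract_features(m, scale = 2.5)
  expect_equal(unname(f2[c("CP", "BL", "BW")]),
               unname(f1[c("CP", "BL", "BW")] * 2.5), tolerance = 1e-12)
  expect_identical(f1[c("RA", "E")], f2[c("RA", "E")])
})

test_that("features are rotation-robust for noise-free superellipses", {
  base <- NULL
  for (ang in c(0, 30, 60)) {
    sp <- silhouette_spec(150, 80, orientation_deg = ang,
                          shape_exponent = 2.5)
    fv <- extract_features(render_mask(sp)$mask)
    if (is.null(base)) base <- fv
    expect_equal(unname(fv[c("CP", "BL", "BW")]),
                 unname(base[c("CP", "BL", "BW")]), tolerance = 0.02)
    expect_lt(abs(fv["E"] - base["E"]), 0.02)
  }
})

test_that("RA increases strictly with generated shape area", {
  ras <- vapply(c(60, 90, 120, 150), function(a) {
    relative_area(preprocess_mask(ellipse_mask(a, a * 0.6, canvas = 400)))
  }, numeric(1))
  expect_true(all(diff(ras) > 0))
})

test_that("batch extraction writes the interchange feature table", {
  dir <- withr::local_tempdir()
  write_mask_png(ellipse_mask(80, 50, canvas = 200), file.path(dir, "m1.png"))
  write_mask_png(ellipse_mask(60, 40, canvas = 200), file.path(dir, "m2.png"))
  csv <- file.path(dir, "features.csv")
  tab <- extract_features_dir(dir, out_csv = csv)
  expect_identical(names(tab), c("mask_id", "RA", "CP", "BL", "BW", "E"))
  expect_identical(tab$mask_id, c("m1", "m2"))
  expect_identical(utils::read.csv(csv)$mask_id, c("m1", "m2"))
})
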