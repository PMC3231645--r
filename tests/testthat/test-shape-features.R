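test_that("polygonal fitting finds square corners and honors tolerance", {
  ct <- square_contour(10, 10, 100)
  poly <- fit_polygon(ct, 1.5)
  expect_equal(nrow(poly$vertices), 4)
  corners <- rbind(c(10, 10), c(10, 110), c(110, 110), c(110, 10))
  expect_setequal(paste(poly$vertices[, 1], poly$vertices[, 2]),
                  paste(corners[, 1], corners[, 2]))
  # zero tolerance keeps every contour point
  poly0 <- fit_polygon(ct, 0)
  expect_equal(nrow(poly0$vertices), nrow(ct$points))
  # circle with tolerance 2: no discarded point deviates more than 2 px
  ct2 <- extract_contour(make_disk_image(100))
  poly2 <- fit_polygon(ct2, 2)
  expect_lte(poly2$max_deviation, 2)
})

test_that("shrinking tolerance shrinks deviation and grows the vertex count", {
  ct <- extract_contour(make_disk_image(90))
  tols <- c(4, 2, 1, 0.5)
  fits <- lapply(tols, function(tl) fit_polygon(ct, tl))
  devs <- vapply(fits, `[[`, numeric(1), "max_deviation")
  nv <- vapply(fits, function(p) nrow(p$vertices), numeric(1))
  expect_true(all(diff(devs) <= 0))
  expect_true(all(diff(nv) >= 0))
})

test_that("polygon perimeter counts rasterized side pixels without double counting", {
  sq <- structure(list(points = rbind(c(1, 1), c(1, 101), c(101, 101),
                                      c(101, 1)),
                       closed = TRUE, method = "synthetic",
                       diagnostics = list()), class = "leaf_contour")
  # direct polygon on the 4 corners of a side-100 square
  poly <- fit_polygon(square_contour(1, 1, 100), 1.5)
  expect_equal(polygon_perimeter(poly), 400)
  expect_equal(polygon_perimeter(poly, "euclidean"), 400)
  # triangle with a diagonal side: matches the brute-force rasterizer oracle
  tri <- structure(list(vertices = rbind(c(1, 1), c(1, 100), c(100, 1)),
                        tolerance_px = 0,
                        triangles = matrix(c(1, 2, 3), 1),
                        max_deviation = 0), class = "polygon_fit")
  expect_equal(polygon_perimeter(tri),
               polygon_boundary_pixels_oracle(tri$vertices))
})

test_that("triangulated polygon area equals the shoelace oracle", {
  tri <- structure(list(vertices = rbind(c(0, 0), c(10, 0), c(0, 10)),
                        tolerance_px = 0, triangles = matrix(c(1, 2, 3), 1),
                        max_deviation = 0), class = "polygon_fit")
  expect_equal(polygon_area(tri), 50)
  sq1 <- structure(list(vertices = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)),
                        tolerance_px = 0,
                        triangles = rbind(c(1, 2, 3), c(1, 3, 4)),
                        max_deviation = 0), class = "polygon_fit")
  expect_equal(polygon_area(sq1), 1)
  # random simple polygons: triangulated area vs whole-polygon shoelace
  set.seed(42)
  for (i in 1:200) {
    v <- random_simple_polygon(12)
    poly <- structure(list(vertices = v, tolerance_px = 0,
                           triangles = leafgrade:::ear_clip(v),
                           max_deviation = 0), class = "polygon_fit")
    expect_lt(abs(polygon_area(poly) - shoelace_oracle(v)), 1)
  }
})

test_that("rasterized perimeter tracks the Euclidean polygon length", {
  # per-side pixel count is max(|dr|,|dc|), bounded by [L/sqrt(2), L] of the
  # Euclidean side length; the bound is attained only by 45-degree sides
  set.seed(7)
  for (i in 1:50) {
    v <- round(random_simple_polygon(8, r_min = 60, r_max = 100,
                                     center = c(150, 150)))
    v <- v[!duplicated(v), , drop = FALSE]
    if (nrow(v) < 3) next
    poly <- structure(list(vertices = v, tolerance_px = 0,
                           triangles = leafgrade:::ear_clip(v),
                           max_deviation = 0), class = "polygon_fit")
    px <- polygon_perimeter(poly, "pixels")
    eu <- polygon_perimeter(poly, "euclidean")
    expect_lte(px, eu + 1e-9)
    expect_gte(px, eu / sqrt(2) - 1e-9)
  }
  # on orientation-diverse contour-fitted polygons (the pipeline's actual
  # use) the count sits within 10% of the Euclidean length
  for (shape in list(make_disk_image(100),
                     generate_leaf(default_class_specs()$B4L, 512,
                                   seed = 55)$image)) {
    poly <- fit_polygon(extract_contour(shape), 2)
    px <- polygon_perimeter(poly, "pixels")
    eu <- polygon_perimeter(poly, "euclidean")
    expect_lt(abs(px - eu) / eu, 0.10)
  }
})

test_that("disfigurement matches generator ground truth", {
  spec0 <- leaf_class_spec("H0", mean_rgb = c(205, 145, 70),
                           rgb_spread = c(10, 9, 8.5), texture_grain = 4,
                           hole_fraction = 0, size_range = c(260, 330),
                           texture_depth = 0.04)
  lf0 <- generate_leaf(spec0, 512, seed = 21)
  sf0 <- shape_features(lf0$image)
  expect_equal(sf0$disfigurement_pct, 0)
  spec5 <- leaf_class_spec("H5", mean_rgb = c(205, 145, 70),
                           rgb_spread = c(10, 9, 8.5), texture_grain = 4,
                           hole_fraction = 0.05, size_range = c(260, 330),
                           texture_depth = 0.04)
  lf5 <- generate_leaf(spec5, 512, seed = 22)
  sf5 <- shape_features(lf5$image)
  expect_lt(abs(sf5$disfigurement_pct - 100 * lf5$truth$true_hole_fraction),
            0.5)
})

test_that("shape features are deterministic and carry a sane bounding box", {
  lf <- generate_leaf(default_class_specs()$X1L, 512, seed = 31)
  a <- shape_features(lf$image)
  b <- shape_features(lf$image)
  expect_identical(a[c("area_px", "perimeter_px", "disfigurement_pct")],
                   b[c("area_px", "perimeter_px", "disfigurement_pct")])
  expect_gt(a$area_px, 0)
  expect_gte(a$perimeter_px, 3)
  expect_true(a$height_px >= 1 && a$width_px >= 1)
  expect_lte(a$height_px * a$width_px, 512 * 512)
  expect_gte(a$height_px * a$width_px, a$area_px)
})

test_that("degenerate contours are rejected", {
  line <- structure(list(points = cbind(5, 1:30), closed = TRUE,
                         method = "synthetic", diagnostics = list()),
                    class = "leaf_contour")
  expect_error(fit_polygon(line, 2), "degenerate|collinear")
})
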