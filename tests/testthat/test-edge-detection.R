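test_that("LoG kernel matches the analytic form and its symmetries", {
  cfg <- edge_config(sigma = 1, kernel_radius = 4)
  k <- log_kernel(cfg)
  r <- cfg$kernel_radius
  ctr <- r + 1
  # center value -1/(pi sigma^4)
  expect_equal(k[ctr, ctr], -1 / pi, tolerance = 1e-12)
  # the factor (1 - (x^2+y^2)/(2 sigma^2)) vanishes at x^2 + y^2 = 2 sigma^2
  expect_equal(k[ctr + 1, ctr + 1], 0, tolerance = 1e-15)
  # radial symmetry, exact
  expect_identical(k, k[rev(seq_len(2 * r + 1)), ])
  expect_identical(k, t(k))
  # sign change along an axis between floor(sqrt(2) sigma) and ceil
  for (sigma in c(1, 1.5, 2, 3)) {
    kk <- log_kernel(edge_config(sigma = sigma))
    cc <- ncol(kk) %/% 2 + 1
    lo <- floor(sqrt(2) * sigma); hi <- ceiling(sqrt(2) * sigma)
    expect_lt(kk[cc, cc + lo], 0)
    expect_gte(kk[cc, cc + hi], 0)
  }
  # truncated coefficients nearly cancel at r = 4 sigma
  expect_lt(abs(sum(log_kernel(edge_config(sigma = 2)))), 1e-3)
})

test_that("LoG kernel agrees with a finite-difference Laplacian of the Gaussian", {
  sigma <- 1
  k <- log_kernel(edge_config(sigma = sigma, kernel_radius = 4))
  h <- 1e-3
  gauss <- function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)) /
    (2 * pi * sigma^2)
  fd <- outer(-4:4, -4:4, Vectorize(function(x, y) {
    (gauss(x + h, y) + gauss(x - h, y) + gauss(x, y + h) + gauss(x, y - h) -
       4 * gauss(x, y)) / h^2
  }))
  expect_lt(max(abs(fd - k)), 5e-3)
})

test_that("gaussian smoothing preserves constants and matches brute force", {
  cfg <- edge_config(sigma = 1.2, kernel_radius = 4)
  const <- matrix(100, 20, 20)
  expect_equal(gaussian_smooth(const, cfg), const, tolerance = 1e-9)
  # centered impulse reproduces the normalized kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_smooth(imp, cfg)
  kg <- leafgrade:::gaussian_kernel(cfg)
  expect_equal(sm[7:15, 7:15], kg[1:9, 1:9], tolerance = 1e-9)
  # random grid against a nested-loop convolution oracle
  set.seed(11)
  x <- matrix(runif(16 * 16, 0, 255), 16, 16)
  expect_equal(gaussian_smooth(x, cfg), conv2_bruteforce(x, kg),
               tolerance = 1e-9)
})

test_that("binarize recovers the leaf area and rejects empty scenes", {
  lf <- generate_leaf(default_class_specs()$B4L, 512, seed = 5)
  mask <- binarize(lf$image)
  expect_lt(abs(sum(mask) - lf$truth$true_area_px) / lf$truth$true_area_px,
            0.02)
  # all-background image: detection error
  blank <- leaf_image(array(250, c(64, 64, 3)))
  expect_error(binarize(blank), "no leaf")
  # idempotence: re-binarizing a mask-rendered image returns the same mask
  px <- array(250, c(dim(mask), 3))
  for (ch in 1:3) { p <- px[, , ch]; p[mask] <- 100; px[, , ch] <- p }
  expect_identical(unname(binarize(leaf_image(px)) == TRUE),
                   unname(mask == TRUE))
})

test_that("extracted contours are closed, 8-connected and duplicate-free", {
  imgs <- list(make_disk_image(100), make_square_image(200),
               generate_leaf(default_class_specs()$S1, 512, seed = 9)$image)
  for (img in imgs) {
    ct <- extract_contour(img)
    expect_true(ct$closed)
    expect_silent(validate_contour(ct))
  }
})

test_that("contour geometry recovers analytic disk and square measures", {
  ct <- extract_contour(make_disk_image(100))
  poly <- fit_polygon(ct, 2)
  # contour-derived perimeter (Euclidean polygon length) near circumference
  expect_lt(abs(polygon_perimeter(poly, "euclidean") - 2 * pi * 100) /
              (2 * pi * 100), 0.05)
  # enclosed area near the analytic disk area
  expect_lt(abs(polygon_area(poly) - pi * 100^2) / (pi * 100^2), 0.03)

  ct2 <- extract_contour(make_square_image(200))
  poly2 <- fit_polygon(ct2, 2)
  expect_lt(abs(polygon_area(poly2) - 200^2) / 200^2, 0.02)
  # blank image: contour error
  expect_error(extract_contour(leaf_image(array(250, c(64, 64, 3)))),
               "no leaf")
})

test_that("LoG zero-crossings cover the leaf boundary at default scale", {
  lf <- generate_leaf(default_class_specs()$X1L, 512, seed = 3)
  ct <- extract_contour(lf$image)
  expect_identical(ct$method, "log-zero-crossing")
  expect_gte(ct$diagnostics$coverage, 0.9)
})

test_that("increasing sigma does not increase the edge-component count", {
  lf <- generate_leaf(default_class_specs()$S1, 512, seed = 7)
  lum <- luminance(lf$image)
  counts <- vapply(c(1, 2, 3, 4), function(s) {
    zc <- log_zero_crossings(lum, edge_config(sigma = s))
    max(EBImage::bwlabel(zc))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
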