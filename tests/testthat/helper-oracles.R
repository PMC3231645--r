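# Shared fixtures and independent oracles, built in code at test time.

# --- image builders -------------------------------------------------------

make_disk_image <- function(r, canvas = 512, col = c(120, 100, 60),
                            bg = 250) {
  px <- array(bg, c(canvas, canvas, 3))
  ctr <- canvas / 2
  d2 <- outer((1:canvas - ctr)^2, (1:canvas - ctr)^2, `+`)
  m <- d2 <= r^2
  for (ch in 1:3) {
    p <- px[, , ch]; p[m] <- col[ch]; px[, , ch] <- p
  }
  leaf_image(px, background_rgb = rep(bg, 3))
}

make_square_image <- function(side, canvas = 512, col = c(120, 100, 60),
                              bg = 250) {
  px <- array(bg, c(canvas, canvas, 3))
  i0 <- floor((canvas - side) / 2)
  for (ch in 1:3) px[i0:(i0 + side - 1), i0:(i0 + side - 1), ch] <- col[ch]
  leaf_image(px, background_rgb = rep(bg, 3))
}

# ordered closed contour of an axis-aligned square, counter-clockwise,
# corners at (r0,c0) and (r0+side, c0+side)
square_contour <- function(r0, c0, side) {
  top <- cbind(r0, c0:(c0 + side))
  right <- cbind((r0 + 1):(r0 + side), c0 + side)
  bottom <- cbind(r0 + side, (c0 + side - 1):c0)
  left <- cbind((r0 + side - 1):(r0 + 1), c0)
  pts <- rbind(top, right, bottom, left)
  structure(list(points = unname(pts), closed = TRUE, method = "synthetic",
                 diagnostics = list()), class = "leaf_contour")
}

# --- brute-force oracles --------------------------------------------------

# nested-loop 2-D convolution with mirror (half-sample symmetric) boundary
conv2_bruteforce <- function(x, kern) {
  r <- (nrow(kern) - 1) / 2
  n <- nrow(x); m <- ncol(x)
  reflect <- function(i, nn) {
    while (i < 1 || i > nn) {
      if (i < 1) i <- 1 - i
      if (i > nn) i <- 2 * nn + 1 - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + kern[a + r + 1, b + r + 1] *
        x[reflect(i - a, n), reflect(j - b, m)]
    }
    out[i, j] <- acc
  }
  out
}

# nested-loop GLCM counts oracle
glcm_bruteforce <- function(levels, offset, n_levels = 32) {
  dx <- offset[1]; dy <- offset[2]
  n <- nrow(levels); m <- ncol(levels)
  counts <- matrix(0L, n_levels, n_levels)
  for (r in 1:n) for (c in 1:m) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 < 1 || r2 > n || c2 < 1 || c2 > m) next
    a <- levels[r, c]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1L
  }
  counts
}

# integer Bresenham line rasterizer (both endpoints included)
bresenham_oracle <- function(a, b) {
  x0 <- a[1]; y0 <- a[2]; x1 <- b[1]; y1 <- b[2]
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  err <- dx - dy
  pts <- matrix(0L, dx + dy + 1, 2)
  k <- 0
  repeat {
    k <- k + 1
    pts[k, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[1:k, , drop = FALSE]
}

# unique pixel count of a rasterized polygon boundary
polygon_boundary_pixels_oracle <- function(v) {
  n <- nrow(v)
  px <- do.call(rbind, lapply(seq_len(n), function(k)
    bresenham_oracle(v[k, ], v[(k %% n) + 1, ])))
  nrow(unique(px))
}

# whole-polygon shoelace area
shoelace_oracle <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  abs(sum(x * ny - nx * y)) / 2
}

# random star-shaped (hence simple) polygon around a center
random_simple_polygon <- function(n_vertices, r_min = 20, r_max = 100,
                                  center = c(0, 0)) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, r_min, r_max)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# small specs for fast experiment tests
tiny_class_specs <- function() {
  list(
    A = leaf_class_spec("A", mean_rgb = c(215, 185, 95),
                        rgb_spread = c(9, 8, 7.5), texture_grain = 2,
                        hole_fraction = 0.015, size_range = c(60, 80),
                        texture_depth = 0.035),
    B = leaf_class_spec("B", mean_rgb = c(205, 145, 70),
                        rgb_spread = c(10, 9, 8.5), texture_grain = 4,
                        hole_fraction = 0.05, size_range = c(85, 105),
                        texture_depth = 0.04),
    C = leaf_class_spec("C", mean_rgb = c(170, 150, 85),
                        rgb_spread = c(10, 9.5, 9), texture_grain = 6,
                        hole_fraction = 0.09, size_range = c(70, 95),
                        texture_depth = 0.045)
  )
}

# well-separated Gaussian blob features for network tests
separable_blobs <- function(n_per_class = 30, spread = 0.01, seed = 1) {
  centers <- rbind(c(0.2, 0.2, 0.8), c(0.8, 0.2, 0.2), c(0.5, 0.8, 0.5))
  classes <- c("X1L", "B4L", "S1")
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(3 * n_per_class, mean = rep(centers[k, ],
                                                      each = n_per_class),
                          sd = spread), n_per_class, 3)))
    y <- rep(classes, each = n_per_class)
    ord <- sample(length(y))
    list(x = X[ord, ], y = y[ord], classes = classes)
  })
}
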