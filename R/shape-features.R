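#' @title Polygonal fitting and the three shape features
#' @description The smooth leaf contour is replaced by a polygon whose
#'   vertices are contour points (Ramer-Douglas-Peucker simplification on the
#'   closed curve), the polygon is triangulated, and the three shape features
#'   are measured on it: surface area (triangulated pixel area), surface
#'   perimeter (pixels on the rasterized polygon sides), and disfigurement
#'   (percentage of interior pixels matching the background color - holes and
#'   damage visible through the leaf).
#' @name shape-features
NULL

# Perpendicular distance from points to the segment (a, b); falls back to
# endpoint distance outside the segment's span.
point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- clamp(t, 0, 1)
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Iterative Ramer-Douglas-Peucker on an open chain; returns kept indices.
rdp_chain <- function(pts, tol) {
  n <- nrow(pts)
  keep <- c(1L, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- point_segment_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- mid[which.max(d)]
    if (max(d) > tol) {
      keep <- c(keep, k)
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  sort(unique(keep))
}

signed_area2 <- function(v) {
  # twice the signed (shoelace) area, same orientation convention as the
  # cross products in ear_clip (first coordinate = x, second = y)
  r <- v[, 1]; c_ <- v[, 2]
  nr <- c(r[-1], r[1]); nc <- c(c_[-1], c_[1])
  sum(r * nc - nr * c_)
}

# Ear-clipping triangulation of a simple polygon; returns index triples.
# The containment test per candidate ear is vectorized over the remaining
# vertices, so the whole triangulation is ~O(n^2) elementary operations.
ear_clip <- function(v) {
  n <- nrow(v)
  if (n < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  orient <- sign(signed_area2(v))
  if (orient == 0) stop("degenerate (collinear) polygon", call. = FALSE)
  idx <- seq_len(n)
  tris <- vector("list", n - 2)
  nt <- 0L
  guard <- 0
  while (length(idx) > 3) {
    guard <- guard + 1
    if (guard > 2 * n) stop("triangulation failed: polygon may self-intersect",
                            call. = FALSE)
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[((k - 2) %% m) + 1]; i1 <- idx[k]; i2 <- idx[(k %% m) + 1]
      a <- v[i0, ]; b <- v[i1, ]; c_ <- v[i2, ]
      cz <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
      if (cz == 0) {
        # collinear ear: zero-area triangle, always safe to clip
        nt <- nt + 1L; tris[[nt]] <- c(i0, i1, i2)
        idx <- idx[-k]; clipped <- TRUE; break
      }
      if (sign(cz) != orient) next  # reflex vertex
      others <- idx[idx != i0 & idx != i1 & idx != i2]
      if (length(others)) {
        p <- v[others, , drop = FALSE]
        d1 <- (b[1] - a[1]) * (p[, 2] - a[2]) -
          (b[2] - a[2]) * (p[, 1] - a[1])
        d2 <- (c_[1] - b[1]) * (p[, 2] - b[2]) -
          (c_[2] - b[2]) * (p[, 1] - b[1])
        d3 <- (a[1] - c_[1]) * (p[, 2] - c_[2]) -
          (a[2] - c_[2]) * (p[, 1] - c_[1])
        has_neg <- d1 < 0 | d2 < 0 | d3 < 0
        has_pos <- d1 > 0 | d2 > 0 | d3 > 0
        if (any(!(has_neg & has_pos))) next  # another vertex inside the ear
      }
      nt <- nt + 1L; tris[[nt]] <- c(i0, i1, i2)
      idx <- idx[-k]; clipped <- TRUE; break
    }
    if (!clipped) stop("triangulation failed: no ear found", call. = FALSE)
  }
  nt <- nt + 1L; tris[[nt]] <- idx
  do.call(rbind, tris[seq_len(nt)])
}

#' Fit a polygon to a closed contour
#'
#' Ramer-Douglas-Peucker simplification of the closed contour: the curve is
#' split at two mutually far points, each half is recursively simplified, and
#' every original contour point ends up within `tolerance_px` of the polygon
#' boundary. A zero tolerance keeps every contour point. The polygon is
#' triangulated by ear clipping for area computation.
#'
#' @param contour a closed `leaf_contour` with at least 3 points.
#' @param tolerance_px maximum allowed point-to-segment deviation in pixels.
#'   Default 2.
#' @return An object of class `polygon_fit`: `vertices` (ordered `(row, col)`
#'   matrix, a subset of the contour points), `tolerance_px`, `triangles`
#'   (vertex index triples), and `max_deviation` (largest distance of any
#'   contour point from the polygon boundary).
#' @export
fit_polygon <- function(contour, tolerance_px = 2) {
  stopifnot(inherits(contour, "leaf_contour"))
  if (!contour$closed || nrow(contour$points) < 3)
    stop("contour must be closed with at least 3 points", call. = FALSE)
  if (tolerance_px < 0) stop("`tolerance_px` must be >= 0", call. = FALSE)
  pts <- contour$points
  n <- nrow(pts)
  if (tolerance_px == 0) {
    vid <- seq_len(n)
  } else {
    # split at two mutually far points: the point farthest from pts[1],
    # then the point farthest from that one
    d1 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
    i1 <- which.max(d1)
    d2 <- (pts[, 1] - pts[i1, 1])^2 + (pts[, 2] - pts[i1, 2])^2
    i2 <- which.max(d2)
    lo <- min(i1, i2); hi <- max(i1, i2)
    chain1 <- lo:hi
    chain2 <- c(hi:n, 1:lo)
    k1 <- chain1[rdp_chain(pts[chain1, , drop = FALSE], tolerance_px)]
    k2 <- chain2[rdp_chain(pts[chain2, , drop = FALSE], tolerance_px)]
    vid <- sort(unique(c(k1, k2)))
  }
  v <- pts[vid, , drop = FALSE]
  if (nrow(v) < 3 || signed_area2(v) == 0)
    stop("degenerate contour: polygonal fit is collinear", call. = FALSE)
  tris <- ear_clip(v)
  # audit: distance of every contour point to its nearest polygon side
  devs <- rep(Inf, n)
  m <- nrow(v)
  for (k in seq_len(m)) {
    a <- v[k, ]; b <- v[(k %% m) + 1, ]
    devs <- pmin(devs, point_segment_dist(pts, a, b))
  }
  structure(list(vertices = v, vertex_index = vid,
                 tolerance_px = tolerance_px, triangles = tris,
                 max_deviation = max(devs)),
            class = "polygon_fit")
}

#' @export
print.polygon_fit <- function(x, ...) {
  cat(sprintf("<polygon_fit: %d vertices, tol %.2f px, max dev %.2f px>\n",
              nrow(x$vertices), x$tolerance_px, x$max_deviation))
  invisible(x)
}

# Pixels of the 8-connected Bresenham rasterization of segment a -> b,
# excluding the final endpoint (so chained sides share vertices once).
bresenham_open <- function(a, b) {
  n_steps <- max(abs(b - a))
  if (n_steps == 0) return(matrix(a, 1, 2))
  t <- seq(0, n_steps - 1) / n_steps
  cbind(round(a[1] + t * (b[1] - a[1])), round(a[2] + t * (b[2] - a[2])))
}

#' Surface perimeter of a fitted polygon
#'
#' The paper's measure is the number of pixels on the rasterized polygon
#' sides (8-connected line drawing), with each shared vertex pixel counted
#' once; for a side this is the Chebyshev length `max(|dr|, |dc|)`. The
#' Euclidean side-length sum is available as an alternative estimator free of
#' the ~10% digitization bias the pixel count carries on oblique or curved
#' boundaries.
#'
#' @param poly a [fit_polygon()] result.
#' @param method `"pixels"` (default, the pixel count) or `"euclidean"`.
#' @return Perimeter in pixels; an integer count for `method = "pixels"`.
#' @export
polygon_perimeter <- function(poly, method = c("pixels", "euclidean")) {
  stopifnot(inherits(poly, "polygon_fit"))
  method <- match.arg(method)
  v <- poly$vertices
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  if (method == "pixels") {
    sum(pmax(abs(nxt[, 1] - v[, 1]), abs(nxt[, 2] - v[, 2])))
  } else {
    sum(sqrt((nxt[, 1] - v[, 1])^2 + (nxt[, 2] - v[, 2])^2))
  }
}

#' Surface area of a fitted polygon
#'
#' Sum of the (shoelace) areas of the triangles of the fitted polygon,
#' rounded to the nearest integer pixel count; equal to the whole-polygon
#' shoelace area up to rounding.
#'
#' @param poly a [fit_polygon()] result.
#' @return Integer pixel area.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "polygon_fit"))
  v <- poly$vertices
  a <- sum(apply(poly$triangles, 1, function(tr) {
    abs(signed_area2(v[tr, , drop = FALSE])) / 2
  }))
  round(a)
}

# Strict-interior pixel mask of a polygon by even-odd scanline at pixel
# centers; rasterized boundary pixels are excluded.
polygon_interior_mask <- function(poly, dims) {
  v <- poly$vertices
  n <- nrow(v)
  mask <- matrix(FALSE, dims[1], dims[2])
  r1 <- v[, 1]; c1 <- v[, 2]
  r2 <- c(r1[-1], r1[1]); c2 <- c(c1[-1], c1[1])
  keep <- r1 != r2  # horizontal edges contribute no crossings
  er1 <- r1[keep]; ec1 <- c1[keep]; er2 <- r2[keep]; ec2 <- c2[keep]
  lo <- pmin(er1, er2); hi <- pmax(er1, er2)
  rows <- max(1, min(lo)):min(dims[1], max(hi))
  for (y in rows) {
    # half-open rule [min, max): vertex-on-scanline counted once
    act <- which(lo <= y & y < hi)
    if (!length(act)) next
    xs <- ec1[act] + (y - er1[act]) * (ec2[act] - ec1[act]) /
      (er2[act] - er1[act])
    xs <- sort(xs)
    if (length(xs) < 2) next
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k] + 1e-9); b <- floor(xs[k + 1] - 1e-9)
      if (b >= a) mask[y, clamp(a, 1, dims[2]):clamp(b, 1, dims[2])] <- TRUE
    }
  }
  # remove rasterized boundary pixels: interior is strictly inside
  for (k in seq_len(n)) {
    px <- bresenham_open(v[k, ], v[(k %% n) + 1, ])
    ok <- px[, 1] >= 1 & px[, 1] <= dims[1] & px[, 2] >= 1 & px[, 2] <= dims[2]
    mask[px[ok, , drop = FALSE]] <- FALSE
  }
  mask
}

#' Disfigurement of a leaf
#'
#' Counts the pixels strictly inside the fitted polygon (even-odd rule on
#' pixel centers, boundary pixels excluded) and those among them whose color
#' matches the background within a per-channel tolerance; the disfigurement
#' is their ratio as a percentage. Background-colored interior pixels are
#' holes or damage visible through the leaf.
#'
#' @param image a [leaf_image()].
#' @param poly a [fit_polygon()] result lying inside the image.
#' @param bg_tolerance per-channel absolute intensity tolerance for a pixel
#'   to count as background-colored. Default 10 (tolerates hole-rim
#'   anti-aliasing).
#' @return Disfigurement percentage in `[0, 100]`.
#' @export
disfigurement <- function(image, poly, bg_tolerance = 10) {
  stopifnot(inherits(image, "leaf_image"), inherits(poly, "polygon_fit"))
  dims <- dim(image$pixels)[1:2]
  if (min(poly$vertices) < 1 || max(poly$vertices[, 1]) > dims[1] ||
      max(poly$vertices[, 2]) > dims[2])
    stop("polygon exceeds image bounds", call. = FALSE)
  interior <- polygon_interior_mask(poly, dims)
  n_int <- sum(interior)
  if (n_int == 0) stop("polygon has no interior pixels", call. = FALSE)
  px <- image$pixels
  bg <- image$background_rgb
  is_bg <- abs(px[, , 1] - bg[1]) <= bg_tolerance &
    abs(px[, , 2] - bg[2]) <= bg_tolerance &
    abs(px[, , 3] - bg[3]) <= bg_tolerance
  100 * sum(is_bg & interior) / n_int
}

#' Extract the three shape features of a leaf image
#'
#' Composes contour extraction, polygonal fitting, and the area / perimeter /
#' disfigurement measures; also reports the bounding-box height and width of
#' the fitted polygon.
#'
#' @param image a [leaf_image()] containing a single leaf.
#' @param config an [edge_config()].
#' @param tolerance_px polygonal fitting tolerance in pixels. Default 2.
#' @param contour optional precomputed contour (skips extraction).
#' @return A list of class `shape_features`: `area_px`, `perimeter_px`
#'   (pixel count), `perimeter_euclid_px` (Euclidean polygon length),
#'   `disfigurement_pct`, `height_px`, `width_px`, and the `polygon` used.
#' @export
shape_features <- function(image, config = edge_config(), tolerance_px = 2,
                           contour = NULL) {
  if (is.null(contour)) contour <- extract_contour(image, config)
  poly <- fit_polygon(contour, tolerance_px)
  out <- list(
    area_px = polygon_area(poly),
    perimeter_px = polygon_perimeter(poly, "pixels"),
    perimeter_euclid_px = polygon_perimeter(poly, "euclidean"),
    disfigurement_pct = disfigurement(image, poly),
    height_px = max(poly$vertices[, 1]) - min(poly$vertices[, 1]) + 1L,
    width_px = max(poly$vertices[, 2]) - min(poly$vertices[, 2]) + 1L,
    polygon = poly
  )
  class(out) <- "shape_features"
  out
}

#' @export
print.shape_features <- function(x, ...) {
  cat(sprintf(paste0("<shape_features: area %d px, perimeter %d px, ",
                     "disfigurement %.2f%%, bbox %d x %d>\n"),
              x$area_px, x$perimeter_px, x$disfigurement_pct,
              x$height_px, x$width_px))
  invisible(x)
}
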