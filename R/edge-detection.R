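#' Edge-detection configuration
#'
#' Parameters of the Laplacian-of-Gaussian (LoG) edge pipeline. The Gaussian
#' scale `sigma` trades noise suppression against edge localization; the
#' kernel radius truncates the LoG support (at `r >= 4 sigma` the truncated
#' coefficients sum to nearly zero). The binarization threshold is applied to
#' the per-pixel distance from the background color, either as a fixed
#' intensity in `[0, 255]` or estimated by Otsu's method.
#'
#' @param sigma Gaussian scale in pixels, `> 0`. Default 2.
#' @param kernel_radius integer kernel radius; the kernel side is
#'   `2 * kernel_radius + 1`. Default `ceiling(4 * sigma)`.
#' @param binarize_threshold scalar in `[0, 255]`, or `"otsu"`.
#' @return An object of class `edge_config`.
#' @export
edge_config <- function(sigma = 2, kernel_radius = ceiling(4 * sigma),
                        binarize_threshold = "otsu") {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be a positive scalar", call. = FALSE)
  kernel_radius <- as.integer(kernel_radius)
  if (kernel_radius < ceiling(3 * sigma))
    stop("`kernel_radius` must be at least ceiling(3 * sigma)", call. = FALSE)
  if (!(identical(binarize_threshold, "otsu") ||
        (is.numeric(binarize_threshold) && length(binarize_threshold) == 1 &&
         binarize_threshold >= 0 && binarize_threshold <= 255)))
    stop("`binarize_threshold` must be in [0, 255] or \"otsu\"", call. = FALSE)
  structure(list(sigma = sigma, kernel_radius = kernel_radius,
                 binarize_threshold = binarize_threshold),
            class = "edge_config")
}

#' Laplacian-of-Gaussian kernel
#'
#' Samples
#' \deqn{-\frac{1}{\pi\sigma^4}\left(1 - \frac{x^2+y^2}{2\sigma^2}\right)
#'       e^{-\frac{x^2+y^2}{2\sigma^2}}}
#' at integer offsets on a `(2r+1) x (2r+1)` grid. The kernel is radially
#' symmetric, negative at the center, and changes sign on the circle of
#' radius \eqn{\sqrt{2}\sigma}.
#'
#' @param config an [edge_config()].
#' @return A square numeric matrix of LoG coefficients.
#' @export
log_kernel <- function(config = edge_config()) {
  stopifnot(inherits(config, "edge_config"))
  s2 <- config$sigma^2
  r <- config$kernel_radius
  off <- -r:r
  d2 <- outer(off^2, off^2, `+`)
  -(1 / (pi * s2^2)) * (1 - d2 / (2 * s2)) * exp(-d2 / (2 * s2))
}

# Unit-sum sampled Gaussian kernel on the same grid.
gaussian_kernel <- function(config = edge_config()) {
  s2 <- config$sigma^2
  r <- config$kernel_radius
  off <- -r:r
  d2 <- outer(off^2, off^2, `+`)
  k <- exp(-d2 / (2 * s2))
  k / sum(k)
}

#' Gaussian pre-smoothing
#'
#' Convolution with a unit-sum sampled Gaussian, mirror-symmetric boundary
#' extension; output has the dimensions of the input, and a constant image
#' maps to itself.
#'
#' @param image single-channel numeric matrix.
#' @param config an [edge_config()].
#' @return A smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(image, config = edge_config()) {
  if (!is.matrix(image) || length(image) == 0)
    stop("`image` must be a nonempty matrix", call. = FALSE)
  conv2_mirror(image, gaussian_kernel(config))
}

#' LoG-filter a single-channel image
#'
#' @param image single-channel numeric matrix.
#' @param config an [edge_config()].
#' @return The LoG response matrix.
#' @export
log_filter <- function(image, config = edge_config()) {
  if (!is.matrix(image) || length(image) == 0)
    stop("`image` must be a nonempty matrix", call. = FALSE)
  conv2_mirror(image, log_kernel(config))
}

#' Zero-crossings of the LoG response
#'
#' Marks pixels where the LoG response changes sign against the right or
#' lower neighbor and the local response step exceeds a fraction of the
#' maximum step (suppressing flat-region noise crossings).
#'
#' @param image single-channel matrix, or a [leaf_image()] (its luminance is
#'   used).
#' @param config an [edge_config()].
#' @param min_step_frac minimum |response step| across the crossing as a
#'   fraction of the largest step in the image. Default 0.05.
#' @return A logical matrix of edge pixels.
#' @export
log_zero_crossings <- function(image, config = edge_config(),
                               min_step_frac = 0.05) {
  if (inherits(image, "leaf_image")) image <- luminance(image)
  L <- log_filter(image, config)
  n <- nrow(L); m <- ncol(L)
  zc <- matrix(FALSE, n, m)
  # horizontal neighbor
  a <- L[, -m, drop = FALSE]; b <- L[, -1, drop = FALSE]
  cross_h <- (a * b) < 0
  step_h <- abs(a - b)
  # vertical neighbor
  c_ <- L[-n, , drop = FALSE]; d <- L[-1, , drop = FALSE]
  cross_v <- (c_ * d) < 0
  step_v <- abs(c_ - d)
  thr <- min_step_frac * max(step_h, step_v, 0)
  zc[, -m] <- zc[, -m] | (cross_h & step_h >= thr)
  zc[-n, ] <- zc[-n, ] | (cross_v & step_v >= thr)
  zc
}

#' Segment the leaf from the background
#'
#' Pixels whose maximum per-channel distance from the background color
#' exceeds the threshold are foreground; the largest connected component is
#' kept and, by default, interior holes are filled so the mask is the full
#' leaf region (holes are measured later as disfigurement).
#'
#' @param image a [leaf_image()].
#' @param config an [edge_config()]; its `binarize_threshold` is used.
#' @param fill_holes fill interior holes of the leaf mask? Default `TRUE`.
#' @return A logical `H x W` matrix (leaf = `TRUE`) with attributes
#'   `threshold` (the value used).
#' @export
binarize <- function(image, config = edge_config(), fill_holes = TRUE) {
  stopifnot(inherits(image, "leaf_image"))
  px <- image$pixels
  bg <- image$background_rgb
  d <- pmax(abs(px[, , 1] - bg[1]), abs(px[, , 2] - bg[2]),
            abs(px[, , 3] - bg[3]))
  thr <- config$binarize_threshold
  if (identical(thr, "otsu")) {
    if (max(d) <= 0)
      stop("no leaf found: image is uniform background", call. = FALSE)
    thr <- 255 * EBImage::otsu(EBImage::Image(d / 255), range = c(0, 1))
  }
  fg <- d > thr
  if (!any(fg))
    stop("no leaf found: no pixel exceeds the background-distance threshold",
         call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < 16)
    stop("no leaf found: largest foreground component is tiny", call. = FALSE)
  if (length(sizes) > 1 && sort(sizes, decreasing = TRUE)[2] >=
        0.5 * sizes[keep])
    stop("ambiguous scene: multiple similar-size foreground components",
         call. = FALSE)
  mask <- matrix(as.vector(lab) == keep, nrow(fg), ncol(fg))
  if (fill_holes)
    mask <- matrix(as.vector(EBImage::fillHull(mask * 1)) > 0,
                   nrow(fg), ncol(fg))
  attr(mask, "threshold") <- as.numeric(thr)
  mask
}

# Moore-neighbor boundary tracing with Jacob's stopping criterion.
# Returns an ordered (row, col) matrix of 8-connected boundary pixels of the
# largest-object mask; consecutive points (and last -> first) are neighbors.
trace_boundary <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  # clockwise Moore neighborhood, starting east
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  start <- which(mask)[1]
  if (is.na(start)) stop("empty mask", call. = FALSE)
  # column-major which(): first TRUE in the leftmost nonempty column
  r0 <- ((start - 1) %% n) + 1
  c0 <- ((start - 1) %/% n) + 1
  if (sum(mask) == 1) return(matrix(c(r0, c0), 1, 2))
  inside <- function(r, c) r >= 1 && r <= n && c >= 1 && c <= m && mask[r, c]
  pts_r <- integer(0); pts_c <- integer(0)
  # backtrack direction: we entered the start pixel from the west
  cur_r <- r0; cur_c <- c0
  dir <- 5L  # index of the backtrack neighbor (west), search starts after it
  first_next <- NA
  repeat {
    pts_r <- c(pts_r, cur_r); pts_c <- c(pts_c, cur_c)
    found <- FALSE
    for (k in 1:8) {
      j <- ((dir + k - 1) %% 8) + 1
      rr <- cur_r + dr[j]; cc <- cur_c + dc[j]
      if (inside(rr, cc)) {
        # next backtrack: neighbor index pointing back toward cur
        dir <- ((j + 4 - 1) %% 8) + 1
        cur_r <- rr; cur_c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur_r == r0 && cur_c == c0) {
      if (is.na(first_next)) first_next <- length(pts_r) + 1
      # Jacob's criterion: stop when the start pixel is re-entered
      break
    }
    if (length(pts_r) > 4 * (n + m) * 4) stop("boundary tracing runaway",
                                              call. = FALSE)
  }
  cbind(row = pts_r, col = pts_c)
}

new_contour <- function(points, closed = TRUE, method = "mask-boundary",
                        diagnostics = list()) {
  structure(list(points = points, closed = closed, method = method,
                 diagnostics = diagnostics),
            class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour: %d points, %s, method=%s>\n",
              nrow(x$points), if (x$closed) "closed" else "open", x$method))
  invisible(x)
}

#' Check the closure and connectivity invariants of a contour
#'
#' Consecutive points (and last to first when closed) must be 8-connected
#' neighbors, and no pixel may appear twice except the implied closure.
#'
#' @param contour a contour returned by [extract_contour()].
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_contour <- function(contour) {
  p <- contour$points
  if (nrow(p) < 1) stop("empty contour", call. = FALSE)
  if (nrow(p) > 1) {
    nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    if (!contour$closed) nxt <- p[c(2:nrow(p), nrow(p)), , drop = FALSE]
    step <- pmax(abs(nxt[, 1] - p[, 1]), abs(nxt[, 2] - p[, 2]))
    if (any(step > 1) || any(step[-length(step)] == 0))
      stop("contour points are not consecutive 8-neighbors", call. = FALSE)
  }
  if (anyDuplicated(paste(p[, 1], p[, 2])))
    stop("contour revisits a pixel", call. = FALSE)
  invisible(TRUE)
}

#' Extract the closed leaf contour
#'
#' Segments the leaf, LoG-filters the luminance channel, locates
#' zero-crossings of the response, and links them into a single closed
#' 1-pixel contour by snapping to the traced boundary of the leaf mask (the
#' mask boundary cycle supplies the ordering; the zero-crossing set validates
#' it). If the zero-crossings fail to cover the boundary - e.g. at very low
#' contrast - the traced mask boundary itself is returned, flagged as the
#' fallback.
#'
#' @param image a [leaf_image()] containing a single leaf.
#' @param config an [edge_config()].
#' @param mask optional precomputed leaf mask (from [binarize()]).
#' @param min_coverage minimum fraction of boundary points within 2 px of a
#'   LoG zero-crossing for the contour to count as LoG-derived. Default 0.9.
#' @return A `leaf_contour`: ordered `(row, col)` points (1-based), closed,
#'   with diagnostics (`coverage`, `method`).
#' @export
extract_contour <- function(image, config = edge_config(), mask = NULL,
                            min_coverage = 0.9) {
  stopifnot(inherits(image, "leaf_image"))
  if (is.null(mask)) mask <- binarize(image, config)
  bnd <- trace_boundary(mask)
  zc <- log_zero_crossings(image, config)
  # coverage: boundary points with a zero-crossing within Chebyshev radius 2
  covered <- rep(FALSE, nrow(bnd))
  for (dr in -2:2) for (dc in -2:2) {
    rr <- clamp(bnd[, 1] + dr, 1, nrow(zc))
    cc <- clamp(bnd[, 2] + dc, 1, ncol(zc))
    covered <- covered | zc[cbind(rr, cc)]
  }
  cov <- mean(covered)
  method <- if (cov >= min_coverage) "log-zero-crossing" else "mask-fallback"
  if (method == "mask-fallback")
    warning(sprintf(paste("LoG zero-crossings cover only %.0f%% of the leaf",
                          "boundary; returning the mask boundary"), 100 * cov),
            call. = FALSE)
  ct <- new_contour(bnd, closed = TRUE, method = method,
                    diagnostics = list(coverage = cov,
                                       n_boundary = nrow(bnd)))
  validate_contour(ct)
  ct
}

#' Euclidean length of a contour's 8-connected chain
#'
#' Straight steps count 1 and diagonal steps \eqn{\sqrt 2}; the closing step
#' is included for closed contours.
#'
#' @param contour a `leaf_contour`.
#' @return Chain length in pixels.
#' @export
contour_chain_length <- function(contour) {
  p <- contour$points
  if (nrow(p) < 2) return(0)
  nxt <- rbind(p[-1, , drop = FALSE], if (contour$closed) p[1, , drop = FALSE])
  sum(sqrt((nxt[, 1] - p[, 1])^2 + (nxt[, 2] - p[, 2])^2))
}

#' Export a contour as CSV
#'
#' @param contour a `leaf_contour`.
#' @param path output CSV path; columns `row`, `col`.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(contour$points), path, row.names = FALSE)
  invisible(path)
}

#' Export a contour as a single-polygon JSON for inspection
#'
#' @param contour a `leaf_contour`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_contour_json <- function(contour, path) {
  obj <- list(type = "Polygon", closed = contour$closed,
              coordinates = unname(apply(contour$points, 1, as.numeric,
                                         simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
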