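#' @title Gray-level co-occurrence texture features
#' @description The luminance channel is degraded from 256 to 32 gray levels
#'   (purely to keep the co-occurrence matrix tractable), a directional
#'   32 x 32 gray-level co-occurrence matrix (GLCM) is accumulated over the
#'   leaf pixels at a fixed displacement, and three statistics are read off
#'   the probability-normalized matrix: energy \eqn{\sum p_{ij}^2}, entropy
#'   \eqn{-\sum p_{ij}\log_2 p_{ij}}, and contrast
#'   \eqn{\sum (i-j)^2 p_{ij}}.
#' @name texture-features
NULL

#' Degrade an image to 32 gray levels
#'
#' Luminance is binned as `floor(luminance / 8)`, so 0 maps to level 0 and
#' 255 to level 31. Pixels outside the mask are `NA` and never pair into the
#' co-occurrence matrix.
#'
#' @param image a [leaf_image()] or a luminance matrix.
#' @param mask optional logical mask of valid pixels.
#' @param n_levels number of gray levels. Default 32.
#' @return An integer matrix of levels `0 .. n_levels - 1`, `NA` outside the
#'   mask.
#' @export
degrade_gray <- function(image, mask = NULL, n_levels = 32) {
  lum <- if (inherits(image, "leaf_image")) luminance(image) else image
  bin <- 256 / n_levels
  lev <- pmin(floor(lum / bin), n_levels - 1)
  if (!is.null(mask)) lev[!mask] <- NA
  lev
}

#' Gray-level co-occurrence matrix
#'
#' `counts[i + 1, j + 1]` is the number of pixel pairs at displacement
#' `offset = (dx, dy)` (columns right, rows down) whose gray levels are `i`
#' then `j`, both pixels inside the mask. The matrix is directional (not
#' symmetrized); reversing the offset transposes it.
#'
#' @param levels integer level matrix from [degrade_gray()] (`NA` = outside
#'   mask).
#' @param offset integer displacement `c(dx, dy)`; default `c(1, 0)`, the
#'   pixel to the immediate right.
#' @param n_levels matrix dimension. Default 32.
#' @return An object of class `glcm`: `counts` (`n_levels x n_levels`),
#'   `offset`, `n_levels`, `normalized = FALSE`.
#' @export
glcm <- function(levels, offset = c(1, 0), n_levels = 32) {
  stopifnot(is.matrix(levels), length(offset) == 2)
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  if (dx == 0 && dy == 0) stop("offset must be nonzero", call. = FALSE)
  n <- nrow(levels); m <- ncol(levels)
  if (abs(dx) >= m || abs(dy) >= n)
    stop("offset exceeds image extent", call. = FALSE)
  r_src <- max(1, 1 - dy):min(n, n - dy)
  c_src <- max(1, 1 - dx):min(m, m - dx)
  a <- levels[r_src, c_src, drop = FALSE]
  b <- levels[r_src + dy, c_src + dx, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid pixel pairs for this offset", call. = FALSE)
  code <- a[ok] * n_levels + b[ok] + 1
  counts <- matrix(0, n_levels, n_levels)
  tab <- tabulate(code, nbins = n_levels * n_levels)
  counts <- matrix(tab, n_levels, n_levels, byrow = TRUE)
  structure(list(counts = counts, offset = c(dx, dy), n_levels = n_levels,
                 normalized = FALSE),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm %d x %d, offset (%d,%d), %s, total %s>\n",
              x$n_levels, x$n_levels, x$offset[1], x$offset[2],
              if (x$normalized) "normalized" else "raw counts",
              format(sum(x$counts))))
  invisible(x)
}

#' Normalize a GLCM to probabilities
#'
#' @param g a [glcm()].
#' @return The GLCM with entries summing to 1 and `normalized = TRUE`;
#'   idempotent.
#' @export
normalize_glcm <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (g$normalized) return(g)
  tot <- sum(g$counts)
  if (tot <= 0) stop("empty co-occurrence matrix", call. = FALSE)
  g$counts <- g$counts / tot
  g$normalized <- TRUE
  g
}

glcm_probs <- function(g, raw = FALSE) {
  if (raw) return(g$counts)
  if (!g$normalized) {
    message("normalizing co-occurrence matrix before computing statistics")
    g <- normalize_glcm(g)
  }
  g$counts
}

#' Texture energy
#'
#' \eqn{E = \sum_{i,j} p_{ij}^2} on the probability-normalized matrix
#' (`1/N^2 <= E <= 1`); with `raw = TRUE` the statistic is computed on raw
#' counts as the formula is printed in some sources.
#'
#' @param g a [glcm()].
#' @param raw compute on raw counts instead of probabilities.
#' @return Scalar energy.
#' @export
texture_energy <- function(g, raw = FALSE) {
  p <- glcm_probs(g, raw)
  sum(p^2)
}

#' Texture entropy
#'
#' \eqn{H = -\sum_{i,j} p_{ij} \log_2 p_{ij}} with \eqn{0 \log 0 := 0}. The
#' conventional sign makes entropy nonnegative; `signed = TRUE` drops the
#' minus sign (the raw summation form), which is negative for probabilities.
#'
#' @param g a [glcm()].
#' @param signed return the signed summation \eqn{\sum p \log_2 p}.
#' @param raw compute on raw counts instead of probabilities.
#' @return Scalar entropy in bits.
#' @export
texture_entropy <- function(g, signed = FALSE, raw = FALSE) {
  p <- glcm_probs(g, raw)
  p <- p[p > 0]
  h <- sum(p * log2(p))
  if (signed) h else -h
}

#' Texture contrast
#'
#' \eqn{C = \sum_{i,j} (i - j)^2 p_{ij}}; zero exactly when all mass lies on
#' the diagonal.
#'
#' @param g a [glcm()].
#' @param raw compute on raw counts instead of probabilities.
#' @return Scalar contrast.
#' @export
texture_contrast <- function(g, raw = FALSE) {
  p <- glcm_probs(g, raw)
  lv <- seq_len(g$n_levels) - 1
  w <- outer(lv, lv, `-`)^2
  sum(w * p)
}

#' Extract the three texture features of a leaf image
#'
#' @param image a [leaf_image()].
#' @param mask logical mask of leaf-tissue pixels.
#' @param offset GLCM displacement `c(dx, dy)`. Default `c(1, 0)`.
#' @return Named vector `c(energy, entropy, contrast)`.
#' @export
texture_features <- function(image, mask, offset = c(1, 0)) {
  lev <- degrade_gray(image, mask)
  g <- normalize_glcm(glcm(lev, offset))
  c(energy = texture_energy(g), entropy = texture_entropy(g),
    contrast = texture_contrast(g))
}
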