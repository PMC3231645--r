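#' Color features: per-channel variance over the leaf
#'
#' The three color features are the population variances (divide by `n`) of
#' the red, green and blue channels over the leaf-mask pixels only; the
#' uniform background would otherwise dominate the statistic. A constant
#' channel has variance 0.
#'
#' @param image a [leaf_image()].
#' @param mask logical leaf mask (e.g. from [binarize()]); only `TRUE`
#'   pixels enter the statistic.
#' @return A named numeric vector `c(var_r, var_g, var_b)`.
#' @export
rgb_variance <- function(image, mask) {
  stopifnot(inherits(image, "leaf_image"), is.logical(mask))
  if (!any(mask)) stop("empty leaf mask", call. = FALSE)
  px <- image$pixels
  pop_var <- function(x) mean((x - mean(x))^2)
  c(var_r = pop_var(px[, , 1][mask]),
    var_g = pop_var(px[, , 2][mask]),
    var_b = pop_var(px[, , 3][mask]))
}
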