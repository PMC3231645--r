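#' Feature names in canonical order
#'
#' The pipeline's interchange order: three shape features (area, perimeter,
#' disfigurement), three texture features (energy, entropy, contrast), three
#' color features (red/green/blue channel variance).
#'
#' @return Character vector of the nine feature names.
#' @export
feature_names <- function() {
  c("area_px", "perimeter_px", "disfigurement_pct",
    "energy", "entropy", "contrast",
    "var_r", "var_g", "var_b")
}

#' Extract the nine-feature vector from a leaf image
#'
#' Runs the full feature-extraction chain once per image: segmentation,
#' LoG contour and polygonal fit for the shape features; 32-level GLCM for
#' the texture features; channel variances for the color features. Texture
#' and color are measured over leaf tissue only (mask pixels that are not
#' background-colored, i.e. excluding holes).
#'
#' @param image a [leaf_image()].
#' @param config an [edge_config()].
#' @param tolerance_px polygonal fitting tolerance. Default 2.
#' @param glcm_offset GLCM displacement. Default `c(1, 0)`.
#' @param bg_tolerance per-channel background-match tolerance. Default 10.
#' @return Named numeric vector of the nine features, in [feature_names()]
#'   order.
#' @export
extract_features <- function(image, config = edge_config(), tolerance_px = 2,
                             glcm_offset = c(1, 0), bg_tolerance = 10) {
  mask <- binarize(image, config)
  contour <- extract_contour(image, config, mask = mask)
  sf <- shape_features(image, config, tolerance_px, contour = contour)
  px <- image$pixels
  bg <- image$background_rgb
  is_bg <- abs(px[, , 1] - bg[1]) <= bg_tolerance &
    abs(px[, , 2] - bg[2]) <= bg_tolerance &
    abs(px[, , 3] - bg[3]) <= bg_tolerance
  tissue <- mask & !is_bg
  cf <- rgb_variance(image, tissue)
  tf <- texture_features(image, tissue, offset = glcm_offset)
  out <- c(sf$area_px, sf$perimeter_px, sf$disfigurement_pct,
           tf[["energy"]], tf[["entropy"]], tf[["contrast"]],
           cf[["var_r"]], cf[["var_g"]], cf[["var_b"]])
  names(out) <- feature_names()
  out
}

#' Write a feature table as CSV
#'
#' @param features matrix or data frame of feature rows (columns in
#'   [feature_names()] order), with optional `path` and `label` columns
#'   prepended.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
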