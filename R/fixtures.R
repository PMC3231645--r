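#' Load a reference feature table or the worked example
#'
#' Machine-readable transcriptions of the reference tables ship with the
#' package: shape features of sample leaves (`"table1"`), their color
#' (`"table2"`) and texture (`"table3"`) features, the class-mean features of
#' the standard specimens (`"table4"`), the features of one test leaf
#' (`"table5"`), the membership grades of that leaf's nine features
#' (`"table6"`), and the printed worked-example vectors with discrepancy
#' flags (`"worked_example"`). Values are stored verbatim; where a printed
#' value disagrees with recomputation, the fixture records both (see the
#' `notes` field). The table-4/5 feature magnitudes are demo inputs only -
#' the source images were never deposited, so they are not regeneration
#' targets.
#'
#' @param table_id one of `"table1"` .. `"table6"`, `"worked_example"`.
#' @return An object of class `paper_fixture`: `table_id`, `data` (a data
#'   frame, or a list for the worked example), `notes`. For `"table6"` the
#'   element `membership_matrices` holds the three sub-factor evaluation
#'   matrices (rows = sub-factors, columns = classes).
#' @export
load_fixture <- function(table_id) {
  files <- c(table1 = "table1_shape.csv", table2 = "table2_color.csv",
             table3 = "table3_texture.csv", table4 = "table4_class_means.csv",
             table5 = "table5_test_leaf.csv", table6 = "table6_membership.csv",
             worked_example = "worked_example.json")
  if (!table_id %in% names(files))
    stop(sprintf("unknown fixture '%s'; known: %s", table_id,
                 paste(names(files), collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", files[[table_id]], package = "leafgrade",
                      mustWork = TRUE)
  notes <- character(0)
  if (table_id == "worked_example") {
    data <- jsonlite::read_json(path, simplifyVector = TRUE)
    notes <- c("printed B2/B3 and V2 entries carry discrepancy flags where",
               "they disagree with recomputation from the membership table")
  } else {
    data <- utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  out <- list(table_id = table_id, data = data, notes = notes)
  if (table_id == "table6") {
    m <- as.matrix(data[, -1])
    rownames(m) <- data$class
    out$membership_matrices <- list(
      shape = t(m[, 1:3]), texture = t(m[, 4:6]), color = t(m[, 7:9])
    )
    notes <- "columns are per-feature membership grades; each sums to 1"
  }
  out$notes <- notes
  structure(out, class = "paper_fixture")
}

#' @export
print.paper_fixture <- function(x, ...) {
  cat(sprintf("<paper_fixture %s>\n", x$table_id))
  if (is.data.frame(x$data)) utils::head(x$data) else utils::str(x$data)
  invisible(x)
}
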