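#' @title Two-level fuzzy comprehensive evaluation
#' @description The factor set has three categories (shape, texture, color),
#'   each with three sub-factors. Within a category, the sub-factor weight
#'   vector composes the 3 x 3 membership matrix into a one-level evaluation
#'   vector `B_i = A_i . R_i`; across categories the category weights compose
#'   the stacked `B` into the two-level vector `V = A . B`, which is
#'   normalized to sum to one and decided by arg-max. Composition is the
#'   weighted-average operator `M(.,+)` - it exactly reproduces the reference
#'   worked example, which max-min composition does not - and preserves unit
#'   mass: if every membership row and every weight vector sums to 1, so do
#'   each `B_i` and `V`.
#' @name fce-engine
NULL

check_weights <- function(w, what, n = 3) {
  if (length(w) != n || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop(sprintf("%s must be %d nonnegative weights summing to 1", what, n),
         call. = FALSE)
  as.numeric(w)
}

#' Weight configuration for the two-level evaluation
#'
#' Defaults are the reference values: category weights
#' `A = (0.35, 0.2, 0.45)` (shape, texture, color - color judged most
#' informative, texture least) and sub-factor weights `A1 = (0.3, 0.4, 0.3)`,
#' `A2 = (0.4, 0.3, 0.3)`, `A3 = (0.3, 0.3, 0.4)`.
#'
#' @param A category weights (shape, texture, color).
#' @param A1,A2,A3 sub-factor weights within each category.
#' @return An object of class `fce_weights`.
#' @export
fce_weights <- function(A = c(0.35, 0.2, 0.45),
                        A1 = c(0.3, 0.4, 0.3),
                        A2 = c(0.4, 0.3, 0.3),
                        A3 = c(0.3, 0.3, 0.4)) {
  structure(list(A = check_weights(A, "A"),
                 A1 = check_weights(A1, "A1"),
                 A2 = check_weights(A2, "A2"),
                 A3 = check_weights(A3, "A3")),
            class = "fce_weights")
}

#' Read a weight configuration from YAML or JSON
#'
#' Expects a mapping `weights: {A: [...], A1: [...], A2: [...], A3: [...]}`
#' (or the same four vectors at the top level).
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return An [fce_weights()].
#' @export
read_weights <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML weight files",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(obj$weights)) obj <- obj$weights
  fce_weights(A = unlist(obj$A), A1 = unlist(obj$A1), A2 = unlist(obj$A2),
              A3 = unlist(obj$A3))
}

check_membership_matrix <- function(R, what = "R") {
  R <- as.matrix(R)
  if (any(R < 0) || any(R > 1))
    stop(sprintf("%s entries must lie in [0, 1]", what), call. = FALSE)
  if (any(abs(rowSums(R) - 1) > 1e-6))
    stop(sprintf("%s rows must sum to 1", what), call. = FALSE)
  R
}

#' One-level fuzzy evaluation
#'
#' `B_i[c] = sum_f A_i[f] R_i[f, c]`: the weighted-average composition of a
#' sub-factor weight vector with a membership matrix.
#'
#' @param A_i sub-factor weight vector (length = rows of `R_i`).
#' @param R_i membership matrix, sub-factors x classes, rows summing to 1.
#' @return The one-level evaluation vector `B_i` (components in `[0, 1]`).
#' @export
one_level <- function(A_i, R_i) {
  R_i <- as.matrix(R_i)
  if (length(A_i) != nrow(R_i))
    stop("weight length must match membership-matrix rows", call. = FALSE)
  as.vector(A_i %*% R_i)
}

#' Two-level fuzzy evaluation
#'
#' `V[c] = sum_i A[i] B[i, c]` over the stacked one-level vectors.
#'
#' @param A category weight vector (length = rows of `B`).
#' @param B matrix whose rows are the one-level vectors `B_i`.
#' @return The two-level evaluation vector `V`.
#' @export
two_level <- function(A, B) {
  B <- as.matrix(B)
  if (length(A) != nrow(B))
    stop("weight length must match the number of one-level vectors",
         call. = FALSE)
  as.vector(A %*% B)
}

#' Normalize an evaluation vector
#'
#' Each component is divided by the component sum; idempotent.
#'
#' @param V evaluation vector with positive sum.
#' @return `V / sum(V)`.
#' @export
normalize_v <- function(V) {
  s <- sum(V)
  if (!is.finite(s) || s <= 0)
    stop("evaluation vector must have a positive sum", call. = FALSE)
  V / s
}

#' Decide the class from an evaluation vector
#'
#' Returns the class of the maximal component; exact ties are broken by the
#' declared class order, with a warning.
#'
#' @param V normalized evaluation vector.
#' @param classes class labels, same length as `V`.
#' @return List with `label` and `memberships` (named `V`).
#' @export
decide_class <- function(V, classes = c("X1L", "B4L", "S1")) {
  if (length(V) != length(classes))
    stop("`V` and `classes` must align", call. = FALSE)
  top <- which(V == max(V))
  if (length(top) > 1)
    warning(sprintf("tie between classes %s; taking the first",
                    paste(classes[top], collapse = ", ")), call. = FALSE)
  list(label = classes[top[1]], memberships = stats::setNames(V, classes))
}

#' Run the full two-level evaluation on membership matrices
#'
#' @param R_list list of three membership matrices (shape, texture, color),
#'   each sub-factors x classes with unit-sum rows.
#' @param weights an [fce_weights()].
#' @param classes class labels in column order.
#' @return An object of class `fce_result`: `R` (the input matrices), `B`
#'   (3 x 3, rows `B1..B3`), `V`, `V_normalized`, `label`, `memberships`.
#' @export
fce_evaluate <- function(R_list, weights = fce_weights(),
                         classes = c("X1L", "B4L", "S1")) {
  stopifnot(inherits(weights, "fce_weights"))
  if (length(R_list) != 3)
    stop("`R_list` must hold the three category matrices", call. = FALSE)
  R_list <- lapply(seq_along(R_list), function(i)
    check_membership_matrix(R_list[[i]], paste0("R", i)))
  sub_w <- list(weights$A1, weights$A2, weights$A3)
  B <- do.call(rbind, lapply(1:3, function(i)
    one_level(sub_w[[i]], R_list[[i]])))
  rownames(B) <- c("B1", "B2", "B3")
  colnames(B) <- classes
  V <- two_level(weights$A, B)
  Vn <- normalize_v(V)
  dec <- decide_class(Vn, classes)
  structure(list(R = R_list, B = B, V = stats::setNames(V, classes),
                 V_normalized = stats::setNames(Vn, classes),
                 label = dec$label, memberships = dec$memberships,
                 weights = weights, classes = classes),
            class = "fce_result")
}

#' Grade one leaf from its nine features
#'
#' Full decision chain: membership matrices from the trained category
#' networks, one-level and two-level composition, normalization, arg-max
#' decision. All intermediates are kept in the result for audit.
#'
#' @param features9 nine-feature vector in [feature_names()] order.
#' @param nets list of three trained category networks
#'   ([train_category_net()]).
#' @param weights an [fce_weights()].
#' @param readout membership readout passed to [build_R()].
#' @return An `fce_result` (see [fce_evaluate()]).
#' @export
grade_leaf <- function(features9, nets, weights = fce_weights(),
                       readout = c("marginal", "clamped")) {
  R_list <- build_R(features9, nets, readout = readout)
  fce_evaluate(R_list, weights, classes = nets[[1]]$classes)
}

#' @export
print.fce_result <- function(x, ...) {
  cat("Two-level fuzzy comprehensive evaluation\n")
  cat("One-level vectors B (rows B1..B3):\n")
  print(round(x$B, 2))
  cat("V          :", paste(sprintf("%.4f", x$V), collapse = " "), "\n")
  cat("V normalized:", paste(sprintf("%.4f", x$V_normalized), collapse = " "),
      "\n")
  cat("Decided class:", x$label, "\n")
  invisible(x)
}
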