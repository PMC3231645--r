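#' @title Membership estimation with a 3-5-3 backpropagation network
#' @description Each factor category (shape, texture, color) gets its own
#'   small feed-forward network: 3 input neurons (the category's features),
#'   5 hidden and 3 output neurons (one per grade class), logistic sigmoid
#'   on both layers. The net is trained by online gradient descent on squared
#'   error against one-hot class targets until every training example's
#'   arg-max output matches its label ("all the output is correct") or an
#'   epoch cap is reached. At prediction time the three outputs are
#'   renormalized to sum to one and read as fuzzy membership grades.
#' @name membership-network
NULL

#' Training configuration for a category network
#'
#' The stopping rule is "all the output is correct", read with a margin:
#' every output neuron must lie within `target_margin` of its one-hot target
#' (so the true-class output is at least `1 - target_margin` and the others
#' at most `target_margin`), which implies arg-max correctness. A bare
#' arg-max check (`target_margin` close to 0.5) stops within a few epochs
#' with barely-differentiated outputs; the margin keeps training until the
#' outputs are usable as membership grades.
#'
#' @param learning_rate online gradient-descent step. Default 0.5.
#' @param max_epochs epoch cap. Default 5000.
#' @param target_margin scalar in `(0, 0.5)`. Default 0.2.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.5, max_epochs = 5000,
                         target_margin = 0.2) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (max_epochs < 1) stop("`max_epochs` must be >= 1", call. = FALSE)
  if (target_margin <= 0 || target_margin >= 0.5)
    stop("`target_margin` must lie in (0, 0.5)", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 target_margin = target_margin),
            class = "train_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass on already-scaled inputs (3-vector) -> raw outputs (3-vector).
mlp_forward_scaled <- function(params, xs) {
  h <- sigmoid(params$W1 %*% xs + params$b1)
  as.vector(sigmoid(params$W2 %*% h + params$b2))
}

scale_inputs <- function(params, x) {
  rng <- params$x_max - params$x_min
  xs <- (x - params$x_min) / ifelse(rng > 0, rng, 1)
  xs[rng == 0] <- 0.5  # constant training feature carries no information
  clamp(xs, 0, 1)
}

#' Train one category's membership network
#'
#' Inputs are min-max scaled to `[0, 1]` using training-set bounds (raw
#' feature magnitudes - areas near 1e4 against variances near 1e2 - would
#' saturate the sigmoids). Weights are initialized uniformly on
#' `(-0.5, 0.5)` from the seed; training is deterministic given (data order,
#' seed, config). Arg-max ties during the stopping check count as incorrect.
#'
#' @param features numeric `n x 3` matrix, one row per specimen.
#' @param labels class label per row; every class must appear at least once
#'   and at least two classes are required.
#' @param config a [train_config()].
#' @param seed integer seed for weight initialization.
#' @param classes class order for the output neurons; defaults to first
#'   appearance order in `labels`.
#' @return An object of class `mlp_params`: weights (`W1` 5x3, `b1`,
#'   `W2` 3x5, `b2`), scaling bounds, scaled training means (used when
#'   memberships are read per sub-factor), `classes`, `epochs`, `converged`.
#' @export
train_category_net <- function(features, labels, config = train_config(),
                               seed = 1, classes = NULL) {
  features <- as.matrix(features)
  if (ncol(features) != 3)
    stop("`features` must have exactly 3 columns", call. = FALSE)
  if (nrow(features) != length(labels))
    stop("`features` rows and `labels` must align", call. = FALSE)
  if (any(!is.finite(features)))
    stop("non-finite feature values", call. = FALSE)
  if (is.null(classes)) classes <- unique(as.character(labels))
  labels <- as.character(labels)
  if (!all(labels %in% classes))
    stop("labels outside the declared class set", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("degenerate data: need at least two classes", call. = FALSE)
  if (!all(classes %in% labels))
    stop("degenerate data: every class needs at least one example",
         call. = FALSE)
  n_class <- length(classes)
  x_min <- apply(features, 2, min)
  x_max <- apply(features, 2, max)
  params <- with_seed(derive_seed(seed, 77), {
    list(W1 = matrix(stats::runif(15, -0.5, 0.5), 5, 3),
         b1 = stats::runif(5, -0.5, 0.5),
         W2 = matrix(stats::runif(5 * n_class, -0.5, 0.5), n_class, 5),
         b2 = stats::runif(n_class, -0.5, 0.5))
  })
  params$x_min <- x_min
  params$x_max <- x_max
  params$classes <- classes

  n <- nrow(features)
  xs <- t(apply(features, 1, function(r) scale_inputs(params, r)))
  targets <- matrix(0, n, n_class)
  targets[cbind(seq_len(n), match(labels, classes))] <- 1
  y_idx <- match(labels, classes)
  lr <- config$learning_rate

  W1 <- params$W1; b1 <- params$b1; W2 <- params$W2; b2 <- params$b2
  converged <- FALSE
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    for (i in seq_len(n)) {
      x <- xs[i, ]
      h <- as.vector(sigmoid(W1 %*% x + b1))
      o <- as.vector(sigmoid(W2 %*% h + b2))
      delta_o <- (o - targets[i, ]) * o * (1 - o)
      delta_h <- as.vector(crossprod(W2, delta_o)) * h * (1 - h)
      W2 <- W2 - lr * tcrossprod(delta_o, h)
      b2 <- b2 - lr * delta_o
      W1 <- W1 - lr * tcrossprod(delta_h, x)
      b1 <- b1 - lr * delta_h
    }
    # stopping rule: every training example's outputs within target_margin
    # of the one-hot target, which implies strict arg-max correctness
    # (ties count as incorrect)
    H <- sigmoid(tcrossprod(xs, W1) + matrix(b1, n, 5, byrow = TRUE))
    O <- sigmoid(tcrossprod(H, W2) + matrix(b2, n, n_class, byrow = TRUE))
    top <- max.col(O, ties.method = "first")
    top2 <- max.col(O, ties.method = "last")
    if (all(top == y_idx & top2 == y_idx) &&
        max(abs(O - targets)) <= config$target_margin) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("training stopped at max_epochs before all outputs were correct",
            call. = FALSE)
  params$W1 <- W1; params$b1 <- b1; params$W2 <- W2; params$b2 <- b2
  params$x_mean_scaled <- colMeans(xs)
  params$x_train_scaled <- xs
  params$y_train <- labels
  params$epochs <- epoch
  params$converged <- converged
  params$seed <- as.integer(seed)
  params$learning_rate <- lr
  class(params) <- "mlp_params"
  params
}

# Vectorized forward pass over the rows of a scaled input matrix.
mlp_forward_matrix <- function(params, X) {
  n <- nrow(X)
  H <- sigmoid(tcrossprod(X, params$W1) + matrix(params$b1, n, 5, byrow = TRUE))
  sigmoid(tcrossprod(H, params$W2) +
            matrix(params$b2, n, length(params$classes), byrow = TRUE))
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("<mlp_params 3-5-%d: classes %s, %d epochs%s>\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$epochs, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict membership grades for one feature triple
#'
#' The network outputs (each in `(0, 1)`) are divided by their sum, giving a
#' membership vector over the classes that sums to one.
#'
#' @param params trained [train_category_net()] parameters.
#' @param features numeric 3-vector on the raw feature scale.
#' @return Named membership vector summing to 1.
#' @export
predict_membership <- function(params, features) {
  stopifnot(inherits(params, "mlp_params"), length(features) == 3)
  o <- mlp_forward_scaled(params, scale_inputs(params, as.numeric(features)))
  s <- sum(o)
  if (s < 1e-12) stop("network outputs vanished; cannot normalize",
                      call. = FALSE)
  stats::setNames(o / s, params$classes)
}

#' Build the three sub-factor evaluation matrices
#'
#' The category network takes all three features jointly, but the evaluation
#' matrix needs one membership row per single sub-factor: the degree to which
#' that feature value alone supports each class. Two readouts of the trained
#' net are provided.
#'
#' `"marginal"` (default): for sub-factor `j` the net is evaluated over the
#' whole training set with feature `j` replaced by the observed (scaled)
#' value and the other two inputs kept at each specimen's own values; the
#' normalized outputs are averaged per class and then across classes
#' (a uniform class prior). This marginalizes the unobserved features over
#' the empirical data distribution, so the network is only ever evaluated
#' near feature combinations it was trained on, and the row approximates the
#' marginal class membership of the single feature: uninformative features
#' yield near-uniform rows rather than arbitrary ones.
#'
#' `"clamped"`: the other two inputs are clamped to their scaled training-set
#' means and the net is evaluated once. Simpler, but the probe point is a
#' feature combination the net never saw (and the clamped means themselves
#' carry class evidence), so rows for weakly informative features can be
#' biased arbitrarily.
#'
#' Each row of each returned matrix sums to 1.
#'
#' @param features9 named or ordered nine-feature vector
#'   (see [feature_names()]).
#' @param nets list of three trained [train_category_net()] parameter sets,
#'   in category order (shape, texture, color).
#' @param readout `"marginal"` (default) or `"clamped"`.
#' @return A list of three `3 x 3` membership matrices (rows = sub-factors,
#'   columns = classes), named `shape`, `texture`, `color`.
#' @export
build_R <- function(features9, nets, readout = c("marginal", "clamped")) {
  if (length(nets) != 3 || !all(vapply(nets, inherits, TRUE, "mlp_params")))
    stop("`nets` must be three trained category networks", call. = FALSE)
  readout <- match.arg(readout)
  features9 <- as.numeric(features9)
  if (length(features9) != 9)
    stop("`features9` must have nine entries", call. = FALSE)
  cats <- c("shape", "texture", "color")
  out <- vector("list", 3)
  for (i in 1:3) {
    params <- nets[[i]]
    f <- features9[(3 * i - 2):(3 * i)]
    fs <- scale_inputs(params, f)
    rows <- matrix(0, 3, length(params$classes))
    for (j in 1:3) {
      if (readout == "marginal") {
        if (is.null(params$x_train_scaled))
          stop("marginal readout needs the training data stored in `nets`",
               call. = FALSE)
        X <- params$x_train_scaled
        X[, j] <- fs[j]
        O <- mlp_forward_matrix(params, X)
        s <- rowSums(O)
        if (any(s < 1e-12)) stop("network outputs vanished; cannot normalize",
                                 call. = FALSE)
        M <- O / s
        by_class <- rowsum(M, params$y_train) /
          as.vector(table(params$y_train))
        r <- colMeans(by_class)
      } else {
        xin <- params$x_mean_scaled
        xin[j] <- fs[j]
        r <- mlp_forward_scaled(params, xin)
        if (sum(r) < 1e-12) stop("network outputs vanished; cannot normalize",
                                 call. = FALSE)
      }
      rows[j, ] <- r / sum(r)
    }
    dimnames(rows) <- list(paste0("U", i, 1:3), params$classes)
    out[[i]] <- rows
  }
  names(out) <- cats
  out
}

#' Save or load trained category networks as JSON
#'
#' @param nets list of three [train_category_net()] parameter sets.
#' @param path JSON file path.
#' @return `path` invisibly for save; the list of `mlp_params` for load.
#' @export
save_models <- function(nets, path) {
  ser <- lapply(nets, function(p) {
    list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
         x_min = p$x_min, x_max = p$x_max,
         x_mean_scaled = p$x_mean_scaled,
         x_train_scaled = p$x_train_scaled, y_train = p$y_train,
         classes = p$classes,
         epochs = p$epochs, converged = p$converged, seed = p$seed,
         learning_rate = p$learning_rate)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  as_mat <- function(x, nc) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = nc, byrow = TRUE)
  }
  lapply(ser, function(p) {
    p$W1 <- as_mat(p$W1, 3)
    p$W2 <- as_mat(p$W2, 5)
    if (!is.null(p$x_train_scaled))
      p$x_train_scaled <- as_mat(p$x_train_scaled, 3)
    p$classes <- as.character(p$classes)
    p$y_train <- as.character(p$y_train)
    class(p) <- "mlp_params"
    p
  })
}
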