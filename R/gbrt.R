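#' Fit a single least-squares regression tree
#'
#' Greedy top-down splitting that maximises the squared-error reduction of
#' the residual vector.  Split candidates are midpoints between
#' consecutive distinct sorted values of each feature; equal-gain ties are
#' broken towards the lowest feature index, then the lowest threshold, so
#' fitting is fully deterministic.  Leaves predict the mean residual of
#' their samples.
#'
#' @param x Numeric matrix (samples x features).
#' @param r Numeric residual vector, one per row of `x`.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum samples per leaf.
#' @return A `gbrt_tree`: list of parallel node arrays (`feature`
#'   0-based, -1 for leaves; `threshold`; `left`/`right` 0-based child
#'   indices; `value` node means).
#' @export
fit_tree <- function(x, r, max_depth = 8, min_leaf = 1) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty input")
  if (length(r) != nrow(x) || any(!is.finite(r))) stop("residuals must be finite, one per sample")
  tree <- fit_tree_cpp(x, as.numeric(r), as.integer(max_depth), as.integer(min_leaf))
  class(tree) <- "gbrt_tree"
  tree
}

#' Predict from a single regression tree
#'
#' @param tree A `gbrt_tree` from [fit_tree()].
#' @param x Numeric matrix of samples.
#' @return Numeric vector of leaf values (routing left iff
#'   `x[, feature] <= threshold`).
#' @export
predict_tree <- function(tree, x) {
  predict_tree_cpp(unclass(tree), as.matrix(x))
}

#' Fit a gradient-boosted regression-tree model
#'
#' Additive model `f(x) = F0 + sum_m eps * T_m(x)` trained by
#' least-squares boosting on 0/1 labels: each depth-limited tree is fit to
#' the residuals of the ensemble so far, then added with shrinkage `eps`.
#' The defaults (`n_trees = 2000`, `shrinkage = 0.005`, `max_depth = 8`,
#' base score 0) are the model's standard operating point; there is no
#' row or feature subsampling and no early stopping, so two fits on
#' identical inputs produce bit-identical models.
#'
#' @param x Numeric matrix (samples x features) or a `variant_features`
#'   object, in which case labels are taken from its variant table unless
#'   supplied.
#' @param y Numeric 0/1 labels (1 = disease-associated, 0 = neutral).
#' @param n_trees Number of boosting iterations.
#' @param shrinkage Learning rate `eps`.
#' @param max_depth Maximum tree depth.
#' @param min_leaf Minimum samples per leaf (default 5: single-sample
#'   leaves at depth 8 overfit pathologically on small data).
#' @param feature_config Optional `feature_config` tag recorded in the
#'   model (taken from a `variant_features` input automatically).
#' @return A `gbrt` model: trees, `shrinkage`, `base_score`, `mse_path`
#'   (training mean-squared error after each iteration) and the feature
#'   configuration/names used.
#' @export
gbrt_fit <- function(x, y = NULL, n_trees = 2000, shrinkage = 0.005,
                     max_depth = 8, min_leaf = 5, feature_config = NULL) {
  if (inherits(x, "variant_features")) {
    if (is.null(y)) {
      if (!"label" %in% names(x$variants)) stop("no labels in variant_features and none supplied")
      y <- x$variants$label
    }
    feature_config <- feature_config %||% x$config
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("labels must match rows of x")
  if (any(is.na(y)) || !all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  fit <- fit_gbrt_cpp(x, y, as.integer(n_trees), shrinkage,
                      as.integer(max_depth), as.integer(min_leaf), 0)
  out <- list(
    trees = fit$trees,
    shrinkage = shrinkage,
    base_score = 0,
    n_trees = length(fit$trees),
    max_depth = max_depth,
    min_leaf = min_leaf,
    feature_names = colnames(x),
    feature_config = feature_config,
    n_features = ncol(x),
    mse_path = fit$mse_path,
    train_mse = if (n_trees > 0) fit$mse_path[n_trees] else mean(y^2)
  )
  class(out) <- "gbrt"
  out
}

#' @export
print.gbrt <- function(x, ...) {
  cat(sprintf(
    "<gbrt> %d trees, shrinkage %g, depth <= %d, %d features%s\n",
    x$n_trees, x$shrinkage, x$max_depth, x$n_features,
    if (!is.null(x$feature_config)) sprintf(" (config '%s')", x$feature_config$name) else ""
  ))
  invisible(x)
}

#' Score samples with a boosted-tree model
#'
#' @param object A `gbrt` model.
#' @param newdata Numeric matrix (or `variant_features`) whose column count
#'   matches the model.
#' @param type `"score"` for the raw regression score, `"class"` for the
#'   thresholded disease/neutral call.
#' @param cutoff Classification cutoff (used for `type = "class"`).
#' @param ... Unused.
#' @return Numeric scores, or a character vector of
#'   `"disease"`/`"neutral"` calls.
#' @export
predict.gbrt <- function(object, newdata, type = c("score", "class"),
                         cutoff = 0.45, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "variant_features")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("feature length mismatch: model expects %d, got %d",
                 object$n_features, ncol(newdata)))
  }
  scores <- predict_gbrt_cpp(object$trees, newdata, object$shrinkage, object$base_score)
  if (type == "score") scores else classify_score(scores, cutoff)
}

#' Threshold scores into disease/neutral calls
#'
#' A variant is called disease-associated iff its score is strictly
#' greater than the cutoff.  The default cutoff 0.45 optimises the MCC on
#' training data; 0.55 trades recall for a lower false-positive rate and
#' 0.20 does the reverse.
#'
#' @param score Numeric score(s).
#' @param cutoff Decision cutoff.
#' @return Character vector of `"disease"` / `"neutral"`.
#' @export
classify_score <- function(score, cutoff = 0.45) {
  if (any(!is.finite(score))) stop("scores must be finite")
  ifelse(score > cutoff, "disease", "neutral")
}

#' Score a variant table and attach calls
#'
#' @param model A `gbrt` model.
#' @param features A `variant_features` object (same configuration as the
#'   model).
#' @param cutoff Decision cutoff for the class column.
#' @return The feature object's variant tibble with `score` and `class`
#'   columns appended.
#' @export
predict_variants <- function(model, features, cutoff = 0.45) {
  stopifnot(inherits(features, "variant_features"))
  scores <- predict(model, features$x)
  dplyr::mutate(features$variants,
                score = scores,
                class = classify_score(scores, cutoff))
}

#' Per-tree summary of a boosted model
#'
#' @param x A `gbrt` model.
#' @param ... Unused.
#' @return A tibble with one row per tree: node and leaf counts and the
#'   training MSE after the tree was added.
#' @export
tidy.gbrt <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(x$n_trees),
    n_nodes = vapply(x$trees, function(t) length(t$feature), integer(1)),
    n_leaves = vapply(x$trees, function(t) sum(t$feature < 0), integer(1)),
    train_mse = as.numeric(x$mse_path)
  )
}

#' One-row summary of a boosted model
#'
#' @param x A `gbrt` model.
#' @param ... Unused.
#' @return A one-row tibble of hyperparameters and final training MSE.
#' @export
glance.gbrt <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    shrinkage = x$shrinkage,
    max_depth = x$max_depth,
    min_leaf = x$min_leaf,
    n_features = x$n_features,
    config = if (is.null(x$feature_config)) NA_character_ else x$feature_config$name,
    train_mse = x$train_mse
  )
}
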