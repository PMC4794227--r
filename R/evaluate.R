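normalize_calls <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (!all(x %in% c("disease", "neutral"))) {
      stop("calls must be 'disease' or 'neutral' (or 0/1)")
    }
    as.integer(x == "disease")
  } else {
    x <- as.integer(x)
    if (any(is.na(x)) || !all(x %in% c(0L, 1L))) stop("calls must be 0/1")
    x
  }
}

#' Confusion counts for disease/neutral calls
#'
#' Positives are disease-associated variations.
#'
#' @param pred Predicted calls (`"disease"`/`"neutral"`, or 0/1).
#' @param labels True labels in the same encoding.
#' @return A `confusion_counts` one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred, labels) {
  p <- normalize_calls(pred)
  y <- normalize_calls(labels)
  if (length(p) != length(y)) stop("length mismatch between predictions and labels")
  out <- tibble::tibble(
    tp = sum(p == 1 & y == 1),
    tn = sum(p == 0 & y == 0),
    fp = sum(p == 1 & y == 0),
    fn = sum(p == 0 & y == 1)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Binary classification metrics from confusion counts
#'
#' Computes the Matthews correlation coefficient
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`,
#' accuracy, sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' and negative predictive values.  When any factor of the MCC denominator
#' is zero (a degenerate table) the MCC is defined as 0; an undefined PPV
#' or NPV (empty predicted class) is reported as `NA`, not 0.
#'
#' @param counts A `confusion_counts` row (or anything with tp/tn/fp/fn).
#' @return A one-row tibble: counts plus `MCC`, `ACC`, `Sen`, `Spe`,
#'   `PPV`, `NPV`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  tibble::tibble(
    tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    MCC = mcc,
    ACC = (tp + tn) / total,
    Sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    Spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Area under the ROC curve (rank formulation)
#'
#' AUC is computed as the probability that a randomly chosen
#' disease-associated variation scores higher than a randomly chosen
#' neutral one, counting ties as 1/2 — the Mann-Whitney rank formulation,
#' which is exact under ties (no trapezoid approximation needed).
#'
#' @param scores Numeric scores (higher = more disease-like).
#' @param labels True labels (0/1 or `"disease"`/`"neutral"`); both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- normalize_calls(labels)
  if (length(scores) != length(y)) stop("length mismatch")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Emits one `(FPR, TPR)` point per distinct score threshold (calls are
#' `score >= threshold`), plus the trivial end points.
#'
#' @inheritParams roc_auc
#' @return An `entvar_roc` tibble with columns `threshold`, `FPR`, `TPR`.
#' @export
roc_curve <- function(scores, labels) {
  y <- normalize_calls(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(
      threshold = t,
      FPR = sum(scores >= t & y == 0) / n_neg,
      TPR = sum(scores >= t & y == 1) / n_pos
    )
  })
  out <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, FPR = 0, TPR = 0),
    pts,
    tibble::tibble(threshold = -Inf, FPR = 1, TPR = 1)
  )
  class(out) <- c("entvar_roc", class(out))
  out
}

#' False-positive rate on an all-neutral variant set
#'
#' For a set where every variation is (assumed) neutral, the
#' false-positive rate is simply the fraction called disease-associated:
#' `fp / (fp + tn)`.
#'
#' @param pred Predicted calls on the all-neutral set.
#' @return Fraction in \[0, 1\].
#' @export
false_positive_rate <- function(pred) {
  p <- normalize_calls(pred)
  if (length(p) == 0) stop("empty prediction set")
  mean(p == 1)
}

#' Cross-dataset regression of false-positive rates
#'
#' Ordinary least squares of one benchmark's per-method FPR on another's,
#' with the Pearson correlation of the pairs.  When two putatively neutral
#' benchmarks are compared across several methods, the fit's value at
#' `x = 0` (the intercept) estimates the apparent contamination — the
#' residual true-positive fraction — of the `y`-axis set.
#'
#' @param pairs Tibble (or data frame) with numeric columns `x` and `y`,
#'   one row per method; at least 3 rows.
#' @return A one-row tibble: `slope`, `intercept`, `pearson_r`, `n`.
#' @export
fpr_cross_regression <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 (x, y) pairs")
  if (stats::sd(pairs$x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x, data = pairs)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = stats::cor(pairs$x, pairs$y),
    n = nrow(pairs)
  )
}

#' Full evaluation report for scored variants
#'
#' Bundles the thresholded confusion counts, the derived metrics and the
#' threshold-free AUC for one scored, labelled variant set.
#'
#' @param scores Numeric scores.
#' @param labels True 0/1 labels (both classes present).
#' @param cutoff Decision cutoff for the thresholded metrics.
#' @return A one-row tibble: `cutoff`, counts, `MCC`, `ACC`, `Sen`, `Spe`,
#'   `PPV`, `NPV`, `AUC`.
#' @export
evaluation_report <- function(scores, labels, cutoff = 0.45) {
  m <- classification_metrics(confusion(classify_score(scores, cutoff), labels))
  dplyr::bind_cols(tibble::tibble(cutoff = cutoff), m,
                   tibble::tibble(AUC = roc_auc(scores, labels)))
}
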