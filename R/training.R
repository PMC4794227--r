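#' Per-protein balance status of a labelled variant set
#'
#' A protein is *balanced* when it has at least one disease-associated
#' variation and its neutral/disease ratio lies in `[lower, upper]`
#' (inclusive; defaults 0.3 and 3.0).  Proteins without disease variations
#' have ratio `Inf` and are unbalanced.
#'
#' @param variants Labelled variant tibble (`label` 0/1).
#' @param lower,upper Inclusive ratio bounds.
#' @return A tibble with one row per protein: `protein_id`, `n_disease`,
#'   `n_neutral`, `ratio`, `balanced`.
#' @export
balance_status <- function(variants, lower = 0.3, upper = 3.0) {
  if (!"label" %in% names(variants) || any(is.na(variants$label))) {
    stop("balance_status requires complete 0/1 labels")
  }
  out <- dplyr::summarise(
    dplyr::group_by(variants, .data$protein_id),
    n_disease = sum(.data$label == 1),
    n_neutral = sum(.data$label == 0),
    .groups = "drop"
  )
  dplyr::mutate(
    out,
    ratio = ifelse(.data$n_disease > 0, .data$n_neutral / .data$n_disease, Inf),
    balanced = .data$n_disease > 0 & .data$ratio >= lower & .data$ratio <= upper
  )
}

#' Over-sample variations on balanced proteins
#'
#' Replicates every variation on a balanced protein so it appears
#' `copies` times in total (the default 6 means the original plus five
#' replicas); variations on unbalanced proteins pass through once.  This
#' counters the dominance of neutral variations on neutral-only proteins
#' during training: after over-sampling, neutral variations on balanced
#' and unbalanced proteins are roughly equally numerous.  Balance is
#' assessed on the supplied (training) set itself, and over-sampling
#' should be applied to the training side only, after splitting.
#'
#' @param variants Labelled variant tibble.
#' @param copies Total copies of each balanced-protein variation (>= 1).
#' @param lower,upper Balance-ratio bounds, see [balance_status()].
#' @return The augmented variant tibble
#'   (`copies * n_balanced + n_unbalanced` rows).
#' @export
oversample_balanced <- function(variants, copies = 6, lower = 0.3, upper = 3.0) {
  if (copies < 1) stop("copies must be >= 1")
  status <- balance_status(variants, lower, upper)
  balanced_ids <- status$protein_id[status$balanced]
  w <- ifelse(variants$protein_id %in% balanced_ids, as.integer(copies), 1L)
  tidyr::uncount(dplyr::mutate(variants, .copies = w), weights = .data$.copies)
}

#' Random variation-level train/test split
#'
#' Disjoint, exhaustive and reproducible for a fixed seed; at
#' `fraction = 0.5` the two sides differ in size by at most one.
#'
#' @param variants Variant tibble.
#' @param fraction Fraction assigned to the training side.
#' @param seed Integer seed (required: splits must be reproducible).
#' @return A list with elements `train` and `test`.
#' @export
split_variants <- function(variants, fraction = 0.5, seed) {
  if (missing(seed)) stop("a seed is required for a reproducible split")
  n <- nrow(variants)
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(fraction * n + 0.5)
  list(
    train = variants[sort(perm[seq_len(n_train)]), , drop = FALSE],
    test = variants[sort(perm[setdiff(seq_len(n), seq_len(n_train))]), , drop = FALSE]
  )
}

#' Group-aware k-fold cross-validation splits
#'
#' Assigns whole groups (e.g. protein families) to folds so that no group
#' ever appears on both sides of a fold — the hardest evaluation setting,
#' where test variations share no family with the training set.  Groups
#' are shuffled by seed, then greedily packed largest-first into the
#' currently smallest fold (by variant count), which keeps fold sizes
#' balanced.
#'
#' @param variants Variant tibble.
#' @param group_of Tibble with columns `protein_id` and `group`, or a
#'   named character vector mapping protein id to group label.  Every
#'   protein in `variants` must be covered.
#' @param k Number of folds (must not exceed the number of groups).
#' @param seed Integer seed.
#' @return A list of `k` elements, each `list(train = , test = )`; the
#'   test sides partition `variants`.
#' @export
grouped_kfold <- function(variants, group_of, k = 10, seed) {
  if (missing(seed)) stop("a seed is required for reproducible folds")
  if (is.data.frame(group_of)) {
    group_map <- stats::setNames(as.character(group_of$group), group_of$protein_id)
  } else {
    group_map <- group_of
  }
  missing_ids <- setdiff(unique(variants$protein_id), names(group_map))
  if (length(missing_ids) > 0) {
    stop("no group label for protein(s): ", paste(missing_ids, collapse = ", "))
  }
  grp <- unname(group_map[variants$protein_id])
  groups <- unique(grp)
  if (k > length(groups)) stop("k exceeds the number of groups")
  sizes <- table(grp)[groups]
  order_seeded <- withr::with_seed(seed, sample(seq_along(groups)))
  groups <- groups[order_seeded]
  sizes <- as.integer(sizes[order_seeded])
  ord <- order(-sizes)  # largest first; ties keep shuffled order
  fold_of_group <- integer(length(groups))
  fold_sizes <- integer(k)
  for (g in ord) {
    f <- which.min(fold_sizes)
    fold_of_group[g] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[g]
  }
  fold_of_row <- fold_of_group[match(grp, groups)]
  lapply(seq_len(k), function(f) {
    list(
      train = variants[fold_of_row != f, , drop = FALSE],
      test = variants[fold_of_row == f, , drop = FALSE]
    )
  })
}

#' Remove common variants by allele frequency
#'
#' Variants whose population allele frequency is at or above the
#' threshold (default 0.17) are assumed neutral and removed before
#' annotation; variants with no recorded frequency are kept.  The default
#' reflects the observation that common exome variants are almost never
#' disease-associated, and typically shrinks an exome's candidate list to
#' about a quarter.
#'
#' @param variants Variant tibble with an optional `allele_freq` column.
#' @param threshold Removal threshold (inclusive).
#' @return The filtered tibble.
#' @export
allele_frequency_filter <- function(variants, threshold = 0.17) {
  if (!"allele_freq" %in% names(variants)) return(variants)
  keep <- is.na(variants$allele_freq) | variants$allele_freq < threshold
  variants[keep, , drop = FALSE]
}
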