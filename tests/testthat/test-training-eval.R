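make_labelled <- function(counts) {
  # counts: list of c(n_disease, n_neutral) per protein
  dplyr::bind_rows(purrr::imap(counts, function(cnt, id) {
    n <- sum(cnt)
    tibble::tibble(
      protein_id = id,
      position = seq_len(n) + 1L,
      wild_aa = "A",
      mutant_aa = "V",
      label = rep(c(1L, 0L), times = cnt)
    )
  }))
}

test_that("balance status applies inclusive ratio bounds and requires disease variants", {
  v <- make_labelled(list(even = c(3, 3), skewed = c(1, 4), neutral_only = c(0, 5),
                          low_edge = c(10, 3), high_edge = c(1, 3)))
  st <- balance_status(v)
  st <- st[match(c("even", "skewed", "neutral_only", "low_edge", "high_edge"), st$protein_id), ]
  expect_equal(st$ratio, c(1, 4, Inf, 0.3, 3))
  expect_equal(st$balanced, c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("over-sampling replicates balanced-protein variations to six copies", {
  v <- make_labelled(list(bal = c(2, 3), unbal = c(0, 4)))
  out <- oversample_balanced(v, copies = 6)
  expect_equal(nrow(out), 6 * 5 + 4)
  counts <- dplyr::count(out, .data$protein_id, .data$label)
  expect_equal(counts$n[counts$protein_id == "bal" & counts$label == 1], 12)
  expect_equal(counts$n[counts$protein_id == "bal" & counts$label == 0], 18)
  expect_equal(counts$n[counts$protein_id == "unbal"], 4)
  expect_error(oversample_balanced(v, copies = 0), "copies")
  # no balanced proteins -> identity
  v2 <- make_labelled(list(a = c(0, 3), b = c(5, 0)))
  expect_equal(nrow(oversample_balanced(v2)), nrow(v2))
})

test_that("the count identity |out| = copies * n_balanced + n_unbalanced holds per class", {
  v <- withr::with_seed(50, make_labelled(stats::setNames(
    lapply(1:30, function(i) c(sample(0:6, 1), sample(0:10, 1))),
    sprintf("P%02d", 1:30)
  )))
  st <- balance_status(v)
  out <- oversample_balanced(v, copies = 6)
  for (lab in 0:1) {
    n_bal <- sum(v$label == lab & v$protein_id %in% st$protein_id[st$balanced])
    n_unb <- sum(v$label == lab) - n_bal
    expect_equal(sum(out$label == lab), 6 * n_bal + n_unb)
  }
})

test_that("variation-level splits are disjoint, exhaustive and reproducible", {
  v <- make_labelled(list(p = c(5, 5)))
  s1 <- split_variants(v, 0.5, seed = 99)
  s2 <- split_variants(v, 0.5, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$train), 5)
  expect_equal(nrow(s1$test), 5)
  expect_equal(dplyr::bind_rows(s1$train, s1$test) |> dplyr::arrange(.data$position),
               dplyr::arrange(v, .data$position))

  v11 <- make_labelled(list(p = c(6, 5)))
  s <- split_variants(v11, 0.5, seed = 1)
  expect_true(abs(nrow(s$train) - nrow(s$test)) <= 1)
  expect_error(split_variants(v), "seed")
})

test_that("grouped k-fold never leaks a group across a fold boundary", {
  v <- make_labelled(stats::setNames(
    lapply(1:12, function(i) c(2, 2)), sprintf("P%02d", 1:12)
  ))
  groups <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:12),
    group = rep(sprintf("fam%d", 1:4), each = 3)  # isoforms share a family
  )
  folds <- grouped_kfold(v, groups, k = 2, seed = 7)
  gmap <- stats::setNames(groups$group, groups$protein_id)
  for (f in folds) {
    expect_length(intersect(gmap[unique(f$train$protein_id)],
                            gmap[unique(f$test$protein_id)]), 0)
  }
  test_union <- dplyr::bind_rows(lapply(folds, `[[`, "test"))
  expect_equal(nrow(test_union), nrow(v))
  expect_error(grouped_kfold(v, groups, k = 5, seed = 1), "exceeds")
})

test_that("greedy packing balances folds for equal-sized groups", {
  v <- make_labelled(stats::setNames(
    lapply(1:20, function(i) c(1, 1)), sprintf("P%02d", 1:20)
  ))
  groups <- tibble::tibble(protein_id = sprintf("P%02d", 1:20),
                           group = sprintf("g%02d", 1:20))
  folds <- grouped_kfold(v, groups, k = 10, seed = 3)
  sizes <- vapply(folds, function(f) nrow(f$test), integer(1))
  expect_true(max(sizes) - min(sizes) <= 2)  # within one group (2 variants) of each other
})

test_that("the allele-frequency pre-filter removes common variants only", {
  v <- tibble::tibble(
    protein_id = "P", position = 1:4, wild_aa = "A", mutant_aa = "V",
    allele_freq = c(0.20, 0.169, 0.17, NA)
  )
  out <- allele_frequency_filter(v)
  expect_equal(out$allele_freq, c(0.169, NA))
  # absent column passes through
  expect_equal(allele_frequency_filter(v[, 1:4]), v[, 1:4])
})

test_that("confusion counts follow the disease-positive convention", {
  c1 <- confusion(rep("disease", 3) |> c(rep("neutral", 2)),
                  c(1, 1, 1, 0, 0))
  expect_equal(unlist(c1[, c("tp", "tn", "fp", "fn")]), c(tp = 3, tn = 2, fp = 0, fn = 0))
  c2 <- confusion(rep("disease", 5), c(1, 1, 1, 0, 0))
  expect_equal(c2$fp, 2)
  # hand-tallied 7-item fixture
  pred <- c("disease", "neutral", "disease", "disease", "neutral", "neutral", "disease")
  truth <- c(1, 1, 0, 1, 0, 1, 0)
  c3 <- confusion(pred, truth)
  expect_equal(unlist(c3[, c("tp", "tn", "fp", "fn")]), c(tp = 2, tn = 1, fp = 2, fn = 2))
  expect_error(confusion(pred[1:3], truth), "length mismatch")
})

test_that("metrics reproduce the worked confusion table", {
  perfect <- classification_metrics(tibble::tibble(tp = 3, tn = 2, fp = 0, fn = 0))
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$Sen, 1)
  expect_equal(perfect$Spe, 1)

  m <- classification_metrics(tibble::tibble(tp = 2, tn = 3, fp = 1, fn = 1))
  expect_equal(m$MCC, 5 / 12)
  expect_equal(m$MCC, (2 * 3 - 1 * 1) / sqrt(3 * 3 * 4 * 4))
  expect_equal(m$ACC, 5 / 7)
  expect_equal(m$Sen, 2 / 3)
  expect_equal(m$Spe, 3 / 4)
  expect_equal(m$PPV, 2 / 3)
  expect_equal(m$NPV, 3 / 4)

  # everything predicted neutral: a zero factor in the denominator -> MCC := 0
  all_neutral <- classification_metrics(tibble::tibble(tp = 0, tn = 4, fp = 0, fn = 2))
  expect_equal(all_neutral$MCC, 0)
  expect_true(is.na(all_neutral$PPV))  # undefined, not zero
})

test_that("MCC and companion metrics obey label-exchange symmetry", {
  withr::with_seed(60, {
    for (i in 1:20) {
      counts <- tibble::tibble(tp = sample(0:20, 1), tn = sample(0:20, 1),
                               fp = sample(0:20, 1), fn = sample(0:20, 1))
      if (sum(counts) == 0) next
      swapped <- tibble::tibble(tp = counts$tn, tn = counts$tp,
                                fp = counts$fn, fn = counts$fp)
      m1 <- classification_metrics(counts)
      m2 <- classification_metrics(swapped)
      expect_equal(m1$MCC, m2$MCC)
      expect_equal(m1$Sen, m2$Spe)
      expect_equal(m1$PPV, m2$NPV)
    }
  })
})

test_that("AUC follows the rank formulation and its invariances", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 3 / 4)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  withr::with_seed(61, {
    for (i in 1:25) {
      n <- sample(4:30, 1)
      scores <- round(runif(n), 1)  # induces ties
      labels <- rbinom(n, 1, 0.5)
      if (sum(labels) %in% c(0, n)) next
      auc <- roc_auc(scores, labels)
      expect_equal(auc, pair_auc(scores, labels))
      # invariance under strictly increasing transforms
      expect_equal(roc_auc(exp(3 * scores), labels), auc)
      expect_equal(roc_auc(rank(scores, ties.method = "average"), labels), auc)
    }
  })
})

test_that("rank-formulation AUC agrees with an established ROC implementation", {
  withr::with_seed(65, {
    scores <- round(runif(80), 1)
    labels <- rbinom(80, 1, 0.5)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(scores, labels), ref)
})

test_that("the ROC curve steps from (0,0) to (1,1)", {
  withr::with_seed(62, {
    scores <- runif(40)
    labels <- rbinom(40, 1, 0.5)
  })
  curve <- roc_curve(scores, labels)
  expect_equal(curve$FPR[1], 0)
  expect_equal(curve$TPR[1], 0)
  expect_equal(curve$FPR[nrow(curve)], 1)
  expect_equal(curve$TPR[nrow(curve)], 1)
  expect_true(all(diff(curve$FPR) >= 0))
  expect_true(all(diff(curve$TPR) >= 0))
})

test_that("false-positive rate on all-neutral sets is the disease-call fraction", {
  expect_equal(false_positive_rate(rep("neutral", 100)), 0)
  expect_equal(false_positive_rate(c(rep("disease", 10), rep("neutral", 90))), 0.10)
  expect_error(false_positive_rate(character(0)), "empty")
  # raising the cutoff can only lower the FPR
  withr::with_seed(63, scores <- runif(200))
  expect_lte(false_positive_rate(classify_score(scores, 0.55)),
             false_positive_rate(classify_score(scores, 0.45)))
})

test_that("the FPR cross-regression matches the closed-form OLS oracle", {
  pairs <- tibble::tibble(x = c(38.7, 44.2, 31.6, 26.1, 46.4, 9.0),
                          y = c(42.6, 48.2, 36.4, 29.3, 51.5, 10.7))
  fit <- fpr_cross_regression(pairs)
  oracle <- ols_normal_equations(pairs$x, pairs$y)
  expect_equal(fit$slope, unname(oracle["slope"]))
  expect_equal(fit$intercept, unname(oracle["intercept"]))

  collinear <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  fit2 <- fpr_cross_regression(collinear)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$pearson_r, 1)

  expect_error(fpr_cross_regression(pairs[1:2, ]), "at least 3")
  expect_error(fpr_cross_regression(tibble::tibble(x = c(1, 1, 1), y = 1:3)), "variance")
})

test_that("evaluation reports bundle thresholded metrics with AUC", {
  withr::with_seed(64, {
    scores <- c(runif(30, 0.4, 1), runif(30, 0, 0.6))
    labels <- rep(c(1, 0), each = 30)
  })
  rep45 <- evaluation_report(scores, labels, cutoff = 0.45)
  expect_true(all(c("MCC", "ACC", "Sen", "Spe", "PPV", "NPV", "AUC") %in% names(rep45)))
  expect_equal(rep45$AUC, roc_auc(scores, labels))
  expect_equal(rep45$Spe, 1 - false_positive_rate(classify_score(scores[labels == 0], 0.45)))
})
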