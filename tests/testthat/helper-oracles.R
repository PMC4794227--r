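# Independent reference implementations used as oracles.  They share no
# code with the package: trees are nested lists grown by exhaustive split
# search in plain R, distances are brute-force loops, AUC is literal
# pair enumeration.

# ---- reference least-squares regression tree -------------------------------

ref_fit_tree <- function(x, r, max_depth, min_leaf, depth = 0) {
  n <- nrow(x)
  node <- list(leaf = TRUE, value = sum(r) / n)
  if (depth >= max_depth || n < 2 * min_leaf || min(r) == max(r)) return(node)
  best <- list(gain = 0)
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    rs <- r[ord]
    for (t in seq_len(n - 1)) {
      if (xs[t] >= xs[t + 1]) next
      nl <- t; nr <- n - t
      if (nl < min_leaf || nr < min_leaf) next
      sl <- sum(rs[seq_len(t)]); sr <- sum(rs) - sl
      gain <- sl^2 / nl + sr^2 / nr - sum(rs)^2 / n
      if (gain > best$gain) {
        best <- list(gain = gain, feature = j, threshold = (xs[t] + xs[t + 1]) / 2)
      }
    }
  }
  if (is.null(best$feature)) return(node)
  go_left <- x[, best$feature] <= best$threshold
  list(
    leaf = FALSE, feature = best$feature, threshold = best$threshold,
    left = ref_fit_tree(x[go_left, , drop = FALSE], r[go_left], max_depth, min_leaf, depth + 1),
    right = ref_fit_tree(x[!go_left, , drop = FALSE], r[!go_left], max_depth, min_leaf, depth + 1)
  )
}

ref_predict_tree <- function(node, x) {
  apply(x, 1, function(row) {
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    }
    node$value
  })
}

ref_fit_gbrt <- function(x, y, n_trees, shrinkage, max_depth, min_leaf) {
  f <- rep(0, nrow(x))
  trees <- vector("list", n_trees)
  for (m in seq_len(n_trees)) {
    trees[[m]] <- ref_fit_tree(x, y - f, max_depth, min_leaf)
    f <- f + shrinkage * ref_predict_tree(trees[[m]], x)
  }
  list(trees = trees, shrinkage = shrinkage)
}

ref_predict_gbrt <- function(model, x) {
  f <- rep(0, nrow(x))
  for (tr in model$trees) f <- f + model$shrinkage * ref_predict_tree(tr, x)
  f
}

# ---- brute-force geometry --------------------------------------------------

brute_force_neighbors <- function(structure, position, cutoff) {
  i <- which(structure$position == position)
  out <- integer(0)
  for (j in seq_len(nrow(structure))) {
    if (j == i) next
    d <- sqrt((structure$x[j] - structure$x[i])^2 +
                (structure$y[j] - structure$y[i])^2 +
                (structure$z[j] - structure$z[i])^2)
    if (d <= cutoff) out <- c(out, j)
  }
  out
}

brute_force_contact_composition <- function(structure, position, cutoff) {
  nb <- brute_force_neighbors(structure, position, cutoff)
  comp <- stats::setNames(numeric(20), aa_alphabet())
  if (length(nb) == 0) return(comp)
  for (j in nb) comp[structure$aa[j]] <- comp[structure$aa[j]] + 1
  comp / length(nb)
}

# ---- pairwise AUC ----------------------------------------------------------

pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# ---- closed-form OLS -------------------------------------------------------

ols_normal_equations <- function(x, y) {
  xbar <- mean(x); ybar <- mean(y)
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  c(slope = slope, intercept = ybar - slope * xbar)
}

# ---- identity-window subset enumeration ------------------------------------

# all maximal subsets of non-query rows that satisfy the window to the
# query and mutual identity <= max_id
enumerate_maximal_subsets <- function(aln, min_id = 0.35, max_id = 0.90) {
  n <- nrow(aln$mat)
  rows <- setdiff(seq_len(n), 1L)
  ok_query <- rows[aln$identity[rows] >= min_id & aln$identity[rows] <= max_id]
  valid <- function(set) {
    if (length(set) < 2) return(TRUE)
    for (a in seq_along(set)) {
      for (b in seq_len(a - 1)) {
        if (pairwise_identity(aln$mat[set[a], ], aln$mat[set[b], ]) > max_id) return(FALSE)
      }
    }
    TRUE
  }
  subsets <- list()
  for (bits in 0:(2^length(ok_query) - 1)) {
    set <- ok_query[bitwAnd(bits, 2^(seq_along(ok_query) - 1)) > 0]
    if (valid(set)) subsets <- c(subsets, list(set))
  }
  is_maximal <- vapply(subsets, function(s) {
    extras <- setdiff(ok_query, s)
    !any(vapply(extras, function(e) valid(c(s, e)), logical(1)))
  }, logical(1))
  subsets[is_maximal]
}

# ---- tiny fixture builders -------------------------------------------------

make_test_alignment <- function(rows, query_id = "Q") {
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- mat[1, ] != "-"
  new_aa_alignment(query_id, sprintf("R%d", seq_len(nrow(mat))), mat[, keep, drop = FALSE])
}

random_cloud_structure <- function(n, seed, spread = 15) {
  withr::with_seed(seed, {
    new_calpha_structure(
      "CLOUD", seq_len(n),
      sample(aa_alphabet(), n, replace = TRUE),
      matrix(stats::runif(3 * n, 0, spread), ncol = 3)
    )
  })
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_res <- qr(matrix(stats::rnorm(9), 3))
    q <- qr.Q(qr_res)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

rotate_structure <- function(structure, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  new_calpha_structure(attr(structure, "protein_id") %||% "ROT",
                       structure$position, structure$aa, xyz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
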