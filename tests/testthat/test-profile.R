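# identity helpers -----------------------------------------------------------

test_that("pairwise identity is computed over mutually ungapped columns", {
  expect_equal(pairwise_identity(c("A", "C", "D"), c("A", "C", "D")), 1)
  expect_equal(pairwise_identity(c("A", "C", "D"), c("A", "-", "E")), 0.5)
  expect_equal(pairwise_identity(c("A", "-"), c("-", "A")), 0)  # no shared column
})

test_that("identity window removes too-similar and too-remote homologs", {
  q <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  identical_row <- q                   # identity 1.0 > 0.90 -> removed
  remote <- q; remote[5:20] <- "G"     # identity 5/20 = 0.25 < 0.35 -> removed
  mid <- q; mid[1:8] <- "G"            # identity 13/20 = 0.65 -> kept
  aln <- new_aa_alignment("Q", c("Q", "ident", "remote", "mid"),
                          rbind(q, identical_row, remote, mid))
  kept <- filter_by_identity(aln)
  expect_equal(kept$ids, c("Q", "mid"))
})

test_that("greedy mutual-redundancy filtering picks a maximal valid subset", {
  q <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  h1 <- q; h1[1:8] <- "G"             # 0.65 to query
  h2 <- h1; h2[20] <- "G"             # 0.95 to h1, 0.60 to query
  h3 <- q; h3[9:16] <- "A"            # 0.60 to query
  h4 <- q; h4[1:13] <- "W"            # 0.35 to query (inclusive lower bound)
  h5 <- q                             # 1.0, outside window
  aln <- new_aa_alignment("Q", c("Q", paste0("h", 1:5)), rbind(q, h1, h2, h3, h4, h5))
  kept <- filter_by_identity(aln)
  # h1 kept first, h2 excluded as redundant with h1, h5 excluded by window
  expect_equal(kept$ids, c("Q", "h1", "h3", "h4"))
  kept_rows <- match(kept$ids[-1], aln$ids)
  maximal <- enumerate_maximal_subsets(aln)
  expect_true(any(vapply(maximal, function(s) setequal(s, kept_rows), logical(1))))
})

test_that("the retained set is invariant to appending window-violating rows", {
  aln <- make_alignment(30, 8, 10, 0.5, seed = 21)
  base <- filter_by_identity(aln)
  dup_of_kept <- aln$mat[match(base$ids[2], aln$ids), ]
  remote <- rep("W", 30)
  aug <- new_aa_alignment(
    aln$query_id, c(aln$ids, "dup", "remote"),
    rbind(aln$mat, dup_of_kept, remote)
  )
  expect_equal(filter_by_identity(aug)$ids, base$ids)
})

# profile construction --------------------------------------------------------

test_that("profile counts include the query and normalise per position", {
  aln <- make_test_alignment(c("AAG", "AVG", "-VG", "--G"))
  prof <- build_profile(aln)
  expect_equal(prof$coverage, c(2L, 3L, 4L))
  expect_equal(unname(prof$freqs[1, c("A")]), 1)
  expect_equal(unname(prof$freqs[2, c("A", "V")]), c(1 / 3, 2 / 3))
  expect_equal(sum(prof$freqs[3, ]), 1)
})

test_that("a column of {A, A, V, gap} gives f_A = 2/3, f_V = 1/3, coverage 3", {
  aln <- make_test_alignment(c("A", "A", "V", "-"))
  prof <- build_profile(aln)
  expect_equal(unname(prof$freqs[1, "A"]), 2 / 3)
  expect_equal(unname(prof$freqs[1, "V"]), 1 / 3)
  expect_equal(prof$coverage[1], 3L)
})

test_that("query-only profiles are one-hot; nonstandard-only columns are empty", {
  aln <- make_test_alignment("ACD")
  prof <- build_profile(aln)
  expect_equal(prof$coverage, rep(1L, 3))
  for (p in 1:3) {
    expect_equal(sum(prof$freqs[p, ]), 1)
    expect_equal(unname(prof$freqs[p, query_sequence(aln)[p]]), 1)
  }
  # homolog-only column of gaps/nonstandard letters next to the query's X
  aln2 <- make_test_alignment(c("XA", "-A", "XA"))
  prof2 <- build_profile(aln2)
  expect_equal(prof2$coverage[1], 0L)
  expect_equal(sum(prof2$freqs[1, ]), 0)
})

# entropy ---------------------------------------------------------------------

test_that("column entropy has the closed-form values", {
  expect_equal(round(position_entropy(rep(0.05, 20)), 3), 2.996)
  expect_equal(position_entropy(one_hot_aa("W")), 0)
  expect_equal(position_entropy(c(0.5, 0.5, rep(0, 18))), log(2))
  expect_equal(position_entropy(rep(0, 20)), 0)  # no-coverage convention
  expect_error(position_entropy(c(-0.1, rep(0.1, 11), rep(0, 8))), "negative")
})

test_that("relative entropy is centred: query-only and uniform profiles give RS = 0", {
  prof_query <- build_profile(make_test_alignment("ACDEF"))
  trk <- relative_entropy(prof_query)
  expect_equal(trk$S, rep(0, 5))
  expect_equal(trk$RS, rep(0, 5))

  prof_unif <- list(query_id = "U", query = rep("A", 4),
                    freqs = matrix(0.05, 4, 20, dimnames = list(NULL, aa_alphabet())),
                    coverage = rep(20L, 4))
  class(prof_unif) <- "aa_profile"
  expect_equal(relative_entropy(prof_unif)$RS, rep(0, 4))
})

test_that("a (0, ln2, ln2) entropy track centres to the hand-computed RS", {
  freqs <- rbind(
    one_hot_aa("A"),
    c(0.5, 0.5, rep(0, 18)),
    c(0.5, 0.5, rep(0, 18))
  )
  prof <- list(query_id = "T", query = c("A", "A", "A"), freqs = freqs,
               coverage = rep(2L, 3))
  class(prof) <- "aa_profile"
  trk <- relative_entropy(prof)
  expect_equal(attr(trk, "mean_S"), 2 * log(2) / 3)
  expect_equal(trk$RS, c(-2 * log(2) / 3, log(2) / 3, log(2) / 3))
  expect_equal(round(trk$RS, 4), c(-0.4621, 0.2310, 0.2310))
})

test_that("entropy bounds and RS centring hold on generated alignments", {
  for (seed in 1:5) {
    aln <- make_alignment(40, 15, 12, 0.6, seed = seed)
    prof <- build_profile(filter_by_identity(aln))
    trk <- relative_entropy(prof)
    expect_true(all(trk$S >= 0 & trk$S <= log(20) + 1e-12))
    expect_lt(abs(sum(trk$RS)), 1e-6)
    covered <- which(trk$coverage > 0)
    expect_true(all(abs(rowSums(prof$freqs[covered, , drop = FALSE]) - 1) < 1e-9))
    # equality cases: S = 0 iff one-hot
    one_hot_cols <- which(apply(prof$freqs, 1, function(f) any(f == 1)))
    expect_equal(which(trk$S == 0 & trk$coverage > 0), intersect(one_hot_cols, covered))
  }
})

test_that("relative entropy rejects zero-length profiles", {
  prof <- list(query_id = "E", query = character(0),
               freqs = matrix(0, 0, 20), coverage = integer(0))
  class(prof) <- "aa_profile"
  expect_error(relative_entropy(prof), "zero-length")
})
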