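#' Build a per-position frequency profile from an alignment
#'
#' Counts the 20 standard amino-acid types in each column of the (already
#' identity-filtered) alignment, query row included, and normalises each
#' column by the number of contributing sequences at that position.  Gaps
#' and non-standard letters contribute to neither numerator nor
#' denominator; a column with no standard letters has coverage 0 and an
#' all-zero frequency vector.
#'
#' @param aln An `aa_alignment` (typically after [filter_by_identity()]).
#' @return An `aa_profile`: list with `query_id`, `query` (residues),
#'   `freqs` (length x 20 matrix, columns in [aa_alphabet()] order, rows
#'   summing to 1 where coverage > 0) and `coverage` (integer counts).
#' @export
build_profile <- function(aln) {
  mat <- aln$mat
  L <- ncol(mat)
  freqs <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  coverage <- integer(L)
  for (p in seq_len(L)) {
    col <- mat[, p]
    col <- col[col %in% AA_ALPHABET]
    coverage[p] <- length(col)
    if (length(col) > 0) {
      freqs[p, ] <- tabulate(aa_index(col), nbins = 20) / length(col)
    }
  }
  out <- list(
    query_id = aln$query_id,
    query = query_sequence(aln),
    freqs = freqs,
    coverage = coverage
  )
  class(out) <- "aa_profile"
  out
}

#' @export
print.aa_profile <- function(x, ...) {
  cat(sprintf(
    "<aa_profile> '%s': %d positions, median coverage %d\n",
    x$query_id, nrow(x$freqs), as.integer(stats::median(x$coverage))
  ))
  invisible(x)
}

#' Shannon entropy of one profile column
#'
#' S = -sum_l f_l ln(f_l) in nats, with 0 * ln 0 := 0.  A fully conserved
#' (one-hot) column has S = 0; a uniform column has S = ln(20) = 2.996.
#' An all-zero column (no coverage) is assigned S = 0, the same value as a
#' fully conserved position: zero information maps to zero entropy.
#'
#' @param freqs Numeric vector of 20 non-negative frequencies summing to 1
#'   (or all zero for a no-coverage column).
#' @return Entropy in nats, in \[0, ln(20)\].
#' @export
position_entropy <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequency")
  nz <- freqs > 0
  if (!any(nz)) return(0)
  s <- -sum(freqs[nz] * log(freqs[nz]))
  if (s <= 0) 0 else s  # guard the one-hot case against signed zero
}

#' Per-position absolute and relative sequence entropy
#'
#' Computes S at every position of the profile and the relative entropy
#' RS = S - <S>, where <S> is the unweighted mean of S over the whole
#' protein.  Subtracting the protein mean removes protein-level effects
#' such as shallow profiles: a query-only profile has S = 0 everywhere and
#' hence RS = 0 everywhere.  RS sums to zero over the protein by
#' construction.
#'
#' @param profile An `aa_profile` from [build_profile()].
#' @return An `entropy_track`: tibble with columns `position`, `S`, `RS`,
#'   `coverage`, carrying the protein mean entropy as attribute `mean_S`.
#' @export
relative_entropy <- function(profile) {
  L <- nrow(profile$freqs)
  if (L < 1) stop("zero-length profile")
  S <- vapply(seq_len(L), function(p) position_entropy(profile$freqs[p, ]), numeric(1))
  mean_S <- mean(S)
  out <- tibble::tibble(
    position = seq_len(L),
    S = S,
    RS = S - mean_S,
    coverage = profile$coverage
  )
  attr(out, "mean_S") <- mean_S
  attr(out, "query_id") <- profile$query_id
  class(out) <- c("entropy_track", class(out))
  out
}

#' One-call entropy track from a raw alignment
#'
#' Convenience pipeline: identity-window filtering, profile construction,
#' and relative-entropy computation.
#'
#' @param aln An `aa_alignment`.
#' @param min_id,max_id Identity window passed to [filter_by_identity()].
#' @return An `entropy_track` tibble (see [relative_entropy()]).
#' @export
entropy_track <- function(aln, min_id = 0.35, max_id = 0.90) {
  relative_entropy(build_profile(filter_by_identity(aln, min_id, max_id)))
}
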