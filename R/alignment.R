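#' Construct an alignment set in query coordinates
#'
#' An `aa_alignment` holds a query sequence and its aligned homologs as a
#' character matrix whose columns are the query's residue positions:
#' columns where the query is gapped have already been dropped, so every
#' per-position array downstream shares the query coordinate system.
#'
#' @param query_id Identifier of the query (row 1).
#' @param ids Character vector of row identifiers (query first).
#' @param mat Character matrix, rows = sequences, columns = query positions,
#'   gap character `"-"`.
#' @return An `aa_alignment` object.
#' @export
new_aa_alignment <- function(query_id, ids, mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1, length(ids) == nrow(mat))
  if (any(mat[1, ] == "-")) stop("query row may not contain gaps in query coordinates")
  out <- list(
    query_id = query_id,
    ids = ids,
    mat = mat,
    identity = vapply(seq_len(nrow(mat)), function(i) pairwise_identity(mat[1, ], mat[i, ]), numeric(1))
  )
  class(out) <- "aa_alignment"
  out
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf(
    "<aa_alignment> query '%s': %d positions, %d sequence(s) (query + %d homologs)\n",
    x$query_id, ncol(x$mat), nrow(x$mat), nrow(x$mat) - 1L
  ))
  invisible(x)
}

#' Number of alignment columns (query length)
#' @param aln An `aa_alignment`.
#' @return Integer length of the ungapped query.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Query sequence of an alignment
#' @param aln An `aa_alignment`.
#' @return Character vector of the query's residues, one per position.
#' @export
query_sequence <- function(aln) unname(aln$mat[1, ])

#' Read an aligned FASTA file
#'
#' The first record is the query; all records must have equal aligned
#' length.  Columns where the query carries a gap are dropped so that the
#' resulting profile has exactly one column per query residue.
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return An `aa_alignment` in query coordinates.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0) stop("empty alignment file: ", path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1) stop("aligned sequences have unequal lengths in ", path)
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  dimnames(mat) <- NULL
  ids <- sub("\\s.*$", "", names(seqs))
  keep_cols <- mat[1, ] != "-"
  mat <- mat[, keep_cols, drop = FALSE]
  new_aa_alignment(query_id = ids[1], ids = ids, mat = mat)
}

#' Write an alignment back to FASTA
#'
#' Writes the alignment as stored (query coordinates, so the query row is
#' ungapped); reading the file back with [read_alignment()] reproduces the
#' same in-memory content.
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `aln`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(apply(aln$mat, 1, paste0, collapse = ""))
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(aln)
}

#' Pairwise sequence identity over mutually ungapped columns
#'
#' Identity = matches / number of columns where both rows are non-gap; if
#' the rows share no ungapped column the identity is 0.
#'
#' @param a,b Character vectors of equal length (aligned rows).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (n == 0) return(0)
  sum(a[both] == b[both]) / n
}

#' Filter alignment rows to an identity window
#'
#' Retains homologs whose identity to the query lies in
#' `[min_id, max_id]` and that are mutually non-redundant (pairwise
#' identity among retained homologs at most `max_id`).  Redundancy removal
#' is greedy in input order: a row is kept iff it satisfies the window
#' against the query and is at most `max_id` identical to every previously
#' kept homolog.  The query row is always retained.  The default window
#' (35--90%) avoids over-representation of near-identical sequences while
#' excluding remote, possibly misaligned hits.
#'
#' @param aln An `aa_alignment`.
#' @param min_id,max_id Identity window bounds (fractions).
#' @return An `aa_alignment` containing the query plus retained homologs.
#' @export
filter_by_identity <- function(aln, min_id = 0.35, max_id = 0.90) {
  n <- nrow(aln$mat)
  keep <- 1L
  for (i in seq_len(n)[-1]) {
    id_q <- aln$identity[i]
    if (id_q < min_id || id_q > max_id) next
    ok <- TRUE
    for (j in setdiff(keep, 1L)) {
      if (pairwise_identity(aln$mat[i, ], aln$mat[j, ]) > max_id) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  new_aa_alignment(aln$query_id, aln$ids[keep], aln$mat[keep, , drop = FALSE])
}
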