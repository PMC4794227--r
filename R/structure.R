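#' Amino-acid composition of the Calpha contact shell of a residue
#'
#' Neighbors are all residues of the supplied structure model (other than
#' the mutated position itself) whose Calpha lies within `cutoff` Angstrom
#' (boundary inclusive) of the mutated position's Calpha.  The returned
#' vector holds the fractions of the 20 amino-acid types among those
#' neighbors; a residue with no neighbors gets the all-zero sentinel
#' vector, which is distinct from the error raised when the position is
#' absent from the model.
#'
#' @param structure A `calpha_structure`.
#' @param position 1-based residue position (must be present in the model).
#' @param cutoff Distance cutoff in Angstrom (default 12; 8 is the common
#'   alternative).
#' @return Named numeric vector of 20 fractions in [aa_alphabet()] order.
#' @export
contact_composition <- function(structure, position, cutoff = 12) {
  i <- match(position, structure$position)
  if (is.na(i)) {
    stop("position ", position, " absent from structure model")
  }
  dx <- structure$x - structure$x[i]
  dy <- structure$y - structure$y[i]
  dz <- structure$z - structure$z[i]
  d2 <- dx * dx + dy * dy + dz * dz
  nb <- which(d2 <= cutoff^2)
  nb <- nb[nb != i]
  comp <- stats::setNames(numeric(20), AA_ALPHABET)
  if (length(nb) == 0) return(comp)
  counts <- tabulate(aa_index(structure$aa[nb]), nbins = 20)
  comp[] <- counts / length(nb)
  comp
}

#' Amino-acid composition of a sequence segment
#'
#' Fractions of the 20 standard types over `sequence[start..end]`
#' (1-based, inclusive).  Non-standard letters are excluded from both
#' numerator and denominator; a segment containing only non-standard
#' letters yields the all-zero sentinel.
#'
#' @param sequence Character vector of residues (or a single string).
#' @param segment List or one-row data frame with `start` and `end`.
#' @return Named numeric vector of 20 fractions in [aa_alphabet()] order.
#' @export
domain_composition <- function(sequence, segment) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  start <- as.integer(segment$start)
  end <- as.integer(segment$end)
  if (start < 1 || end > length(sequence) || start > end) {
    stop(sprintf("segment [%d, %d] out of bounds for sequence of length %d",
                 start, end, length(sequence)))
  }
  letters <- sequence[start:end]
  letters <- letters[letters %in% AA_ALPHABET]
  comp <- stats::setNames(numeric(20), AA_ALPHABET)
  if (length(letters) == 0) return(comp)
  comp[] <- tabulate(aa_index(letters), nbins = 20) / length(letters)
  comp
}

#' Find the segment covering a position
#'
#' Returns the (non-overlapping) segment containing `position`; when no
#' supplied segment covers it — or no segments are supplied at all — the
#' whole-sequence fallback segment `[1, sequence_length]` is returned, so
#' every residue always has a domain context.
#'
#' @param position 1-based residue position.
#' @param segments Tibble with columns `start`, `end` (possibly 0 rows), or `NULL`.
#' @param sequence_length Length of the protein sequence.
#' @return A list with elements `start` and `end`.
#' @export
segment_of <- function(position, segments, sequence_length) {
  if (!is.null(segments) && nrow(segments) > 0) {
    hit <- which(segments$start <= position & position <= segments$end)
    if (length(hit) == 1) {
      return(list(start = as.integer(segments$start[hit]),
                  end = as.integer(segments$end[hit])))
    }
  }
  list(start = 1L, end = as.integer(sequence_length))
}
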