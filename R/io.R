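#' Read a variant table
#'
#' Parses a tab-separated table of single amino-acid substitutions with
#' header columns `protein_id`, `position`, `wild_aa`, `mutant_aa` and
#' optionally `label` (1 = disease-associated, 0 = neutral) and
#' `allele_freq` (fraction in \[0, 1\]).  Row order is preserved and
#' duplicated substitutions are retained, so over-sampled training tables
#' round-trip unchanged.
#'
#' Amino-acid letters are accepted case-insensitively but must be one of
#' the 20 standard residues; a row whose wild-type equals its mutant, whose
#' position is not a positive integer, or whose label is missing while
#' `require_labels = TRUE`, is rejected with its row number.
#'
#' @param path Path to a TSV file.
#' @param require_labels If `TRUE`, every row must carry a 0/1 label.
#' @return A tibble with columns `protein_id` (character), `position`
#'   (integer), `wild_aa`, `mutant_aa` (upper-case character), and, when
#'   present in the file, `label` (integer) and `allele_freq` (double).
#' @export
read_variant_table <- function(path, require_labels = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("protein_id", "position", "wild_aa", "mutant_aa")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_variants(tibble::tibble(
    protein_id = raw$protein_id,
    position = suppressWarnings(as.integer(raw$position)),
    position_raw = raw$position,
    wild_aa = toupper(raw$wild_aa),
    mutant_aa = toupper(raw$mutant_aa),
    label = if ("label" %in% names(raw)) suppressWarnings(as.integer(raw$label)) else NULL,
    label_raw = if ("label" %in% names(raw)) raw$label else NULL,
    allele_freq = if ("allele_freq" %in% names(raw)) suppressWarnings(as.numeric(raw$allele_freq)) else NULL
  ), require_labels = require_labels, has_label_col = "label" %in% names(raw))
}

validate_variants <- function(v, require_labels, has_label_col) {
  row_err <- function(rows, msg) {
    stop(sprintf("variant table row %s: %s", paste(rows, collapse = ", "), msg), call. = FALSE)
  }
  bad <- which(is.na(v$position) | v$position < 1 |
                 (!is.na(suppressWarnings(as.numeric(v$position_raw))) &
                    suppressWarnings(as.numeric(v$position_raw)) != v$position))
  if (length(bad) > 0) row_err(bad, "malformed position (must be a 1-based integer)")
  bad <- which(!is_standard_aa(v$wild_aa) | !is_standard_aa(v$mutant_aa))
  if (length(bad) > 0) row_err(bad, "unknown amino-acid letter (20 standard residues only)")
  bad <- which(v$wild_aa == v$mutant_aa)
  if (length(bad) > 0) row_err(bad, "wild equals mutant")
  if ("label" %in% names(v)) {
    bad <- which(!is.na(v$label_raw) & (is.na(v$label) | !(v$label %in% c(0L, 1L))))
    if (length(bad) > 0) row_err(bad, "label must be 0 (neutral) or 1 (disease)")
  }
  if (require_labels) {
    if (!has_label_col) stop("variant table has no 'label' column but labels are required")
    bad <- which(is.na(v$label))
    if (length(bad) > 0) row_err(bad, "missing label")
  }
  if ("allele_freq" %in% names(v)) {
    bad <- which(!is.na(v$allele_freq) & (v$allele_freq < 0 | v$allele_freq > 1))
    if (length(bad) > 0) row_err(bad, "allele_freq outside [0, 1]")
  }
  v$position_raw <- NULL
  v$label_raw <- NULL
  v
}

#' Write a variant table (or prediction table) to TSV
#'
#' @param variants A tibble of variants, optionally with `score` / `class`
#'   columns added by [predict_variants()].
#' @param path Output path.
#' @return `variants`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(variants)
}

#' Read a domain/segment boundary table
#'
#' Segments are 1-based inclusive `[start, end]` spans of a protein
#' sequence (typically template-aligned regions that were modelled
#' independently).  Segments of one protein may not overlap.
#'
#' @param path Path to a TSV with header columns `protein_id`, `start`, `end`.
#' @return A tibble with columns `protein_id`, `start`, `end` (integer).
#' @export
read_domain_segments <- function(path) {
  seg <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ))
  validate_segments(seg)
}

validate_segments <- function(seg) {
  if (any(is.na(seg$start) | is.na(seg$end) | seg$start < 1 | seg$start > seg$end)) {
    stop("segments must satisfy 1 <= start <= end")
  }
  chk <- dplyr::group_by(seg, .data$protein_id)
  chk <- dplyr::arrange(chk, .data$start, .by_group = TRUE)
  overlap <- dplyr::summarise(chk, bad = any(.data$start[-1] <= .data$end[-length(.data$end)]))
  if (any(overlap$bad)) {
    stop("overlapping segments for protein(s): ",
         paste(overlap$protein_id[overlap$bad], collapse = ", "))
  }
  seg
}

#' Read a Calpha-trace structure model from a PDB file
#'
#' Only `ATOM` records whose atom name is `CA` are used; the first model
#' and the first alternate location of each residue are kept.  Residue
#' identities come from the 3-letter residue name; residues with
#' non-standard names are skipped with a warning (the feature space is
#' fixed at the 20 standard types).  Residue numbering is preserved, so
#' chains with gaps keep their original positions.
#'
#' @param path Path to a PDB-format file.
#' @param protein_id Identifier to attach; defaults to the file name.
#' @return A `calpha_structure`: a tibble with columns `position`
#'   (integer), `aa` (one-letter code), `x`, `y`, `z` (Angstrom).
#' @export
read_calpha_structure <- function(path, protein_id = NULL) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("no CA atoms found in ", path)
  # first alternate location per residue
  at <- at[!duplicated(at$resno), , drop = FALSE]
  std <- at$resid %in% names(AA_THREE_TO_ONE)
  if (any(!std)) {
    warning("skipping ", sum(!std), " non-standard residue(s): ",
            paste(unique(at$resid[!std]), collapse = ", "))
    at <- at[std, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no standard-residue CA atoms found in ", path)
  at <- at[order(at$resno), , drop = FALSE]
  new_calpha_structure(
    protein_id = protein_id %||% basename(path),
    position = as.integer(at$resno),
    aa = unname(AA_THREE_TO_ONE[at$resid]),
    xyz = cbind(at$x, at$y, at$z)
  )
}

new_calpha_structure <- function(protein_id, position, aa, xyz) {
  stopifnot(all(diff(position) > 0), all(is.finite(xyz)))
  out <- tibble::tibble(
    position = as.integer(position), aa = aa,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  attr(out, "protein_id") <- protein_id
  class(out) <- c("calpha_structure", class(out))
  out
}

#' Write a Calpha-trace structure model as PDB ATOM records
#'
#' @param structure A `calpha_structure` (see [read_calpha_structure()]).
#' @param path Output path.
#' @return `structure`, invisibly.
#' @export
write_calpha_structure <- function(structure, path) {
  one_to_three <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(structure)), one_to_three[structure$aa], structure$position,
    structure$x, structure$y, structure$z
  )
  writeLines(c(lines, "END"), path)
  invisible(structure)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
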