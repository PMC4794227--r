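#' Feature configuration (full model and ablation presets)
#'
#' The full configuration encodes each substitution as 81 values in fixed
#' block order: relative entropy (1), wild-type one-hot (20), mutant
#' one-hot (20), domain composition (20), contact composition (20).
#' Ablation presets switch blocks off or change the contact cutoff:
#'
#' * `full` — all four blocks, 12 A contact cutoff (81 features)
#' * `cut8` — all four blocks, 8 A contact cutoff (81)
#' * `notyp` — no wild/mutant one-hot blocks (41)
#' * `nodom` — no domain composition (61)
#' * `nocnt` — no contact composition (61)
#' * `noent` — no entropy feature (80)
#' * `onlydom` — domain composition alone (20)
#'
#' @param preset One of the preset names above, or `NULL` to set flags
#'   directly.
#' @param use_types,use_domain,use_contact,use_entropy Block flags
#'   (ignored when `preset` is given).
#' @param contact_cutoff Calpha contact cutoff in Angstrom.
#' @return A `feature_config` object.
#' @export
#' @examples
#' feature_config("full")
#' feature_config("cut8")$contact_cutoff
feature_config <- function(preset = c("full", "cut8", "notyp", "nodom",
                                      "nocnt", "noent", "onlydom"),
                           use_types = TRUE, use_domain = TRUE,
                           use_contact = TRUE, use_entropy = TRUE,
                           contact_cutoff = 12) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    flags <- switch(preset,
      full    = list(TRUE, TRUE, TRUE, TRUE, 12),
      cut8    = list(TRUE, TRUE, TRUE, TRUE, 8),
      notyp   = list(FALSE, TRUE, TRUE, TRUE, 12),
      nodom   = list(TRUE, FALSE, TRUE, TRUE, 12),
      nocnt   = list(TRUE, TRUE, FALSE, TRUE, 12),
      noent   = list(TRUE, TRUE, TRUE, FALSE, 12),
      onlydom = list(FALSE, TRUE, FALSE, FALSE, 12)
    )
    use_types <- flags[[1]]; use_domain <- flags[[2]]
    use_contact <- flags[[3]]; use_entropy <- flags[[4]]
    contact_cutoff <- flags[[5]]
  } else {
    preset <- "custom"
  }
  if (!any(use_types, use_domain, use_contact, use_entropy)) {
    stop("at least one feature block must be enabled")
  }
  out <- list(
    name = preset,
    use_types = use_types, use_domain = use_domain,
    use_contact = use_contact, use_entropy = use_entropy,
    contact_cutoff = contact_cutoff
  )
  class(out) <- "feature_config"
  out
}

#' @export
print.feature_config <- function(x, ...) {
  cat(sprintf(
    "<feature_config> '%s': %d features (entropy=%s, types=%s, domain=%s, contact=%s @ %g A)\n",
    x$name, length(feature_names(x)), x$use_entropy, x$use_types,
    x$use_domain, x$use_contact, x$contact_cutoff
  ))
  invisible(x)
}

#' Names of the features produced by a configuration
#'
#' @param config A `feature_config`.
#' @return Character vector in the fixed block order
#'   (RS | wild | mutant | domain | contact).
#' @export
feature_names <- function(config) {
  c(
    if (config$use_entropy) "RS",
    if (config$use_types) paste0("wild_", AA_ALPHABET),
    if (config$use_types) paste0("mut_", AA_ALPHABET),
    if (config$use_domain) paste0("dom_", AA_ALPHABET),
    if (config$use_contact) paste0("cnt_", AA_ALPHABET)
  )
}

#' One-hot encode an amino-acid letter
#'
#' @param aa One of the 20 standard one-letter codes.
#' @return Named 20-vector with a single 1 at the letter's alphabetical
#'   index.
#' @export
one_hot_aa <- function(aa) {
  i <- aa_index(aa)
  if (length(aa) != 1 || is.na(i)) stop("unknown amino-acid letter: ", aa)
  v <- stats::setNames(numeric(20), AA_ALPHABET)
  v[i] <- 1
  v
}

#' Assemble the feature vector of one substitution
#'
#' Concatenates the enabled blocks in the fixed order
#' RS | wild one-hot | mutant one-hot | domain composition | contact
#' composition.  With the full configuration the vector has 81 values.
#'
#' @param wild_aa,mutant_aa Wild-type and mutant one-letter codes.
#' @param rs Relative entropy at the mutated position (ignored unless the
#'   entropy block is enabled).
#' @param domain Domain composition 20-vector (ignored unless enabled).
#' @param contact Contact composition 20-vector (ignored unless enabled).
#' @param config A `feature_config`.
#' @return Named numeric vector, `length(feature_names(config))` long.
#' @export
assemble_features <- function(wild_aa, mutant_aa, rs = NULL, domain = NULL,
                              contact = NULL, config = feature_config("full")) {
  parts <- list()
  if (config$use_entropy) {
    if (is.null(rs) || !is.finite(rs)) stop("entropy feature enabled but RS missing")
    parts$RS <- c(RS = as.numeric(rs))
  }
  if (config$use_types) {
    w <- one_hot_aa(wild_aa); m <- one_hot_aa(mutant_aa)
    names(w) <- paste0("wild_", AA_ALPHABET)
    names(m) <- paste0("mut_", AA_ALPHABET)
    parts$wild <- w
    parts$mut <- m
  }
  if (config$use_domain) {
    if (is.null(domain) || length(domain) != 20) stop("domain block enabled but composition missing")
    parts$dom <- stats::setNames(as.numeric(domain), paste0("dom_", AA_ALPHABET))
  }
  if (config$use_contact) {
    if (is.null(contact) || length(contact) != 20) stop("contact block enabled but composition missing")
    parts$cnt <- stats::setNames(as.numeric(contact), paste0("cnt_", AA_ALPHABET))
  }
  unlist(unname(parts))
}

#' Encode a variant table into a feature matrix
#'
#' Runs the whole feature pipeline for each substitution: identity-window
#' filtering and entropy of the protein's alignment, domain composition of
#' the covering segment (whole sequence when no segment covers the
#' position), and contact composition at the configuration's cutoff.  The
#' wild-type letter of every variant is checked against the query sequence
#' at that position; a mismatch is an error, because silently scoring the
#' wrong residue is the worst failure mode of a variant annotator.
#'
#' Variants on proteins lacking a structure model (or at positions missing
#' from the model) cannot get contact features; by default they are
#' dropped with a warning, or kept with all-zero composition sentinels
#' when `on_missing_structure = "zero"`.
#'
#' @param variants Tibble from [read_variant_table()] (or compatible).
#' @param alignments Named list of `aa_alignment` objects, one per protein.
#' @param structures Named list of `calpha_structure` objects.
#' @param segments Tibble with `protein_id`, `start`, `end`, or `NULL`.
#' @param config A `feature_config`.
#' @param on_missing_structure `"drop"` (default) or `"zero"`.
#' @param min_id,max_id Identity window for profile construction.
#' @return A `variant_features` object: list with `x` (matrix, one row per
#'   kept variant), `variants` (kept rows), `dropped` (rows without
#'   structure under `"drop"`), and `config`.
#' @export
encode_variants <- function(variants, alignments, structures = list(),
                            segments = NULL, config = feature_config("full"),
                            on_missing_structure = c("drop", "zero"),
                            min_id = 0.35, max_id = 0.90) {
  on_missing_structure <- match.arg(on_missing_structure)
  need_struct <- config$use_contact
  prots <- unique(variants$protein_id)
  missing_aln <- setdiff(prots, names(alignments))
  if (length(missing_aln) > 0) {
    stop("no alignment for protein(s): ", paste(missing_aln, collapse = ", "))
  }

  # per-protein context, computed once
  ctx <- lapply(stats::setNames(prots, prots), function(p) {
    trk <- entropy_track(alignments[[p]], min_id = min_id, max_id = max_id)
    list(
      query = query_sequence(alignments[[p]]),
      rs = trk$RS,
      structure = structures[[p]],
      segs = if (is.null(segments)) NULL else segments[segments$protein_id == p, , drop = FALSE]
    )
  })

  n <- nrow(variants)
  keep <- logical(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- variants$protein_id[i]
    pos <- variants$position[i]
    cx <- ctx[[p]]
    if (pos > length(cx$query)) {
      stop(sprintf("variant %s position %d beyond query length %d", p, pos, length(cx$query)))
    }
    if (cx$query[pos] != variants$wild_aa[i]) {
      stop(sprintf("reference mismatch for %s position %d: query has %s, variant claims %s",
                   p, pos, cx$query[pos], variants$wild_aa[i]))
    }
    has_struct <- !is.null(cx$structure) && pos %in% cx$structure$position
    if (need_struct && !has_struct && on_missing_structure == "drop") {
      keep[i] <- FALSE
      next
    }
    contact <- if (!config$use_contact) NULL
      else if (has_struct) contact_composition(cx$structure, pos, config$contact_cutoff)
      else stats::setNames(numeric(20), AA_ALPHABET)
    domain <- if (!config$use_domain) NULL else {
      seg <- segment_of(pos, cx$segs, length(cx$query))
      domain_composition(cx$query, seg)
    }
    rows[[i]] <- assemble_features(
      wild_aa = variants$wild_aa[i], mutant_aa = variants$mutant_aa[i],
      rs = if (config$use_entropy) cx$rs[pos] else NULL,
      domain = domain, contact = contact, config = config
    )
    keep[i] <- TRUE
  }
  dropped <- variants[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) {
    warning(nrow(dropped), " variant(s) dropped for lack of structural coverage")
  }
  x <- do.call(rbind, rows[keep])
  if (is.null(x)) x <- matrix(numeric(0), 0, length(feature_names(config)))
  colnames(x) <- feature_names(config)
  out <- list(
    x = x,
    variants = variants[keep, , drop = FALSE],
    dropped = dropped,
    config = config
  )
  class(out) <- "variant_features"
  out
}

#' @export
print.variant_features <- function(x, ...) {
  cat(sprintf(
    "<variant_features> %d variants x %d features (config '%s'; %d dropped)\n",
    nrow(x$x), ncol(x$x), x$config$name, nrow(x$dropped)
  ))
  invisible(x)
}

#' Tidy a variant feature matrix into one tibble
#'
#' @param x A `variant_features` object.
#' @param ... Unused.
#' @return A tibble: the kept variant rows with one column per feature.
#' @export
tidy.variant_features <- function(x, ...) {
  dplyr::bind_cols(x$variants, tibble::as_tibble(x$x))
}
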