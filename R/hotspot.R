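#' Saturation-mutagenesis scan of one protein
#'
#' Scores, at every covered residue position, all 19 substitutions other
#' than the reference amino acid.  A position is covered when every
#' feature block the model needs is computable there — in particular,
#' when the model uses contact features, the position must be present in
#' the structure model.  Uncovered positions are omitted (not scored as
#' zero).
#'
#' @param model A `gbrt` model carrying a feature configuration.
#' @param alignment The protein's `aa_alignment`.
#' @param structure The protein's `calpha_structure`, or `NULL` when the
#'   model uses no contact features.
#' @param segments Segment tibble for the protein (columns
#'   `protein_id`, `start`, `end`), or `NULL`.
#' @param protein_id Identifier recorded in the scan (defaults to the
#'   alignment's query id).
#' @param min_id,max_id Identity window for profile construction.
#' @return A `saturation_scan` tibble: `position`, `wild_aa`, `mutant_aa`,
#'   `score` (19 rows per covered position), with attributes `protein_id`,
#'   `covered` (positions scanned) and `n_positions` (sequence length).
#' @export
saturation_scan <- function(model, alignment, structure = NULL, segments = NULL,
                            protein_id = NULL, min_id = 0.35, max_id = 0.90) {
  if (is.null(model$feature_config)) {
    stop("model carries no feature configuration; cannot build features")
  }
  config <- model$feature_config
  protein_id <- protein_id %||% alignment$query_id
  query <- query_sequence(alignment)
  L <- length(query)
  covered <- seq_len(L)
  if (config$use_contact) {
    if (is.null(structure)) stop("model uses contact features but no structure supplied")
    covered <- intersect(covered, structure$position)
  }
  if (length(covered) == 0) stop("no covered positions to scan")

  variants <- purrr::map_dfr(covered, function(pos) {
    tibble::tibble(
      protein_id = protein_id,
      position = as.integer(pos),
      wild_aa = query[pos],
      mutant_aa = setdiff(AA_ALPHABET, query[pos])
    )
  })
  feats <- encode_variants(
    variants,
    alignments = stats::setNames(list(alignment), protein_id),
    structures = if (is.null(structure)) list() else stats::setNames(list(structure), protein_id),
    segments = segments, config = config,
    min_id = min_id, max_id = max_id
  )
  out <- dplyr::mutate(feats$variants, score = predict(model, feats$x))
  attr(out, "protein_id") <- protein_id
  attr(out, "covered") <- covered
  attr(out, "n_positions") <- L
  class(out) <- c("saturation_scan", class(out))
  out
}

#' Call hot-spot positions from a saturation scan
#'
#' A position is *hot* iff all 19 of its substitution scores are strictly
#' greater than the cutoff; the hot-spot fraction is the number of hot
#' positions divided by the number of covered positions (uncovered
#' positions enter neither numerator nor denominator).
#'
#' @param scan A `saturation_scan`.
#' @param cutoff Score cutoff (default 0.45).
#' @return A `hotspot_profile`: list with `protein_id`, `hot_positions`,
#'   `covered`, `fraction_hot`, `cutoff`.
#' @export
hot_positions <- function(scan, cutoff = 0.45) {
  per_pos <- dplyr::summarise(
    dplyr::group_by(scan, .data$position),
    min_score = min(.data$score), .groups = "drop"
  )
  hot <- per_pos$position[per_pos$min_score > cutoff]
  covered <- attr(scan, "covered")
  out <- list(
    protein_id = attr(scan, "protein_id"),
    hot_positions = as.integer(hot),
    covered = as.integer(covered),
    fraction_hot = length(hot) / length(covered),
    cutoff = cutoff
  )
  class(out) <- "hotspot_profile"
  out
}

#' @export
print.hotspot_profile <- function(x, ...) {
  cat(sprintf(
    "<hotspot_profile> '%s': %d/%d covered positions hot (fraction %.3f, cutoff %g)\n",
    x$protein_id, length(x$hot_positions), length(x$covered), x$fraction_hot, x$cutoff
  ))
  invisible(x)
}

#' Per-protein hot-spot fractions with isoform averaging
#'
#' When several isoform sequences share a protein id, the protein's
#' hot-spot fraction is the mean of its isoforms' fractions.
#'
#' @param profiles A list of `hotspot_profile` objects, or a tibble with
#'   columns `protein_id` and `fraction_hot` (one row per isoform).
#' @return A tibble with one row per protein: `protein_id`,
#'   `fraction_hot` (isoform mean), `n_isoforms`.
#' @export
hotspot_fractions <- function(profiles) {
  tbl <- if (is.data.frame(profiles)) {
    profiles
  } else {
    purrr::map_dfr(profiles, function(p) {
      tibble::tibble(protein_id = p$protein_id, fraction_hot = p$fraction_hot)
    })
  }
  dplyr::summarise(
    dplyr::group_by(tbl, .data$protein_id),
    fraction_hot = mean(.data$fraction_hot),
    n_isoforms = dplyr::n(),
    .groups = "drop"
  )
}

#' Attribute curve over hot-spot-fraction thresholds
#'
#' For each threshold `t`, averages an external per-protein attribute
#' (e.g. number of protein-protein interactions, or a 0/1
#' disease-association flag, whose mean is a cumulative fraction) over
#' the proteins whose hot-spot fraction is at least `t`, and reports the
#' Pearson correlation between the threshold grid and the curve values.
#' Thresholds with no qualifying protein are omitted with a message.
#'
#' @param per_protein Tibble with columns `fraction_hot` and `value`
#'   (the attribute), one row per protein; at least 2 proteins.
#' @param thresholds Sorted numeric vector of thresholds.
#' @return A `threshold_curve`: list with `curve` (tibble `threshold`,
#'   `mean_value`, `n`) and `pearson_r`.
#' @export
threshold_curve <- function(per_protein, thresholds = seq(0, 0.7, by = 0.05)) {
  if (nrow(per_protein) < 2) stop("need at least 2 proteins")
  pts <- purrr::map_dfr(thresholds, function(t) {
    qual <- per_protein$value[per_protein$fraction_hot >= t]
    if (length(qual) == 0) {
      return(tibble::tibble(threshold = t, mean_value = NA_real_, n = 0L))
    }
    tibble::tibble(threshold = t, mean_value = mean(qual), n = length(qual))
  })
  dropped <- sum(pts$n == 0)
  if (dropped > 0) {
    message(dropped, " threshold(s) had no qualifying protein and were omitted")
    pts <- pts[pts$n > 0, , drop = FALSE]
  }
  r <- if (nrow(pts) >= 2 && stats::sd(pts$mean_value) > 0 && stats::sd(pts$threshold) > 0) {
    stats::cor(pts$threshold, pts$mean_value)
  } else {
    NA_real_
  }
  out <- list(curve = pts, pearson_r = r)
  class(out) <- "threshold_curve"
  out
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold_curve> %d points, Pearson r = %s\n",
              nrow(x$curve),
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Tidy a hot-spot profile into per-position calls
#'
#' @param x A `hotspot_profile`.
#' @param ... Unused.
#' @return A tibble with `position` (covered positions) and logical `hot`.
#' @export
tidy.hotspot_profile <- function(x, ...) {
  tibble::tibble(
    position = x$covered,
    hot = x$covered %in% x$hot_positions
  )
}
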