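#' Specification for a synthetic benchmark dataset
#'
#' Describes the study conditions the generator emulates: per-protein
#' homolog alignments with a controllable fraction of conserved columns,
#' Calpha chain models with known geometry, and labelled substitutions
#' whose disease probability is a logistic function of planted signal
#' carried by the relative entropy (conserved positions are
#' disease-enriched) and, optionally, by the hydrophobic fraction of the
#' contact shell.  The defaults (20 proteins of length 100, 40 homologs,
#' half the columns conserved, 2,000 variants, neutral/disease ratio 1,
#' entropy slope 6 and contact slope 2) give a strongly recoverable
#' signal at a scale that trains in well under two minutes on one CPU.
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length (residues).
#' @param n_homologs Homolog rows per alignment (before identity filtering).
#' @param conserved_fraction Fraction of columns held identical across
#'   homologs.
#' @param substitution_rate Per-letter resampling probability in variable
#'   columns (controls homolog identity relative to the 35--90% window).
#' @param n_variants Total number of labelled substitutions.
#' @param neutral_disease_ratio Target neutral/disease ratio per protein
#'   (in expectation).
#' @param signal_entropy Logistic slope on `-RS` (0 = no entropy signal).
#' @param signal_contact Logistic slope on the centred hydrophobic contact
#'   fraction (0 = no contact signal).
#' @param geometry `"extended"` or `"helix"` chain geometry.
#' @param seed Integer seed; fully determines the dataset.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 20, length = 100, n_homologs = 40,
                           conserved_fraction = 0.5, substitution_rate = 0.5,
                           n_variants = 2000, neutral_disease_ratio = 1,
                           signal_entropy = 6, signal_contact = 2,
                           geometry = c("extended", "helix"), seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(
    n_proteins >= 1, length >= 2, n_homologs >= 0,
    conserved_fraction >= 0, conserved_fraction <= 1,
    substitution_rate >= 0, substitution_rate <= 1,
    n_variants >= 1, neutral_disease_ratio > 0
  )
  out <- list(
    n_proteins = n_proteins, length = length, n_homologs = n_homologs,
    conserved_fraction = conserved_fraction, substitution_rate = substitution_rate,
    n_variants = n_variants, neutral_disease_ratio = neutral_disease_ratio,
    signal_entropy = signal_entropy, signal_contact = signal_contact,
    geometry = geometry, seed = as.integer(seed)
  )
  class(out) <- "synthetic_spec"
  out
}

#' Generate a synthetic homolog alignment
#'
#' The query is drawn uniformly over the 20 standard letters.  Conserved
#' columns are identical across all homologs; in variable columns each
#' homolog letter is independently resampled (uniformly over the 20
#' types, so it may resample to the same letter) with probability
#' `substitution_rate`.  Homolog identity to the query is therefore
#' about `1 - rate * 19/20` on variable columns, which lets the rate
#' place identities inside or outside the 35--90% filtering window.
#'
#' @param length Number of columns (query residues).
#' @param n_homologs Number of homolog rows.
#' @param conserved_columns Integer vector of conserved column indices, or
#'   a single count (columns then drawn at random).
#' @param substitution_rate Per-letter resampling probability.
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream (used when a caller manages the seed).
#' @param query_id Identifier for the query row.
#' @return An `aa_alignment`.
#' @export
make_alignment <- function(length, n_homologs, conserved_columns,
                           substitution_rate, seed = NULL, query_id = "QUERY") {
  gen <- function() {
    # a single number is a count (columns drawn at random); a longer
    # vector is taken as explicit column indices
    if (length(conserved_columns) == 1) {
      cons <- sort(sample.int(length, conserved_columns[1]))
    } else {
      cons <- sort(unique(as.integer(conserved_columns)))
    }
    query <- sample(AA_ALPHABET, length, replace = TRUE)
    mat <- matrix(rep(query, each = n_homologs + 1), nrow = n_homologs + 1)
    if (n_homologs > 0) {
      variable <- setdiff(seq_len(length), cons)
      for (p in variable) {
        flip <- stats::runif(n_homologs) < substitution_rate
        if (any(flip)) {
          mat[1 + which(flip), p] <- sample(AA_ALPHABET, sum(flip), replace = TRUE)
        }
      }
    }
    new_aa_alignment(
      query_id = query_id,
      ids = c(query_id, sprintf("%s_h%03d", query_id, seq_len(n_homologs))),
      mat = mat
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic Calpha chain model
#'
#' `extended` places the trace on a straight line at 3.8 A spacing, so an
#' interior residue has exactly 6 neighbors within 12 A (3 x 3.8 = 11.4)
#' and 4 within 8 A; `helix` uses ideal alpha-helix parameters (rise
#' 1.5 A per residue, 100 degrees per turn, radius 2.3 A).
#'
#' @param length Number of residues.
#' @param geometry `"extended"` or `"helix"`.
#' @param sequence Optional residue letters (defaults to a uniform draw).
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @param protein_id Identifier attached to the model.
#' @return A `calpha_structure`.
#' @export
make_structure <- function(length, geometry = c("extended", "helix"),
                           sequence = NULL, seed = NULL, protein_id = "SYN") {
  geometry <- match.arg(geometry)
  gen <- function() {
    seq_letters <- sequence %||% sample(AA_ALPHABET, length, replace = TRUE)
    stopifnot(length(seq_letters) == length)
    i <- seq_len(length) - 1
    xyz <- switch(geometry,
      extended = cbind(3.8 * i, 0, 0),
      helix = cbind(
        2.3 * cos(i * 100 * pi / 180),
        2.3 * sin(i * 100 * pi / 180),
        1.5 * i
      )
    )
    new_calpha_structure(protein_id, seq_len(length), seq_letters, xyz)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a complete labelled synthetic dataset
#'
#' Produces, per protein: an alignment, a chain model whose residues match
#' the query sequence, a two-segment domain table, and a share of the
#' variant budget.  Substitution positions are drawn uniformly; the
#' disease probability of a substitution at position `p` is
#' `plogis(b + signal_entropy * (-RS_p) + signal_contact * (h_p - <h>))`,
#' where `RS` is the relative entropy computed by the package's own
#' profile pipeline, `h_p` the hydrophobic fraction of the 12 A contact
#' shell, and the per-protein intercept `b` is calibrated so the expected
#' disease fraction matches the target neutral/disease ratio.  With both
#' slopes at 0 labels are independent of every feature (the null
#' condition).
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `variants` (labelled tibble), `alignments`,
#'   `structures` (named lists), `segments` (tibble), `truth` (per-variant
#'   disease probabilities) and `spec`.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  target_p <- 1 / (1 + spec$neutral_disease_ratio)
  if (target_p <= 0 || target_p >= 1) stop("infeasible neutral/disease ratio target")
  withr::with_seed(spec$seed, {
    ids <- sprintf("SP%03d", seq_len(spec$n_proteins))
    per_prot <- diff(round(seq(0, spec$n_variants, length.out = spec$n_proteins + 1)))
    alignments <- list()
    structures <- list()
    seg_rows <- list()
    var_rows <- list()
    for (k in seq_along(ids)) {
      id <- ids[k]
      n_cons <- round(spec$conserved_fraction * spec$length)
      aln <- make_alignment(spec$length, spec$n_homologs, n_cons,
                            spec$substitution_rate, seed = NULL, query_id = id)
      query <- query_sequence(aln)
      struct <- make_structure(spec$length, spec$geometry, sequence = query,
                               seed = NULL, protein_id = id)
      half <- floor(spec$length / 2)
      segs <- tibble::tibble(
        protein_id = id,
        start = c(1L, half + 1L),
        end = c(half, as.integer(spec$length))
      )
      trk <- entropy_track(aln)
      h <- vapply(seq_len(spec$length), function(p) {
        comp <- contact_composition(struct, p, 12)
        sum(comp[AA_HYDROPHOBIC])
      }, numeric(1))
      eta <- spec$signal_entropy * (-trk$RS) + spec$signal_contact * (h - mean(h))
      b <- tryCatch(
        stats::uniroot(function(b) mean(stats::plogis(b + eta)) - target_p,
                       interval = c(-40, 40))$root,
        error = function(e) stop("could not calibrate intercept for ratio target: ", conditionMessage(e))
      )
      n_v <- per_prot[k]
      if (n_v > 0) {
        pos <- sample.int(spec$length, n_v, replace = TRUE)
        mut <- vapply(pos, function(p) sample(setdiff(AA_ALPHABET, query[p]), 1), character(1))
        p_dis <- stats::plogis(b + eta[pos])
        var_rows[[k]] <- tibble::tibble(
          protein_id = id,
          position = as.integer(pos),
          wild_aa = query[pos],
          mutant_aa = mut,
          label = stats::rbinom(n_v, 1, p_dis),
          p_disease = p_dis
        )
      }
      alignments[[id]] <- aln
      structures[[id]] <- struct
      seg_rows[[k]] <- segs
    }
    variants <- dplyr::bind_rows(var_rows)
    list(
      variants = dplyr::select(variants, -"p_disease"),
      truth = variants$p_disease,
      alignments = alignments,
      structures = structures,
      segments = dplyr::bind_rows(seg_rows),
      spec = spec
    )
  })
}

#' Write a synthetic dataset to plain-text fixture files
#'
#' Writes one aligned FASTA and one PDB per protein plus `variants.tsv`
#' and `segments.tsv`, in the formats every reader of the package
#' consumes.
#'
#' @param dataset Output of [make_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dataset$alignments)) {
    write_alignment(dataset$alignments[[id]], file.path(dir, paste0(id, ".aln.fasta")))
    write_calpha_structure(dataset$structures[[id]], file.path(dir, paste0(id, ".pdb")))
  }
  write_variant_table(dataset$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(dataset$segments, file.path(dir, "segments.tsv"))
  invisible(dir)
}
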