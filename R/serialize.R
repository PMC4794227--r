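# Model files are JSON documents whose floating-point fields are written
# as C99 hexadecimal float literals ("%a"), so a serialised model predicts
# bit-identically after loading.

GBRT_FORMAT <- "entvar-gbrt/1"

hexify <- function(x) {
  out <- sprintf("%a", x)
  out[is.na(x)] <- NA_character_
  out
}

unhexify <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[is.na(x)] <- NA_real_
  out
}

#' Write a boosted-tree model to a structured text file
#'
#' The file is JSON with a format tag, the feature configuration, the
#' shrinkage/base score, and every tree's node arrays.  Floating-point
#' values are stored as hexadecimal float literals, so
#' `read_gbrt(write_gbrt(m))` predicts bit-identically to `m`.
#'
#' @param model A `gbrt` model.
#' @param path Output path.
#' @return `model`, invisibly.
#' @export
write_gbrt <- function(model, path) {
  stopifnot(inherits(model, "gbrt"))
  doc <- list(
    format = GBRT_FORMAT,
    shrinkage = hexify(model$shrinkage),
    base_score = hexify(model$base_score),
    n_trees = model$n_trees,
    max_depth = model$max_depth,
    min_leaf = model$min_leaf,
    n_features = model$n_features,
    feature_names = model$feature_names,
    feature_config = if (is.null(model$feature_config)) NULL else {
      fc <- model$feature_config
      list(name = fc$name, use_types = fc$use_types, use_domain = fc$use_domain,
           use_contact = fc$use_contact, use_entropy = fc$use_entropy,
           contact_cutoff = fc$contact_cutoff)
    },
    trees = lapply(model$trees, function(t) {
      list(feature = t$feature, threshold = hexify(t$threshold),
           left = t$left, right = t$right, value = hexify(t$value))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", pretty = FALSE)
  invisible(model)
}

#' Load a boosted-tree model from file
#'
#' @param path Path written by [write_gbrt()].
#' @return A `gbrt` model predicting bit-identically to the serialised one.
#' @export
read_gbrt <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$format, GBRT_FORMAT)) {
    stop("unrecognised model file format tag: ", doc$format %||% "<none>")
  }
  fc <- NULL
  if (!is.null(doc$feature_config)) {
    fc <- feature_config(
      preset = NULL,
      use_types = doc$feature_config$use_types,
      use_domain = doc$feature_config$use_domain,
      use_contact = doc$feature_config$use_contact,
      use_entropy = doc$feature_config$use_entropy,
      contact_cutoff = doc$feature_config$contact_cutoff
    )
    fc$name <- doc$feature_config$name
  }
  trees <- lapply(doc$trees, function(t) {
    list(
      feature = as.integer(t$feature),
      threshold = unhexify(t$threshold),
      left = as.integer(t$left),
      right = as.integer(t$right),
      value = unhexify(t$value)
    )
  })
  out <- list(
    trees = trees,
    shrinkage = unhexify(doc$shrinkage),
    base_score = unhexify(doc$base_score),
    n_trees = as.integer(doc$n_trees),
    max_depth = as.integer(doc$max_depth),
    min_leaf = as.integer(doc$min_leaf),
    feature_names = doc$feature_names,
    feature_config = fc,
    n_features = as.integer(doc$n_features),
    mse_path = NULL,
    train_mse = NA_real_
  )
  class(out) <- "gbrt"
  out
}
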