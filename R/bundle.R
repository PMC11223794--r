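bundle_schema_version <- 1L

#' Package an end-to-end model into a portable single-file bundle
#'
#' Writes a `*.imotif` bundle: a POSIX tar archive (written with
#' R's internal tar) containing `manifest.json` (all scalar fields, feature
#' names, normalizer vectors — readable standalone), `model.bin` (the
#' serialized fitted pipeline, tagged with its serialization format) and
#' `checksum` (MD5 of the other two members, verified on load).
#'
#' @param model An `im_model` from [automl_train()].
#' @param path Output file path (conventionally `*.imotif`).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(model, path) {
  stopifnot(inherits(model, "im_model"))
  norm <- model$normalizer
  if (length(norm$center) != length(model$feature_names)) {
    stop("packaging error: normalizer width (", length(norm$center),
         ") does not match feature count (", length(model$feature_names), ")",
         call. = FALSE)
  }
  if (!length(model$feature_names)) {
    stop("packaging error: empty feature-name list", call. = FALSE)
  }
  if (!(model$label_min < model$label_max)) {
    stop("packaging error: label_min must be below label_max", call. = FALSE)
  }
  manifest <- list(
    schema_version = bundle_schema_version,
    detection_params = unclass(model$detection_params),
    feature_names = model$feature_names,
    selected_features = model$pipeline$selected,
    normalizer = list(
      method = norm$method,
      center = unname(norm$center),
      scale = unname(norm$scale),
      constant = unname(norm$constant),
      names = norm$names
    ),
    model_family = model$pipeline$model,
    fs_method = model$pipeline$fs_method,
    serialization = "rds",
    label_kind = model$label_kind,
    label_min = model$label_min,
    label_max = model$label_max,
    cv_r2 = model$pipeline$cv_r2,
    test_r2 = model$pipeline$test_r2,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    provenance = list(
      seed = model$seed,
      n_train = model$n_train,
      n_test = model$n_test,
      budget = unclass(model$result$budget),
      n_configs = nrow(model$result$history)
    )
  )
  stage <- tempfile("imbundle")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  saveRDS(model, file.path(stage, "model.bin"), version = 2)
  sums <- tools::md5sum(file.path(stage, c("manifest.json", "model.bin")))
  writeLines(paste(unname(sums), basename(names(sums))),
             file.path(stage, "checksum"))
  out_path <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(getwd(), path)
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(out_path, files = c("manifest.json", "model.bin", "checksum"),
             tar = "internal")
  invisible(path)
}

#' Load a model bundle
#'
#' Verifies the stored checksums and the schema version before
#' deserializing the model blob.
#'
#' @param path Path to a bundle written by [write_bundle()].
#' @return An `im_bundle`: the manifest plus the restored `im_model`.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle not found: ", path, call. = FALSE)
  stage <- tempfile("imbundle")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  utils::untar(normalizePath(path), exdir = stage, tar = "internal")
  needed <- file.path(stage, c("manifest.json", "model.bin", "checksum"))
  if (!all(file.exists(needed))) {
    stop("malformed bundle: missing members in ", path, call. = FALSE)
  }
  sums <- utils::read.table(needed[3], col.names = c("md5", "file"),
                            stringsAsFactors = FALSE)
  actual <- tools::md5sum(file.path(stage, sums$file))
  if (!all(unname(actual) == sums$md5)) {
    stop("bundle checksum mismatch: ", path, " is corrupt or was tampered with",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(needed[1], simplifyVector = TRUE)
  if (manifest$schema_version > bundle_schema_version) {
    stop("bundle schema version ", manifest$schema_version,
         " is newer than this reader (", bundle_schema_version, ")",
         call. = FALSE)
  }
  model <- readRDS(needed[2])
  structure(list(manifest = manifest, model = model), class = "im_bundle")
}

#' @export
print.im_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("i-motif model bundle (schema v%d)\n", m$schema_version))
  cat(sprintf("  %s + %s predicting %s in [%.3g, %.3g]\n",
              m$fs_method, m$model_family, m$label_kind, m$label_min, m$label_max))
  invisible(x)
}

as_im_model <- function(x) {
  if (inherits(x, "im_bundle")) x$model
  else if (inherits(x, "im_model")) x
  else stop("expected an im_model or im_bundle", call. = FALSE)
}

#' Score candidate motifs with a fitted model or bundle
#'
#' Runs detection with the model's stored parameters, extracts and
#' normalizes its feature set, predicts the label (e.g. transition pH) and
#' derives the stability score
#' `clamp((label - label_min) / (label_max - label_min), 0, 1)` from the
#' training-label range.
#'
#' @param model An `im_model` or `im_bundle`.
#' @param x A DNA string, named character vector, or candidate tibble from
#'   [find_imotifs()].
#' @return The candidate tibble with `predicted_label` and
#'   `stability_score` columns appended; zero rows when no motif is found.
#' @export
score_sequences <- function(model, x) {
  m <- as_im_model(model)
  cands <- if (is.data.frame(x)) x else find_imotifs(x, m$detection_params)
  if (nrow(cands) == 0L) {
    cands$predicted_label <- numeric(0)
    cands$stability_score <- numeric(0)
    return(cands)
  }
  feats <- extract_features(cands)
  Xn <- apply_normalizer(m$normalizer,
                         as.matrix(feats[, m$normalizer$names, drop = FALSE]))
  colnames(Xn) <- m$normalizer$names
  pred <- stats::predict(m$pipeline, Xn[, m$feature_names, drop = FALSE])
  cands$predicted_label <- as.numeric(pred)
  cands$stability_score <- pmin(pmax(
    (cands$predicted_label - m$label_min) / (m$label_max - m$label_min), 0), 1)
  cands
}

#' @rdname score_sequences
#' @param path Path to a FASTA file.
#' @export
score_fasta <- function(model, path) {
  m <- as_im_model(model)
  score_sequences(model, find_imotifs(read_fasta(path), m$detection_params))
}
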