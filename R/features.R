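#' Canonical i-motif feature names
#'
#' The fixed, ordered 33-feature set shared by every scoring model: 13
#' structural descriptors (motif length, tract count/length statistics,
#' loop count/length statistics, total loop length, fraction of the motif
#' inside C-tracts), the 4 mono-nucleotide fractions and the 16 dinucleotide
#' frequencies (AA..TT, row-major A,C,G,T order) over the motif. Length
#' statistics use the population (divide-by-n) variance; dinucleotide
#' frequencies are counts divided by motif length minus one.
#'
#' @format A character vector of length 33.
#' @export
imotif_feature_names <- c(
  "motif_length", "n_tracts",
  "tract_len_mean", "tract_len_min", "tract_len_max", "tract_len_var",
  "n_loops",
  "loop_len_mean", "loop_len_min", "loop_len_max", "loop_len_var",
  "loop_len_total", "tract_fraction",
  "frac_A", "frac_C", "frac_G", "frac_T",
  paste0("dinuc_", c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))))
)

#' Extract the canonical 33 features from candidates
#'
#' @param candidates A candidate tibble from [find_imotifs()] or
#'   [enumerate_candidates()].
#' @return The input tibble's identifying columns (`seq_id`, `start`, `end`,
#'   `strand`, `sequence`, when present) followed by the 33 feature columns
#'   named by [imotif_feature_names].
#' @examples
#' enumerate_candidates("CCCTAACCCTAACCCTAACCC") |> extract_features()
#' @export
extract_features <- function(candidates) {
  id_cols <- intersect(c("seq_id", "start", "end", "strand", "sequence"),
                       names(candidates))
  feats <- purrr::pmap(
    list(candidates$sequence, candidates$tract_lengths, candidates$loop_lengths),
    feature_vector
  )
  fm <- do.call(rbind, feats)
  if (is.null(fm)) fm <- matrix(numeric(0), ncol = 33L,
                                dimnames = list(NULL, imotif_feature_names))
  dplyr::bind_cols(candidates[id_cols], tibble::as_tibble(fm))
}

# One 33-vector from the motif sequence and its tract/loop length vectors.
feature_vector <- function(sequence, tract_lengths, loop_lengths) {
  s <- toupper(sequence)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  mono <- vapply(bases, function(b) sum(chars == b), numeric(1)) / n
  if (n >= 2L) {
    di <- paste0(chars[-n], chars[-1L])
    di_names <- c(t(outer(bases, bases, paste0)))
    dinuc <- vapply(di_names, function(d) sum(di == d), numeric(1)) / (n - 1L)
  } else {
    dinuc <- rep(0, 16L)
  }
  v <- c(
    n, length(tract_lengths),
    mean(tract_lengths), min(tract_lengths), max(tract_lengths), pop_var(tract_lengths),
    length(loop_lengths),
    loop_stat(loop_lengths, mean), loop_stat(loop_lengths, min),
    loop_stat(loop_lengths, max), pop_var(loop_lengths),
    sum(loop_lengths), sum(tract_lengths) / n,
    mono, dinuc
  )
  names(v) <- imotif_feature_names
  v
}

loop_stat <- function(x, f) if (length(x) == 0L) 0 else f(x)

#' Featurize bare i-motif sequences
#'
#' Re-validates each sequence against the detection grammar (the full
#' sequence must parse as a single motif under `params`: a greedy scan
#' anchored at the first base has to span the final base) and extracts the
#' canonical features from the validated parse.
#'
#' @param sequences Character vector of candidate i-motif sequences.
#' @param params A [detection_params()] object.
#' @return A tibble with one row per *input* sequence: `sequence`, `valid`,
#'   and the 33 feature columns (NA for invalid rows).
#' @export
featurize_sequences <- function(sequences, params = detection_params()) {
  rows <- purrr::map(sequences, function(s) {
    cand <- full_span_candidate(s, params)
    if (is.null(cand)) {
      na_feats <- tibble::as_tibble(as.list(stats::setNames(
        rep(NA_real_, 33L), imotif_feature_names
      )))
      return(dplyr::bind_cols(tibble::tibble(sequence = s, valid = FALSE), na_feats))
    }
    f <- extract_features(cand)
    dplyr::bind_cols(tibble::tibble(sequence = s, valid = TRUE),
                     f[, imotif_feature_names])
  })
  dplyr::bind_rows(rows)
}

# Parse a full sequence as exactly one motif, or NULL.
full_span_candidate <- function(s, params) {
  p <- params
  p$greedy <- TRUE
  p$allow_overlap <- TRUE
  p$scan_reverse_complement <- FALSE
  cands <- enumerate_candidates(s, p)
  hit <- cands[cands$start == 0L & cands$end == nchar(s), ]
  if (nrow(hit) == 0L) return(NULL)
  # re-resolve loop placement under the caller's loop mode for the fixed span
  hit[1, ]
}

#' Fit a feature normalizer
#'
#' @param x Numeric matrix or data frame of features (rows = motifs).
#' @param method `"zscore"` (center by column mean, scale by population
#'   standard deviation) or `"minmax"` (map the training range to `[0,1]`).
#' @return An `im_normalizer` with `center`, `scale`, `method` and a
#'   `constant` flag per column; constant columns get scale 1 and are passed
#'   through unchanged (minus their center).
#' @examples
#' fit_normalizer(matrix(rnorm(20), 10, 2))
#' @export
fit_normalizer <- function(x, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "zscore" && nrow(x) < 2L) {
    stop("zscore normalization requires at least 2 rows", call. = FALSE)
  }
  if (method == "zscore") {
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  } else {
    center <- apply(x, 2L, min)
    scale <- apply(x, 2L, max) - center
  }
  constant <- scale <= 0
  scale[constant] <- 1
  structure(
    list(center = center, scale = scale, constant = constant, method = method,
         names = colnames(x)),
    class = "im_normalizer"
  )
}

#' Apply (or invert) a fitted normalizer
#'
#' @param normalizer An `im_normalizer` from [fit_normalizer()].
#' @param x Matrix or data frame with the same columns the normalizer was
#'   fitted on.
#' @return A numeric matrix of the same shape.
#' @export
apply_normalizer <- function(normalizer, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(normalizer$center))
  sweep(sweep(x, 2L, normalizer$center), 2L, normalizer$scale, "/")
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(normalizer, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, normalizer$scale, "*"), 2L, normalizer$center, "+")
}

#' @export
print.im_normalizer <- function(x, ...) {
  cat(sprintf("i-motif feature normalizer (%s, %d columns, %d constant)\n",
              x$method, length(x$center), sum(x$constant)))
  invisible(x)
}
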