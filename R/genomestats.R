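#' Cytosine density of a genome
#'
#' Fraction of unambiguous bases that are cytosine, pooled over all records,
#' case-insensitive. N and other ambiguity codes are excluded from both
#' numerator and denominator; `genome_length` counts every base including
#' ambiguous ones (single-strand assembly length).
#'
#' @param x Path to a FASTA file or a named character vector of sequences.
#' @return A one-row tibble with `genome_length` and `c_density`.
#' @examples
#' c_density(c(chr = "ACGT"))
#' @export
c_density <- function(x) {
  seqs <- as_genome(x)
  counts <- base_counts(seqs)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) stop("genome contains no unambiguous ACGT bases", call. = FALSE)
  tibble::tibble(
    genome_length = sum(counts),
    c_density = counts[["C"]] / acgt
  )
}

as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && !is.null(x) && file.exists(x)) {
    read_fasta(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    toupper(x)
  } else {
    stop("expected a FASTA path or a character vector of sequences", call. = FALSE)
  }
}

base_counts <- function(seqs) {
  set <- Biostrings::DNAStringSet(toupper(seqs))
  freq <- Biostrings::alphabetFrequency(set, baseOnly = FALSE)
  totals <- colSums(freq)
  c(A = totals[["A"]], C = totals[["C"]], G = totals[["G"]], T = totals[["T"]],
    other = sum(totals) - totals[["A"]] - totals[["C"]] - totals[["G"]] - totals[["T"]])
}

#' Genome-scale i-motif summary (iPM and friends)
#'
#' Scans both strands with non-overlapping motif calls and reports the
#' motif density as i-motifs per million nucleotides,
#' `iPM = n_motifs / genome_length * 1e6`, where `genome_length` is the
#' single-strand assembly length (including ambiguous bases). With a fitted
#' model, the mean stability score over all motifs is added.
#'
#' @param x FASTA path or named character vector.
#' @param params [detection_params()]; `scan_reverse_complement` is forced
#'   on and `allow_overlap` off for density statistics.
#' @param model Optional `im_model` or `im_bundle` for scoring.
#' @param label Species/assembly name for the summary row.
#' @return A one-row tibble: `label`, `genome_length`, `c_density`,
#'   `n_motifs`, `ipm`, `mean_score` (NA without a model).
#' @export
genome_summary <- function(x, params = detection_params(), model = NULL,
                           label = "genome") {
  seqs <- as_genome(x)
  p <- params
  p$scan_reverse_complement <- TRUE
  p$allow_overlap <- FALSE
  cands <- find_imotifs(seqs, p)
  dens <- c_density(seqs)
  mean_score <- NA_real_
  if (!is.null(model) && nrow(cands) > 0L) {
    scored <- score_sequences(model, cands)
    mean_score <- mean(scored$stability_score)
  }
  tibble::tibble(
    label = label,
    genome_length = dens$genome_length,
    c_density = dens$c_density,
    n_motifs = nrow(cands),
    ipm = nrow(cands) / dens$genome_length * 1e6,
    mean_score = mean_score
  )
}

#' Cross-genome comparison table with relative scores
#'
#' Min–max normalizes the per-genome mean stability scores to a 0–1
#' `relative_score` so densities and stabilities can be ranked side by
#' side across species.
#'
#' @param summaries A tibble of [genome_summary()] rows (or a list of them).
#' @return The combined tibble with a `relative_score` column. When all
#'   mean scores are equal the relative score is defined as 0.5, with a
#'   warning.
#' @export
summarize_genomes <- function(summaries) {
  tbl <- if (is.data.frame(summaries)) summaries else dplyr::bind_rows(summaries)
  if (nrow(tbl) < 2L || all(is.na(tbl$mean_score))) {
    tbl$relative_score <- NA_real_
    return(tbl)
  }
  rng <- range(tbl$mean_score, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("all mean scores are equal; relative scores set to 0.5")
    tbl$relative_score <- ifelse(is.na(tbl$mean_score), NA_real_, 0.5)
  } else {
    tbl$relative_score <- (tbl$mean_score - rng[1]) / diff(rng)
  }
  tbl
}

#' Plot a cross-genome summary
#'
#' @param object A tibble from [summarize_genomes()] or bound
#'   [genome_summary()] rows.
#' @param ... Unused.
#' @return A ggplot of iPM per genome (and relative score when present).
#' @export
plot_genome_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$label, .data$ipm),
                                       y = .data$ipm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "i-motifs per million nucleotides (iPM)") +
    ggplot2::theme_minimal()
}
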