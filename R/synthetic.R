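# Synthetic data: motif-spiked genomes with ground truth and labelled
# feature-response training sets. Everything is reproducible from
# (specification, seed); sub-operations derive child seeds from the one
# global seed.

#' Specification for synthetic genome generation
#'
#' @param genome_length Background length in nucleotides.
#' @param gc_content Fraction of G+C in the background (in (0,1)).
#' @param n_motifs Number of i-motifs to spike in.
#' @param motif_params [detection_params()] defining the motif grammar.
#' @param seed Mandatory integer seed.
#' @return An `im_synth_spec` list.
#' @export
synthetic_spec <- function(genome_length = 1e5, gc_content = 0.4,
                           n_motifs = 10L, motif_params = detection_params(),
                           seed) {
  stopifnot(!missing(seed), gc_content > 0, gc_content < 1, genome_length > 0)
  structure(
    list(genome_length = as.integer(genome_length), gc_content = gc_content,
         n_motifs = as.integer(n_motifs), motif_params = motif_params,
         seed = as.integer(seed)),
    class = "im_synth_spec"
  )
}

#' Random motif-free background sequence
#'
#' Draws i.i.d. bases at the requested composition, then destroys any
#' accidental valid i-motif (on either strand) by C-to-T substitution of one
#' tract base, re-scanning until the detection engine certifies the sequence
#' clean.
#'
#' @param length Sequence length.
#' @param gc Target GC fraction.
#' @param seed Integer seed.
#' @param params Motif grammar the background must be free of.
#' @return A single DNA string with no detectable motif on either strand.
#' @export
random_background <- function(length, gc = 0.4, seed = 1L,
                              params = detection_params()) {
  stopifnot(length > 0)
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(probs), length, replace = TRUE, prob = probs)
  p <- params
  p$scan_reverse_complement <- TRUE
  p$allow_overlap <- TRUE
  repeat {
    s <- paste(chars, collapse = "")
    hits <- find_imotifs(c(bg = s), p)
    if (nrow(hits) == 0L) return(s)
    for (i in seq_len(nrow(hits))) {
      # first tract base of the motif, in forward-strand coordinates
      pos <- if (hits$strand[i] == "+") hits$start[i] + 1L else hits$end[i]
      chars[pos] <- if (hits$strand[i] == "+") "T" else "A"
    }
  }
}

# Sample one motif sequence uniformly from the constraint grammar: tract
# count, tract lengths and loop lengths uniform within bounds; loop bases
# drawn from {A,G,T} so tracts and ground-truth coordinates stay exact.
sample_motif <- function(params) {
  b <- loop_bounds(params)
  k <- sample_int_range(params$n_tracts_min, params$n_tracts_max)
  tract_lens <- vapply(seq_len(k), function(i) {
    sample_int_range(params$tract_len_min, params$tract_len_max)
  }, integer(1))
  if (k >= 2L) {
    roles <- loop_roles(k)
    loop_lens <- vapply(roles, function(r) {
      bb <- if (r == "side") b$side else b$middle
      sample_int_range(bb[1], bb[2])
    }, integer(1))
  } else {
    loop_lens <- integer(0)
  }
  parts <- character(0)
  for (i in seq_len(k)) {
    parts <- c(parts, strrep("C", tract_lens[i]))
    if (i < k) {
      parts <- c(parts, paste(sample(c("A", "G", "T"), loop_lens[i],
                                     replace = TRUE), collapse = ""))
    }
  }
  paste(parts, collapse = "")
}

sample_int_range <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  as.integer(sample(seq(lo, hi), 1L))
}

#' Spike ground-truth i-motifs into a background sequence
#'
#' Motifs are sampled uniformly from the constraint grammar, placed at
#' random non-overlapping positions at least 50 nt apart, on random strands
#' (a "-" motif is inserted as its reverse complement). The bases flanking
#' each insert are forced to non-C/non-G so the spiked tract boundaries are
#' exact. The truth table is verified against a greedy both-strand scan
#' before returning.
#'
#' @param background A motif-free DNA string (see [random_background()]).
#' @param n Number of motifs to spike.
#' @param params [detection_params()] grammar to sample from.
#' @param seed Integer seed.
#' @return A list: `genome` (named character vector of length 1) and
#'   `truth`, a tibble with `seq_id`, 0-based half-open `start`/`end`,
#'   `strand` and the C-rich `sequence` of every spiked motif.
#' @export
spike_motifs <- function(background, n, params = detection_params(), seed = 1L) {
  set.seed(seed + 1L)
  L <- nchar(background)
  if (n == 0L) {
    return(list(genome = c(synth = background),
                truth = tibble::tibble(seq_id = character(0), start = integer(0),
                                       end = integer(0), strand = character(0),
                                       sequence = character(0))))
  }
  motifs <- vapply(seq_len(n), function(i) sample_motif(params), character(1))
  widths <- nchar(motifs)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  sep <- 50L
  # each insert is flanked by a C/G-free buffer so no tract can reach across
  # a motif boundary within loop range
  buffer <- params$loop_max + params$tract_len_max
  block <- widths + 2L * buffer
  need <- sum(block) + (n - 1L) * sep
  if (need > L) {
    stop("background too short for ", n, " motifs with ", sep,
         " nt separation", call. = FALSE)
  }
  # random non-overlapping placement: distribute the slack uniformly
  slack <- L - need
  cuts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  prefix <- cumsum(c(0L, utils::head(block, -1L))) + (seq_len(n) - 1L) * sep
  starts <- cuts + prefix + buffer # 0-based motif starts
  chars <- strsplit(background, "")[[1]]
  for (i in seq_len(n)) {
    ins <- if (strands[i] == "+") motifs[i] else revcomp(motifs[i])
    idx <- seq(starts[i] + 1L, starts[i] + widths[i]) # 1-based slice
    chars[idx] <- strsplit(ins, "")[[1]]
    for (j in c(seq(starts[i] - buffer + 1L, starts[i]),
                seq(starts[i] + widths[i] + 1L, starts[i] + widths[i] + buffer))) {
      if (chars[j] == "C") chars[j] <- "T"
      if (chars[j] == "G") chars[j] <- "A"
    }
  }
  genome <- c(synth = paste(chars, collapse = ""))
  truth <- tibble::tibble(
    seq_id = "synth", start = starts, end = starts + widths,
    strand = strands, sequence = motifs
  )
  truth <- dplyr::arrange(truth, .data$start)
  p <- params
  p$greedy <- TRUE
  p$scan_reverse_complement <- TRUE
  p$allow_overlap <- FALSE
  found <- find_imotifs(genome, p)
  if (!identical(nrow(found), nrow(truth)) ||
      !all(found$start == truth$start & found$end == truth$end &
           found$strand == truth$strand)) {
    stop("internal error: greedy scan did not recover the spiked truth table",
         call. = FALSE)
  }
  list(genome = genome, truth = truth)
}

#' Generate a motif-spiked synthetic genome
#'
#' Convenience wrapper: [random_background()] then [spike_motifs()] under
#' one specification.
#'
#' @param spec An [synthetic_spec()].
#' @return A list with `genome` (named character vector) and the `truth`
#'   tibble of spiked coordinates.
#' @export
synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "im_synth_spec"))
  bg <- random_background(spec$genome_length, spec$gc_content, spec$seed,
                          spec$motif_params)
  spike_motifs(bg, spec$n_motifs, spec$motif_params, spec$seed)
}

#' Default linear label model for synthetic training sets
#'
#' Three informative structural features with a transition-pH-like
#' intercept; coefficients are in label units per raw feature unit.
#'
#' @return A list with `coefficients` (named), `intercept` and `noise_sd`.
#' @export
default_label_model <- function() {
  list(
    coefficients = c(loop_len_mean = -0.12, tract_len_mean = 0.25, frac_C = 1.2),
    intercept = 5.8,
    noise_sd = 0.1
  )
}

#' Labelled synthetic training set with a known feature–response law
#'
#' Samples `n` random valid i-motif sequences from the grammar and labels
#' them `intercept + sum(coef * feature) + N(0, noise_sd)` over the raw
#' (unnormalized) canonical features. With `target_r2` set, `noise_sd` is
#' derived so the population signal-to-total variance ratio equals it.
#'
#' @param n Number of rows (at least 10).
#' @param label_model List with `coefficients` over canonical feature names,
#'   `intercept` and `noise_sd` (see [default_label_model()]).
#' @param seed Integer seed.
#' @param params Motif grammar to sample sequences from.
#' @param target_r2 Optional signal R² in (0,1) overriding `noise_sd`.
#' @param ph_window Optional numeric length-2; labels are clipped into this
#'   plausible pH window when supplied.
#' @return A tibble with `sequence` and `label`; attributes `truth` (the
#'   label model actually used, including the realised `noise_sd`) and
#'   `features` (the raw feature tibble).
#' @export
labelled_dataset <- function(n, label_model = default_label_model(), seed = 1L,
                             params = detection_params(), target_r2 = NULL,
                             ph_window = NULL) {
  stopifnot(n >= 10L)
  set.seed(seed + 2L)
  seqs <- vapply(seq_len(n), function(i) sample_motif(params), character(1))
  feats <- featurize_sequences(seqs, params)
  stopifnot(all(feats$valid))
  coefs <- label_model$coefficients
  stopifnot(all(names(coefs) %in% imotif_feature_names))
  Xs <- as.matrix(feats[, names(coefs), drop = FALSE])
  signal <- label_model$intercept + drop(Xs %*% coefs)
  noise_sd <- label_model$noise_sd
  if (!is.null(target_r2)) {
    stopifnot(target_r2 > 0, target_r2 < 1)
    vs <- stats::var(signal)
    noise_sd <- sqrt(vs * (1 - target_r2) / target_r2)
  }
  label <- signal + stats::rnorm(n, 0, noise_sd)
  if (!is.null(ph_window)) {
    label <- pmin(pmax(label, ph_window[1]), ph_window[2])
  }
  out <- tibble::tibble(sequence = seqs, label = label)
  attr(out, "truth") <- list(coefficients = coefs,
                             intercept = label_model$intercept,
                             noise_sd = noise_sd, signal = signal)
  attr(out, "features") <- feats
  out
}
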