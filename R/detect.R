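#' Find maximal runs of cytosine in a DNA sequence
#'
#' @param sequence A single DNA string. Matching is case-insensitive; any
#'   non-C character (including N) terminates a run.
#' @return A tibble with 0-based half-open `start`/`end` coordinates and
#'   `length` of every maximal C-run, sorted by `start`. An empty sequence
#'   yields zero rows.
#' @examples
#' find_c_runs("CCCACCC")
#' @export
find_c_runs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  r <- c_run_bounds(toupper(sequence))
  tibble::tibble(start = r$starts, end = r$ends, length = r$ends - r$starts)
}

# 0-based run bounds; input assumed uppercase
c_run_bounds <- function(s) {
  if (nchar(s) == 0L) return(list(starts = integer(0), ends = integer(0)))
  m <- gregexpr("C+", s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(starts = integer(0), ends = integer(0)))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  list(starts = starts, ends = starts + lens)
}

# Precomputed per-sequence scan context.
# Eligible runs are maximal C-runs long enough to host a tract; the "gap"
# between consecutive eligible runs is everything in between (it may contain
# shorter C-runs, which by construction are below tract_len_min).
detect_context <- function(s, p) {
  r <- c_run_bounds(s)
  elig <- which(r$ends - r$starts >= p$tract_len_min)
  ne <- length(elig)
  gap_len <- integer(0)
  gap_ok <- logical(0)
  if (ne >= 2L) {
    e_start <- r$starts[elig]
    e_end <- r$ends[elig]
    gap_len <- e_start[-1L] - e_end[-ne]
    gap_ok <- vapply(seq_len(ne - 1L), function(i) {
      if (p$allow_n_in_loops) return(TRUE)
      g <- substr(s, e_end[i] + 1L, e_start[i + 1L])
      !grepl("[^ACGT]", g)
    }, logical(1))
  }
  list(
    seq = s, n = nchar(s),
    starts = r$starts[elig], ends = r$ends[elig], lens = r$ends[elig] - r$starts[elig],
    gap_len = gap_len, gap_ok = gap_ok
  )
}

loop_role_bounds <- function(bounds, i, k) {
  if (i == 1L || i == k - 1L) bounds$side else bounds$middle
}

# Feasible motif end positions for a k-tract motif whose first tract starts
# at q inside eligible run `ei`. Forward DP over trailing-leftover values
# (C's of a run spilled into the following loop, capped below tract_len_min).
# Returns NULL when infeasible, else c(min_end, max_end).
span_ends <- function(ctx, p, bounds, ei, q, k) {
  m <- p$tract_len_min
  M <- p$tract_len_max
  ne <- length(ctx$starts)
  if (ei + k - 1L > ne) return(NULL)
  avail1 <- ctx$ends[ei] - q
  if (avail1 < m) return(NULL)
  if (k == 1L) {
    lmax <- min(M, avail1)
    return(q + c(m, lmax))
  }
  lmax1 <- min(M, avail1)
  b_prev <- avail1 - (m:lmax1)
  b_prev <- b_prev[b_prev <= m - 1L]
  if (length(b_prev) == 0L) return(NULL)
  if (k > 2L) {
    for (i in 2:(k - 1L)) {
      gi <- ei + i - 2L # gap index before run i of the motif
      if (!ctx$gap_ok[gi]) return(NULL)
      g <- ctx$gap_len[gi]
      lb <- loop_role_bounds(bounds, i - 1L, k)
      len_i <- ctx$lens[ei + i - 1L]
      b_new <- integer(0)
      for (b in 0:min(m - 1L, len_i - m)) {
        a_lo0 <- max(0L, len_i - M - b)
        a_hi0 <- min(m - 1L, len_i - m - b)
        if (a_hi0 < a_lo0) next
        for (pb in b_prev) {
          a_lo <- max(a_lo0, lb[1] - pb - g)
          a_hi <- min(a_hi0, lb[2] - pb - g)
          if (a_hi >= a_lo) {
            b_new <- c(b_new, b)
            break
          }
        }
      }
      if (length(b_new) == 0L) return(NULL)
      b_prev <- b_new
    }
  }
  gi <- ei + k - 2L
  if (!ctx$gap_ok[gi]) return(NULL)
  g <- ctx$gap_len[gi]
  lb <- loop_role_bounds(bounds, k - 1L, k)
  len_k <- ctx$lens[ei + k - 1L]
  start_k <- ctx$starts[ei + k - 1L]
  min_end <- NA_integer_
  max_end <- NA_integer_
  for (a in 0:min(m - 1L, len_k - m)) {
    lp <- b_prev + g + a
    if (!any(lp >= lb[1] & lp <= lb[2])) next
    lmax <- min(M, len_k - a)
    min_end <- min(min_end, start_k + a + m, na.rm = TRUE)
    max_end <- max(max_end, start_k + a + lmax, na.rm = TRUE)
  }
  if (is.na(min_end)) return(NULL)
  c(min_end, max_end)
}

# All tract placements for a k-tract motif spanning exactly [q, e).
# Returns a list of list(starts=, lens=) with absolute 0-based tract starts.
placements_for_span <- function(ctx, p, bounds, ei, q, e, k) {
  m <- p$tract_len_min
  M <- p$tract_len_max
  out <- list()
  if (k == 1L) {
    l <- e - q
    if (l >= m && l <= min(M, ctx$ends[ei] - q)) {
      out[[1]] <- list(starts = q, lens = l)
    }
    return(out)
  }
  avail1 <- ctx$ends[ei] - q
  recurse <- function(i, starts, lens, prev_b) {
    run <- ei + i - 1L
    if (i == k) {
      g <- ctx$gap_len[run - 1L]
      lb <- loop_role_bounds(bounds, k - 1L, k)
      len_k <- ctx$lens[run]
      start_k <- ctx$starts[run]
      for (a in 0:min(m - 1L, len_k - m)) {
        lp <- prev_b + g + a
        if (lp < lb[1] || lp > lb[2]) next
        l <- e - (start_k + a)
        if (l < m || l > min(M, len_k - a)) next
        out[[length(out) + 1L]] <<- list(starts = c(starts, start_k + a),
                                         lens = c(lens, l))
      }
      return(invisible())
    }
    g <- ctx$gap_len[run - 1L]
    lb <- loop_role_bounds(bounds, i - 1L, k)
    len_i <- ctx$lens[run]
    start_i <- ctx$starts[run]
    for (a in 0:min(m - 1L, len_i - m)) {
      lp <- prev_b + g + a
      if (lp < lb[1] || lp > lb[2]) next
      for (l in m:min(M, len_i - a)) {
        b <- len_i - a - l
        if (b > m - 1L) next
        recurse(i + 1L, c(starts, start_i + a), c(lens, l), b)
      }
    }
    invisible()
  }
  for (l1 in m:min(M, avail1)) {
    b1 <- avail1 - l1
    if (b1 > m - 1L) next
    recurse(2L, q, l1, b1)
  }
  out
}

pop_var <- function(x) {
  if (length(x) == 0L) return(0)
  mean((x - mean(x))^2)
}

placement_loops <- function(pl) {
  k <- length(pl$starts)
  if (k < 2L) return(integer(0))
  pl$starts[-1L] - (pl$starts[-k] + pl$lens[-k])
}

# Objective-based choice among placements; ties broken by leftmost tract
# placement (lexicographically smallest start vector, then largest lengths).
best_placement <- function(placements, loop_mode) {
  stopifnot(length(placements) > 0L)
  keys <- lapply(placements, function(pl) {
    loops <- placement_loops(pl)
    v <- pop_var(loops)
    side <- if (length(loops) > 0L) loops[1] + loops[length(loops)] else 0
    if (loop_mode == "equal_loops") c(v, side) else c(side, v)
  })
  best <- 1L
  for (i in seq_along(placements)[-1L]) {
    if (placement_less(keys[[i]], placements[[i]], keys[[best]], placements[[best]])) {
      best <- i
    }
  }
  placements[[best]]
}

placement_less <- function(key_a, pl_a, key_b, pl_b) {
  for (j in seq_along(key_a)) {
    if (key_a[j] < key_b[j] - 1e-12) return(TRUE)
    if (key_a[j] > key_b[j] + 1e-12) return(FALSE)
  }
  cmp <- c(pl_a$starts, -pl_a$lens) - c(pl_b$starts, -pl_b$lens)
  nz <- which(cmp != 0)
  length(nz) > 0L && cmp[nz[1]] < 0
}

candidate_row <- function(seq_id, s, strand, pl, src_len = NULL) {
  k <- length(pl$starts)
  start <- pl$starts[1]
  end <- pl$starts[k] + pl$lens[k]
  loops <- placement_loops(pl)
  roles <- loop_roles(k)
  tibble::tibble(
    seq_id = seq_id,
    start = start, end = end, width = end - start,
    strand = strand,
    sequence = substr(s, start + 1L, end),
    n_tracts = k,
    tract_starts = list(pl$starts - start),
    tract_lengths = list(pl$lens),
    loop_lengths = list(loops),
    loop_roles = list(roles)
  )
}

loop_roles <- function(k) {
  if (k < 2L) return(character(0))
  roles <- rep("middle", k - 1L)
  roles[1] <- "side"
  roles[k - 1L] <- "side"
  roles
}

#' Enumerate putative i-motifs in one DNA sequence
#'
#' Core candidate enumeration on the given (C-rich) strand. Every maximal
#' C-run long enough to host a tract contributes anchor positions; for each
#' anchor the minimal (non-greedy) or maximal (greedy) valid motif starting
#' there is emitted, with tract offsets inside long C-runs resolved by the
#' loop-placement objective. A loop may contain cytosines, but never a run of
#' `tract_len_min` or more consecutive C (such a run must host a tract).
#'
#' @param sequence A single DNA string.
#' @param params A [detection_params()] object.
#' @param seq_id Identifier recorded in the `seq_id` column.
#' @return A tibble of candidates sorted by `start` with 0-based half-open
#'   coordinates, the motif `sequence`, and list-columns `tract_starts`
#'   (0-based offsets relative to the motif start), `tract_lengths`,
#'   `loop_lengths` and `loop_roles`. With `allow_overlap = FALSE`,
#'   overlapping candidates are resolved left-to-right.
#' @examples
#' enumerate_candidates("CCCTAACCCTAACCCTAACCC", detection_params())
#' @export
enumerate_candidates <- function(sequence, params = detection_params(),
                                 seq_id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  validate_params(params)
  s <- toupper(sequence)
  ctx <- detect_context(s, params)
  bounds <- loop_bounds(params)
  m <- params$tract_len_min
  rows <- list()
  for (ei in seq_along(ctx$starts)) {
    for (q in ctx$starts[ei]:(ctx$ends[ei] - m)) {
      span <- anchor_span(ctx, params, bounds, ei, q)
      if (is.null(span)) next
      pls <- placements_for_span(ctx, params, bounds, ei, q, span$end, span$k)
      if (length(pls) == 0L) next # defensive; span implies feasibility
      pl <- best_placement(pls, params$loop_mode)
      rows[[length(rows) + 1L]] <- candidate_row(seq_id, s, "+", pl)
    }
  }
  out <- if (length(rows) == 0L) empty_candidates() else dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$start, .data$end)
  if (!params$allow_overlap) out <- drop_overlaps(out)
  out
}

# Best span for an anchor: smallest feasible tract count and minimal end
# (non-greedy) or largest count and maximal end (greedy).
anchor_span <- function(ctx, p, bounds, ei, q) {
  best <- NULL
  for (k in p$n_tracts_min:p$n_tracts_max) {
    ends <- span_ends(ctx, p, bounds, ei, q, k)
    if (is.null(ends)) next
    if (p$greedy) {
      if (is.null(best) || ends[2] >= best$end) best <- list(k = k, end = ends[2])
    } else {
      if (is.null(best) || ends[1] < best$end) best <- list(k = k, end = ends[1])
    }
  }
  best
}

empty_candidates <- function() {
  tibble::tibble(
    seq_id = character(0), start = integer(0), end = integer(0),
    width = integer(0), strand = character(0), sequence = character(0),
    n_tracts = integer(0), tract_starts = list(), tract_lengths = list(),
    loop_lengths = list(), loop_roles = list()
  )
}

# Left-to-right overlap resolution: keep the leftmost candidate, drop any
# candidate intersecting a kept one. Assumes sorted by (start, end).
drop_overlaps <- function(cands) {
  if (nrow(cands) <= 1L) return(cands)
  keep <- logical(nrow(cands))
  last_end <- -1L
  for (i in seq_len(nrow(cands))) {
    if (cands$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cands$end[i]
    }
  }
  cands[keep, ]
}

#' Locate tracts and loops within a candidate region
#'
#' Given a stretch of sequence containing the C-runs of one motif, chooses
#' the tract placement (which cytosines of each long C-run form the tract)
#' optimising the loop objective: `equal_loops` minimises the variance of
#' loop lengths; `short_side_loops` minimises the summed length of the two
#' side loops, then the variance. Ties are broken by the leftmost placement.
#' Motif boundaries float inside the region: cytosines of the first and last
#' runs left out of their tracts fall outside the motif.
#'
#' @param region A DNA string containing the candidate's C-runs.
#' @param params A [detection_params()] object; `loop_mode` selects the
#'   objective.
#' @return `NULL` when no feasible placement exists, otherwise a list with
#'   tibbles `tracts` (start, end, length) and `loops` (start, end, role,
#'   length), 0-based half-open, relative to the region.
#' @examples
#' assign_loops("CCCCACCCTTTTCCCACCCC",
#'              detection_params(loop_mode = "short_side_loops"))
#' @export
assign_loops <- function(region, params = detection_params()) {
  stopifnot(is.character(region), length(region) == 1L)
  validate_params(params)
  s <- toupper(region)
  ctx <- detect_context(s, params)
  bounds <- loop_bounds(params)
  k <- length(ctx$starts)
  if (k < params$n_tracts_min || k > params$n_tracts_max) return(NULL)
  m <- params$tract_len_min
  pls <- list()
  for (q in ctx$starts[1]:(ctx$ends[1] - m)) {
    ends <- span_ends(ctx, params, bounds, 1L, q, k)
    if (is.null(ends)) next
    for (e in ends[1]:ends[2]) {
      pls <- c(pls, placements_for_span(ctx, params, bounds, 1L, q, e, k))
    }
  }
  if (length(pls) == 0L) return(NULL)
  pl <- best_placement(pls, params$loop_mode)
  loops <- placement_loops(pl)
  kk <- length(pl$starts)
  tract_end <- pl$starts + pl$lens
  list(
    tracts = tibble::tibble(start = pl$starts, end = tract_end, length = pl$lens),
    loops = tibble::tibble(
      start = tract_end[-kk], end = pl$starts[-1L],
      role = loop_roles(kk), length = loops
    )
  )
}

#' Scan sequences (both strands) for i-motifs
#'
#' @param x A named character vector of DNA sequences, a
#'   `Biostrings::DNAStringSet`, or a single unnamed string.
#' @param params A [detection_params()] object. When
#'   `scan_reverse_complement` is `TRUE`, motifs on the reverse complement
#'   are reported with strand `"-"` and coordinates mapped back to the
#'   forward strand; overlap resolution is applied per strand.
#' @return A candidate tibble (see [enumerate_candidates()]) sorted by
#'   `seq_id` and `start`. `sequence` is always the motif in its C-rich
#'   orientation.
#' @examples
#' find_imotifs(c(frag = "CCCTAACCCTAACCCTAACCC"))
#' @export
find_imotifs <- function(x, params = detection_params()) {
  validate_params(params)
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else {
    stopifnot(is.character(x))
    seqs <- x
  }
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) "seq" else paste0("seq", seq_along(seqs))
  }
  res <- purrr::imap(seqs, function(s, id) {
    s <- toupper(s)
    fwd <- enumerate_candidates(s, params, seq_id = id)
    if (!params$scan_reverse_complement) return(fwd)
    rc <- revcomp(s)
    rev_hits <- enumerate_candidates(rc, params, seq_id = id)
    if (nrow(rev_hits) > 0L) {
      L <- nchar(s)
      new_start <- L - rev_hits$end
      rev_hits$end <- L - rev_hits$start
      rev_hits$start <- new_start
      rev_hits$strand <- "-"
    }
    dplyr::bind_rows(fwd, rev_hits)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty_candidates())
  dplyr::arrange(out, .data$seq_id, .data$start, .data$end)
}

#' Scan a FASTA file for i-motifs
#'
#' Reads a (possibly gzipped) multi-record FASTA and runs [find_imotifs()]
#' on every record. Motifs never span records.
#'
#' @param path Path to a FASTA file.
#' @param params A [detection_params()] object.
#' @return A candidate tibble, see [find_imotifs()].
#' @export
scan_fasta <- function(path, params = detection_params()) {
  seqs <- read_fasta(path)
  find_imotifs(seqs, params)
}

read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]), collapse = "")
}

#' Write candidates to a BED6 file
#'
#' Coordinates are 0-based half-open. The score column carries the
#' stability score scaled to 0-1000 when a `stability_score` column is
#' present, otherwise 0.
#'
#' @param candidates A candidate tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(candidates, path) {
  score <- if ("stability_score" %in% names(candidates)) {
    as.integer(round(pmin(pmax(candidates$stability_score, 0), 1) * 1000))
  } else {
    rep(0L, nrow(candidates))
  }
  bed <- tibble::tibble(
    chrom = candidates$seq_id,
    start = candidates$start,
    end = candidates$end,
    name = paste0("iM_", seq_len(nrow(candidates))),
    score = score,
    strand = candidates$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a human-readable TSV report of candidates
#'
#' Coordinates are 1-based inclusive in this report (BED output keeps the
#' 0-based half-open convention).
#'
#' @param candidates A candidate tibble, optionally with `predicted_label`
#'   and `stability_score` columns from [score_sequences()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, path) {
  rep_tbl <- tibble::tibble(
    seq_id = candidates$seq_id,
    start_1based = candidates$start + 1L,
    end_1based = candidates$end,
    length = candidates$width,
    strand = candidates$strand,
    sequence = candidates$sequence,
    tract_lengths = vapply(candidates$tract_lengths, paste, character(1), collapse = ","),
    loop_lengths = vapply(candidates$loop_lengths, paste, character(1), collapse = ",")
  )
  if ("predicted_label" %in% names(candidates)) {
    rep_tbl$predicted_label <- candidates$predicted_label
  }
  if ("stability_score" %in% names(candidates)) {
    rep_tbl$stability_score <- candidates$stability_score
  }
  readr::write_tsv(rep_tbl, path)
  invisible(path)
}
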