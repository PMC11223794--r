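# Independent brute-force oracle for the motif grammar.
#
# Works character-by-character on substrings, with no shared code with the
# run-based detection engine: a substring is a valid motif iff it parses as
# tract / loop / ... / tract where tracts are all-C with length in the tract
# range, every loop contains at least one non-C, no run of tract_len_min or
# more C's, no ambiguous base (unless allowed), and loop lengths respect
# their side/middle bounds for the parse's final tract count.

oracle_role_bounds <- function(p) {
  or_else <- function(a, b) if (is.null(a)) b else a
  list(
    side = c(or_else(p$side_loop_min, p$loop_min), or_else(p$side_loop_max, p$loop_max)),
    middle = c(or_else(p$middle_loop_min, p$loop_min), or_else(p$middle_loop_max, p$loop_max))
  )
}

# All parses of the FULL string s; each parse: starts (0-based, relative),
# lens, loops.
oracle_parses <- function(s, p) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  is_c <- ch == "C"
  m <- p$tract_len_min
  M <- p$tract_len_max
  rb <- oracle_role_bounds(p)
  hi_any <- max(rb$side[2], rb$middle[2])
  res <- list()
  loop_content_ok <- function(from, to) {
    sub <- ch[from:to]
    if (!p$allow_n_in_loops && any(!sub %in% c("A", "C", "G", "T"))) return(FALSE)
    if (all(sub == "C")) return(FALSE)
    r <- rle(sub == "C")
    maxrun <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    maxrun < m
  }
  recurse <- function(pos, starts, lens, loops) {
    for (l in m:M) {
      if (pos + l > n) break
      if (!all(is_c[(pos + 1):(pos + l)])) break
      st <- c(starts, pos)
      le <- c(lens, l)
      k <- length(st)
      if (pos + l == n && k >= p$n_tracts_min && k <= p$n_tracts_max) {
        ok <- TRUE
        for (i in seq_along(loops)) {
          b <- if (i == 1L || i == k - 1L) rb$side else rb$middle
          if (loops[i] < b[1] || loops[i] > b[2]) {
            ok <- FALSE
            break
          }
        }
        if (ok) res[[length(res) + 1L]] <<- list(starts = st, lens = le, loops = loops)
      }
      if (k < p$n_tracts_max) {
        for (L in 1:hi_any) {
          if (pos + l + L + m > n) break
          if (!loop_content_ok(pos + l + 1L, pos + l + L)) next
          recurse(pos + l + L, st, le, c(loops, L))
        }
      }
    }
  }
  recurse(0L, integer(0), integer(0), integer(0))
  res
}

oracle_parse_key <- function(pp, loop_mode, q) {
  loops <- pp$loops
  v <- if (length(loops) == 0L) 0 else mean((loops - mean(loops))^2)
  sidesum <- if (length(loops) == 0L) 0 else loops[1] + loops[length(loops)]
  obj <- if (loop_mode == "equal_loops") c(v, sidesum) else c(sidesum, v)
  c(obj, q + pp$starts, -pp$lens)
}

oracle_key_less <- function(a, b) {
  len <- min(length(a), length(b))
  for (i in seq_len(len)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  length(a) < length(b)
}

# Full enumeration by brute force over every (start, end) substring.
oracle_enumerate <- function(s, p) {
  s <- toupper(s)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  m <- p$tract_len_min
  M <- p$tract_len_max
  rb <- oracle_role_bounds(p)
  maxspan <- p$n_tracts_max * M + (p$n_tracts_max - 1L) * max(rb$side[2], rb$middle[2])
  rows <- list()
  for (q in 0:(n - 1L)) {
    if (ch[q + 1L] != "C") next
    # parseable (end, k) pairs for a motif whose first tract starts at q
    pairs <- list()
    parse_cache <- list()
    for (e in (q + 1L):min(n, q + maxspan)) {
      if (ch[e] != "C") next
      parses <- oracle_parses(substr(s, q + 1L, e), p)
      if (length(parses) == 0L) next
      parse_cache[[as.character(e)]] <- parses
      for (k in unique(vapply(parses, function(pp) length(pp$starts), integer(1)))) {
        pairs[[length(pairs) + 1L]] <- c(e, k)
      }
    }
    if (length(pairs) == 0L) next
    tab <- do.call(rbind, pairs)
    pick <- if (p$greedy) {
      tab[order(tab[, 1], tab[, 2], decreasing = TRUE)[1], ]
    } else {
      tab[order(tab[, 1], tab[, 2])[1], ]
    }
    e <- pick[1]
    k <- pick[2]
    parses <- Filter(function(pp) length(pp$starts) == k,
                     parse_cache[[as.character(e)]])
    best <- parses[[1]]
    best_key <- oracle_parse_key(best, p$loop_mode, q)
    for (pp in parses[-1]) {
      key <- oracle_parse_key(pp, p$loop_mode, q)
      if (oracle_key_less(key, best_key)) {
        best <- pp
        best_key <- key
      }
    }
    rows[[length(rows) + 1L]] <- list(
      start = q, end = e, tract_starts = best$starts,
      tract_lengths = best$lens, loop_lengths = best$loops
    )
  }
  if (!p$allow_overlap && length(rows) > 1L) {
    kept <- list()
    last_end <- -1L
    for (r in rows) { # rows are already in start order
      if (r$start >= last_end) {
        kept[[length(kept) + 1L]] <- r
        last_end <- r$end
      }
    }
    rows <- kept
  }
  rows
}

# Canonical comparable form of a candidate tibble
candidate_signature <- function(cands) {
  lapply(seq_len(nrow(cands)), function(i) {
    list(start = cands$start[i], end = cands$end[i],
         tract_starts = as.integer(cands$tract_starts[[i]]),
         tract_lengths = as.integer(cands$tract_lengths[[i]]),
         loop_lengths = as.integer(cands$loop_lengths[[i]]))
  })
}

oracle_signature <- function(rows) {
  lapply(rows, function(r) {
    list(start = as.integer(r$start), end = as.integer(r$end),
         tract_starts = as.integer(r$tract_starts),
         tract_lengths = as.integer(r$tract_lengths),
         loop_lengths = as.integer(r$loop_lengths))
  })
}

random_dna <- function(n, pC = 0.35) {
  pr <- c(A = (1 - pC) / 3, C = pC, G = (1 - pC) / 3, T = (1 - pC) / 3)
  paste(sample(names(pr), n, replace = TRUE, prob = pr), collapse = "")
}
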