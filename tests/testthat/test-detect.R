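test_that("find_c_runs returns maximal sorted runs and matches a scan oracle", {
  expect_equal(find_c_runs("CCCACCC")[, c("start", "end")],
               tibble::tibble(start = c(0L, 4L), end = c(3L, 7L)))
  expect_equal(nrow(find_c_runs("AGTG")), 0L)
  expect_equal(nrow(find_c_runs("")), 0L)

  set.seed(11)
  for (rep in 1:10) {
    s <- random_dna(200)
    runs <- find_c_runs(s)
    # character-by-character scan oracle
    ch <- strsplit(s, "")[[1]] == "C"
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    expect_equal(runs$start, starts[r$values])
    expect_equal(runs$end, ends[r$values])
  }
})

test_that("single-motif detection resolves span, tracts and loops", {
  cand <- enumerate_candidates("CCCTAACCCTAACCCTAACCC", detection_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 0L)
  expect_equal(cand$end, 21L)
  expect_equal(cand$n_tracts, 4L)
  expect_equal(cand$tract_lengths[[1]], rep(3L, 4))
  expect_equal(cand$loop_lengths[[1]], rep(3L, 4 - 1))

  # ten consecutive C cannot host four separated tracts
  expect_equal(nrow(enumerate_candidates("CCCCCCCCCC", detection_params())), 0L)

  # a record of only N yields nothing
  expect_equal(nrow(enumerate_candidates(strrep("N", 100), detection_params())), 0L)
})

test_that("invalid detection parameters name the offending field", {
  expect_error(detection_params(tract_len_min = 4, tract_len_max = 3),
               "tract_len_max")
  expect_error(detection_params(loop_min = 0), "loop_min")
  expect_error(detection_params(side_loop_max = 99), "side_loop_max")
})

test_that("loop placement optimises the configured objective", {
  region <- "CCCCACCCTTTTCCCACCCC"
  eq <- assign_loops(region, detection_params(loop_mode = "equal_loops"))
  expect_equal(eq$loops$length, c(2L, 4L, 2L))
  expect_equal(eq$loops$role, c("side", "middle", "side"))
  ss <- assign_loops(region, detection_params(loop_mode = "short_side_loops"))
  expect_equal(ss$loops$length, c(1L, 4L, 1L))

  # no freedom when every run is exactly tract_len_min long
  rigid <- "CCCTACCCGTTACCCTTCCC"
  a <- assign_loops(rigid, detection_params(loop_mode = "equal_loops"))
  b <- assign_loops(rigid, detection_params(loop_mode = "short_side_loops"))
  expect_identical(a, b)
  expect_equal(a$tracts$length, rep(3L, 4))

  # infeasible region is rejected, not an error
  expect_null(assign_loops("CCCTTTCCC", detection_params()))
})

test_that("loop placement matches exhaustive offset search on random regions", {
  set.seed(42)
  for (mode in c("equal_loops", "short_side_loops")) {
    p <- detection_params(loop_mode = mode)
    n_checked <- 0
    for (rep in 1:40) {
      lens <- sample(3:5, 4, replace = TRUE)
      loops <- sample(1:8, 3, replace = TRUE)
      region <- paste0(
        strrep("C", lens[1]),
        paste(sample(c("A", "T"), loops[1], TRUE), collapse = ""),
        strrep("C", lens[2]),
        paste(sample(c("A", "T"), loops[2], TRUE), collapse = ""),
        strrep("C", lens[3]),
        paste(sample(c("A", "T"), loops[3], TRUE), collapse = ""),
        strrep("C", lens[4])
      )
      got <- assign_loops(region, p)
      if (is.null(got)) next
      n_checked <- n_checked + 1
      # brute force: score every parse of every substring spanning all runs
      best_key <- NULL
      for (q in 0:(nchar(region) - 1)) {
        for (e in (q + 1):nchar(region)) {
          for (pp in oracle_parses(substr(region, q + 1, e), p)) {
            key <- oracle_parse_key(pp, mode, q)
            if (is.null(best_key) || oracle_key_less(key, best_key)) best_key <- key
          }
        }
      }
      got_loops <- got$loops$length
      got_key <- c(
        if (mode == "equal_loops") {
          c(mean((got_loops - mean(got_loops))^2), got_loops[1] + got_loops[3])
        } else {
          c(got_loops[1] + got_loops[3], mean((got_loops - mean(got_loops))^2))
        },
        got$tracts$start, -got$tracts$length
      )
      expect_equal(got_key, best_key)
    }
    expect_gt(n_checked, 20)
  }
})

test_that("enumeration equals the brute-force substring-grammar oracle", {
  set.seed(7)
  combos <- expand.grid(greedy = c(FALSE, TRUE),
                        loop_mode = c("equal_loops", "short_side_loops"),
                        stringsAsFactors = FALSE)
  for (rep in 1:25) {
    s <- random_dna(120, pC = 0.4)
    for (i in seq_len(nrow(combos))) {
      p <- detection_params(greedy = combos$greedy[i],
                            loop_mode = combos$loop_mode[i])
      got <- enumerate_candidates(s, p)
      expect_identical(candidate_signature(got), oracle_signature(oracle_enumerate(s, p)),
                       info = sprintf("rep %d greedy=%s mode=%s", rep,
                                      combos$greedy[i], combos$loop_mode[i]))
    }
  }
})

test_that("oracle equivalence holds with overlaps allowed and per-role bounds", {
  set.seed(19)
  p <- detection_params(allow_overlap = TRUE)
  p2 <- detection_params(side_loop_min = 1, side_loop_max = 4,
                         middle_loop_min = 2, middle_loop_max = 9)
  for (rep in 1:10) {
    s <- random_dna(120, pC = 0.4)
    for (pp in list(p, p2)) {
      expect_identical(candidate_signature(enumerate_candidates(s, pp)),
                       oracle_signature(oracle_enumerate(s, pp)))
    }
  }
})

test_that("relaxing constraints never loses candidates when overlap is allowed", {
  set.seed(23)
  tight <- detection_params(loop_max = 6, allow_overlap = TRUE)
  loose <- detection_params(loop_max = 12, allow_overlap = TRUE)
  wide_tract <- detection_params(loop_max = 6, tract_len_max = 6, allow_overlap = TRUE)
  for (rep in 1:15) {
    s <- random_dna(250, pC = 0.4)
    n_tight <- nrow(enumerate_candidates(s, tight))
    expect_gte(nrow(enumerate_candidates(s, loose)), n_tight)
    expect_gte(nrow(enumerate_candidates(s, wide_tract)), n_tight)
  }
})

test_that("every candidate tiles into alternating tracts and loops", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_dna(300, pC = 0.4)
    cands <- find_imotifs(c(x = s), detection_params(allow_overlap = TRUE))
    for (i in seq_len(nrow(cands))) {
      tr <- cands$tract_lengths[[i]]
      lp <- cands$loop_lengths[[i]]
      expect_equal(sum(tr) + sum(lp), cands$width[i])
      expect_equal(length(lp), cands$n_tracts[i] - 1L)
      # motif sequence starts and ends with a tract
      sq <- cands$sequence[i]
      expect_equal(substr(sq, 1, tr[1]), strrep("C", tr[1]))
      k <- length(tr)
      expect_equal(substr(sq, nchar(sq) - tr[k] + 1, nchar(sq)), strrep("C", tr[k]))
    }
  }
})

test_that("reverse-complement scanning is symmetric and maps coordinates", {
  p <- detection_params()
  s <- "TTTGGGTTAGGGTTAGGGTTAGGGTTT" # G-rich: motif only on the minus strand
  hits <- find_imotifs(c(chr = s), p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 24L)
  expect_equal(hits$sequence, "CCCTAACCCTAACCCTAACCC")

  set.seed(5)
  for (rep in 1:8) {
    s <- random_dna(300, pC = 0.35)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    both <- find_imotifs(c(x = s), p)
    fwd_only <- detection_params(scan_reverse_complement = FALSE)
    n_fwd <- nrow(find_imotifs(c(x = s), fwd_only))
    n_rc_fwd <- nrow(find_imotifs(c(x = rc), fwd_only))
    expect_equal(nrow(both), n_fwd + n_rc_fwd)
  }

  # two-record file where record 2 is the reverse complement of record 1
  s <- "AATCCCTACCCGTTACCCATCCCTTT"
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  hits2 <- find_imotifs(c(a = s, b = rc), p)
  counts <- table(hits2$seq_id)
  expect_equal(unname(counts[["a"]]), unname(counts[["b"]]))
  expect_setequal(unique(hits2$strand[hits2$seq_id == "a"]), "+")
  expect_setequal(unique(hits2$strand[hits2$seq_id == "b"]), "-")
})

test_that("FASTA scanning reads plain and gzipped files and reports bad input", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 first record", "AATCCCTACCCGTTACCCATCCCTTT",
               ">chr2", strrep("N", 40)), tmp)
  hits <- scan_fasta(tmp, detection_params())
  expect_true(all(hits$seq_id == "chr1"))
  expect_gte(nrow(hits), 1L)

  gz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "w")
  writeLines(c(">chr1", "AATCCCTACCCGTTACCCATCCCTTT"), con)
  close(con)
  expect_equal(nrow(scan_fasta(gz, detection_params())), 1L)

  expect_error(scan_fasta(tempfile()), "not found")
})

test_that("BED and TSV outputs round-trip coordinates and strands", {
  cands <- find_imotifs(c(chr = "AATCCCTACCCGTTACCCATCCCTTTT"), detection_params())
  bed <- tempfile(fileext = ".bed")
  write_bed(cands, bed)
  b <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                       show_col_types = FALSE)
  expect_equal(b$start, cands$start)
  expect_equal(b$end, cands$end)
  expect_equal(b$strand, cands$strand)

  tsv <- tempfile(fileext = ".tsv")
  write_report(cands, tsv)
  r <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(r$start_1based, cands$start + 1L)
  expect_equal(r$end_1based, cands$end)
  expect_equal(r$length, cands$width)
})
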