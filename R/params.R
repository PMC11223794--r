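#' Detection parameters for i-motif scanning
#'
#' Bundles every structural knob of the i-motif caller into one validated
#' object. An i-motif is modelled as `n_tracts` C-tracts (runs of consecutive
#' cytosines on the C-rich strand) separated by loops; the first and last
#' loops are "side" loops, interior ones "middle" loops.
#'
#' @param n_tracts_min,n_tracts_max Number of C-tracts a motif may contain
#'   (default exactly 4, the canonical intramolecular i-motif).
#' @param tract_len_min,tract_len_max Consecutive cytosines per tract
#'   (default 3 to 5).
#' @param loop_min,loop_max Overall loop-length bounds in nucleotides
#'   (default 1 to 12), used for any role without a per-role override.
#' @param side_loop_min,side_loop_max,middle_loop_min,middle_loop_max
#'   Optional per-role loop bounds overriding `loop_min`/`loop_max`.
#' @param greedy If `FALSE` (default) the motif anchored at a feasible
#'   first-tract position is the minimal-length valid motif there; if `TRUE`
#'   it is the maximal-length valid motif.
#' @param allow_overlap If `FALSE` (default) overlapping candidates are
#'   resolved left-to-right: the leftmost candidate is kept and any candidate
#'   intersecting a kept one is dropped.
#' @param loop_mode Placement objective when a C-run is longer than the
#'   chosen tract: `"equal_loops"` minimises the variance of loop lengths,
#'   `"short_side_loops"` minimises the summed side-loop length first, then
#'   the variance. Ties are broken by the leftmost placement.
#' @param scan_reverse_complement Scan the reverse complement too (default
#'   `TRUE`; motifs found there are reported with strand `"-"` and
#'   forward-strand coordinates).
#' @param allow_n_in_loops Permit ambiguous bases (N and other non-ACGT
#'   letters) inside loops. Default `FALSE` for conservative motif calls.
#'
#' @return An object of class `im_params` (a named list).
#' @examples
#' p <- detection_params()
#' p$tract_len_min
#' @export
detection_params <- function(n_tracts_min = 4L, n_tracts_max = 4L,
                             tract_len_min = 3L, tract_len_max = 5L,
                             loop_min = 1L, loop_max = 12L,
                             side_loop_min = NULL, side_loop_max = NULL,
                             middle_loop_min = NULL, middle_loop_max = NULL,
                             greedy = FALSE, allow_overlap = FALSE,
                             loop_mode = c("equal_loops", "short_side_loops"),
                             scan_reverse_complement = TRUE,
                             allow_n_in_loops = FALSE) {
  loop_mode <- match.arg(loop_mode)
  p <- list(
    n_tracts_min = as.integer(n_tracts_min),
    n_tracts_max = as.integer(n_tracts_max),
    tract_len_min = as.integer(tract_len_min),
    tract_len_max = as.integer(tract_len_max),
    loop_min = as.integer(loop_min),
    loop_max = as.integer(loop_max),
    side_loop_min = if (is.null(side_loop_min)) NULL else as.integer(side_loop_min),
    side_loop_max = if (is.null(side_loop_max)) NULL else as.integer(side_loop_max),
    middle_loop_min = if (is.null(middle_loop_min)) NULL else as.integer(middle_loop_min),
    middle_loop_max = if (is.null(middle_loop_max)) NULL else as.integer(middle_loop_max),
    greedy = isTRUE(greedy),
    allow_overlap = isTRUE(allow_overlap),
    loop_mode = loop_mode,
    scan_reverse_complement = isTRUE(scan_reverse_complement),
    allow_n_in_loops = isTRUE(allow_n_in_loops)
  )
  class(p) <- "im_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid detection parameter `", field, "`: ", msg, call. = FALSE)
  }
  scalar_fields <- c("n_tracts_min", "n_tracts_max", "tract_len_min",
                     "tract_len_max", "loop_min", "loop_max")
  for (f in scalar_fields) {
    chk(length(p[[f]]) == 1L && !is.na(p[[f]]), f, "must be a single non-missing integer")
  }
  chk(p$n_tracts_min >= 1L, "n_tracts_min", "must be >= 1")
  chk(p$tract_len_min >= 1L, "tract_len_min", "must be >= 1")
  chk(p$loop_min >= 1L, "loop_min", "must be >= 1")
  chk(p$n_tracts_min <= p$n_tracts_max, "n_tracts_max", "must be >= n_tracts_min")
  chk(p$tract_len_min <= p$tract_len_max, "tract_len_max", "must be >= tract_len_min")
  chk(p$loop_min <= p$loop_max, "loop_max", "must be >= loop_min")
  role_fields <- c("side_loop_min", "side_loop_max", "middle_loop_min", "middle_loop_max")
  for (f in role_fields) {
    v <- p[[f]]
    if (!is.null(v)) {
      chk(length(v) == 1L && !is.na(v) && v >= 1L && v <= 50L, f,
          "per-role loop bounds must lie in [1, 50]")
    }
  }
  b <- loop_bounds(p)
  chk(b$side[1] <= b$side[2], "side_loop_max", "side loop minimum exceeds maximum")
  chk(b$middle[1] <= b$middle[2], "middle_loop_max", "middle loop minimum exceeds maximum")
  invisible(p)
}

# Resolved per-role loop bounds: list(side = c(lo, hi), middle = c(lo, hi))
loop_bounds <- function(p) {
  side <- c(p$side_loop_min %||% p$loop_min, p$side_loop_max %||% p$loop_max)
  middle <- c(p$middle_loop_min %||% p$loop_min, p$middle_loop_max %||% p$loop_max)
  list(side = as.integer(side), middle = as.integer(middle))
}

#' @export
print.im_params <- function(x, ...) {
  b <- loop_bounds(x)
  cat("i-motif detection parameters\n")
  cat(sprintf("  C-tracts: %d-%d, tract length %d-%d\n",
              x$n_tracts_min, x$n_tracts_max, x$tract_len_min, x$tract_len_max))
  cat(sprintf("  loops: side %d-%d, middle %d-%d (mode: %s)\n",
              b$side[1], b$side[2], b$middle[1], b$middle[2], x$loop_mode))
  cat(sprintf("  greedy: %s, allow_overlap: %s, reverse complement: %s\n",
              x$greedy, x$allow_overlap, x$scan_reverse_complement))
  invisible(x)
}
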