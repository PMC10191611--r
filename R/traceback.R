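#' Regenerate the edge bitvectors of a cell from the store
#'
#' In `entries` and `entries-dent` modes (SENE), the edge bitvectors `I`,
#' `D`, `S`, `M` are not stored; this recomputes them by re-applying the
#' cell update to the stored neighbor entries. In `edges` mode the stored
#' `I`, `D`, `M` are read directly and `S` is derived by shifting `D`. Both
#' paths agree bit-for-bit on every shared cell. At the match row `d = 0`
#' only the `M` edge exists (it equals the stored entry); `I`, `D`, `S` are
#' returned as all-ones.
#'
#' In `entries-dent` mode the arithmetic happens in the trimmed width; only
#' bits `j <= W - O - 1` of the result are meaningful, which covers every
#' bit a truncated traceback may query.
#'
#' @param fill A [fill_table()] result.
#' @param d Row (edit count), `0 <= d < rows_computed`.
#' @param i Column, `0 <= i < n` (and within the trimmed region for
#'   `entries-dent`).
#' @return List with bit strings `I`, `D`, `S`, `M`, `entry`.
#' @examples
#' f <- fill_table("ACGT", "ACGA", window_params(W = 4, O = 0, dent = FALSE))
#' regenerate_edges(f, 1, 0)$M  # "0110"
#' @export
regenerate_edges <- function(fill, d, i) {
  stopifnot(inherits(fill, "frg_fill"))
  d <- as.integer(d); i <- as.integer(i)
  if (d < 0L || d >= fill$rows_computed)
    stop("row d outside the computed rows", call. = FALSE)
  dent <- identical(fill$mode, "entries-dent")
  if (fill$mode == "edges") {
    if (i < 0L || i > fill$n) stop("column i out of range", call. = FALSE)
    if (d == 0L) {
      ones <- .bv_ones(fill$m)
      M <- fill$stored$M[1L, i + 1L]
      return(list(I = ones, D = ones, S = ones, M = M, entry = M))
    }
    I <- fill$stored$I[d + 1L, i + 1L]
    D <- fill$stored$D[d + 1L, i + 1L]
    M <- fill$stored$M[d + 1L, i + 1L]
    S <- .bv_shl(D)
    return(list(I = I, D = D, S = S, M = M,
                entry = .bv_and(.bv_and(I, D), .bv_and(S, M))))
  }
  ent <- fill$stored$entries
  cols <- fill$cols_stored
  w <- fill$bits_per_entry
  if (d == 0L) {
    if (i < 0L || i >= cols)
      stop("(d, i) outside the stored region", call. = FALSE)
    ones <- .bv_ones(w)
    M <- ent[1L, i + 1L]
    return(list(I = ones, D = ones, S = ones, M = M, entry = M))
  }
  if (i < 0L || i + 1L >= cols)
    stop("(d, i) outside the stored region", call. = FALSE)
  mask <- build_pattern_masks(fill$pattern)$masks
  ch <- substr(fill$text, i + 1L, i + 1L)
  mk <- if (ch %in% c("A", "C", "G", "T")) mask[[ch]] else mask$other
  if (dent) mk <- substr(mk, 1L, w)  # trimmed mask: bits j = 0 .. w-1
  dc_cell(north = ent[d, i + 1L], northeast = ent[d, i + 2L],
          east = ent[d + 1L, i + 2L], mask = mk)
}

#' Select the traceback edge at a bit position
#'
#' Returns the first of `M`, `S`, `D`, `I` (fixed priority) whose bitvector
#' has bit `j` equal to 0. Matches are cost-free so `M` comes first;
#' preferring `S` among the cost-1 edges keeps the walk on the diagonal.
#' Any fixed order is valid; this one is deterministic and documented.
#'
#' @param edges An edge set as returned by [regenerate_edges()] or
#'   [dc_cell()].
#' @param j Bit index with `edges$entry` bit `j` equal to 0.
#' @param match_only If `TRUE` (the match row `d = 0`), only `M` is
#'   eligible.
#' @return One of `"M"`, `"S"`, `"D"`, `"I"`.
#' @export
select_edge <- function(edges, j, match_only = FALSE) {
  order <- if (match_only) "M" else c("M", "S", "D", "I")
  for (e in order)
    if (.bv_bit(edges[[e]], j) == 0L) return(e)
  stop("select_edge: no zero bit among the candidate edges ",
       "(violates the AND identity)", call. = FALSE)
}

#' Trace one window back into edit operations
#'
#' Walks the path of 0s from `(d = d_opt, i = 0, j = 0)` toward the
#' north-east corner, emitting `=` (match), `X` (substitution), `I`
#' (insertion) and `D` (deletion). A non-terminal window stops as soon as
#' `i` or `j` reaches `W - O`, so with DENT only the trimmed region is ever
#' touched. A terminal window continues until both sequences are consumed;
#' if the pattern runs out first the remaining text is appended as a `D`
#' tail (and symmetrically an `I` tail as a fallback).
#'
#' @param text,pattern Window sequences (length at most `params$W`).
#' @param params A [window_params()] object.
#' @param terminal Is this the final window (trace to the corner)?
#' @return Object of class `"frg_window_result"`: `ops` (letter string),
#'   `text_consumed`, `pattern_consumed`, `d_start`, `padded_tail`, plus
#'   fill metadata and traffic counters.
#' @examples
#' traceback_window("ACGT", "ACGA", window_params(W = 4, O = 0,
#'                  dent = FALSE))$ops  # "===X"
#' @export
traceback_window <- function(text, pattern, params = window_params(),
                             terminal = TRUE) {
  params <- .as_params(params)
  if (params$dent && terminal)
    stop("DENT only supports truncated (non-terminal) tracebacks; ",
         "use dent = FALSE for a terminal window", call. = FALSE)
  res <- cpp_traceback(.norm_seq(text), .norm_seq(pattern), params$W,
                       params$O, params$mode, params$et, terminal)
  res$params <- params
  class(res) <- "frg_window_result"
  res
}

#' @export
print.frg_window_result <- function(x, ...) {
  cat(sprintf("window traceback: %s\n", canonicalize_cigar(x$ops)))
  cat(sprintf("  consumed (text, pattern) = (%d, %d), d_start = %d, padded tail = %d\n",
              x$text_consumed, x$pattern_consumed, x$d_start, x$padded_tail))
  invisible(x)
}
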