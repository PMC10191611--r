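# Bitvector primitives on "0"/"1" strings, bit j = 0 leftmost (most
# significant). These pure-R versions define the contract; the compiled fill
# uses the same conventions on machine words and is cross-checked against
# them in the tests.

.bv_check <- function(x, what = "bitvector") {
  if (length(x) != 1L || is.na(x) || !grepl("^[01]*$", x))
    stop(sprintf("%s must be a single string of 0s and 1s", what),
         call. = FALSE)
  x
}

# left shift: bit j+1 moves into bit j, vacated bit m-1 filled with 0
.bv_shl <- function(s) {
  m <- nchar(s)
  if (m == 0L) return(s)
  paste0(substr(s, 2L, m), "0")
}

.bv_op <- function(a, b, op) {
  if (nchar(a) != nchar(b))
    stop("bitvector width mismatch", call. = FALSE)
  if (nchar(a) == 0L) return(a)
  ai <- utf8ToInt(a) - 48L
  bi <- utf8ToInt(b) - 48L
  intToUtf8(op(ai, bi) + 48L)
}
.bv_and <- function(a, b) .bv_op(a, b, function(x, y) x * y)
.bv_or  <- function(a, b) .bv_op(a, b, function(x, y) pmax(x, y))
.bv_bit <- function(s, j) as.integer(substr(s, j + 1L, j + 1L))
.bv_ones <- function(m) strrep("1", m)

#' Build per-character pattern masks
#'
#' The mask for character `X` has bit `i` equal to 0 exactly where
#' `pattern[i] == X`; the match update rule ORs the mask of the current text
#' character into the shifted east neighbor. Characters outside `A/C/G/T`
#' (e.g. `N`) get a 1 in all four masks at their position, so they never
#' match and always cost an edit; the catch-all `other` mask (all ones) is
#' used when the *text* holds an ambiguous character.
#'
#' @param pattern Nucleotide string (case-insensitive; `U` treated as `T`).
#' @return Object of class `"frg_masks"`: a list with `width` and `masks`
#'   (named bit strings for `A`, `C`, `G`, `T` and `other`).
#' @examples
#' build_pattern_masks("ACGA")$masks$A  # "0110"
#' @export
build_pattern_masks <- function(pattern) {
  pattern <- .norm_seq(pattern)
  m <- nchar(pattern)
  chars <- if (m > 0L) strsplit(pattern, "", fixed = TRUE)[[1]] else character()
  masks <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    if (m == 0L) "" else paste(ifelse(chars == b, "0", "1"), collapse = "")
  })
  masks$other <- .bv_ones(m)
  structure(list(width = m, pattern = pattern, masks = masks),
            class = "frg_masks")
}

#' Boundary-column bitvector
#'
#' The rightmost DP column models the empty text suffix: pattern suffix `j`
#' is reachable at cost `d` exactly when its `m - j` characters can all be
#' inserted, i.e. `m - j <= d`. Hence the `d` least significant bits are 0
#' and the rest 1.
#'
#' @param d Edit count (row index), `d >= 0`.
#' @param m Bitvector width (pattern length).
#' @return A bit string of width `m`.
#' @examples
#' boundary_vector(2, 4)  # "1100"
#' @export
boundary_vector <- function(d, m) {
  d <- as.integer(d); m <- as.integer(m)
  if (is.na(d) || d < 0L) stop("d must be >= 0", call. = FALSE)
  if (is.na(m) || m < 0L) stop("m must be >= 0", call. = FALSE)
  if (d >= m) return(strrep("0", m))
  paste0(strrep("1", m - d), strrep("0", d))
}

#' One interior DP cell update
#'
#' Computes the four edge bitvectors and the ANDed entry of a cell from its
#' neighbors: insertion from the north, deletion and substitution from the
#' north-east, match from the east (shifted and ORed with the pattern mask
#' of the current text character).
#'
#' @param north `R[d-1][i]` bit string.
#' @param northeast `R[d-1][i+1]` bit string.
#' @param east `R[d][i+1]` bit string.
#' @param mask Pattern mask of `text[i]`.
#' @return List with bit strings `I`, `D`, `S`, `M` and `entry`
#'   (`entry = I & D & S & M`; `S = D << 1`).
#' @examples
#' dc_cell("1111", "1111", "1110", "1101")$entry  # "1100"
#' @export
dc_cell <- function(north, northeast, east, mask) {
  for (x in list(north, northeast, east, mask)) .bv_check(x)
  widths <- c(nchar(north), nchar(northeast), nchar(east), nchar(mask))
  if (length(unique(widths)) != 1L)
    stop("dc_cell: all inputs must have equal width", call. = FALSE)
  I <- .bv_shl(north)
  D <- northeast
  S <- .bv_shl(D)
  M <- .bv_or(.bv_shl(east), mask)
  list(I = I, D = D, S = S, M = M,
       entry = .bv_and(.bv_and(I, D), .bv_and(S, M)))
}

#' Fill the bitvector DP table for one window
#'
#' Row `d = 0` is the match-only row; rows are filled in increasing edit
#' count `d`, each from the boundary column leftward. `d_opt` is the first
#' row whose leftmost bit `j = 0` is 0: the minimum number of edits needed
#' to match the whole pattern against some prefix of the text. With
#' `params$et` on, no row beyond `d_opt` is computed.
#'
#' The storage mode follows `params` (`edges`, `entries`, or
#' `entries-dent`); write-traffic counters record exactly the bits crossing
#' the store boundary (forefront rows held in registers are free).
#'
#' @param text,pattern Nucleotide strings of length at most `params$W`.
#' @param params A [window_params()] object.
#' @return Object of class `"frg_fill"`: `d_opt`, `rows_computed`, traffic
#'   counters (`bits_written`, `cells_written`, `capacity_bits`), the full
#'   computed `table` (character matrix of bit strings, rows `d = 0, ...`),
#'   and the mode-dependent `stored` payloads.
#' @examples
#' f <- fill_table("ACGT", "ACGA", window_params(W = 4, O = 0, dent = FALSE))
#' f$d_opt           # 1
#' f$table[2, 3]     # entry at d = 1, i = 2: "1100"
#' @export
fill_table <- function(text, pattern, params = window_params()) {
  params <- .as_params(params)
  text <- .norm_seq(text); pattern <- .norm_seq(pattern)
  res <- cpp_fill_table(text, pattern, params$W, params$O, params$mode,
                        params$et)
  res$text <- text; res$pattern <- pattern; res$params <- params
  class(res) <- "frg_fill"
  res
}

#' @export
print.frg_fill <- function(x, ...) {
  cat(sprintf("bitvector DP fill: n = %d, m = %d, W = %d, mode = %s\n",
              x$n, x$m, x$W, x$mode))
  cat(sprintf("  d_opt = %d, rows computed = %d / %d\n",
              x$d_opt, x$rows_computed, x$k + 1L))
  cat(sprintf("  store: %d cells, %.0f bits written (capacity %.0f bits)\n",
              x$cells_written, x$bits_written, x$capacity_bits))
  invisible(x)
}
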