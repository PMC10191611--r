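#' Aligner configuration: window size, overlap and improvement flags
#'
#' Validates one aligner configuration. Each window aligns up to `W`
#' characters of each sequence; only the first `W - O` characters are
#' committed, the remaining `O` are re-examined in the next window. `W`
#' bounds the edits considered per window (the row count `k` of the DP table
#' is fixed to `W`). Larger `W` and `O` improve accuracy at the cost of more
#' computation per committed character.
#'
#' @param W Window size in characters, `1 <= W <= 64` (bitvectors are held
#'   in single machine words).
#' @param O Window overlap in characters, `0 <= O < W`.
#' @param sene Store only ANDed entries and regenerate edges during
#'   traceback, instead of storing three edge bitvectors per cell.
#' @param dent Trim the stored table to the `W - O + 1` columns and bits a
#'   truncated traceback can reach. Requires `sene`; automatically disabled
#'   for terminal windows, which trace to the corner.
#' @param et Early termination: stop the row-wise fill at the first row
#'   whose leftmost most-significant bit is 0.
#' @param preset `"long"` (`W = 64, O = 33`) or `"short"` (`W = 32, O = 17`);
#'   overrides `W` and `O`. The defaults are the long-read preset: `O = 33`
#'   makes the trimmed DENT bitvectors exactly 32 bits.
#' @return An object of class `"frg_params"`.
#' @examples
#' window_params()                 # long-read preset, all improvements on
#' window_params(preset = "short")
#' window_params(W = 16, O = 7, dent = FALSE)
#' @export
window_params <- function(W = 64L, O = 33L, sene = TRUE, dent = TRUE,
                          et = TRUE, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("long", "short"))
    if (preset == "long") { W <- 64L; O <- 33L } else { W <- 32L; O <- 17L }
  }
  W <- as.integer(W); O <- as.integer(O)
  if (length(W) != 1L || is.na(W) || W < 1L || W > 64L)
    stop("W must be a single integer in [1, 64]", call. = FALSE)
  if (length(O) != 1L || is.na(O) || O < 0L || O >= W)
    stop("O must satisfy 0 <= O < W", call. = FALSE)
  sene <- isTRUE(sene); dent <- isTRUE(dent); et <- isTRUE(et)
  if (dent && !sene)
    stop("dent requires sene (DENT trims the entries table)", call. = FALSE)
  structure(
    list(W = W, O = O, k = W, sene = sene, dent = dent, et = et,
         mode = if (!sene) "edges" else if (dent) "entries-dent" else "entries"),
    class = "frg_params")
}

#' @export
print.frg_params <- function(x, ...) {
  cat(sprintf("window params: W = %d, O = %d (k = W)\n", x$W, x$O))
  cat(sprintf("  improvements: sene = %s, dent = %s, et = %s (store mode: %s)\n",
              x$sene, x$dent, x$et, x$mode))
  invisible(x)
}

.as_params <- function(params) {
  if (inherits(params, "frg_params")) return(params)
  stop("params must be created with window_params()", call. = FALSE)
}

# uppercase, RNA U -> T; anything outside A/C/G/T is kept and treated as
# never-matching by the DP
.norm_seq <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}
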