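# Evaluation harnesses: early-termination skip fraction, storage
# footprint/traffic report, accuracy quantiles vs the exact oracle, and the
# correctly-aligned-bases metric.

#' Mean fraction of DP rows skipped by early termination
#'
#' Generates `n_pairs` i.i.d. uniform random pairs, both of length `W`,
#' fills a single window per pair with early termination on, and records
#' `(k - d_opt) / (k + 1)`: the fraction of table rows never computed.
#' Uncorrelated random pairs over a 4-letter alphabet have an expected edit
#' distance of at most `3W/4`, so on average at least a quarter of the rows
#' are skipped; correlated (real candidate) pairs skip far more.
#'
#' @param n_pairs Number of random pairs.
#' @param W Window size (both sequences have this length).
#' @param seed Optional RNG seed (caller's RNG state restored on exit).
#' @param pairs Optional data frame with `text`, `pattern` columns to use
#'   instead of random pairs (lengths must be at most `W`).
#' @return List with `mean_fraction`, the per-pair `fractions`, `W` and
#'   `n_pairs`.
#' @export
skip_fraction_experiment <- function(n_pairs = 1000L, W = 64L, seed = NULL,
                                     pairs = NULL) {
  W <- as.integer(W)
  if (is.null(pairs)) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(as.integer(seed))
    }
    n_pairs <- as.integer(n_pairs)
    if (is.na(n_pairs) || n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
    draw <- function() paste(sample(c("A", "C", "G", "T"), W, replace = TRUE),
                             collapse = "")
    pairs <- data.frame(text = replicate(n_pairs, draw()),
                        pattern = replicate(n_pairs, draw()),
                        stringsAsFactors = FALSE)
  }
  k <- W
  fr <- vapply(seq_len(nrow(pairs)), function(r) {
    f <- cpp_fill_table(.norm_seq(pairs$text[r]), .norm_seq(pairs$pattern[r]),
                        W, 0L, "entries", TRUE)
    (k - f$d_opt) / (k + 1)
  }, numeric(1))
  list(mean_fraction = mean(fr), fractions = fr, W = W, n_pairs = nrow(pairs))
}

#' Storage footprint and write-traffic report
#'
#' Fills one representative full window (`n = m = W`, early termination
#' off so all `k + 1` rows are built) in each storage mode and reads the
#' store counters: capacity in bytes, bits written during the fill, and
#' bits read back during a truncated traceback. All ratios are derived
#' from the counters, never hard-coded. At `W = 64, O = 33` the entries
#' table holds `65 * 65` entries of 64 bits = 33,800 bytes; the
#' edges/entries write ratio is exactly 3, entries/entries-dent is
#' `(65*64)/(32*32) ~ 4.06` (rounds to 4) and edges/entries-dent
#' `~ 12.19` (rounds to 12).
#'
#' @param W,O Window size and overlap.
#' @return Object of class `"frg_traffic_report"`: a data frame `modes`
#'   (per-mode counters) and a list `ratios`.
#' @export
footprint_report <- function(W = 64L, O = 33L) {
  p <- window_params(W = W, O = O)  # validates W, O
  W <- p$W; O <- p$O
  base <- c("A", "C", "G", "T")
  text <- paste(rep(base, length.out = W), collapse = "")
  pattern <- paste(rep(rev(base), length.out = W), collapse = "")
  modes <- c("edges", "entries", "entries-dent")
  rows <- lapply(modes, function(md) {
    f <- cpp_fill_table(text, pattern, W, O, md, FALSE)
    tb <- cpp_traceback(text, pattern, W, O, md, FALSE, FALSE)
    data.frame(mode = md,
               stored_bytes = f$capacity_bits / 8,
               bits_written = f$bits_written,
               cells_written = f$cells_written,
               bits_read_traceback = tb$bits_read)
  })
  tab <- do.call(rbind, rows)
  bw <- structure(tab$bits_written, names = tab$mode)
  sb <- structure(tab$stored_bytes, names = tab$mode)
  ratios <- list(
    stored_bytes = c(edges_over_entries = unname(sb["edges"] / sb["entries"]),
                     entries_over_dent = unname(sb["entries"] / sb["entries-dent"]),
                     edges_over_dent = unname(sb["edges"] / sb["entries-dent"])),
    bits_written = c(edges_over_entries = unname(bw["edges"] / bw["entries"]),
                     entries_over_dent = unname(bw["entries"] / bw["entries-dent"]),
                     edges_over_dent = unname(bw["edges"] / bw["entries-dent"])))
  structure(list(W = W, O = O, modes = tab, ratios = ratios),
            class = "frg_traffic_report")
}

#' @export
print.frg_traffic_report <- function(x, ...) {
  cat(sprintf("store traffic report, W = %d, O = %d (full window, ET off)\n",
              x$W, x$O))
  print(x$modes, row.names = FALSE)
  r <- x$ratios$bits_written
  cat(sprintf("write-reduction: SENE %.2fx, DENT %.2fx, combined %.2fx (rounds to %d)\n",
              r["edges_over_entries"], r["entries_over_dent"],
              r["edges_over_dent"], round(r["edges_over_dent"])))
  invisible(x)
}

#' Alignment-score quantiles versus the exact oracle
#'
#' For each `(W, O)` grid point, aligns every pair with the windowed
#' heuristic and with the exact Levenshtein oracle, scores both CIGARs
#' under the same affine model, and tabulates lower-tail quantiles of the
#' score difference (heuristic minus oracle; 0 means the heuristic found a
#' score-optimal alignment, negative means worse). The 0.001 quantile of
#' 1000 pairs is the single worst pair, so small sets make the extreme
#' quantiles noisy.
#'
#' @param pairs Data frame with `text` and `pattern` columns.
#' @param grid Data frame with columns `W` and `O`, one row per
#'   configuration (default: sweep `W` with `O = W %/% 2 + 1`).
#' @param scoring A [scoring_params()] object.
#' @param probs Quantile probabilities (lower tail, order statistics).
#' @return Object of class `"frg_quantile_table"`: a data frame with one
#'   row per grid point and one column per quantile.
#' @export
accuracy_quantiles <- function(pairs,
                               grid = data.frame(W = c(16L, 32L, 64L),
                                                 O = c(16L, 32L, 64L) %/% 2L + 1L),
                               scoring = scoring_params(),
                               probs = c(0.5, 0.1, 0.01, 0.001)) {
  if (nrow(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  oracle_scores <- vapply(seq_len(nrow(pairs)), function(r)
    affine_score(edit_align(pairs$text[r], pairs$pattern[r])$cigar, scoring),
    numeric(1))
  out <- lapply(seq_len(nrow(grid)), function(g) {
    p <- window_params(W = grid$W[g], O = grid$O[g])
    deltas <- vapply(seq_len(nrow(pairs)), function(r)
      affine_score(frg_align(pairs$text[r], pairs$pattern[r], p)$cigar,
                   scoring) - oracle_scores[r], numeric(1))
    q <- quantile(deltas, probs = probs, type = 1, names = FALSE)
    cbind(data.frame(W = p$W, O = p$O),
          as.data.frame(as.list(structure(q, names = sprintf("q%g", probs)))))
  })
  structure(list(table = do.call(rbind, out), probs = probs,
                 n_pairs = nrow(pairs)),
            class = "frg_quantile_table")
}

#' @export
print.frg_quantile_table <- function(x, ...) {
  cat(sprintf("score-delta quantiles vs exact oracle (%d pairs; 0 = optimal)\n",
              x$n_pairs))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fraction of correctly placed read bases
#'
#' A pattern (read) base is counted as correctly aligned when the predicted
#' CIGAR assigns it the same text offset as the ground-truth CIGAR, with
#' inserted bases required to be insertions in both. Placement, not
#' match/mismatch status, is what is scored: an `X` in one script and an
#' `=` in the other at the same offset still count as agreeing.
#'
#' @param predicted An [frg_align()] result or a CIGAR string.
#' @param truth_cigar Ground-truth CIGAR string.
#' @return Fraction in `[0, 1]` (1 for an empty pattern).
#' @examples
#' correct_base_fraction("1I1=1D", "2=")  # 0
#' @export
correct_base_fraction <- function(predicted, truth_cigar) {
  pred <- if (inherits(predicted, "frg_alignment")) predicted$cigar
          else as.character(predicted)
  placement <- function(cig) {
    tab <- cigar_ops(cig)
    if (any(tab$op == "M"))
      stop("placement needs the extended dialect (=/X)", call. = FALSE)
    ops <- rep(tab$op, tab$length)
    toff <- cumsum(ops %in% c("=", "X", "D")) - (ops %in% c("=", "X", "D"))
    # one entry per pattern base: its text offset, or NA for insertions
    keep <- ops %in% c("=", "X", "I")
    ifelse(ops[keep] == "I", NA_integer_, toff[keep])
  }
  pp <- placement(pred); tp <- placement(truth_cigar)
  if (length(pp) != length(tp))
    stop("predicted and truth CIGARs consume different pattern lengths",
         call. = FALSE)
  ct <- cigar_consumed(pred)["text"]
  if (ct != cigar_consumed(truth_cigar)["text"])
    stop("predicted and truth CIGARs consume different text lengths",
         call. = FALSE)
  if (length(pp) == 0L) return(1)
  agree <- (is.na(pp) & is.na(tp)) |
    (!is.na(pp) & !is.na(tp) & pp == tp)
  mean(agree)
}
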