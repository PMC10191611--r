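#' Generate ground-truthed synthetic read/reference pairs
#'
#' Emulates candidate pairs handed to an aligner by a seeding-and-chaining
#' mapper: a uniform random reference segment over the alphabet, and a read
#' derived from it by an i.i.d. per-position error process. Each reference
#' position is mutated with probability `error_rate`; the edit type is
#' drawn from `mix`. Substitutions replace the base with a different
#' uniform base, deletions drop it, insertions add one uniform random base
#' before it. Every mutated position contributes exactly one edit, so the
#' expected edit count per pair is `error_rate * ref_length`. The applied
#' script is retained as a canonical ground-truth CIGAR.
#'
#' The defaults mirror a common long-read simulation setting: 10 kb
#' reference segments at a 5% target error rate. The error process is
#' position-independent (no homopolymer-aware or burst model), which is a
#' documented limitation relative to real long-read simulators.
#'
#' @param n_pairs Number of pairs.
#' @param ref_length Reference segment length in bases.
#' @param error_rate Per-position mutation probability, `0 <= e < 1`.
#' @param mix Proportions of (substitution, insertion, deletion); must be
#'   non-negative and sum to 1.
#' @param seed Optional RNG seed; identical spec + seed reproduce the
#'   records exactly. The caller's RNG state is restored on exit.
#' @param alphabet Character vector of bases.
#' @return Data frame with columns `id`, `text` (reference segment),
#'   `pattern` (read) and `truth_cigar`.
#' @examples
#' p <- synthetic_pairs(2, ref_length = 50, error_rate = 0.1, seed = 1)
#' p$truth_cigar
#' @export
synthetic_pairs <- function(n_pairs, ref_length = 10000L, error_rate = 0.05,
                            mix = c(sub = 1/3, ins = 1/3, del = 1/3),
                            seed = NULL, alphabet = c("A", "C", "G", "T")) {
  n_pairs <- as.integer(n_pairs); ref_length <- as.integer(ref_length)
  if (is.na(n_pairs) || n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  if (is.na(ref_length) || ref_length < 0L)
    stop("ref_length must be >= 0", call. = FALSE)
  if (!is.numeric(error_rate) || is.na(error_rate) ||
      error_rate < 0 || error_rate >= 1)
    stop("error_rate must satisfy 0 <= e < 1", call. = FALSE)
  mix <- as.numeric(mix)
  if (length(mix) != 3L || any(is.na(mix)) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8)
    stop("mix must be 3 non-negative proportions summing to 1", call. = FALSE)
  alphabet <- unique(toupper(as.character(alphabet)))
  if (length(alphabet) < 2L) stop("alphabet needs >= 2 characters", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  recs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    L <- ref_length
    ref <- sample(alphabet, L, replace = TRUE)
    read_frag <- ref
    op_frag <- rep("=", L)
    mut <- which(runif(L) < error_rate)
    if (length(mut) > 0L) {
      type <- sample(c("X", "I", "D"), length(mut), replace = TRUE, prob = mix)
      xs <- mut[type == "X"]
      if (length(xs) > 0L) {
        read_frag[xs] <- vapply(ref[xs], function(b)
          sample(setdiff(alphabet, b), 1L), character(1), USE.NAMES = FALSE)
        op_frag[xs] <- "X"
      }
      ds <- mut[type == "D"]
      if (length(ds) > 0L) { read_frag[ds] <- ""; op_frag[ds] <- "D" }
      is <- mut[type == "I"]
      if (length(is) > 0L) {
        read_frag[is] <- paste0(sample(alphabet, length(is), replace = TRUE),
                                ref[is])
        op_frag[is] <- "I="
      }
    }
    recs[[p]] <- list(id = sprintf("pair%04d", p),
                      text = paste(ref, collapse = ""),
                      pattern = paste(read_frag, collapse = ""),
                      truth_cigar = canonicalize_cigar(
                        paste(op_frag, collapse = "")))
  }
  data.frame(id = vapply(recs, `[[`, "", "id"),
             text = vapply(recs, `[[`, "", "text"),
             pattern = vapply(recs, `[[`, "", "pattern"),
             truth_cigar = vapply(recs, `[[`, "", "truth_cigar"),
             stringsAsFactors = FALSE)
}
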