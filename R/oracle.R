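# Exact reference computations, independent of the bitvector path: used by
# the tests and the accuracy harness, and usable as a (slow, exact) aligner.

#' Exact Levenshtein alignment with traceback
#'
#' Full quadratic dynamic program over unit costs. The traceback tie-break
#' is fixed and documented: on equal cost, prefer the diagonal (`=`/`X`)
#' over deletion (`D`, consumes `a`) over insertion (`I`, consumes `b`), so
#' the CIGAR is reproducible; only the distance is used in acceptance
#' comparisons.
#'
#' @param a Text (reference-role) string.
#' @param b Pattern (read-role) string.
#' @param cigar Also compute the edit script (quadratic memory).
#' @return List with `distance` and (if requested) `cigar`.
#' @examples
#' edit_align("ACGT", "ACGA")$distance  # 1
#' edit_align("ACGT", "CGTA")$cigar     # "1D3=1I"
#' @export
edit_align <- function(a, b, cigar = TRUE) {
  a <- .norm_seq(a); b <- .norm_seq(b)
  res <- cpp_levenshtein(a, b, cigar)
  out <- list(distance = res$distance)
  if (cigar) out$cigar <- canonicalize_cigar(res$ops)
  out
}

#' Minimum distance of a pattern suffix to the prefixes of a text suffix
#'
#' `min` over `t` of `Levenshtein(pattern_suffix, text_suffix[0:t))`. This
#' is the exact semantics the bitvector table realizes: bit `j` of
#' `R[d][i]` is 0 iff
#' `prefix_min_distance(pattern[j:m), text[i:n)) <= d`. (A plain
#' suffix-vs-suffix reading differs: the published update rules charge
#' nothing for unused text, because shifted-in zeros keep trailing text
#' free. The tests pin the prefix-min semantics exhaustively.)
#'
#' @param pattern_suffix,text_suffix Strings.
#' @return Integer distance.
#' @examples
#' prefix_min_distance("GA", "GT")  # 1
#' prefix_min_distance("AA", "A")   # 1
#' @export
prefix_min_distance <- function(pattern_suffix, text_suffix) {
  cpp_prefix_min(.norm_seq(pattern_suffix), .norm_seq(text_suffix))
}
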