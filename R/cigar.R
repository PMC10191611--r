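# CIGAR plumbing: the extended SAM dialect with =, X, I, D run-length ops.
# I consumes pattern (read/query) only, D consumes text (reference) only.

.cigar_letters <- c("=", "X", "I", "D", "M")

#' Run-length encode edit operations into a CIGAR string
#'
#' Accepts a vector of single-letter ops, a single string of letters, or a
#' parsed op table, merges adjacent equal ops and renders the SAM text
#' dialect (e.g. `"3=1X"`). With `collapse_m = TRUE`, `=` and `X` are
#' collapsed to `M` for compatibility with consumers of the classic dialect.
#'
#' @param ops Character vector of ops, a single concatenated string, or a
#'   data frame with columns `op` and `length`.
#' @param collapse_m Collapse `=`/`X` runs into `M`.
#' @return A CIGAR string (empty input gives `""`).
#' @examples
#' canonicalize_cigar(c("=", "=", "=", "X"))  # "3=1X"
#' canonicalize_cigar("==DD")                 # "2=2D"
#' @export
canonicalize_cigar <- function(ops, collapse_m = FALSE) {
  if (is.data.frame(ops)) {
    letters <- rep(as.character(ops$op), ops$length)
  } else {
    ops <- as.character(ops)
    letters <- if (length(ops) == 1L && (nchar(ops) > 1L || nchar(ops) == 0L))
      strsplit(ops, "", fixed = TRUE)[[1]] else ops
  }
  if (length(letters) == 0L) return("")
  bad <- setdiff(unique(letters), .cigar_letters)
  if (length(bad) > 0L)
    stop("unknown CIGAR op letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (collapse_m) letters[letters %in% c("=", "X")] <- "M"
  r <- rle(letters)
  paste0(r$lengths, r$values, collapse = "")
}

#' Parse a CIGAR string into an op table
#'
#' @param cigar A CIGAR string such as `"3=1X"`.
#' @return Data frame with columns `op` (character) and `length` (integer).
#' @export
cigar_ops <- function(cigar) {
  cigar <- as.character(cigar)
  if (length(cigar) != 1L || is.na(cigar))
    stop("cigar must be a single string", call. = FALSE)
  if (nchar(cigar) == 0L)
    return(data.frame(op = character(), length = integer()))
  if (!grepl("^([0-9]+[=XIDM])+$", cigar))
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XIDM]", cigar))[[1]]
  if (any(lens < 1L)) stop("CIGAR run lengths must be >= 1", call. = FALSE)
  data.frame(op = ops, length = lens)
}

#' Count edits in a CIGAR
#'
#' Total length of `X`, `I` and `D` runs. Errors on `M` ops, whose
#' match/mismatch status is unresolved.
#'
#' @param cigar A CIGAR string or a [cigar_ops()] table.
#' @return Integer edit count.
#' @examples
#' count_edits("3=1X")  # 1
#' @export
count_edits <- function(cigar) {
  tab <- if (is.data.frame(cigar)) cigar else cigar_ops(cigar)
  if (any(tab$op == "M"))
    stop("count_edits requires the extended dialect (=/X, not M)",
         call. = FALSE)
  sum(tab$length[tab$op %in% c("X", "I", "D")])
}

#' Sequence lengths consumed by a CIGAR
#'
#' @param cigar A CIGAR string or op table.
#' @return Named integer vector `c(text = , pattern = )`: `=`/`X`/`M`
#'   consume both, `D` text only, `I` pattern only.
#' @export
cigar_consumed <- function(cigar) {
  tab <- if (is.data.frame(cigar)) cigar else cigar_ops(cigar)
  both <- tab$op %in% c("=", "X", "M")
  c(text = sum(tab$length[both | tab$op == "D"]),
    pattern = sum(tab$length[both | tab$op == "I"]))
}

#' Affine-gap scoring constants
#'
#' Single-affine gap model: a CIGAR scores
#' `match * (= bases) - mismatch * (X bases)` minus, for every maximal
#' `I`/`D` run, `gap_open + gap_extend * run_length`. The defaults
#' (2, 4, 4, 2) are a common single-affine approximation of short/long-read
#' mapper defaults; quantile comparisons are invariant to the exact choice
#' as long as both sides are scored with the same constants.
#'
#' @param match,mismatch,gap_open,gap_extend Non-negative integers.
#' @return Object of class `"frg_scoring"`.
#' @export
scoring_params <- function(match = 2L, mismatch = 4L, gap_open = 4L,
                           gap_extend = 2L) {
  v <- c(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend)
  if (any(is.na(v)) || any(v < 0))
    stop("all scoring constants must be non-negative", call. = FALSE)
  structure(lapply(v, as.integer), class = "frg_scoring")
}

#' Score a CIGAR under an affine gap model
#'
#' @param cigar A CIGAR string or op table in the extended dialect (`M` ops
#'   are an error: the scorer needs `=`/`X` resolution).
#' @param scoring A [scoring_params()] object.
#' @return Integer score (higher is better).
#' @examples
#' affine_score("3=1X")   # 3*2 - 4 = 2
#' affine_score("2=2D")   # 4 - (4 + 2*2) = -4
#' @export
affine_score <- function(cigar, scoring = scoring_params()) {
  stopifnot(inherits(scoring, "frg_scoring"))
  tab <- if (is.data.frame(cigar)) cigar else cigar_ops(cigar)
  if (any(tab$op == "M"))
    stop("affine_score requires =/X resolution; M ops are not scoreable",
         call. = FALSE)
  # merge any split runs so each I/D row is a maximal gap
  if (nrow(tab) > 0L) tab <- cigar_ops(canonicalize_cigar(tab))
  gaps <- tab$op %in% c("I", "D")
  scoring$match * sum(tab$length[tab$op == "="]) -
    scoring$mismatch * sum(tab$length[tab$op == "X"]) -
    (scoring$gap_open * sum(gaps) +
       scoring$gap_extend * sum(tab$length[gaps]))
}
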