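# Readers and writers. TSV is the canonical pair format; FASTA/FASTQ pairs
# are matched by record order across two files (not by name).

#' Read sequence pairs
#'
#' @param path For `format = "tsv"`: a tab-separated file with columns
#'   `id`, `text`, `pattern` and optionally `truth_cigar` (a header row
#'   with those names is allowed and skipped). For `"fasta"`/`"fastq"`: the file holding the
#'   text (reference-role) records.
#' @param pattern_path Second FASTA/FASTQ file holding the pattern (read)
#'   records, paired with `path` by record order.
#' @param format One of `"tsv"`, `"fasta"`, `"fastq"`.
#' @return Data frame with columns `id`, `text`, `pattern`; sequences are
#'   normalized (upper case, `U` to `T`). Empty sequences are allowed.
#' @export
read_pairs <- function(path, pattern_path = NULL,
                       format = c("tsv", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
      return(data.frame(id = character(), text = character(),
                        pattern = character(), stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(parts, length, 0L)
    bad <- which(nf < 3L | nf > 4L | nf != nf[1])
    if (length(bad) > 0L)
      stop(sprintf("malformed TSV pair record at line %d of %s (need 3 or 4 columns: id, text, pattern[, truth_cigar])",
                   bad[1], path), call. = FALSE)
    tab <- do.call(rbind, parts)
    if (identical(unname(tab[1, 1:3]), c("id", "text", "pattern")))
      tab <- tab[-1, , drop = FALSE]
    out <- data.frame(id = tab[, 1], text = .norm_seq(tab[, 2]),
                      pattern = .norm_seq(tab[, 3]), stringsAsFactors = FALSE)
    if (ncol(tab) == 4L) out$truth_cigar <- tab[, 4]
    out
  } else {
    if (is.null(pattern_path))
      stop("paired-file mode needs both a text and a pattern file",
           call. = FALSE)
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA/FASTQ pairs requires the Biostrings package",
           call. = FALSE)
    tx <- Biostrings::readBStringSet(path, format = format)
    pt <- Biostrings::readBStringSet(pattern_path, format = format)
    if (length(tx) != length(pt))
      stop(sprintf("unequal record counts: %d in %s vs %d in %s",
                   length(tx), path, length(pt), pattern_path),
           call. = FALSE)
    ids <- names(tx)
    if (is.null(ids)) ids <- sprintf("pair%04d", seq_along(tx))
    ids <- sub("\\s.*$", "", ids)
    data.frame(id = ids, text = .norm_seq(as.character(tx)),
               pattern = .norm_seq(as.character(pt)),
               stringsAsFactors = FALSE)
  }
}

#' Write alignments
#'
#' `format = "tsv"` emits a header and one row per pair: `id`, `text_len`,
#' `pattern_len`, `edits`, `cigar`. `format = "paf"` emits PAF-like rows
#' (pattern as query, text as target) with the CIGAR in a `cg:Z:` tag and
#' the edit count in `NM:i:`.
#'
#' @param pairs Data frame with at least `id`, `text`, `pattern` (as from
#'   [read_pairs()] or [synthetic_pairs()]).
#' @param alignments List of [frg_align()] results, one per pair row.
#' @param path Output file path.
#' @param format `"tsv"` or `"paf"`.
#' @param collapse_m Emit CIGARs with `=`/`X` collapsed to `M`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(pairs, alignments, path,
                             format = c("tsv", "paf"), collapse_m = FALSE) {
  format <- match.arg(format)
  if (inherits(alignments, "frg_alignment")) alignments <- list(alignments)
  if (length(alignments) != nrow(pairs))
    stop("need exactly one alignment per pair row", call. = FALSE)
  cig <- vapply(alignments, function(a)
    canonicalize_cigar(a$ops, collapse_m = collapse_m), character(1))
  edits <- vapply(alignments, function(a) a$edits, integer(1))
  tlen <- nchar(pairs$text); plen <- nchar(pairs$pattern)
  if (format == "tsv") {
    lines <- c("id\ttext_len\tpattern_len\tedits\tcigar",
               sprintf("%s\t%d\t%d\t%d\t%s", pairs$id, tlen, plen, edits, cig))
  } else {
    matches <- plen - vapply(alignments, function(a) {
      tab <- cigar_ops(a$cigar)
      sum(tab$length[tab$op %in% c("X", "I")])
    }, numeric(1))
    blocklen <- vapply(alignments, function(a)
      sum(cigar_ops(a$cigar)$length), numeric(1))
    lines <- sprintf(
      "%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t255\tNM:i:%d\tcg:Z:%s",
      pairs$id, plen, 0L, plen, pairs$id, tlen, 0L, tlen,
      as.integer(matches), as.integer(blocklen), edits, cig)
  }
  writeLines(lines, path)
  invisible(path)
}
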