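# Shared fixtures and independent pure-R oracles for the test suite. These
# deliberately avoid the package's compiled code paths.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# classic quadratic Levenshtein DP in pure R
r_lev <- function(a, b) {
  A <- if (nchar(a)) strsplit(a, "")[[1]] else character()
  B <- if (nchar(b)) strsplit(b, "")[[1]] else character()
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- c(i, integer(length(B)))
    for (j in seq_along(B))
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1, cur[j] + 1)
    prev <- cur
  }
  prev[length(B) + 1]
}

# brute-force edit-script enumeration: is there a script of <= d edits?
r_can_edit <- function(a, b, d) {
  if (nchar(a) == 0L) return(nchar(b) <= d)
  if (nchar(b) == 0L) return(nchar(a) <= d)
  if (substr(a, 1, 1) == substr(b, 1, 1) &&
      r_can_edit(substring(a, 2), substring(b, 2), d)) return(TRUE)
  if (d == 0L) return(FALSE)
  r_can_edit(substring(a, 2), substring(b, 2), d - 1L) ||  # substitution
    r_can_edit(substring(a, 2), b, d - 1L) ||              # delete from a
    r_can_edit(a, substring(b, 2), d - 1L)                 # insert into a
}
r_lev_brute <- function(a, b) {
  d <- 0L
  while (!r_can_edit(a, b, d)) d <- d + 1L
  d
}

# min over t of Lev(pattern_suffix, text_suffix[0:t)) in pure R
r_prefix_min <- function(pat, txt) {
  n <- nchar(txt)
  min(vapply(0:n, function(t) r_lev(substr(txt, 1, t), pat), numeric(1)))
}

# all strings over an alphabet with lengths 0..maxlen
all_strings <- function(alphabet, maxlen) {
  out <- ""
  cur <- ""
  for (l in seq_len(maxlen)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

expand_cigar <- function(cig) {
  tab <- cigar_ops(cig)
  rep(tab$op, tab$length)
}

# derive a pattern from a text with i.i.d. errors (no ground truth needed)
mutate_seq <- function(s, e, alphabet = c("A", "C", "G", "T")) {
  if (nchar(s) == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  for (c in ch) {
    r <- runif(1)
    if (r < e / 3) {
      out <- c(out, sample(setdiff(alphabet, c), 1))      # substitution
    } else if (r < 2 * e / 3) {
      out <- c(out, sample(alphabet, 1), c)               # insertion
    } else if (r < e) {
      # deletion: skip
    } else out <- c(out, c)
  }
  paste(out, collapse = "")
}

p_basic <- function(W, O, ...) window_params(W = W, O = O, dent = FALSE, ...)
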