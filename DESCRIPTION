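Package: frugalign
Title: Memory-Frugal Windowed Bitvector Sequence Alignment
Version: 0.1.0
Authors@R:
    person("frugalign", "developers", email = "frugalign@example.org",
           role = c("aut", "cre"))
Description: Pairwise nucleotide sequence alignment with a Bitap-style
    bitvector edit-distance dynamic program, tiled across the input by a
    greedy windowing heuristic and traced back into extended-CIGAR edit
    scripts. Three independently switchable storage optimizations reduce
    the memory footprint and traffic of the traceback table without
    changing any reported alignment: storing only ANDed table entries and
    regenerating edge bitvectors on demand (SENE), trimming the table to
    the region a truncated traceback can reach (DENT), and terminating the
    row-wise fill at the optimal edit count (early termination). Includes
    an exact Levenshtein oracle with traceback, an affine-gap CIGAR
    scorer, a ground-truthed synthetic read-pair generator, evaluation
    harnesses for memory-traffic and accuracy-quantile experiments, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
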