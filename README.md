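# frugalign

Memory-frugal windowed bitvector sequence alignment for R.

## The problem

Read mappers generate millions of candidate read/reference pairs that must
be verified by pairwise alignment — the throughput bottleneck of many
genomics pipelines. Bitvector (Bitap-style) dynamic programming computes
unit-cost edit distance with a handful of word-wide bitwise operations per
cell, and a greedy windowing heuristic makes the runtime linear in the
read length. The catch is the *traceback*: recovering the CIGAR requires
storing the DP table, and the naive store is large enough to spill out of
fast memory and dominate data movement.

`frugalign` implements the windowed bitvector aligner together with three
*exact* storage optimizations — they change memory traffic, never the
reported alignment:

* **SENE** — store only the ANDed entry per cell and regenerate the
  insertion/deletion/substitution/match edge bitvectors on demand during
  traceback (3× less stored and written);
* **DENT** — discard the columns and bits a truncated traceback can never
  reach, keeping `W−O+1` columns × `W−O+1` bits per entry (≈4× fewer
  writes at `W=64, O=33`; ≈12× combined with SENE);
* **ET** — fill the table row-wise and stop at the first row whose
  leftmost most-significant bit is 0 (the edit count); on uncorrelated
  random pairs this skips ~47% of rows, and more on real candidates.

## The model in brief

For a window of text length `n` and pattern length `m ≤ W`, table `R` has
rows `d = 0..k` (`k = W`) of `m`-bit vectors; bit `j` of `R[d][i]` is 0
iff `min_t Lev(pattern[j:m), text[i:i+t)) ≤ d`. Cell updates are

```
I = R[d-1][i]   << 1            # insertion
D = R[d-1][i+1]                 # deletion
S = D << 1                      # substitution
M = (R[d][i+1] << 1) | mask(text[i])   # match
R[d][i] = I & D & S & M
```

`d_opt`, the first row with bit 0 of `R[d][0]` zero, is the window's edit
count; traceback follows the zero bits (priority `M > S > D > I`) and the
windowing driver commits the first `W−O` characters per window, stitching
the fragments into one extended CIGAR (`=`, `X`, `I`, `D`).

## Worked example

```r
library(frugalign)

pair <- synthetic_pairs(1, ref_length = 3000, error_rate = 0.05, seed = 101)
a <- frg_align(pair$text, pair$pattern, window_params(preset = "long"))
print(a)
#> windowed bitvector alignment (W = 64, O = 33)
#>   text 3000 bp vs pattern 2993 bp: 141 edits in 97 window(s)
#>   cigar: 10=2X2=1D23=1I1=1X4=1D19=1X13=1D1=1D22=1D25=2X15=1I18=1D2...
#>   store traffic: 459040 bits written, 273992 bits read

edit_align(pair$text, pair$pattern, cigar = FALSE)$distance
#> [1] 141
correct_base_fraction(a, pair$truth_cigar)
#> [1] 0.9782827
```

The heuristic found a 141-edit alignment — here equal to the exact edit
distance computed by the Levenshtein oracle — and placed 97.8% of read
bases at their ground-truth offsets (the remainder are ambiguous indel
placements in homopolymers, which no aligner can recover reliably).

The storage accounting that motivates the improvements:

```r
print(footprint_report(64, 33))
#> store traffic report, W = 64, O = 33 (full window, ET off)
#>          mode stored_bytes bits_written cells_written bits_read_traceback
#>         edges       101400       811200          4225                5952
#>       entries        33800       270400          4225                5952
#>  entries-dent         8320        66560          2080                2976
#> write-reduction: SENE 3.00x, DENT 4.06x, combined 12.19x (rounds to 12)
```

A small CLI covers alignment, pair generation, the exact oracle and the
evaluation experiments:

```sh
Rscript -e 'frugalign::run_cli()' --args ...   # or use inst/cli/frugalign.R
# e.g.  align --pairs pairs.tsv --preset long --out out.tsv
#       generate --n-pairs 100 --length 10000 --error-rate 0.05 --seed 1 --out pairs.tsv
#       eval --skip -W 64 --n-pairs 1000 --seed 1
```

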