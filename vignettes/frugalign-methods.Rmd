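---
title: "Methods: the windowed bitvector aligner and its frugality modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the windowed bitvector aligner and its frugality modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frugalign)
```

## The model

frugalign solves pairwise approximate string matching under unit edit
costs. Given a *text* (reference-role) and a *pattern* (read-role)
sequence, it reports an edit count and an extended-CIGAR script
(`=`, `X`, `I`, `D`; `I` consumes pattern only, `D` text only).

The core is a Bitap-style bitvector dynamic program. For a window with
text length $n$ and pattern length $m$, the table $R$ has $k+1$ rows
(edit budgets $d = 0 \dots k$, with $k$ fixed to the window size $W$) and
$n+1$ columns; each entry is an $m$-bit vector. Bit $j$ (with $j = 0$ the
most significant bit) of $R[d][i]$ is 0 exactly when

$$\min_{0 \le t \le n-i} \mathrm{Lev}\big(\text{pattern}[j{:}m),\
\text{text}[i{:}i{+}t)\big) \le d,$$

i.e. when the pattern suffix starting at $j$ can be matched against some
*prefix* of the text suffix starting at $i$ within $d$ edits. A common
informal reading states a suffix-vs-suffix distance instead; the published
update rules (shifts that fill in zeros) actually realize the
min-over-prefixes semantics above, because trailing unused text is never
charged. The test suite pins this exact semantics exhaustively against an
independent quadratic DP for all pairs over a two-letter alphabet with
lengths up to 6.

The fill uses four precomputed pattern masks (bit $i$ of mask $X$ is 0 iff
`pattern[i] == X`) and per cell computes

* $I = R[d{-}1][i] \ll 1$ (insertion),
* $D = R[d{-}1][i{+}1]$ (deletion), $S = D \ll 1$ (substitution),
* $M = (R[d][i{+}1] \ll 1)\ \mathrm{OR}\ \mathrm{mask}(\text{text}[i])$ (match),
* entry $= I\ \mathrm{AND}\ D\ \mathrm{AND}\ S\ \mathrm{AND}\ M$,

with the rightmost column seeded by the boundary vector (the $d$ least
significant bits 0) and row $d = 0$ built from matches alone. The smallest
$d$ with bit 0 of $R[d][0]$ zero, `d_opt`, is the window's edit count.
Traceback walks the path of zero bits from $(d_{\text{opt}}, i{=}0,
j{=}0)$ toward the north-east corner, emitting one op per edge.

## Windowing

Long pairs are tiled greedily: each step aligns up to $W$ characters of
each remainder, commits only the first $W-O$ characters of the traceback,
and restarts from the consumed offsets. The final (terminal) window, where
both remainders fit in $W$, is traced to the corner. Because indels make
the two sequences advance unevenly, the driver advances by the *actually
consumed* lengths rather than by a fixed $W-O$ on both sides (the fixed
advance described in prose holds only in the indel-free case; this is the
one place we depart from a literal reading). The heuristic is greedy:
the reported edit count is an upper bound on the true edit distance
(tested exhaustively at small sizes) and is empirically optimal for the
overwhelming majority of realistic candidate pairs at the default preset.

Degenerate inputs are handled without error: if one sequence is exhausted
while the other still has characters (even more than $W$), the remainder
is emitted as a single `I` or `D` run; empty inputs yield empty CIGARs.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `W` | 64 | window size (characters per window, also row budget $k$); 1–64, bitvectors are machine words |
| `O` | 33 | overlap re-examined by the next window; `0 <= O < W` |
| `sene` | on | store ANDed entries only; regenerate edges during traceback |
| `dent` | on | trim the store to $W{-}O{+}1$ columns and bits per entry |
| `et` | on | stop the row-wise fill at `d_opt` |

The presets are `long` ($W{=}64, O{=}33$) and `short` ($W{=}32,
O{=}17$). $O = 33$ at $W = 64$ makes the trimmed DENT vectors exactly
32 bits, matching a 32-bit word. Accuracy sweeps follow the rule
$O = \lfloor W/2 \rfloor + 1$.

## Storage modes and the traffic accounting

The traceback store can hold, per cell: three edge vectors `I`, `D`, `M`
(baseline `edges`; `S` is regenerable as `D << 1`), only the ANDed entry
(`entries`, the SENE mode), or the trimmed entry region (`entries-dent`).
Counters count exactly the bits crossing the store boundary; the forefront
rows that the fill keeps in local arrays ("registers") are free, and every
stored location is written exactly once. Consequences, all read off the
counters rather than hard-coded:

* `entries` at $W = 64$: $65 \times 65$ entries of 64 bits = 33,800 bytes;
  `edges` is exactly $3\times$ that.
* `entries-dent` at $W{=}64, O{=}33$: $65$ rows $\times\ 32$ columns
  $\times\ 32$ bits; the write reduction vs `entries` is
  $\frac{65 \cdot 64}{32 \cdot 32} \approx 4.06$ (rounds to 4), and vs
  `edges` $\approx 12.19$ (rounds to 12).

DENT is safe because a truncated traceback stops as soon as $i$ or $j$
reaches $W-O$: every cell and bit it can touch lies inside the stored
region, and the shifted-in boundary bit it cannot reconstruct (bit
$W-O$ of a trimmed vector) is never queried. DENT is disabled for the
terminal window, which must trace to the corner. Early termination
changes which rows exist but never their contents; rows beyond `d_opt`
cannot be reached by a traceback that starts at `d_opt` and only moves to
cheaper rows. All three improvements are therefore *exact*: the returned
alignment is bit-identical across all six valid flag combinations, which
the acceptance suite verifies on 10,000 random pairs.

## Numerical and design choices

* **Bit order.** $j = 0$ is the most significant bit; a left shift moves
  bit $j{+}1$ into $j$ and zero-fills position $m-1$. This matches the
  convention in which traceback starts at the most significant bit of the
  leftmost column.
* **Traceback tie-break.** Edge priority `M > S > D > I`, fixed and
  deterministic. Matches are free; among cost-1 edges the substitution
  keeps the walk on the diagonal. Any fixed order is valid — co-optimal
  scripts exist — but determinism is required for reproducible output.
* **Terminal tails.** If the pattern is exhausted before the text in the
  terminal window, the remaining text is appended as a `D` tail (an `I`
  tail is the symmetric fallback; insertions at the boundary column
  normally arise from the DP itself). The per-window edit count is the
  number of non-match ops emitted including tails, so the global count is
  always consistent with the CIGAR.
* **Ambiguous bases.** Characters outside `A/C/G/T` (after upper-casing
  and `U -> T`) match nothing, not even themselves, and always cost an
  edit. This is conservative; the exact Levenshtein oracle, by contrast,
  compares raw characters, so oracle-equivalence tests use unambiguous
  alphabets.
* **Scoring.** The affine scorer uses match 2, mismatch 4, gap open 4,
  gap extend 2 — a single-affine approximation of common mapper defaults;
  the source model is named but its constants are not fixed, so they are
  configurable. Quantile comparisons only require that both sides use the
  same constants.
* **Quantiles** are lower-tail order statistics (`type = 1`), so the 0.001
  quantile of 1,000 pairs is literally the worst pair.
* **Oracle tie-break.** The exact DP prefers diagonal over deletion over
  insertion when backtracking. Because the oracle minimizes *edit count*
  and then picks one co-optimal script, the heuristic's script can
  occasionally score *better* under the affine model (it may cluster gaps
  where the oracle's tie-break scattered them); score deltas are therefore
  "approximately non-positive", with rare small positive values, and the
  headline statistic is the median delta, which is 0 at the default
  preset.

## The synthetic generator: what it emulates and what it does not

`synthetic_pairs()` emulates candidate read/reference pairs as a mapper
would hand them to an aligner: a uniform random reference segment
(default 10 kb, the scale of simulated long reads) and a read derived by
mutating each position independently with probability `error_rate`
(default 5%, the target error rate of the simulated long-read setting),
the edit type drawn from `mix` (default 1/3 substitution, 1/3 insertion,
1/3 deletion — the simulator profile behind the original datasets is not
published, so a symmetric mix is used and is a flag). Every mutated
position contributes exactly one edit, so expected edits per pair are
`error_rate * ref_length`, and the applied script is kept as a canonical
ground-truth CIGAR.

The generator is deliberately simple: errors are i.i.d. per position, with
no homopolymer bias, burst errors, chimeras, or coverage structure, and
the reference is uniform random rather than repetitive genomic sequence.
A green accuracy test therefore establishes correct behavior on
*uncorrelated-error* pairs of realistic length and error rate — not
performance on the adversarial repetitive regions where windowed greedy
alignment genuinely loses accuracy, which is a documented limitation of
the approach, mitigated by raising `W` and `O` together.

Uniform random pairs (both length $W$, no correlation) are the stated
world for the early-termination experiment: their expected edit distance
is at most $\tfrac{3}{4}W$, so at least 25% of rows are skipped on
average; the measured value is ~47%, and real (correlated) candidate
pairs skip far more.

## What the tests establish

The non-acceptance suite cross-checks the compiled fill against pure-R
reimplementations of every primitive, against a brute-force edit-script
enumeration, and against `utils::adist`; properties (write-once, ET/SENE/
DENT equivalence, upper-boundedness, CIGAR round-trips) run on seeded
random families. Two scalings keep the default run fast: the exhaustive
upper-bound sweep uses lengths up to 5 (plus sampled length-6 pairs), and
the `adist` cross-check uses 100 pairs; the acceptance suite runs the
stated-size experiments (exhaustive length-6 bit semantics, 10,000-pair
transparency, 1,000-pair skip bound, 200 pairs of 2 kb at 5% error).

## Known limitations

* $W \le 64$: bitvectors are single machine words; multi-word emulation
  is out of scope.
* Greedy windowing carries no optimality guarantee; pathological
  repetitive pairs can be aligned suboptimally at any fixed $W$.
* Unit costs only; the affine model is used for *evaluation*, not for
  alignment.
* The DP is filled row-wise; diagonal-parallel filling and any
  concurrency are out of scope.
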