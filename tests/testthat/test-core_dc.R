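# Pattern masks, boundary column, cell update and table fill.

test_that("pattern masks follow the 0-on-match rule", {
  pm <- build_pattern_masks("ACGA")
  expect_equal(pm$masks$A, "0110")
  expect_equal(pm$masks$C, "1011")
  expect_equal(pm$masks$G, "1101")
  expect_equal(pm$masks$T, "1111")
  expect_equal(pm$masks$other, "1111")

  uniform <- build_pattern_masks("AAAA")
  expect_equal(uniform$masks$A, "0000")
  expect_equal(uniform$masks$C, "1111")
  expect_equal(uniform$masks$G, "1111")
  expect_equal(uniform$masks$T, "1111")

  # ambiguous bases match nothing: bit 3 is 1 in all four masks
  amb <- build_pattern_masks("ACGN")$masks
  for (b in c("A", "C", "G", "T"))
    expect_equal(substr(amb[[b]], 4, 4), "1")

  # normalization: case and RNA U
  expect_equal(build_pattern_masks("acgu")$masks$T, "1110")

  empty <- build_pattern_masks("")
  expect_equal(empty$width, 0L)
  expect_equal(empty$masks$A, "")
})

test_that("each unambiguous position matches exactly one character", {
  set.seed(11)
  for (rep in 1:20) {
    pat <- rand_seq(sample(0:12, 1))
    m <- build_pattern_masks(pat)$masks
    # exactly one 0 per position: the AND of the four masks is all-zeros
    # (an ambiguous base would leave a 1), and the OR is all-ones
    acc_and <- Reduce(frugalign:::.bv_and, m[c("A", "C", "G", "T")])
    acc_or <- Reduce(frugalign:::.bv_or, m[c("A", "C", "G", "T")])
    expect_equal(acc_and, strrep("0", nchar(pat)))
    expect_equal(acc_or, strrep("1", nchar(pat)))
  }
})

test_that("boundary vectors zero out the d least significant bits", {
  expect_equal(boundary_vector(0, 4), "1111")
  expect_equal(boundary_vector(2, 4), "1100")
  expect_equal(boundary_vector(4, 4), "0000")
  expect_equal(boundary_vector(7, 4), "0000")  # d >= m clamps to all-zero
  expect_equal(boundary_vector(3, 0), "")
  expect_error(boundary_vector(-1, 4), "d must be")
})

test_that("dc_cell reproduces the worked four-character example", {
  # text ACGT vs pattern ACGA, cell d = 1, i = 2
  e <- dc_cell(north = "1111", northeast = "1111", east = "1110",
               mask = "1101")
  expect_equal(e$I, "1110")
  expect_equal(e$D, "1111")
  expect_equal(e$S, "1110")
  expect_equal(e$M, "1101")
  expect_equal(e$entry, "1100")
  expect_equal(frugalign:::.bv_bit(e$entry, 2), 0L)  # the marked zero

  # only the shifted-in zeros of I and S survive all-ones inputs
  expect_equal(dc_cell("1111", "1111", "1111", "1111")$entry, "1110")
  expect_error(dc_cell("111", "1111", "1111", "1111"), "width")
})

test_that("dc_cell satisfies the edge-set identities on random inputs", {
  set.seed(12)
  rand_bv <- function(m) paste(sample(c("0", "1"), m, TRUE), collapse = "")
  for (rep in 1:50) {
    m <- sample(1:16, 1)
    e <- dc_cell(rand_bv(m), rand_bv(m), rand_bv(m), rand_bv(m))
    expect_equal(e$S, frugalign:::.bv_shl(e$D))
    expect_equal(e$entry, Reduce(frugalign:::.bv_and,
                                 list(e$I, e$D, e$S, e$M)))
  }
})

test_that("fill_table finds d_opt and honors early termination", {
  f_on <- fill_table("ACGT", "ACGA", p_basic(4, 0))
  expect_equal(f_on$d_opt, 1L)
  expect_equal(f_on$rows_computed, 2L)
  expect_equal(f_on$table[2, 1], "0100")  # R[1][0], leftmost bit 0
  expect_equal(f_on$table[2, 3], "1100")  # R[1][2]

  f_off <- fill_table("ACGT", "ACGA", p_basic(4, 0, et = FALSE))
  expect_equal(f_off$d_opt, 1L)
  expect_equal(f_off$rows_computed, 5L)   # k = W = 4, all rows built

  ident <- fill_table("ACGT", "ACGT", p_basic(8, 0))
  expect_equal(ident$d_opt, 0L)
  expect_equal(ident$rows_computed, 1L)
})

test_that("ET changes only which rows exist, not their contents", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(0:8, 1); m <- sample(0:8, 1)
    txt <- rand_seq(n); pat <- rand_seq(m)
    a <- fill_table(txt, pat, p_basic(8, 0, et = TRUE))
    b <- fill_table(txt, pat, p_basic(8, 0, et = FALSE))
    expect_identical(a$d_opt, b$d_opt)
    expect_identical(a$table, b$table[seq_len(a$rows_computed), , drop = FALSE])
    expect_identical(a$stored$entries,
                     b$stored$entries[seq_len(a$rows_computed), , drop = FALSE])
  }
})

test_that("every stored location is written exactly once, in every mode", {
  W <- 16L; O <- 7L
  txt <- rand_seq(16); pat <- rand_seq(16)
  for (mode in list(window_params(W, O, sene = FALSE, dent = FALSE, et = FALSE),
                    window_params(W, O, dent = FALSE, et = FALSE),
                    window_params(W, O, et = FALSE))) {
    f <- fill_table(txt, pat, mode)
    cols <- f$cols_stored
    expect_equal(f$cells_written, f$rows_computed * cols)
    per_cell <- if (mode$mode == "edges") 3L * f$m else f$bits_per_entry
    expect_equal(f$bits_written, f$cells_written * per_cell)
  }
})

test_that("entries reconstructed from stored edges equal stored entries", {
  set.seed(14)
  for (rep in 1:15) {
    n <- sample(1:12, 1); m <- sample(1:12, 1)
    txt <- rand_seq(n); pat <- rand_seq(m)
    fe <- fill_table(txt, pat, window_params(12, 0, sene = FALSE,
                                             dent = FALSE, et = FALSE))
    fn <- fill_table(txt, pat, window_params(12, 0, dent = FALSE,
                                             et = FALSE))
    for (d in seq_len(fe$rows_computed) - 1L) {
      for (i in 0:(n - 1L)) {
        ee <- regenerate_edges(fe, d, i)
        expect_identical(ee$entry, fn$stored$entries[d + 1L, i + 1L])
      }
    }
  }
})

test_that("table bits agree with the pure-R prefix-min oracle (spot check)", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    txt <- rand_seq(n, c("A", "C")); pat <- rand_seq(m, c("A", "C"))
    f <- fill_table(txt, pat, p_basic(6, 0, et = FALSE))
    for (pick in 1:12) {
      d <- sample(seq_len(f$rows_computed), 1) - 1L
      i <- sample(0:n, 1); j <- sample(seq_len(m), 1) - 1L
      bit <- frugalign:::.bv_bit(f$table[d + 1L, i + 1L], j)
      oracle <- r_prefix_min(substring(pat, j + 1L), substring(txt, i + 1L))
      expect_identical(bit == 0L, oracle <= d)
    }
  }
})

test_that("diagonal semantics: d_opt equals the prefix-min edit distance", {
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(0:6, 1)
    txt <- rand_seq(n, c("A", "C")); pat <- rand_seq(n, c("A", "C"))
    f <- fill_table(txt, pat, p_basic(6, 0))
    expect_equal(f$d_opt, r_prefix_min(pat, txt))
  }
})

test_that("ambiguous bases always cost an edit", {
  # N never matches, not even another N
  expect_equal(frg_align("N", "N", p_basic(4, 0))$cigar, "1X")
  f <- fill_table("ACGN", "ACGN", p_basic(4, 0))
  expect_equal(f$d_opt, 1L)
})
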