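# Traceback: edge regeneration, selection priority, window walks.

test_that("regenerate_edges matches the hand-derived window", {
  f <- fill_table("ACGT", "ACGA", p_basic(4, 0))
  e <- regenerate_edges(f, 1, 0)
  expect_equal(e$M, "0110")
  expect_equal(e$S, "1110")
  expect_equal(e$D, "1111")
  expect_equal(e$I, "1100")
  expect_equal(regenerate_edges(f, 1, 2)$entry, "1100")  # the marked cell
})

test_that("edges mode and entries mode regenerate identical edge sets", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(1:10, 1); m <- sample(1:10, 1)
    txt <- rand_seq(n); pat <- rand_seq(m)
    fe <- fill_table(txt, pat, window_params(10, 0, sene = FALSE,
                                             dent = FALSE, et = FALSE))
    fn <- fill_table(txt, pat, window_params(10, 0, dent = FALSE,
                                             et = FALSE))
    for (d in seq_len(fe$rows_computed) - 1L)
      for (i in 0:(n - 1L))
        expect_identical(regenerate_edges(fe, d, i)[c("I", "D", "S", "M")],
                         regenerate_edges(fn, d, i)[c("I", "D", "S", "M")])
  }
})

test_that("dent mode regenerates the trimmed bits and rejects the rest", {
  W <- 8L; O <- 3L  # stored region: columns 0..5, bits 0..5
  txt <- rand_seq(8); pat <- rand_seq(8)
  fd <- fill_table(txt, pat, window_params(W, O, et = FALSE))
  fn <- fill_table(txt, pat, window_params(W, O, dent = FALSE, et = FALSE))
  w <- fd$bits_per_entry
  for (d in seq_len(fd$rows_computed) - 1L)
    for (i in 0:(fd$cols_stored - 2L)) {
      ed <- regenerate_edges(fd, d, i)
      en <- regenerate_edges(fn, d, i)
      # bits j <= W-O-1 of every edge agree between trimmed and full widths
      for (nm in c("I", "D", "S", "M"))
        expect_identical(substr(ed[[nm]], 1, w - 1L),
                         substr(en[[nm]], 1, w - 1L))
    }
  expect_error(regenerate_edges(fd, 1, fd$cols_stored - 1L),
               "outside the stored region")
})

test_that("select_edge follows the fixed M > S > D > I priority", {
  expect_equal(select_edge(list(M = "0110", S = "1110", D = "1111",
                                I = "1100"), 0), "M")
  expect_equal(select_edge(list(M = "1111", S = "1110", D = "1111",
                                I = "0000"), 3), "S")
  expect_equal(select_edge(list(M = "1111", S = "1111", D = "1111",
                                I = "0111"), 0), "I")
  expect_equal(select_edge(list(M = "0000", S = "0000", D = "0000",
                                I = "0000"), 1, match_only = TRUE), "M")
  expect_error(select_edge(list(M = "1111", S = "1111", D = "1111",
                                I = "1111"), 2), "no zero bit")
})

test_that("terminal and truncated walks reproduce the worked examples", {
  tb <- traceback_window("ACGT", "ACGA", p_basic(4, 0))
  expect_equal(tb$ops, "===X")
  expect_equal(tb$text_consumed, 4L)
  expect_equal(tb$pattern_consumed, 4L)
  expect_equal(tb$d_start, 1L)

  tb2 <- traceback_window("ACGT", "ACGA", p_basic(4, 3), terminal = FALSE)
  expect_equal(tb2$ops, "=")  # stops after the first W - O = 1 edge
  expect_equal(c(tb2$text_consumed, tb2$pattern_consumed), c(1L, 1L))

  tb3 <- traceback_window("AAAA", "AA", p_basic(4, 0))
  expect_equal(tb3$ops, "==DD")
  expect_equal(tb3$padded_tail, 2L)
  expect_equal(c(tb3$text_consumed, tb3$pattern_consumed), c(4L, 2L))
})

test_that("the window result satisfies its accounting invariants", {
  set.seed(22)
  for (rep in 1:40) {
    n <- sample(0:16, 1); m <- sample(0:16, 1)
    txt <- rand_seq(n); pat <- rand_seq(m)
    terminal <- rep %% 2L == 0L
    params <- if (terminal) p_basic(16, 7) else window_params(16, 7)
    tb <- traceback_window(txt, pat, params, terminal = terminal)
    ops <- if (nchar(tb$ops)) strsplit(tb$ops, "")[[1]] else character()
    expect_equal(tb$text_consumed, sum(ops %in% c("=", "X", "D")))
    expect_equal(tb$pattern_consumed, sum(ops %in% c("=", "X", "I")))
    expect_lte(sum(ops %in% c("X", "I", "D")) - tb$padded_tail, tb$d_start)
    if (terminal) {
      expect_equal(tb$text_consumed, n)
      expect_equal(tb$pattern_consumed, m)
    } else {
      expect_lte(tb$text_consumed, 16L - 7L)
      expect_lte(tb$pattern_consumed, 16L - 7L)
    }
  }
})

test_that("storage mode never changes the window result (SENE/DENT exact)", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(1:32, 1); m <- sample(1:32, 1)
    txt <- rand_seq(n); pat <- rand_seq(m)
    base <- traceback_window(txt, pat,
                             window_params(32, 17, sene = FALSE, dent = FALSE),
                             terminal = TRUE)
    sene <- traceback_window(txt, pat, window_params(32, 17, dent = FALSE),
                             terminal = TRUE)
    expect_identical(sene$ops, base$ops)
    nt_base <- traceback_window(txt, pat,
                                window_params(32, 17, sene = FALSE, dent = FALSE),
                                terminal = FALSE)
    nt_sene <- traceback_window(txt, pat, window_params(32, 17, dent = FALSE),
                                terminal = FALSE)
    nt_dent <- traceback_window(txt, pat, window_params(32, 17),
                                terminal = FALSE)
    expect_identical(nt_sene$ops, nt_base$ops)
    expect_identical(nt_dent$ops, nt_base$ops)
  }
})

test_that("dent rejects terminal tracebacks by construction", {
  expect_error(traceback_window("ACGT", "ACGA", window_params(4, 1),
                                terminal = TRUE),
               "non-terminal")
})
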