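test_that("reposition follows the threshold to the nearest matching run", {
  tb <- build_move_table(build_oracle("ACAC$"))
  # run 2 ($, offset 2), want A: nothing above -> down to first A offset
  r1 <- reposition(tb, bipointer(2L, 2L), "A")
  expect_identical(list(r1$run, r1$off), list(3L, 3L))
  # run 3 (A, offset 3), want C: nothing below -> up to last C offset
  r2 <- reposition(tb, bipointer(3L, 3L), "C")
  expect_identical(list(r2$run, r2$off), list(1L, 1L))

  expect_error(reposition(tb, bipointer(2L, 2L), "G"),
               class = "movebwt_absent_char")
  expect_error(reposition(tb, bipointer(1L, 0L), "C"), "already sits")
})

test_that("scan and pointer repositioning agree everywhere", {
  for (seed in c(6, 14)) {
    txt <- if (seed == 6) random_text(500, seed) else
      pangenome_text(120, 4, seed)$text
    o <- build_oracle(txt)
    tb <- build_move_table(o, mode = "constant", d = 3L)
    for (i in seq_along(tb$p)) {
      for (a in BASES4) {
        if (tb$chars[i] == a || o$counts[[a]] == 0L) next
        for (j in tb$p[i]:(tb$p[i] + tb$len[i] - 1L)) {
          expect_identical(
            reposition(tb, bipointer(i, j), a, strategy = "scan"),
            reposition(tb, bipointer(i, j), a, strategy = "pointer"))
        }
      }
    }
  }
})

test_that("PML honors the absent-character and length contracts", {
  tx <- build_text(c(a = "ACACAATT"))   # no G anywhere
  tb <- build_move_table(build_oracle(tx))
  pv <- compute_pml(tb, "GGGG")
  expect_identical(pv$lengths, rep(0L, 4L))

  pv2 <- compute_pml(tb, "ACANT")
  expect_length(pv2$lengths, 5L)
  expect_identical(pv2$lengths[4L], 0L)    # N is a guaranteed mismatch

  expect_error(compute_pml(tb, ""), "empty read")
})

test_that("PMLs are sound: occurring substrings below matching statistics", {
  tx <- pangenome_text(500, 4, seed = 19)
  tb <- build_move_table(build_oracle(tx))
  reads <- generate_reads(tx, 30, 80, error_rate = 0.03,
                          decoy_fraction = 0.2, seed = 3)
  for (s in reads$seqs) {
    v <- compute_pml(tb, s)$lengths
    m <- length(v)
    expect_identical(m, nchar(s))
    ms <- matching_statistics_naive(tx, s)
    expect_true(all(v <= ms))
    expect_true(all(v[-m] <= v[-1] + 1L))    # +1-step Lipschitz
    for (k in which(v > 0L)) {
      expect_true(grepl(substr(s, k, k + v[k] - 1L), tx$text, fixed = TRUE))
    }
  }
})

test_that("default and constant modes give identical PMLs", {
  tx <- pangenome_text(400, 5, seed = 29)
  tabs <- both_tables(tx, d = 2L)
  reads <- generate_reads(tx, 40, 70, error_rate = 0.02,
                          decoy_fraction = 0.25, seed = 8)
  for (s in reads$seqs) {
    expect_identical(compute_pml(tabs$default, s)$lengths,
                     compute_pml(tabs$constant, s)$lengths)
  }
})

test_that("initial_range delimits the F-column block of a character", {
  tb <- build_move_table(build_oracle("ACAC$"))
  rng <- initial_range(tb, "A")
  expect_identical(c(rng$top$off, rng$bottom$off), c(1L, 2L))
  expect_true(initial_range(tb, "G")$empty)

  # blocks over all characters partition [0, n)
  tb2 <- build_move_table(build_oracle(random_text(200, 44)))
  offs <- unlist(lapply(c("A", "C", "G", "T"), function(a) {
    rng <- initial_range(tb2, a)
    if (rng$empty) integer(0) else rng$top$off:rng$bottom$off
  }))
  expect_identical(sort(c(0L, offs)), 0:(tb2$n - 1L))  # row 0 is "$"
})

test_that("backward search equals naive counting", {
  tb <- build_move_table(build_oracle("ACAC$"))
  expect_identical(backward_search_count(tb, "AC"), 2L)
  expect_identical(backward_search_count(tb, "ACAC"), 1L)
  expect_identical(backward_search_count(tb, "G"), 0L)
  expect_error(backward_search_count(tb, "ACN"), "only A, C, G, T")
  expect_error(backward_search_count(tb, ""), "non-empty")

  txt <- pangenome_text(150, 4, seed = 31)
  tabs <- both_tables(txt, d = 2L)
  body <- gsub("[#$]", "", txt$text)
  set.seed(9)
  pats <- c(
    unlist(lapply(1:6, function(L) {
      st <- sample(seq_len(nchar(body) - L + 1L), 25)
      substring(body, st, st + L - 1L)
    })),
    vapply(1:80, function(i) {
      paste(sample(BASES4, sample(1:10, 1), TRUE), collapse = "")
    }, character(1)))
  for (pat in pats) {
    want <- count_naive(txt, pat)
    expect_identical(backward_search_count(tabs$default, pat), want)
    expect_identical(backward_search_count(tabs$constant, pat), want)
  }
})

test_that("batch processing is invariant to batch size", {
  tx <- pangenome_text(300, 4, seed = 37)
  tb <- build_move_table(build_oracle(tx))
  reads <- generate_reads(tx, 45, 60, error_rate = 0.02,
                          decoy_fraction = 0.2, seed = 21)
  ref_pml <- process_batch(tb, reads, "pml", batch_size = 1L)
  ref_cnt <- process_batch(tb, reads, "count", batch_size = 1L)
  for (bs in c(2L, 16L, 32L)) {
    expect_identical(process_batch(tb, reads, "pml", batch_size = bs),
                     ref_pml)
    expect_identical(process_batch(tb, reads, "count", batch_size = bs),
                     ref_cnt)
  }
  # sequential loop gives the same answers
  expect_identical(lapply(seq_along(reads$seqs), function(i) {
    compute_pml(tb, reads$seqs[i], reads$names[i])
  }), ref_pml)
  expect_identical(
    vapply(reads$seqs, function(s) backward_search_count(tb, s),
           integer(1), USE.NAMES = FALSE),
    as.integer(ref_cnt$count))
})

test_that("a read set smaller than the batch is processed exactly once", {
  tx <- pangenome_text(200, 2, seed = 41)
  tb <- build_move_table(build_oracle(tx))
  reads <- generate_reads(tx, 3, 40, seed = 2)
  res <- process_batch(tb, reads, "pml", batch_size = 16L)
  expect_length(res, 3L)
  expect_identical(vapply(res, `[[`, "", "name"), reads$names)
})

test_that("the prefetch hook fires once per LF destination access", {
  tx <- pangenome_text(150, 2, seed = 43)
  tb <- build_move_table(build_oracle(tx))
  reads <- generate_reads(tx, 4, 25, seed = 5)
  hits <- 0L
  res <- process_batch(tb, reads, "pml", batch_size = 2L,
                       prefetch = function(row) hits <<- hits + 1L)
  reset_counters(tb)
  ref <- process_batch(tb, reads, "pml", batch_size = 2L)
  expect_identical(res, ref)
  expect_identical(as.numeric(hits), unname(get_counters(tb)["lf_calls"]))
})

test_that("PML and count output files use the documented formats", {
  tx <- pangenome_text(150, 2, seed = 47)
  tb <- build_move_table(build_oracle(tx))
  reads <- generate_reads(tx, 3, 30, seed = 6)
  f <- tempfile()
  write_pml(process_batch(tb, reads, "pml"), f)
  lines <- readLines(f)
  expect_length(lines, 6L)
  expect_identical(substr(lines[1], 1, 1), ">")
  expect_length(strsplit(lines[2], " ")[[1]], 30L)

  f2 <- tempfile()
  write_counts(process_batch(tb, reads, "count"), f2)
  tab <- read.delim(f2, header = FALSE)
  expect_identical(nrow(tab), 3L)
  expect_true(is.numeric(tab$V2))
})
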