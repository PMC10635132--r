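# Spec-style worked examples use 0-based run indices; the R API is 1-based,
# so indices there appear shifted by one.

test_that("build_rlbwt produces maximal runs tiling the BWT", {
  runs <- build_rlbwt("CC$AA")
  expect_identical(runs$c, c("C", "$", "A"))
  expect_identical(runs$len, c(2L, 1L, 2L))
  expect_identical(runs$p, c(0L, 2L, 3L))

  expect_identical(nrow(build_rlbwt("AAAA")), 1L)
  expect_identical(nrow(build_rlbwt("ACAC")), 4L)
  expect_identical(sum(build_rlbwt("ACAC")$len), 4L)
})

test_that("move table rows carry pi = LF(head) and its containing run", {
  tb <- build_move_table(build_oracle("ACAC$"))
  expect_identical(tb$pi, c(3L, 0L, 1L))
  expect_identical(tb$xi, c(3L, 1L, 1L))
  # every row's xi interval contains pi
  for (i in seq_along(tb$p)) {
    x <- tb$xi[i]
    expect_true(tb$p[x] <= tb$pi[i] && tb$pi[i] < tb$p[x] + tb$len[x])
  }
  expect_error(
    build_move_table(build_oracle("ACAC$"), runs = build_rlbwt("AAAA$")),
    "inconsistent")
})

test_that("degenerate single-run texts build and query", {
  o <- build_oracle("AAAA$")
  tb <- build_move_table(o)
  expect_identical(move_lf_all(tb)$off, lf_direct(o, 0:4))
  expect_identical(move_invert(tb), "AAAA$")
})

test_that("fast_forward scans to the containing run and reports steps", {
  tb <- build_move_table(build_oracle("ACAC$"))
  ff <- fast_forward(tb, 1L, 2L)
  expect_identical(ff$run, 2L)
  expect_identical(ff$steps, 1L)
  ff0 <- fast_forward(tb, 1L, 1L)
  expect_identical(ff0$steps, 0L)
  expect_error(fast_forward(tb, 1L, 99L), "out of range")

  # cross-check against binary-search lookup on random texts
  for (seed in c(4, 9)) {
    tb <- build_move_table(build_oracle(random_text(300, seed)))
    for (j in sample(0:(tb$n - 1L), 50)) {
      target <- run_of_offset(tb, j)
      for (i in unique(c(1L, max(1L, target - 3L), target))) {
        if (tb$p[i] <= j) {
          expect_identical(fast_forward(tb, i, j)$run, target)
        }
      }
    }
  }
})

test_that("move_lf matches the worked example including fast-forwards", {
  tb <- build_move_table(build_oracle("ACAC$"))
  reset_counters(tb)
  p1 <- move_lf(tb, bipointer(1L, 1L))
  expect_identical(list(p1$run, p1$off), list(3L, 4L))
  ctr0 <- get_counters(tb)
  p2 <- move_lf(tb, bipointer(3L, 4L))
  expect_identical(list(p2$run, p2$off), list(2L, 2L))
  expect_identical(unname(get_counters(tb)["fast_forwards"] -
                            ctr0["fast_forwards"]), 1)
  expect_error(move_lf(tb, bipointer(1L, 4L)), "invalid bipointer")
})

test_that("move_lf equals lf_direct at every offset (both modes)", {
  for (seed in 1:6) {
    txt <- if (seed %% 2) random_text(sample(50:500, 1), seed)
           else pangenome_text(150, 3, seed)$text
    o <- build_oracle(txt)
    truth <- lf_direct(o, 0:(o$n - 1L))
    for (mode in c("default", "constant")) {
      tb <- build_move_table(o, mode = mode, d = 3L)
      all <- move_lf_all(tb)
      expect_identical(all$off, truth)
      # scalar path agrees with the vectorized survey
      for (j in sample(0:(o$n - 1L), 30)) {
        pr <- move_lf(tb, bipointer(run_of_offset(tb, j), j))
        expect_identical(pr$off, all$off[j + 1L])
        expect_identical(pr$run, all$run[j + 1L])
      }
      # bijection
      expect_identical(sort(all$off), 0:(o$n - 1L))
    }
  }
})

test_that("chaining move_lf reconstructs the text (matches invert_bwt)", {
  for (txt in list("ACAC$", random_text(200, 15),
                   pangenome_text(120, 4, 3)$text)) {
    o <- build_oracle(txt)
    tb <- build_move_table(o)
    expect_identical(move_invert(tb), txt)
    expect_identical(move_invert(tb), invert_bwt(o))
  }
})

test_that("run_of_offset locates every head and errors out of range", {
  tb <- build_move_table(build_oracle("ACAC$"))
  expect_identical(run_of_offset(tb, 4L), 3L)
  expect_identical(run_of_offset(tb, 0L), 1L)
  expect_identical(run_of_offset(tb, tb$p), seq_along(tb$p))
  expect_error(run_of_offset(tb, 5L), "out of range")
})

test_that("index serialization round-trips every field", {
  o <- build_oracle(pangenome_text(200, 3, 6))
  for (mode in c("default", "constant")) {
    tb <- build_move_table(o, mode = mode, d = 2L)
    f <- tempfile(fileext = ".movi")
    write_index(tb, f)
    tb2 <- read_index(f)
    flds <- setdiff(names(tb), "counters")
    expect_identical(tb[flds], tb2[flds])
    # queries on the deserialized table match the original
    expect_identical(compute_pml(tb2, "ACGTACGT")$lengths,
                     compute_pml(tb, "ACGTACGT")$lengths)
    expect_identical(backward_search_count(tb2, "ACG"),
                     backward_search_count(tb, "ACG"))
  }
})

test_that("rebuilding from identical inputs gives a byte-identical index", {
  tx <- pangenome_text(150, 2, 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_index(build_move_table(build_oracle(tx)), f1)
  write_index(build_move_table(build_oracle(tx)), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("corrupt or mismatched index files raise explicit errors", {
  f <- tempfile()
  tb <- build_move_table(build_oracle("ACAC$"))
  write_index(tb, f)
  sz <- file.size(f)
  trunc <- tempfile()
  writeBin(readBin(f, "raw", n = sz %/% 2L), trunc)
  expect_error(read_index(trunc), "truncated or corrupt")

  other <- tempfile()
  saveRDS(list(format = "something-else"), other)
  expect_error(read_index(other), "not a movebwt index")

  vfile <- tempfile()
  saveRDS(list(format = "movebwt-move-table", version = 99L,
               table = list()), vfile)
  expect_error(read_index(vfile), "version mismatch")
})

test_that("move_stats reports sizes and compressibility", {
  o <- build_oracle(pangenome_text(400, 6, 2))
  st <- move_stats(build_move_table(o, mode = "constant", d = 2L))
  expect_identical(st$n, o$n)
  expect_gte(st$rows, st$r_original)
  expect_identical(st$growth, st$rows / st$r_original)
  expect_gt(st$n_over_r, 1)
})
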