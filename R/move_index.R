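#' Run-length encode a BWT string
#'
#' @param bwt Non-empty BWT string.
#' @return data.frame with one row per maximal run: `c` (character), `len`,
#'   `p` (0-based BWT offset of the run head), and `split` (always `FALSE`
#'   here; [split_runs()] marks subrun heads it introduces).
#' @examples
#' build_rlbwt("CC$AA")
#' @export
build_rlbwt <- function(bwt) {
  if (!is.character(bwt) || length(bwt) != 1L || !nzchar(bwt)) {
    stop("bwt must be a non-empty string")
  }
  rl <- rle(chars_of(bwt))
  data.frame(c = rl$values, len = rl$lengths,
             p = cumsum(c(0L, utils::head(rl$lengths, -1L))),
             split = FALSE, stringsAsFactors = FALSE)
}

#' Build the move table
#'
#' The move table has one row per BWT run (post-splitting in constant mode)
#' with: the run character `c`, length `len`, head offset `p`, the
#' LF-mapping of the head `pi = LF(p)`, and `xi`, the index of the row whose
#' interval contains `pi`. LF-mapping any offset `j` in row `i` is then row
#' arithmetic, `LF(j) = pi[i] + (j - p[i])`, followed by a forward
#' "fast-forward" scan from row `xi[i]` to the row containing the result.
#'
#' Per-row repositioning thresholds (see [compute_thresholds()]) are always
#' attached; in `"constant"` mode runs are first split with parameter `d`
#' (see [split_runs()]) so every LF query fast-forwards fewer than `2d`
#' times, and per-row repositioning pointers are populated
#' ([attach_reposition_pointers()]).
#'
#' Row indices are 1-based (R convention); BWT offsets are 0-based.
#'
#' @param oracle A [build_oracle()] result (with LCP).
#' @param runs Optional run list (defaults to `build_rlbwt(oracle$bwt)`);
#'   must tile the oracle's BWT.
#' @param mode `"default"` or `"constant"`.
#' @param d Splitting parameter for constant mode (`>= 2`).
#' @return A `move_table`.
#' @examples
#' tb <- build_move_table(build_oracle("ACAC$"))
#' tb$pi  # LF of each run head
#' @export
build_move_table <- function(oracle, runs = NULL,
                             mode = c("default", "constant"), d = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(oracle, "bwt_oracle"))
  if (is.null(runs)) runs <- build_rlbwt(oracle$bwt)
  if (paste(rep(runs$c, runs$len), collapse = "") != oracle$bwt) {
    stop("runs are inconsistent with the oracle's BWT")
  }
  r_original <- length(rle(chars_of(oracle$bwt))$lengths)
  if (mode == "constant") {
    runs <- split_runs(oracle, runs, split_config(d))
  }
  p <- as.integer(runs$p)
  pi <- oracle$lf[p + 1L]
  xi <- findInterval(pi, p)
  tb <- structure(list(
    chars = runs$c, len = as.integer(runs$len), p = p, pi = pi, xi = xi,
    split = runs$split, n = oracle$n, r_original = r_original,
    counts = oracle$counts, C = oracle$C,
    mode = mode, d = if (mode == "constant") as.integer(d) else NA_integer_,
    thresholds = compute_thresholds(oracle, runs),
    up_run = NULL, dn_run = NULL,
    counters = new_counters()
  ), class = "move_table")
  if (mode == "constant") tb <- attach_reposition_pointers(tb)
  tb
}

#' @export
print.move_table <- function(x, ...) {
  cat("move_table (", x$mode, " mode",
      if (x$mode == "constant") paste0(", d = ", x$d), "): n = ", x$n,
      ", rows = ", length(x$p), ", r before splitting = ", x$r_original,
      "\n", sep = "")
  invisible(x)
}

#' A (run, offset) pointer into the move table
#'
#' @param run 1-based row index.
#' @param off 0-based global BWT offset; must lie inside the row's interval.
#' @return A `bipointer` list.
#' @export
bipointer <- function(run, off) {
  structure(list(run = as.integer(run), off = as.integer(off)),
            class = "bipointer")
}

#' @export
print.bipointer <- function(x, ...) {
  cat("bipointer: run ", x$run, ", offset ", x$off, "\n", sep = "")
  invisible(x)
}

#' Fast-forward to the row containing an offset
#'
#' Linear forward scan from row `i` (which must start at or before
#' `j_target`) to the unique row whose interval contains `j_target`. The
#' scan length is reported and added to the table's instrumentation
#' counters; in constant mode it is guaranteed to be below `2d`.
#'
#' @param table A `move_table`.
#' @param i Starting row index (1-based).
#' @param j_target 0-based BWT offset.
#' @return list(`run`, `steps`).
#' @export
fast_forward <- function(table, i, j_target) {
  if (j_target >= table$n || j_target < 0L) {
    stop("offset out of range [0, ", table$n, ")")
  }
  p <- table$p
  if (p[i] > j_target) stop("start row begins after the target offset")
  r <- length(p)
  steps <- 0L
  while (i < r && p[i + 1L] <= j_target) {
    i <- i + 1L
    steps <- steps + 1L
  }
  table$counters$fast_forwards <- table$counters$fast_forwards + steps
  list(run = i, steps = steps)
}

#' One LF-mapping step on the move table
#'
#' Computes `off' = pi[i] + (off - p[i])` and fast-forwards from `xi[i]` to
#' the row containing `off'`. Uses only row arithmetic and forward scanning
#' (no rank/select structures). Equals [lf_direct()] at every offset.
#'
#' @param table A `move_table`.
#' @param ptr A [bipointer()].
#' @return The new [bipointer()].
#' @export
move_lf <- function(table, ptr) {
  i <- ptr$run
  p <- table$p
  if (i < 1L || i > length(p) ||
      ptr$off < p[i] || ptr$off >= p[i] + table$len[i]) {
    stop("invalid bipointer")
  }
  off2 <- table$pi[i] + (ptr$off - p[i])
  ff <- fast_forward(table, table$xi[i], off2)
  table$counters$lf_calls <- table$counters$lf_calls + 1L
  bipointer(ff$run, off2)
}

#' LF-mapping of every BWT offset at once
#'
#' Vectorized companion to [move_lf()] used for exhaustive verification and
#' index statistics: applies the per-row arithmetic to all `n` offsets and
#' locates destination rows in bulk. The per-offset fast-forward count is
#' the distance from `xi` to the destination row, identical to the scan
#' length [move_lf()] would take.
#'
#' @param table A `move_table`.
#' @return list(`off`, `run`, `ff`): LF value, destination row, and
#'   fast-forward count for offsets `0..n-1`.
#' @export
move_lf_all <- function(table) {
  run <- rep.int(seq_along(table$p), table$len)
  j <- seq_len(table$n) - 1L
  off2 <- table$pi[run] + (j - table$p[run])
  run2 <- findInterval(off2, table$p)
  list(off = off2, run = run2, ff = run2 - table$xi[run])
}

#' Locate the row containing a BWT offset
#'
#' Binary search over row head offsets; used in construction and tests
#' (query loops use fast-forward scanning instead).
#'
#' @param table A `move_table`.
#' @param j 0-based BWT offset(s).
#' @return 1-based row index (vectorized).
#' @export
run_of_offset <- function(table, j) {
  if (any(j < 0L | j >= table$n)) {
    stop("offset out of range [0, ", table$n, ")")
  }
  findInterval(j, table$p)
}

# --- instrumentation -------------------------------------------------------

new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$lf_calls <- 0
  e$fast_forwards <- 0
  e$reposition_scans <- 0
  e
}

#' Read or reset the table's instrumentation counters
#'
#' Every LF-mapping, fast-forward step and repositioning scan step executed
#' through a `move_table` is tallied; the counts back the predictability
#' contrast between default and constant modes.
#'
#' @param table A `move_table`.
#' @return `get_counters`: named numeric vector (`lf_calls`,
#'   `fast_forwards`, `reposition_scans`). `reset_counters`: the table,
#'   invisibly.
#' @export
get_counters <- function(table) {
  c(lf_calls = table$counters$lf_calls,
    fast_forwards = table$counters$fast_forwards,
    reposition_scans = table$counters$reposition_scans)
}

#' @rdname get_counters
#' @export
reset_counters <- function(table) {
  table$counters$lf_calls <- 0
  table$counters$fast_forwards <- 0
  table$counters$reposition_scans <- 0
  invisible(table)
}

# --- serialization ---------------------------------------------------------

.INDEX_FORMAT <- "movebwt-move-table"
.INDEX_VERSION <- 1L

#' Write / read a move-table index
#'
#' Lossless round trip of every field (mode, d, thresholds, repositioning
#' pointers included) through a versioned single-file container. Reading a
#' truncated or foreign file, or one written by an incompatible format
#' version, raises an explicit error. Instrumentation counters are not part
#' of the index; they start at zero on load, so rebuilding an index from the
#' same inputs yields a byte-identical file.
#'
#' @param table A `move_table`.
#' @param path File path.
#' @return `write_index`: `path` invisibly. `read_index`: the `move_table`.
#' @export
write_index <- function(table, path) {
  stopifnot(inherits(table, "move_table"))
  payload <- unclass(table)
  payload$counters <- NULL
  obj <- list(format = .INDEX_FORMAT, version = .INDEX_VERSION,
              table = payload)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file ", path, " (truncated or corrupt): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, .INDEX_FORMAT)) {
    stop("not a movebwt index file: ", path, call. = FALSE)
  }
  if (!identical(obj$version, .INDEX_VERSION)) {
    stop("index format version mismatch: file has ", obj$version,
         ", this package reads ", .INDEX_VERSION, call. = FALSE)
  }
  tb <- obj$table
  tb$counters <- new_counters()
  structure(tb, class = "move_table")
}

#' Index statistics
#'
#' @param table A `move_table`.
#' @return A `move_stats` list: text length `n`, run count before splitting
#'   `r_original`, current `rows`, compressibility `n_over_r`, row growth
#'   factor from splitting, mode and `d`.
#' @export
move_stats <- function(table) {
  structure(list(
    n = table$n,
    r_original = table$r_original,
    rows = length(table$p),
    n_over_r = table$n / table$r_original,
    growth = length(table$p) / table$r_original,
    mode = table$mode,
    d = table$d
  ), class = "move_stats")
}

#' @export
print.move_stats <- function(x, ...) {
  cat("n:          ", x$n, "\n",
      "r_original: ", x$r_original, "\n",
      "rows:       ", x$rows, "\n",
      "n/r:        ", round(x$n_over_r, 3), "\n",
      "row growth: ", round(x$growth, 4), "\n",
      "mode:       ", x$mode,
      if (!is.na(x$d)) paste0(" (d = ", x$d, ")"), "\n", sep = "")
  invisible(x)
}
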