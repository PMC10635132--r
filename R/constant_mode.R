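#' Splitting configuration for constant mode
#'
#' @param d Integer `>= 2`. After splitting, every LF-mapping query performs
#'   strictly fewer than `2d` fast-forward steps.
#' @return A `split_config` list.
#' @export
split_config <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d < 2) {
    stop("d must be a single integer >= 2")
  }
  structure(list(d = as.integer(d)), class = "split_config")
}

#' Split BWT runs to bound fast-forwards
#'
#' Interval-splitting in the style of the constant-time LF construction:
#' while any run's LF-image interval `[LF(p), LF(p) + len)` contains at
#' least `2d` run-head offsets of the current run set, that run is split at
#' the preimage of the d-th such head. At the fixpoint no image interval
#' holds `2d` heads, so a fast-forward scan -- which only ever crosses heads
#' inside the image interval -- takes fewer than `2d` steps for every
#' possible query. Each pass splits every currently offending run (decisions
#' taken against the pre-pass head set); passes repeat until none offends,
#' which also makes the operation idempotent.
#'
#' Output runs tile `[0, n)`, each a sub-interval of exactly one input run
#' with the same character; heads created by splitting are flagged in the
#' `split` column.
#'
#' @param oracle A [build_oracle()] result.
#' @param runs Run list as from [build_rlbwt()].
#' @param cfg A [split_config()] (or a bare integer `d`).
#' @return Run data.frame (`c`, `len`, `p`, `split`).
#' @export
split_runs <- function(oracle, runs, cfg) {
  if (is.numeric(cfg)) cfg <- split_config(cfg)
  stopifnot(inherits(cfg, "split_config"))
  d <- cfg$d
  p <- as.integer(runs$p)
  len <- as.integer(runs$len)
  cc <- runs$c
  split <- if (is.null(runs$split)) rep(FALSE, length(p)) else runs$split
  lf <- oracle$lf
  guard <- 0L
  repeat {
    q <- lf[p + 1L]
    # heads h with q <= h < q + len, counted against the current head set
    lo <- findInterval(q - 1L, p)
    hi <- findInterval(q + len - 1L, p)
    bad <- which(hi - lo >= 2L * d)
    if (length(bad) == 0L) break
    # d-th head inside each offending image interval, mapped back to the
    # offending run's own coordinates
    cut <- p[lo[bad] + d] - q[bad] + p[bad]
    # apply right-to-left so earlier insertion points stay valid
    for (k in rev(seq_along(bad))) {
      b <- bad[k]
      s <- cut[k]
      left <- s - p[b]
      p <- append(p, s, after = b)
      len <- append(len, len[b] - left, after = b)
      len[b] <- left
      cc <- append(cc, cc[b], after = b)
      split <- append(split, TRUE, after = b)
    }
    guard <- guard + 1L
    if (guard > 64L * length(p)) {
      stop("run splitting failed to reach a fixpoint")  # cannot happen
    }
  }
  data.frame(c = cc, len = len, p = p, split = split,
             stringsAsFactors = FALSE)
}

#' Attach constant-time repositioning pointers
#'
#' For each row `i` and each base `a` different from the row's character:
#' `up_run[i, a]` is the greatest row above (`i' < i`) with character `a`
#' and `dn_run[i, a]` the least row below, or `NA` where none exists. A
#' mismatching query can then jump to its repositioning target in one step
#' instead of scanning run to run. With the DNA alphabet this is the
#' constant-mode complement of the thresholds: two pointers for each of the
#' three non-run bases, six per row.
#'
#' @param table A `move_table`.
#' @return The table with `up_run` / `dn_run` matrices populated.
#' @export
attach_reposition_pointers <- function(table) {
  r <- length(table$p)
  up <- dn <- matrix(NA_integer_, nrow = r, ncol = 4L,
                     dimnames = list(NULL, .BASES))
  for (a in .BASES) {
    ia <- which(table$chars == a)
    if (length(ia) == 0L) next
    pos <- findInterval(seq_len(r), ia)        # a-rows at or above each row
    up[, a] <- ifelse(pos >= 1L, ia[pmax(pos, 1L)], NA_integer_)
    dn[, a] <- ifelse(pos < length(ia), ia[pmin(pos + 1L, length(ia))],
                      NA_integer_)
  }
  own <- cbind(seq_len(r), match(table$chars, .BASES))
  own <- own[!is.na(own[, 2L]), , drop = FALSE]
  up[own] <- NA_integer_   # pointers are defined only for a != run char
  dn[own] <- NA_integer_
  table$up_run <- up
  table$dn_run <- dn
  table
}
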