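#' Compute repositioning thresholds
#'
#' For every run `i` (character `c`) and every base `a != c`, the threshold
#' `t` is the offset separating the run's rows into those that reposition
#' upward (to the nearest `a` above) and those that reposition downward:
#' rows at offsets `j < t` have a longer common prefix with the nearest
#' `a`-terminated row above, rows at `j >= t` with the one below. With `u`
#' the last `a`-occurrence above the run and `v` the first below, `t` is the
#' position of the minimum of the LCP array on `(u, v]` (leftmost minimum on
#' ties, a fixed rule chosen for reproducibility), clamped into
#' `[p, p + len]`. If no `a` occurs above, `t = p` (always down); if none
#' below, `t = p + len` (always up).
#'
#' Because every run in the same gap between consecutive `a`-occurrences
#' shares the same `(u, v]`, the LCP minimum is computed once per gap.
#'
#' @param oracle A [build_oracle()] result with an LCP array.
#' @param runs Run list as from [build_rlbwt()] (post-splitting in constant
#'   mode: thresholds are clamped against the final run intervals).
#' @return Numeric matrix, one row per run, columns `A`,`C`,`G`,`T`; entry
#'   `[i, a]` is the threshold offset, `NA` for the run's own character or
#'   for bases absent from the BWT.
#' @export
compute_thresholds <- function(oracle, runs) {
  if (is.null(oracle$lcp)) {
    stop("oracle was built without an LCP array (with_lcp = FALSE)")
  }
  bw <- chars_of(oracle$bwt)
  lcp <- oracle$lcp                        # R index k+1 holds lcp0[k]
  p <- as.integer(runs$p)
  len <- as.integer(runs$len)
  r <- length(p)
  th <- matrix(NA_real_, nrow = r, ncol = 4L, dimnames = list(NULL, .BASES))
  for (a in .BASES) {
    occ <- which(bw == a) - 1L             # 0-based offsets of a in the BWT
    G <- length(occ)
    if (G == 0L) next
    # leftmost LCP-argmin for each gap g between occ[g] and occ[g+1]
    kmin <- integer(max(G - 1L, 0L))
    if (G >= 2L) {
      for (g in seq_len(G - 1L)) {
        u <- occ[g]
        v <- occ[g + 1L]
        kmin[g] <- u + which.min(lcp[(u + 2L):(v + 1L)])
      }
    }
    iu <- findInterval(p - 0.5, occ)       # a-occurrences above each run
    t <- ifelse(iu == 0L, p,
         ifelse(iu == G, p + len,
                pmin(pmax(kmin[pmax(iu, 1L)], p), p + len)))
    t[runs$c == a] <- NA_real_
    th[, a] <- t
  }
  th
}
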