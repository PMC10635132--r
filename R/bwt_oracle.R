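#' Build the brute-force BWT oracle
#'
#' Computes, directly from the text, the structures that every move-table
#' query is verified against: the suffix array (prefix-doubling,
#' O(n log^2 n)), the BWT (`bwt[i] = text[(sa[i] - 1) mod n]`), the LCP
#' array (Kasai's algorithm), the full LF-mapping, and cumulative character
#' counts `C` (for each character, the number of strictly smaller characters
#' in the text, i.e. the F-column offset where its block begins).
#'
#' All BWT offsets and suffix-array values are 0-based.
#'
#' @param text A `sequence_text` or plain alphabet string ending in `"$"`.
#' @param with_lcp Compute the LCP array? Only needed when the oracle will
#'   feed threshold construction; skipping it speeds up run-count surveys on
#'   long texts.
#' @return A `bwt_oracle`: list with `text`, `n`, `sa`, `bwt`, `lcp`
#'   (`lcp[i]` in R's 1-based indexing is the LCP of the suffixes at rows
#'   `i-2` and `i-1`; `lcp[1] = 0`), `lf` (0-based LF values), `counts`
#'   (per-character totals) and `C` (cumulative counts), both named by the
#'   six-character alphabet.
#' @examples
#' o <- build_oracle("ACAC$")
#' o$sa    # 4 2 0 3 1
#' o$bwt   # "CC$AA"
#' @export
build_oracle <- function(text, with_lcp = TRUE) {
  st <- as_sequence_text(text)
  ranks <- ranks_of(st$text)
  n <- length(ranks)
  sa <- suffix_array(ranks)
  prev <- (sa - 1L) %% n
  bwt_ranks <- ranks[prev + 1L]
  bwt <- paste(.ALPHABET[bwt_ranks], collapse = "")
  counts <- tabulate(ranks, nbins = 6L)
  names(counts) <- .ALPHABET
  C <- c(0L, cumsum(counts))[1:6]
  names(C) <- .ALPHABET
  # LF for every offset: stable sort of BWT positions by character gives the
  # F-column row of each BWT position.
  o <- order(bwt_ranks)
  lf <- integer(n)
  lf[o] <- seq_len(n) - 1L
  lcp <- if (with_lcp) kasai_lcp(ranks, sa) else NULL
  structure(list(text = st, n = n, sa = sa, bwt = bwt,
                 bwt_ranks = bwt_ranks, lcp = lcp, lf = lf,
                 counts = counts, C = C),
            class = "bwt_oracle")
}

#' @export
print.bwt_oracle <- function(x, ...) {
  r <- length(rle(chars_of(x$bwt))$lengths)
  cat("bwt_oracle: n =", x$n, ", BWT runs r =", r,
      if (is.null(x$lcp)) ", no LCP array", "\n")
  invisible(x)
}

# Suffix array by prefix doubling over integer ranks; returns 0-based
# positions. The unique terminator guarantees strict suffix order.
suffix_array <- function(ranks) {
  n <- length(ranks)
  if (n == 1L) return(0L)
  rk <- match(ranks, sort(unique(ranks)))
  k <- 1L
  repeat {
    rk2 <- if (k >= n) rep.int(0L, n) else c(rk[(k + 1L):n], rep.int(0L, k))
    o <- order(rk, rk2)
    r1 <- rk[o]
    r2 <- rk2[o]
    new <- cumsum(c(1L, (r1[-1L] != r1[-n]) | (r2[-1L] != r2[-n])))
    rk[o] <- new
    if (new[n] == n) return(o - 1L)
    k <- k * 2L
  }
}

# Kasai's linear-time LCP from text ranks + suffix array. lcp[1] = 0;
# lcp[i] compares the suffixes at (1-based) rows i-1 and i.
kasai_lcp <- function(ranks, sa) {
  n <- length(ranks)
  row_of <- integer(n)
  row_of[sa + 1L] <- seq_len(n)
  lcp <- integer(n)
  h <- 0L
  for (i0 in 0:(n - 1L)) {
    r <- row_of[i0 + 1L]
    if (r > 1L) {
      j0 <- sa[r - 1L]
      while (i0 + h < n && j0 + h < n &&
             ranks[i0 + h + 1L] == ranks[j0 + h + 1L]) {
        h <- h + 1L
      }
      lcp[r] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Direct LF-mapping on the oracle
#'
#' `lf_direct(oracle, j)` returns `C[bwt[j]] + rank(bwt[j], j)`, the F-column
#' row holding the same text character as BWT offset `j`. Vectorized over
#' `j`. This is the ground truth that [move_lf()] is checked against.
#'
#' @param oracle A [build_oracle()] result.
#' @param j BWT offset(s), 0-based.
#' @return 0-based offset(s) `LF(j)`.
#' @export
lf_direct <- function(oracle, j) {
  if (any(j < 0L | j >= oracle$n)) {
    stop("BWT offset out of range [0, ", oracle$n, ")")
  }
  oracle$lf[j + 1L]
}

#' Invert the BWT
#'
#' Starting from the BWT row whose F character is the terminator (row 0) and
#' chaining the LF-mapping `n` times spells the text right to left; the
#' reconstructed text (terminator included) is returned. Round-tripping any
#' text through [build_oracle()] and `invert_bwt()` is the identity.
#'
#' @param oracle A [build_oracle()] result.
#' @return The text string.
#' @export
invert_bwt <- function(oracle) {
  n <- oracle$n
  bw <- chars_of(oracle$bwt)
  lf <- oracle$lf
  out <- character(n)
  out[n] <- .TERM
  j <- 0L
  if (n >= 2L) {
    for (k in (n - 1L):1L) {
      out[k] <- bw[j + 1L]
      j <- lf[j + 1L]
    }
  }
  paste(out, collapse = "")
}

#' Naive occurrence count
#'
#' Counts (possibly overlapping) start offsets of `pattern` in the text by
#' direct scanning, independent of any index structure. Patterns are over
#' ACGT, so occurrences can never include the separator or terminator.
#'
#' @param text A `sequence_text` or plain text string.
#' @param pattern Non-empty pattern over `{A,C,G,T}`.
#' @return Integer occurrence count.
#' @export
count_naive <- function(text, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop("pattern must be a non-empty string")
  }
  s <- text_string(text)
  Biostrings::countPattern(pattern, Biostrings::BString(s))
}

#' Naive matching statistics
#'
#' `MS[i]` is the length of the longest prefix of `pattern[i..m]` occurring
#' anywhere in the text, computed by direct substring search (each candidate
#' is tested with a literal scan of the text). Serves as the upper-bound
#' oracle for pseudo matching lengths.
#'
#' @param text A `sequence_text` or plain text string.
#' @param pattern Non-empty pattern string.
#' @return Integer vector of length `nchar(pattern)`, 0-based position `i`
#'   at R index `i + 1`.
#' @export
matching_statistics_naive <- function(text, pattern) {
  if (!nzchar(pattern)) stop("pattern must be non-empty")
  s <- text_string(text)
  m <- nchar(pattern)
  ms <- integer(m)
  ell <- 0L
  for (i in seq_len(m)) {
    # MS can drop by at most 1 per position, so resume from there.
    ell <- max(ell - 1L, 0L)
    while (i + ell <= m &&
           grepl(substr(pattern, i, i + ell), s, fixed = TRUE)) {
      ell <- ell + 1L
    }
    ms[i] <- ell
  }
  ms
}
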