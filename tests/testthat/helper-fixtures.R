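# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

BASES4 <- c("A", "C", "G", "T")

# Uniform-random terminated text (no separators).
random_text <- function(n, seed) {
  set.seed(seed)
  paste0(paste(sample(BASES4, n, replace = TRUE), collapse = ""), "$")
}

# Terminated multi-document text from a small synthetic pangenome.
pangenome_text <- function(base_length, n_haplotypes, seed,
                           substitution_rate = 0.001, indel_rate = 0) {
  build_text(generate_pangenome(pangenome_spec(
    base_length, n_haplotypes,
    substitution_rate = substitution_rate,
    indel_rate = indel_rate, seed = seed)))
}

# Number of maximal BWT runs.
run_count <- function(bwt) {
  length(rle(strsplit(bwt, "", fixed = TRUE)[[1L]])$lengths)
}

# Direct pairwise LCP of the suffixes starting at 0-based text offsets a, b
# (character-by-character comparison; independent of the package's LCP).
suffix_lcp <- function(text, a, b) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  h <- 0L
  while (a + h < n && b + h < n && ch[a + h + 1L] == ch[b + h + 1L]) {
    h <- h + 1L
  }
  h
}

# Brute-force matching statistics: full per-position search with no
# incremental shortcuts (quadratic; used to cross-check the package oracle).
brute_ms <- function(text, pattern) {
  m <- nchar(pattern)
  vapply(seq_len(m), function(i) {
    ell <- 0L
    while (i + ell <= m &&
           grepl(substr(pattern, i, i + ell), text, fixed = TRUE)) {
      ell <- ell + 1L
    }
    ell
  }, integer(1L))
}

# Suffix-array / BWT ground truth by explicit enumerate-and-sort.
enumerate_sa <- function(text) {
  n <- nchar(text)
  suffixes <- substring(text, seq_len(n), n)
  # collation order $ < # < A < C < G < T, enforced by rank-remapping
  ranked <- chartr("$#ACGT", "012345", suffixes)
  order(ranked) - 1L
}

# Reconstruct the text by chaining move_lf n times from the terminator's
# BWT position; the characters are collected right-to-left.
move_invert <- function(table) {
  i <- which(table$chars == "$")[1L]
  ptr <- bipointer(i, table$p[i])
  out <- character(table$n)
  for (k in table$n:1L) {
    out[k] <- table$chars[ptr$run]
    ptr <- move_lf(table, ptr)
  }
  paste(out, collapse = "")
}

# Brute-force referee for a threshold decision: from in-run offset j,
# compare the direct suffix LCP with the candidate row above (last a before
# the run) and below (first a after it). Ties allow either direction.
brute_choice <- function(oracle, p, len, j, a) {
  bw <- strsplit(oracle$bwt, "", fixed = TRUE)[[1]]
  occ <- which(bw == a) - 1L
  u <- occ[occ < p]
  v <- occ[occ >= p + len]
  u <- if (length(u)) max(u) else NA
  v <- if (length(v)) min(v) else NA
  txt <- oracle$text$text
  lu <- if (!is.na(u)) suffix_lcp(txt, oracle$sa[j + 1L], oracle$sa[u + 1L])
        else -1L
  lv <- if (!is.na(v)) suffix_lcp(txt, oracle$sa[j + 1L], oracle$sa[v + 1L])
        else -1L
  if (lu > lv) "up" else if (lv > lu) "down" else "tie"
}

# Build oracle + both mode tables once for a text.
both_tables <- function(text, d = 3L) {
  o <- build_oracle(text)
  list(oracle = o,
       default = build_move_table(o),
       constant = build_move_table(o, mode = "constant", d = d))
}
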