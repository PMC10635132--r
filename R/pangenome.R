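#' Specification for a synthetic pangenome
#'
#' Describes a collection of haplotypes derived from one random base
#' sequence. Haplotype 0 is uniform-random over ACGT; each further
#' haplotype is an independent copy of haplotype 0 with i.i.d. substitutions
#' at `substitution_rate` and geometric-length insertions/deletions seeded
#' at `indel_rate` per position. The defaults emulate a closely related
#' haplotype collection: 0.1% substitution divergence and no indels, which
#' keeps the BWT of the concatenation highly run-compressible.
#'
#' @param base_length Length of the base haplotype (bases).
#' @param n_haplotypes Number of haplotypes (including the base).
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-base probability of starting an indel.
#' @param mean_indel_len Mean indel length (geometric).
#' @param seed RNG seed; the whole collection is reproducible from it.
#' @return A `pangenome_spec` list.
#' @export
pangenome_spec <- function(base_length, n_haplotypes,
                           substitution_rate = 0.001, indel_rate = 0,
                           mean_indel_len = 5, seed = 1L) {
  stopifnot(length(base_length) == 1L, base_length >= 1,
            length(n_haplotypes) == 1L, n_haplotypes >= 1)
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("substitution_rate and indel_rate must lie in [0, 1]")
  }
  stopifnot(mean_indel_len >= 1)
  structure(list(base_length = as.integer(base_length),
                 n_haplotypes = as.integer(n_haplotypes),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 mean_indel_len = mean_indel_len,
                 seed = as.integer(seed)),
            class = "pangenome_spec")
}

#' Generate a synthetic pangenome
#'
#' @param spec A [pangenome_spec()].
#' @return Named character vector of haplotype sequences
#'   (`hap0` .. `hap{h-1}`), `hap0` being the base.
#' @examples
#' haps <- generate_pangenome(pangenome_spec(200, 3, seed = 7))
#' nchar(haps)
#' @export
generate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  with_seed(spec$seed, {
    base <- sample(.BASES, spec$base_length, replace = TRUE)
    haps <- vector("list", spec$n_haplotypes)
    haps[[1L]] <- base
    for (h in seq_len(spec$n_haplotypes - 1L)) {
      haps[[h + 1L]] <- mutate_haplotype(base, spec$substitution_rate,
                                         spec$indel_rate, spec$mean_indel_len)
    }
    out <- vapply(haps, paste, character(1L), collapse = "")
    names(out) <- paste0("hap", seq_along(out) - 1L)
    out
  })
}

# Apply i.i.d. substitutions and geometric-length indels to a character
# vector of bases; indels are applied right-to-left to keep positions valid.
mutate_haplotype <- function(base, sub_rate, indel_rate, mean_indel_len) {
  m <- length(base)
  s <- base
  if (sub_rate > 0) {
    idx <- which(stats::runif(m) < sub_rate)
    if (length(idx)) {
      s[idx] <- vapply(s[idx],
                       function(ch) sample(setdiff(.BASES, ch), 1L),
                       character(1L), USE.NAMES = FALSE)
    }
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(m) < indel_rate)
    for (pos in rev(ev)) {
      len <- stats::rgeom(1L, 1 / mean_indel_len) + 1L
      if (stats::runif(1L) < 0.5) {             # insertion after pos
        s <- append(s, sample(.BASES, len, replace = TRUE), after = pos)
      } else {                                  # deletion starting at pos
        drop <- pos:min(pos + len - 1L, length(s))
        if (length(drop) < length(s)) s <- s[-drop]
      }
    }
  }
  if (length(s) == 0L) s <- sample(.BASES, 1L)
  s
}

#' Generate synthetic reads from an indexable text
#'
#' A `1 - decoy_fraction` share of the reads are substrings of single
#' documents (never spanning a separator) with i.i.d. substitution errors at
#' `error_rate`; the remaining reads are uniform-random decoys. The decoy
#' count is `round(decoy_fraction * n_reads)` so the composition is
#' deterministic given the arguments.
#'
#' @param text A `sequence_text` (or plain text string).
#' @param n_reads Number of reads.
#' @param read_len Read length; must not exceed the longest document.
#' @param error_rate Per-base substitution error probability.
#' @param decoy_fraction Fraction of uniform-random decoy reads.
#' @param seed RNG seed.
#' @return A [read_set()].
#' @export
generate_reads <- function(text, n_reads, read_len, error_rate = 0,
                           decoy_fraction = 0, seed = 1L) {
  text <- as_sequence_text(text)
  stopifnot(n_reads >= 1L, read_len >= 1L,
            error_rate >= 0, error_rate <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  b <- text$boundaries
  doc_len <- b$end - b$start
  if (read_len > max(doc_len)) {
    stop("read_len (", read_len, ") exceeds the longest document (",
         max(doc_len), ")")
  }
  eligible <- which(doc_len >= read_len)
  n_decoy <- round(decoy_fraction * n_reads)
  with_seed(seed, {
    seqs <- character(n_reads)
    is_decoy <- c(rep(FALSE, n_reads - n_decoy), rep(TRUE, n_decoy))
    for (i in seq_len(n_reads)) {
      if (is_decoy[i]) {
        seqs[i] <- paste(sample(.BASES, read_len, replace = TRUE),
                         collapse = "")
      } else {
        w <- doc_len[eligible] - read_len + 1L
        doc <- eligible[sample.int(length(eligible), 1L, prob = w)]
        off <- sample.int(doc_len[doc] - read_len + 1L, 1L) - 1L
        s0 <- b$start[doc] + off                     # 0-based text offset
        rd <- chars_of(substr(text$text, s0 + 1L, s0 + read_len))
        if (error_rate > 0) {
          idx <- which(stats::runif(read_len) < error_rate)
          if (length(idx)) {
            rd[idx] <- vapply(rd[idx],
                              function(ch) sample(setdiff(.BASES, ch), 1L),
                              character(1L), USE.NAMES = FALSE)
          }
        }
        seqs[i] <- paste(rd, collapse = "")
      }
    }
    names(seqs) <- sprintf("read_%05d%s", seq_len(n_reads),
                           ifelse(is_decoy, "_decoy", ""))
    read_set(seqs)
  })
}
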