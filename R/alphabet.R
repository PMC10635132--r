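# Character set of the indexable text. The terminator must sort before the
# separator, and both before the four bases: the F-column partition, run
# arithmetic and the "queries never span documents" guarantee all rely on
# this collation order.
.TERM <- "$"
.SEP <- "#"
.BASES <- c("A", "C", "G", "T")
.ALPHABET <- c(.TERM, .SEP, .BASES)

#' Collation rank of index characters
#'
#' The index text is drawn from a six-character alphabet: the terminator
#' (`"$"`), the document separator (`"#"`), and the four DNA bases. This
#' function exposes the collation order used throughout the package:
#' terminator < separator < A < C < G < T.
#'
#' @param chars Character vector of single characters.
#' @return Integer vector of ranks in `1:6`; `NA` for characters outside the
#'   alphabet.
#' @examples
#' collation_rank(c("$", "#", "A", "T"))
#' @export
collation_rank <- function(chars) {
  match(chars, .ALPHABET)
}

# Split a scalar string into single characters.
chars_of <- function(s) {
  strsplit(s, "", fixed = TRUE)[[1L]]
}

# Integer ranks (1..6) of a text string; errors on foreign characters.
ranks_of <- function(s) {
  r <- match(chars_of(s), .ALPHABET)
  if (anyNA(r)) {
    bad <- unique(chars_of(s)[is.na(r)])
    stop("text contains characters outside the index alphabet: ",
         paste(dQuote(bad), collapse = ", "), call. = FALSE)
  }
  r
}

# Reverse complement of an ACGT string.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
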