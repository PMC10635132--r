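#' Read a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a named character vector of
#' uppercase sequences, one element per record, in file order. Record names
#' are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @seealso [write_fasta()], [read_reads()]
#' @export
read_fasta <- function(path) {
  validate_fasta_lines(path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Light pre-validation so empty files and malformed headers produce errors
# that name the offending line (the downstream parser's errors do not).
validate_fasta_lines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA header at line ", first, " of ", path,
         ": expected '>'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Write reads as FASTQ with uniform placeholder qualities.
write_fastq <- function(seqs, path) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("I", nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Read a query read set (FASTA or FASTQ)
#'
#' Reads are kept in file order; FASTQ qualities are ignored. Sequences are
#' uppercased and any character outside `{A,C,G,T,N}` is replaced with `N`
#' (`N` is treated as a guaranteed mismatch by the query layer).
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (sniff the first character), `"fasta"`, or
#'   `"fastq"`.
#' @return A `read_set` object.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L, warn = FALSE)[1], 1L, 1L)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  if (format == "fasta") validate_fasta_lines(path)
  x <- Biostrings::readBStringSet(path, format = format)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(x))
  read_set(seqs, format = format)
}

#' Construct a read set
#'
#' @param seqs Named character vector of read sequences over `{A,C,G,T,N}`.
#' @param format Source format tag (`"fasta"` or `"fastq"`).
#' @return A `read_set`: list with elements `names`, `seqs`, `format`.
#' @export
read_set <- function(seqs, format = "fasta") {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("all reads must be named")
  if (anyDuplicated(nm)) stop("read names must be unique")
  if (any(nchar(seqs) == 0L)) stop("read sequences must be non-empty")
  structure(list(names = unname(nm), seqs = unname(seqs), format = format),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x$seqs), "reads (", x$format, "), lengths ",
      min(nchar(x$seqs)), "-", max(nchar(x$seqs)), "\n", sep = "")
  invisible(x)
}

#' Assemble the indexable text from sequence records
#'
#' Concatenates documents in input order, separated by the separator
#' character `"#"` and terminated by `"$"`. With `include_revcomp = TRUE`
#' the reverse complement of every record is appended as an additional
#' document after the originals (so matches on either strand are found,
#' and the document count doubles exactly). Characters outside ACGT are
#' resolved by `ambiguity_policy`: mapped to `A`, or stripped.
#'
#' All offsets are 0-based and document boundaries are half-open
#' `[start, end)` intervals into the text.
#'
#' @param records Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @param include_revcomp Append reverse-complement documents?
#' @param ambiguity_policy `"map_to_A"` (default) or `"strip"`.
#' @return A `sequence_text`: list with `text` (single string),
#'   `boundaries` (data.frame `name`, `start`, `end`), `includes_revcomp`.
#' @examples
#' build_text(c(a = "ACG"))$text                         # "ACG$"
#' build_text(c(a = "ACG"), include_revcomp = TRUE)$text # "ACG#CGT$"
#' @export
build_text <- function(records, include_revcomp = FALSE,
                       ambiguity_policy = c("map_to_A", "strip")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (length(records) < 1L) stop("at least one record is required")
  nm <- names(records)
  if (is.null(nm) || any(!nzchar(nm))) stop("records must be named")
  seqs <- toupper(unname(unlist(records)))
  seqs <- if (ambiguity_policy == "map_to_A") {
    gsub("[^ACGT]", "A", seqs)
  } else {
    gsub("[^ACGT]", "", seqs)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("record ", dQuote(nm[which(nchar(seqs) == 0L)[1L]]),
         " is empty after applying ambiguity policy ", dQuote(ambiguity_policy))
  }
  if (include_revcomp) {
    seqs <- c(seqs, vapply(seqs, revcomp, character(1L), USE.NAMES = FALSE))
    nm <- c(nm, paste0(nm, "_revcomp"))
  }
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, utils::head(lens + 1L, -1L)))
  structure(list(
    text = paste0(paste(seqs, collapse = .SEP), .TERM),
    boundaries = data.frame(name = nm, start = starts, end = starts + lens,
                            stringsAsFactors = FALSE),
    includes_revcomp = include_revcomp
  ), class = "sequence_text")
}

#' @export
print.sequence_text <- function(x, ...) {
  cat("sequence_text: ", nchar(x$text), " characters, ",
      nrow(x$boundaries), " documents",
      if (x$includes_revcomp) " (reverse complements included)", "\n",
      sep = "")
  invisible(x)
}

# Accept either a sequence_text or a plain alphabet string ("ACAC$") and
# return a sequence_text; used so the oracle and index builders can take
# raw strings in examples and tests.
as_sequence_text <- function(x) {
  if (inherits(x, "sequence_text")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  ch <- chars_of(x)
  ranks_of(x)  # alphabet validation
  if (sum(ch == .TERM) != 1L || ch[length(ch)] != .TERM) {
    stop("text must contain exactly one terminator, at its final position")
  }
  body <- substr(x, 1L, nchar(x) - 1L)
  docs <- if (nchar(body)) strsplit(body, .SEP, fixed = TRUE)[[1L]] else character(0)
  if (length(docs) == 0L) docs <- ""
  names(docs) <- paste0("doc", seq_along(docs))
  lens <- nchar(docs)
  starts <- cumsum(c(0L, utils::head(lens + 1L, -1L)))
  structure(list(
    text = x,
    boundaries = data.frame(name = names(docs), start = starts,
                            end = starts + lens, stringsAsFactors = FALSE),
    includes_revcomp = FALSE
  ), class = "sequence_text")
}

# Plain text string from either representation.
text_string <- function(x) {
  if (inherits(x, "sequence_text")) x$text else as_sequence_text(x)$text
}
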