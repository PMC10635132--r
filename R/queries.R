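is_present <- function(table, ch) {
  !is.na(match(ch, .BASES)) && table$counts[[ch]] > 0L
}

absent_char_error <- function(ch) {
  stop(structure(class = c("movebwt_absent_char", "error", "condition"),
                 list(message = paste0("character ", dQuote(ch),
                                       " does not occur in the BWT"),
                      call = NULL)))
}

#' Reposition a mismatching pointer to a run with the wanted character
#'
#' When the query character `a` differs from the character of the run under
#' the pointer, the pointer must move to the nearest BWT offset holding `a`.
#' The run's threshold for `a` decides the direction: offsets below the
#' threshold go up to the last offset of the nearest `a`-run above; offsets
#' at or above it go down to the first offset of the nearest `a`-run below.
#' The default strategy finds that run by scanning run to run (scan steps
#' are tallied in the instrumentation counters); in constant mode the stored
#' `up_run`/`dn_run` pointer reaches it in one step. Both strategies return
#' identical targets.
#'
#' @param table A `move_table`.
#' @param ptr A [bipointer()] whose run character differs from `a`.
#' @param a Query base.
#' @param strategy `"auto"` (pointer when available, otherwise scan),
#'   `"scan"`, or `"pointer"`.
#' @return The repositioned [bipointer()].
#' @export
reposition <- function(table, ptr, a,
                       strategy = c("auto", "scan", "pointer")) {
  strategy <- match.arg(strategy)
  i <- ptr$run
  if (identical(table$chars[i], a)) {
    stop("pointer already sits in a run with character ", dQuote(a))
  }
  if (!is_present(table, a)) absent_char_error(a)
  go_up <- ptr$off < table$thresholds[i, a]
  if (strategy == "auto") {
    strategy <- if (!is.null(table$up_run)) "pointer" else "scan"
  }
  if (strategy == "pointer") {
    if (is.null(table$up_run)) {
      stop("table has no repositioning pointers (default mode); ",
           "use strategy = \"scan\"")
    }
    j <- if (go_up) table$up_run[i, a] else table$dn_run[i, a]
    if (is.na(j)) {
      stop("internal error: threshold points toward a missing run")
    }
  } else {
    chars <- table$chars
    steps <- 0L
    j <- i
    if (go_up) {
      repeat {
        j <- j - 1L
        steps <- steps + 1L
        if (j < 1L) stop("internal error: no matching run above")
        if (chars[j] == a) break
      }
    } else {
      r <- length(chars)
      repeat {
        j <- j + 1L
        steps <- steps + 1L
        if (j > r) stop("internal error: no matching run below")
        if (chars[j] == a) break
      }
    }
    table$counters$reposition_scans <- table$counters$reposition_scans + steps
  }
  bipointer(j, if (go_up) table$p[j] + table$len[j] - 1L else table$p[j])
}

# --- pseudo matching lengths ----------------------------------------------

# One-read PML state machine. States are environments so the round-robin
# batch driver can advance them in place.
new_pml_state <- function(name, seq) {
  if (!nzchar(seq)) stop("empty read: ", name)
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$chars <- chars_of(toupper(seq))
  e$m <- length(e$chars)
  e$k <- e$m                      # read position under examination (1-based)
  e$lens <- integer(e$m)
  e$run <- 1L                     # fixed start: BWT offset 0
  e$off <- 0L
  e$ell <- 0L
  e$done <- FALSE
  e
}

# Advance one read position: match (case 1) extends the current length and
# LF-steps; mismatch (case 2) repositions via the threshold, resets the
# length to 0, then LF-steps. A character absent from the index (including
# N) resets the length and holds the position without an LF step. The
# prefetch hook receives the estimated destination row before each LF.
pml_step <- function(table, st, prefetch = NULL) {
  ch <- st$chars[st$k]
  if (!is_present(table, ch)) {
    st$ell <- 0L
    st$lens[st$k] <- 0L
  } else {
    if (table$chars[st$run] == ch) {
      st$ell <- st$ell + 1L
    } else {
      np <- reposition(table, bipointer(st$run, st$off), ch)
      st$run <- np$run
      st$off <- np$off
      st$ell <- 0L
    }
    st$lens[st$k] <- st$ell
    if (!is.null(prefetch)) prefetch(table$xi[st$run])
    np <- move_lf(table, bipointer(st$run, st$off))
    st$run <- np$run
    st$off <- np$off
  }
  st$k <- st$k - 1L
  if (st$k == 0L) st$done <- TRUE
  invisible(st)
}

pml_result <- function(st) {
  structure(list(name = st$name, lengths = st$lens), class = "pml_vector")
}

#' Compute pseudo matching lengths for one read
#'
#' Processes the read right to left from a fixed start state (BWT offset 0).
#' At each position, if the BWT character under the pointer equals the read
#' character the current match length grows by one and an LF-mapping step is
#' taken (case 1); otherwise the pointer repositions to the nearest run with
#' the read character as directed by the thresholds, the length resets to 0,
#' and the LF step follows (case 2). `N`, or any base absent from the index,
#' resets the length and holds the pointer in place. PMLs lower-bound the
#' matching statistics: every recorded length `v > 0` certifies that the
#' length-`v` read substring at that position occurs in the text.
#'
#' @param table A `move_table`.
#' @param read Read sequence over `{A,C,G,T,N}`.
#' @param name Read name carried into the result.
#' @return A `pml_vector`: list(`name`, `lengths`), lengths in left-to-right
#'   read order.
#' @export
compute_pml <- function(table, read, name = "read") {
  st <- new_pml_state(name, read)
  while (!st$done) pml_step(table, st)
  pml_result(st)
}

#' @export
print.pml_vector <- function(x, ...) {
  cat(">", x$name, "\n", paste(x$lengths, collapse = " "), "\n", sep = "")
  invisible(x)
}

# --- backward search -------------------------------------------------------

#' Initial backward-search range for one character
#'
#' The BWM rows prefixed by `a` form the contiguous F-column block
#' `[C[a], C[a] + count(a))`; the range's top and bottom pointers delimit it
#' inclusively.
#'
#' @param table A `move_table`.
#' @param a A base.
#' @return A `search_range`: list(`top`, `bottom`, `empty`).
#' @export
initial_range <- function(table, a) {
  cnt <- if (is.na(match(a, .ALPHABET))) 0L else table$counts[[a]]
  if (cnt == 0L) {
    return(structure(list(top = NULL, bottom = NULL, empty = TRUE),
                     class = "search_range"))
  }
  top <- table$C[[a]]
  bottom <- top + cnt - 1L
  structure(list(top = bipointer(run_of_offset(table, top), top),
                 bottom = bipointer(run_of_offset(table, bottom), bottom),
                 empty = FALSE),
            class = "search_range")
}

# Advance a search range by one pattern character; returns the range or
# NULL when it empties. Top moves down to the first a-offset at or below
# it (j_dn), bottom up to the last a-offset at or above it (j_up), then
# both take an LF step.
range_step <- function(table, rng, a, prefetch = NULL) {
  chars <- table$chars
  r <- length(chars)
  top <- rng$top
  bottom <- rng$bottom
  if (chars[top$run] != a) {
    if (!is.null(table$dn_run)) {                 # constant mode: one step
      i <- table$dn_run[top$run, a]
      if (is.na(i)) return(NULL)
    } else {
      i <- top$run
      steps <- 0L
      repeat {
        i <- i + 1L
        steps <- steps + 1L
        if (i > r) return(NULL)
        if (chars[i] == a) break
      }
      table$counters$reposition_scans <-
        table$counters$reposition_scans + steps
    }
    top <- bipointer(i, table$p[i])
  }
  if (chars[bottom$run] != a) {
    if (!is.null(table$up_run)) {
      i <- table$up_run[bottom$run, a]
      if (is.na(i)) return(NULL)
    } else {
      i <- bottom$run
      steps <- 0L
      repeat {
        i <- i - 1L
        steps <- steps + 1L
        if (i < 1L) return(NULL)
        if (chars[i] == a) break
      }
      table$counters$reposition_scans <-
        table$counters$reposition_scans + steps
    }
    bottom <- bipointer(i, table$p[i] + table$len[i] - 1L)
  }
  if (top$off > bottom$off) return(NULL)
  if (!is.null(prefetch)) {
    prefetch(table$xi[top$run])
    prefetch(table$xi[bottom$run])
  }
  structure(list(top = move_lf(table, top), bottom = move_lf(table, bottom),
                 empty = FALSE),
            class = "search_range")
}

#' Count pattern occurrences by backward search
#'
#' Starts from the F-column block of the pattern's last character and, for
#' each earlier character, advances the range's top and bottom pointers with
#' the repositioning rule (top takes the downward target, bottom the upward
#' one) followed by an LF-mapping step. When the pointers cross or a target
#' is missing the pattern does not occur. The final range width is the
#' number of occurrence positions in the text, equal to [count_naive()].
#'
#' @param table A `move_table`.
#' @param pattern Non-empty pattern over `{A,C,G,T}`.
#' @return Integer occurrence count.
#' @export
backward_search_count <- function(table, pattern) {
  chs <- chars_of(toupper(pattern))
  if (length(chs) == 0L) stop("pattern must be non-empty")
  if (any(is.na(match(chs, .BASES)))) {
    stop("pattern must contain only A, C, G, T")
  }
  m <- length(chs)
  rng <- initial_range(table, chs[m])
  if (rng$empty) return(0L)
  if (m >= 2L) {
    for (k in (m - 1L):1L) {
      rng <- range_step(table, rng, chs[k])
      if (is.null(rng)) return(0L)
    }
  }
  rng$bottom$off - rng$top$off + 1L
}

# Count-query state machine for the batch driver.
new_count_state <- function(name, seq) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$chars <- chars_of(toupper(seq))
  e$m <- length(e$chars)
  e$k <- e$m
  e$rng <- NULL
  e$failed <- FALSE
  e$done <- FALSE
  if (e$m == 0L) stop("empty read: ", name)
  if (any(is.na(match(e$chars, .BASES)))) {
    stop("count query read ", name, " contains non-base characters")
  }
  e
}

count_step <- function(table, st, prefetch = NULL) {
  if (is.null(st$rng)) {
    st$rng <- initial_range(table, st$chars[st$m])
    if (st$rng$empty) st$failed <- TRUE
  } else {
    st$rng <- range_step(table, st$rng, st$chars[st$k], prefetch)
    if (is.null(st$rng)) st$failed <- TRUE
  }
  st$k <- st$k - 1L
  if (st$failed || st$k == 0L) st$done <- TRUE
  invisible(st)
}

count_result <- function(st) {
  if (st$failed) 0L else st$rng$bottom$off - st$rng$top$off + 1L
}

# --- interleaved batch driver ---------------------------------------------

#' Process reads in an interleaved batch
#'
#' Runs the per-read query state machines round-robin: up to `batch_size`
#' reads are active at once and each is advanced by one inner-loop iteration
#' per turn, with `prefetch` invoked on the estimated LF destination row
#' before it is accessed (a no-op by default: in this implementation the
#' hook marks where a hardware prefetch would be issued to hide the cache
#' miss of the LF jump). When a read finishes, the next read is loaded into
#' its slot. Results are identical to processing reads one at a time, in
#' input order, for every batch size.
#'
#' @param table A `move_table`.
#' @param reads A [read_set()].
#' @param query `"pml"` or `"count"`.
#' @param batch_size Number of concurrently active reads (default 16).
#' @param prefetch Optional function of one argument (the destination row).
#' @return For `"pml"`: list of `pml_vector`s. For `"count"`: data.frame
#'   with columns `read` and `count`.
#' @export
process_batch <- function(table, reads, query = c("pml", "count"),
                          batch_size = 16L, prefetch = NULL) {
  query <- match.arg(query)
  stopifnot(inherits(reads, "read_set"), batch_size >= 1L)
  new_state <- if (query == "pml") new_pml_state else new_count_state
  step <- if (query == "pml") pml_step else count_step
  finish <- if (query == "pml") pml_result else count_result
  n_reads <- length(reads$seqs)
  results <- vector("list", n_reads)
  slots <- vector("list", batch_size)
  slot_read <- integer(batch_size)           # which read occupies each slot
  next_read <- 1L
  active <- 0L
  repeat {
    progressed <- FALSE
    for (s in seq_len(batch_size)) {
      if (is.null(slots[[s]])) {
        if (next_read <= n_reads) {
          slots[[s]] <- new_state(reads$names[next_read],
                                  reads$seqs[next_read])
          slot_read[s] <- next_read
          next_read <- next_read + 1L
          active <- active + 1L
        } else {
          next
        }
      }
      st <- slots[[s]]
      step(table, st, prefetch)
      progressed <- TRUE
      if (st$done) {
        results[[slot_read[s]]] <- finish(st)
        slots[s] <- list(NULL)
        active <- active - 1L
      }
    }
    if (!progressed && next_read > n_reads && active == 0L) break
  }
  if (query == "count") {
    data.frame(read = reads$names, count = unlist(results),
               stringsAsFactors = FALSE)
  } else {
    results
  }
}

#' Write PML results
#'
#' One record per read: a `">name"` line followed by the space-separated
#' lengths in left-to-right read order.
#'
#' @param results List of `pml_vector`s (from [process_batch()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pml <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (pv in results) {
    writeLines(c(paste0(">", pv$name),
                 paste(pv$lengths, collapse = " ")), con)
  }
  invisible(path)
}

#' Write count results as TSV
#'
#' @param results data.frame from [process_batch()] with `query = "count"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
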