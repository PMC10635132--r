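---
title: "The move-structure index: model, parameters, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The move-structure index: model, parameters, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movebwt)
```

## The model

`movebwt` indexes a terminated text `T[0..n)` built from a collection of
DNA documents joined by a dedicated separator and ended by a terminator,
over the six-character alphabet `$ < # < A < C < G < T`. The separator
sorts between the terminator and the bases; because query patterns are
pure ACGT, a match can never span a document boundary, and any query
character compared against a separator or terminator position falls into
the mismatch path by construction.

The Burrows–Wheeler transform of `T` is taken as the last column of the
matrix of sorted rotations; with a unique smallest terminator this equals
sorting suffixes, which is how the package computes it (prefix-doubling
suffix array, `O(n log^2 n)`). The BWT decomposes into `r` maximal
single-character runs. The move table stores, per run: character `c`,
length `ℓ`, head offset `p`, the LF-mapping of the head `π = LF(p)`, and
`ξ`, the row containing `π`. One LF step at offset `j` in row `i` is

```
LF(j) = π_i + (j − p_i),
```

followed by a forward scan ("fast-forward") from row `ξ_i` to the row
containing the result. No rank/select structure is consulted anywhere in
the query paths; everything is row arithmetic plus sequential scanning,
which is the point of the structure: on large instances the one jump to
row `ξ_i` is the single unpredictable memory access per step.

### Constant mode: run splitting

In default mode the fast-forward length is unbounded in principle. With
splitting parameter `d ≥ 2`, runs are subdivided until no run's LF-image
interval `[LF(p), LF(p) + ℓ)` contains `2d` or more run heads. At that
fixpoint every fast-forward takes fewer than `2d` steps, because a scan
from the row containing `LF(p)` to the row containing `LF(j)` only crosses
heads lying inside the image interval. The implementation splits every
currently offending run once per pass (at the preimage of the d-th covered
head, decisions taken against the pre-pass head set) and repeats to
fixpoint; this reaches the same fixpoint condition as splitting one run at
a time and makes the operation idempotent, which the tests assert
directly. The package makes no claim about the *number* of rows splitting
adds; the guarantee it tests — exhaustively, over every BWT offset — is
the `< 2d` bound itself.

### Thresholds and repositioning

When a query character `a` differs from the run character under the
pointer, the pointer repositions to the nearest BWT offset holding `a`,
either the last `a` above or the first `a` below. The correct direction is
the candidate whose row shares the longer common prefix with the current
row's suffix. Within a run this choice flips at most once, at a
*threshold*: with `u` the last `a`-occurrence above the run and `v` the
first below, the threshold is the position of the minimum of the LCP array
on `(u, v]`, clamped into the run's interval. Rows before it go up, rows
from it on go down. Where the paper-level construction leaves ties
arbitrary, this implementation fixes **leftmost minimum** so that two
builds of the same text are identical; the brute-force referee in the
tests treats equal-LCP ties as satisfied by either direction.

Boundary conventions: no `a` above forces `t = p` (always down); no `a`
below forces `t = p + ℓ` (always up); a base absent from the whole BWT has
no threshold, and queries on it are signalled as a distinct condition.

In default mode the repositioning run is found by scanning run to run (the
scan length is instrumented); in constant mode each row stores, for each
of the three other bases, the nearest matching run above and below — six
pointers — so repositioning is one lookup. Both strategies provably return
the same target, and the tests check this for every (run, offset,
character) combination on their fixtures.

### Pseudo matching lengths

PMLs are computed in one right-to-left pass. The state is a table pointer
and a current length `ℓ`. If the BWT character under the pointer equals
the read character, `ℓ` grows by one (case 1); otherwise the pointer
repositions as above and `ℓ` resets to 0 (case 2); the value is recorded
and an LF step follows. PMLs lower-bound matching statistics — every
recorded `v > 0` certifies that the length-`v` substring at that position
occurs in the text — and satisfy the Lipschitz property
`PML[k] ≤ PML[k+1] + 1`. Both are verified against the naive
matching-statistics oracle for every generated read.

Two details are deliberately fixed where a specification would allow
freedom, so that cross-implementation comparisons are reproducible:

* **Start state.** The pass starts at BWT offset 0 (row 1). Any start
  offset yields valid PMLs; fixing one makes default- and constant-mode
  outputs bit-identical, which the tests assert for every read.
* **Absent characters.** A read character that does not occur in the BWT
  at all — including `N`, which is treated as a guaranteed mismatch —
  records 0, holds the pointer in place, and skips the LF step. This is
  the minimal-state-change rule; rewriting `N` would distort read
  coordinates.

### Count queries

Backward search maintains an inclusive (top, bottom) range of BWM rows
prefixed by the growing query suffix. The initial range is the F-column
block of the last query character, read off the cumulative character
counts. Each earlier character advances the pointers with the
repositioning machinery — the top pointer always takes the downward
target, the bottom pointer the upward one — followed by an LF step on
both. A missing target or crossed pointers mean zero occurrences;
otherwise the final width `bottom − top + 1` is the count, which the tests
hold equal to naive counting for every substring up to length 8 of a
~500-character pangenome plus large samples of random (mostly absent)
patterns.

### Interleaved batch processing

`process_batch()` advances up to `batch_size` (default 16) per-read state
machines round-robin, one inner-loop iteration each, loading the next read
whenever one finishes, and calls a prefetch hook with the estimated LF
destination row before that row is accessed. In compiled implementations
this loop shape hides the latency of the per-step cache miss behind the
other reads' work; here the hook is a no-op marker and the value of the
driver is its contract, which the tests pin down: results are bit-identical
to sequential processing for every batch size.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `mode` | `default` | `constant` adds splitting + pointers: bounded worst case, more rows. |
| `d` | 5 | fast-forward bound `2d`. 5 keeps splitting mild while exercising the machinery; configurable down to 2 for the tightest bound. |
| `batch_size` | 16 | concurrently active reads in the batch driver. |
| `include_revcomp` | off | append reverse-complement documents (doubles document count exactly). |
| `ambiguity_policy` | `map_to_A` | deterministic and length-preserving; `strip` available, erroring on records it would empty. |

All BWT offsets are 0-based with half-open intervals (this removes
off-by-one ambiguity from the run arithmetic); run/row indices in the R
API are 1-based, following R convention.

## What the synthetic generator emulates

`generate_pangenome()` draws one uniform-random base haplotype and derives
the others by i.i.d. substitutions (default rate 0.001, the divergence at
which the scaling behaviour of interest appears) and optional
geometric-length indels (`indel_rate` default 0; mean length 5 when
enabled). `generate_reads()` samples substrings of single documents —
never spanning separators — with i.i.d. substitution errors, plus a
deterministic share of uniform-random decoys. Both are fully reproducible
from their seeds.

This emulates the property that makes run-length compression worthwhile —
many near-identical documents, so `r` grows far more slowly than `n` — and
gives reads with known ground truth. It does **not** emulate biological
repeat structure, indel-rich nanopore error profiles, structural variation
between haplotypes, or base-quality information. Passing tests therefore
demonstrate algorithmic correctness of the index and query machinery, not
classification accuracy on real sequencing data.

## Verification scales and numerical choices

The test suite verifies against brute force at sizes where exhaustive
checking is feasible and fast: LF equivalence and text reconstruction on
100 random 1,000-base texts and ten ~50,000-base synthetic pangenomes (10
haplotypes × 5,000 bases), the `< 2d` bound for d ∈ {2, 3, 5} over every
offset of every fixture, threshold decisions on texts up to 300 bases,
repositioning-strategy agreement up to 500 bases, and PML/count properties
on 1,000 simulated 150-base reads. `scripts/acceptance.R` re-runs the same
measurements at moderately reduced sizes and reports the resulting
agreement percentages and maxima as JSON.

Degenerate inputs are first-class: single-character texts, single-run
BWTs (all pointers absent), all-`A` and strictly alternating texts, reads
of characters absent from the index, and empty ranges in backward search
all have defined behaviour covered by tests.

Serialization writes a versioned container; reading a truncated file or a
foreign/newer format errors explicitly rather than degrading. Instrument
counters (LF calls, fast-forward steps, repositioning scans) are kept out
of the serialized payload so that rebuilding an index from identical
inputs produces a byte-identical file.

## Known limitations

* Index construction is by direct suffix sorting in memory. This is the
  right tool at the scales above; indexing gigabase collections would need
  prefix-free-parsing construction and an on-disk layout, both out of
  scope.
* Both `p` and `π` are stored explicitly per row. Collapsing them into a
  relative offset (as done in space-optimized implementations) would shrink
  rows but lose the global offsets that count queries and the verification
  suite rely on; clarity won.
* The prefetch hook is a structural marker, not a hardware prefetch; R
  offers no such instruction, so the latency-hiding benefit itself is not
  measurable here, only the loop contract.
* PMLs approximate matching statistics from below; they reset on every
  case-2 event and cannot be used to recover MEMs exactly. The two-pass
  matching-statistics algorithm and any classification decision layer on
  top of PMLs are intentionally not implemented.
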