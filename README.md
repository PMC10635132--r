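# movebwt

`movebwt` builds and queries **move-structure** full-text indexes over the
run-length Burrows–Wheeler transform (RLBWT) of pangenome sequence
collections, entirely in R, together with the brute-force oracles needed to
verify every query path exhaustively.

## The problem and the index

Full-text indexes based on the BWT answer arbitrary-length matching queries
against a reference collection. For a pangenome — many near-identical
genomes indexed jointly — the BWT of the concatenated text `T[0..n)` is
highly repetitive: it decomposes into `r ≪ n` maximal single-character
runs. Classic run-length compressed indexes (the r-index family) reach
O(r) space but pay for each LF-mapping step with rank/select queries over
several bitvector and wavelet-tree components, which scatters memory
accesses and makes per-step latency large and unpredictable.

The move structure replaces all of that with a single table `M` with one
row per BWT run:

| field | meaning |
|-------|---------|
| `c`   | run character |
| `ℓ`   | run length |
| `p`   | BWT offset of the run head |
| `π`   | `LF(p)`, the LF-mapping of the run head |
| `ξ`   | index of the run containing `π` |

LF-mapping an offset `j` inside run `i` is then pure row arithmetic,

```
LF(j) = M[i].π + (j − M[i].p)
```

followed by a short forward scan ("fast-forward") from row `ξ` to the row
containing `LF(j)`. In **default** mode the scan length is unbounded in
principle (but logged); in **constant** mode runs are first split with a
parameter `d ≥ 2` so that no LF-image interval covers 2d run heads, which
guarantees *fewer than `2d` fast-forwards for every possible query* — the
package verifies this bound exhaustively over all `n` offsets.

On top of LF-mapping the package implements:

* **Pseudo matching lengths (PML)** — a one-pass, right-to-left
  lower-approximation of matching statistics used for read classification.
  A matching BWT character extends the current match (case 1); a mismatch
  repositions to the nearest run holding the query character — direction
  chosen by **thresholds** precomputed from LCP-array minima — and resets
  the length to 0 (case 2). Constant mode replaces the repositioning scan
  with six per-row pointers (up/down × three non-run bases), making the
  whole inner loop constant-bounded.
* **Count queries** — backward search whose top/bottom range pointers
  advance by the same repositioning machinery (top takes the downward
  target, bottom the upward one); the final range width is the occurrence
  count.
* **Interleaved batch querying** — a round-robin driver that keeps up to
  `batch_size` reads (default 16) in flight and invokes a prefetch hook
  before each LF destination access, mirroring how latency hiding is
  structured on real hardware; results are bit-identical to sequential
  processing.
* **Ground-truth oracles** — suffix array, BWT, LCP, direct LF, naive
  counting and naive matching statistics — plus a synthetic pangenome and
  read generator, so correctness never depends on external data.

## Worked example

```r
library(movebwt)

haps  <- generate_pangenome(pangenome_spec(base_length = 2000,
                                           n_haplotypes = 6,
                                           substitution_rate = 0.001,
                                           seed = 42))
text   <- build_text(haps)          # documents joined by '#', ending in '$'
oracle <- build_oracle(text)        # suffix array, BWT, LCP, LF
index  <- build_move_table(oracle, mode = "constant", d = 5)
move_stats(index)
#> n:          12006
#> r_original: 1593
#> rows:       1593
#> n/r:        7.537
#> row growth: 1
#> mode:       constant (d = 5)
```

Six haplotypes at 0.1% divergence compress to 7.5 BWT positions per run;
here no run needed splitting (`row growth: 1`), so the `2d = 10` bound
already held. Querying a read with a couple of simulated errors:

```r
reads <- generate_reads(text, n_reads = 3, read_len = 60,
                        error_rate = 0.01, decoy_fraction = 1/3, seed = 9)
compute_pml(index, reads$seqs[1], reads$names[1])
#> >read_00001
#> 4 3 2 1 0 0 0 0 0 0 16 15 14 13 12 11 10 9 8 7 6 5 4 3 2 1 0 0 1 0 2 1
#> 0 16 15 14 13 12 11 10 9 8 7 6 5 4 3 2 1 0 4 3 2 1 0 0 0 0 0 0
```

Each entry is the length of a verified match starting at that read
position; the long descending ramps (16, 15, …) are stretches of the read
found intact in the pangenome, and resets to 0 mark mismatch-triggered
repositioning — exactly the profile used to separate genuine reads from
decoys:

```r
compute_pml(index, reads$seqs[3], reads$names[3])   # a random decoy
#> >read_00003_decoy
#> 0 0 0 0 1 0 0 1 0 0 0 2 1 0 1 0 0 0 0 1 0 1 0 0 0 2 1 0 0 0 0 0 0 0 3
#> 2 1 0 1 0 0 0 0 1 0 0 0 0 0 0 1 0 0 0 0 0 0 1 0 0

backward_search_count(index, substr(reads$seqs[1], 1, 20))
#> [1] 0        # the first 20 bases contain a simulated error
count_naive(text, substr(reads$seqs[1], 1, 20))
#> [1] 0        # the naive oracle agrees
```

The same operations are available from a shell through the launcher in
`inst/cli/` (`generate`, `build`, `query --pml|--count`, `stats --json`).

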