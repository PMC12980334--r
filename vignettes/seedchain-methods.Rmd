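---
title: "seedchain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedchain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`seedchain` is a pairwise whole-genome aligner for assembled genomes
(contigs or scaffolds) built on the seed-chain-extend paradigm of the
minimap2 family. Its design centre of gravity is not raw speed but a
*determinism contract*: every parallel code path — partitioned chaining,
chunked stable sorting, batched scheduling — is required to be
output-identical to its sequential reference, for every worker count and
batch size. The package therefore pairs each accelerated component with an
independently written reference implementation and tests exact agreement.

The intended scale is desk scale: megabase genomes, as produced by the
package's own synthetic generator. The pipeline is the real algorithm,
not a toy, but no attempt is made to compete with C aligners on
wall-clock time for gigabase inputs.

## The pipeline

1. **Seeding.** The reference is indexed by *minimizers*: for every window
   of `w` consecutive k-mer start positions, the k-mer(s) with minimal
   canonical hash are sampled. Canonical means the forward and
   reverse-complement 2-bit encodings are both hashed with a fixed integer
   mixing (murmur3-finalizer style) function and the smaller value wins;
   the hash is masked to 52 bits so keys are exact doubles in R. k-mers
   containing `N` are skipped; a window with no valid k-mer emits nothing;
   ties within a window emit all tied positions; palindromic k-mers are
   assigned strand 0. Keys occurring more than `max_occ` times in the
   reference are dropped outright — the standard repeat guard.
   Query minimizers are looked up in the index; each hit yields an
   *anchor* `(qpos, seqid, tpos, strand, span = k)`, with strand the XOR
   of the two minimizer orientations. Anchors are sorted stably by
   `(seqid, strand, tpos, qpos)`.

2. **Chaining.** Anchors from different reference sequences or opposite
   strands can never be joined, so the sorted anchor array is partitioned
   into at most `2 × n_seqs` contiguous runs, and each partition is
   chained independently — this is what makes chaining of a *single* long
   query sequence parallel without locks and without changing output.
   Within a partition the score of the best chain ending at anchor *i* is

   $$f(i) = \max\Big(s_i,\; \max_{j} f(j) + \min(\Delta q, \Delta t, s_i)
     - c(j,i)\Big),$$

   with gap cost $c = \alpha\, s_i\, g + \tfrac12 \log_2(g+1)$,
   $g = |\Delta q - \Delta t|$, and a pair infeasible when either advance
   is non-positive, exceeds `max_gap`, or the skew $g$ exceeds
   `max_skew_bandwidth`. The predecessor search examines the last
   `lookback` anchors. Chains are read out best-first with anchor reuse
   forbidden, and chains below `min_chain_score` or `min_anchors` are
   dropped (their anchors stay consumed, mirroring the greedy readout of
   minimap2). Per-partition chain lists are merged and ordered globally
   by descending score.

3. **Primary/secondary marking.** Two chains compete when their *query*
   intervals overlap; the overlap fraction is the overlap length divided
   by the shorter interval. Walking chains in descending score order, a
   chain is secondary if some already-accepted primary overlaps it by
   strictly more than `mask_level` (default 0.5), else it becomes primary.
   The package ships both the quadratic scan of the primary set and the
   accelerated version that keeps primary intervals in an interval tree
   (an augmented treap) — the two are required to agree exactly on every
   input, and the quadratic version is the oracle in tests.

4. **Extension.** Each chain becomes one PAF record. The CIGAR
   concatenates k-long `M` runs for anchors with affine-gap global
   alignments (Gotoh three-state DP, banded) of the inter-anchor
   sequences. Overlapping consecutive anchors have the later `M` run
   shortened by the larger of the query/target overlaps. There is no
   extension beyond the terminal anchors: the record spans exactly the
   chain's extents, which keeps the stage deterministic and
   oracle-testable at the cost of unaligned flanks.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `k` | 15 | bases | k-mer length; anchors are exact k-mer matches |
| `w` | 10 | k-mer starts | minimizer window; density of seeds ≈ 2/(w+1) |
| `max_occ` | 100 | occurrences | repeat cutoff for index keys |
| `max_gap` | 5000 | bases | max query/target advance between chained anchors |
| `max_skew_bandwidth` | 500 | bases | max \|Δq − Δt\| between chained anchors |
| `min_chain_score` | 40 | score | report threshold |
| `min_anchors` | 3 | anchors | report threshold |
| `gap_open_scale` | 0.01 | score/base² | linear coefficient of the chaining gap cost |
| `lookback` | 50 | anchors | DP predecessor window |
| `match/mismatch` | 2/4 | score | base-level scoring |
| `gap_open/gap_extend` | 4/2 | score | affine gap, cost `open + ext·len` |
| `band` | 500 | cells | half-width of the base-level DP band |
| `mask_level` | 0.5 | fraction | secondary-marking overlap threshold (strict) |
| `batch_bases` | 5e8 | bases | query bases per batch (memory only) |

Defaults sit in the range used by assembly-to-reference presets of the
minimap2 family; all are exposed through `run_config()` and the CLI. The
chaining recurrence constants are this package's own concrete choice of a
minimap2-family cost: the contracts that matter (optimality against
brute force, partition equivalence) are independent of the constants.

## Determinism and numerical choices

* **Tie-breaks are part of the contract.** Predecessor ties in the DP go
  to the largest (closest) index; a tie between extending and starting a
  new chain keeps the single-anchor base. Chain readout breaks score ties
  by ascending anchor index; the merged chain list uses descending score,
  then ascending `(qs, seqid, ts, strand)`. Alignment traceback resolves
  ties diagonal > deletion > insertion. All of these exist so that the
  parallel and sequential paths produce *bit-identical* output.
* Because the traceback tie order prefers deletion over insertion in
  both call directions, swapping the two sequences does not mirror the
  CIGAR run-for-run; it yields another, equally optimal alignment. The
  tested invariants are score symmetry and replay-optimality of the
  mirrored CIGAR.
* The bounded `lookback` window counts *positions*, so the partitioned DP
  and an unpartitioned sequential DP see different candidate windows when
  the window spans a partition boundary. The two are exactly equivalent
  whenever `lookback` is at least the partition size, and the equivalence
  suites run in that regime. At the default `lookback = 50` the
  partitioned result is still deterministic, merely not a literal
  reimplementation of a global scan.
* Chain scores are doubles computed with an identical operation order in
  the compiled kernel and the R reference, so cross-implementation
  comparisons use a standard numerical tolerance while
  worker-count comparisons demand identity.
* `mapq` is a package-defined rule (PAF only constrains the range): 60
  for an uncontested primary, otherwise `round(60·(1 − s₂/s₁))` with
  `s₂` the best score among secondaries overlapping that primary above
  `mask_level`; secondaries get 0.
* Degenerate inputs: queries shorter than `k` (or all `N`) produce zero
  records and exit cleanly; an empty FASTA is a malformed-input error
  with a line number; inter-anchor gap pairs whose length difference
  exceeds `band` are emitted as a pure deletion block followed by a pure
  insertion block rather than aligned.
* Parallelism is implemented as forked worker processes over pure
  functions with results reassembled in task order (longest-first static
  assignment), which makes worker-count invariance a structural property
  rather than a synchronization discipline.

## The synthetic generator

`random_genome()` draws i.i.d. uniform A/C/G/T sequences;
`mutate_genome()` applies structural events first — inversion
(reverse-complement in place), duplication (copy inserted at a reference
coordinate), translocation (cut-and-paste across sequences) — on a
segment representation, then draws SNPs and short indels uniformly
outside all event footprints. Event intervals must be pairwise disjoint
and insertion points may not fall inside another event: this keeps every
truth coordinate exact in both reference and final query systems without
interval arithmetic over cascading edits. The generator is byte-for-byte
reproducible from its seed, and a test replays the truth records over the
reference to reconstruct the query exactly.

What it does *not* emulate: GC skew and composition bias, tandem and
dispersed repeat families (repeats can be injected explicitly as
duplications), sequencing or assembly error profiles, and realistic
divergence processes. Passing the recovery suites therefore demonstrates
correctness of the machinery on repeat-poor, low-divergence inputs — not
sensitivity on hard real genomes. Uniform random sequence is close to
adversarially repeat-free, which is the easy case for seeding; the
occurrence cutoff and secondary marking are exercised through explicit
duplications instead.

Two orientation notes on the recovery suites. A duplication inserted into
the *query* genome yields two query intervals mapping to one reference
interval, which the query-interval marking rules leave both primary; to
reproduce the classic two-chains-one-query-interval configuration the
end-to-end test aligns the original genome (as query) against the
mutated genome (as reference), so the two reference copies compete.
A planted inversion is typically *bridged* by the flanking co-linear
chain (the skew of the bridge is zero), so the reverse-strand chain over
the inverted segment is reported as a secondary record; the recovery
check accordingly looks for a `-` record covering ≥ 90% of the truth
interval without requiring it to be primary.

## Verification protocol and problem sizes

The test suite runs the following (sizes chosen to exercise the
asymptotics while keeping the default run in minutes):

* marking: interval-tree vs quadratic flags on 1,000 random chain sets
  (up to 500 chains) plus nested / exact-threshold / all-equal-score
  adversarial stacks;
* chaining: worker counts {1, 2, 4, 8} and an independent unpartitioned
  R reference on 200 random anchor sets over 1–8 reference sequences;
  brute-force enumeration of all feasible anchor subsets on 500 instances
  of up to 12 anchors;
* interval tree: linear-scan agreement on 1,000 random trees (up to
  1,000 intervals), plus an empirical growth check of the accelerated
  marking on mutually disjoint intervals, the worst case for the
  quadratic scan;
* sorting: equality with a sequential stable radix sort for worker
  counts {1, 2, 4, 8} on randomized keyed payloads;
* alignment kernel: full-DP reference on 500 random pairs up to 12 bp
  (itself validated by exhaustive path enumeration on up to 5 bp), CIGAR
  consistency on every emitted record;
* end to end: byte-identical PAF across workers {1, 2, 4, 8} and batch
  sizes on a two-sequence 1 Mb simulated pair; identity self-alignment;
  inversion and duplication recovery against generator truth.

`scripts/acceptance.R` re-derives the same quantities from scratch at
slightly reduced sizes and writes them as JSON.

## Limitations

* No SAM output, no FASTQ/read mapping modes, no homopolymer-compressed
  seeds, no seed-frequency fraction filter.
* The chaining kernel uses a bounded lookback window, not the range-tree
  RMQ inner loop of newer minimap2 releases; the partitioning layer is
  agnostic to that choice.
* No z-drop or soft end extension; records end at terminal anchors.
* Single affine gap class; long insertions beyond the band appear as
  paired pure-gap blocks.
* Divergence beyond a few percent rapidly erodes seeding, as it does for
  the tools this package models.
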