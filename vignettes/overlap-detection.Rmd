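---
title: "Two-level seed chaining for long-read overlap detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level seed chaining for long-read overlap detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-molecule long-read sequencing (PacBio-style SMRT chemistry)
produces reads tens of kilobases long with a 10–15% per-base error rate
dominated by insertions and deletions. Assembling such data hinges on
finding, among all pairs of raw reads, those whose genomic origins
overlap — and estimating where the overlap lies on each read. Because a
typical project holds 10^5–10^6 reads, base-level alignment of every pair
is out of the question; practical overlappers work from exact shared
*k*-mers ("seeds") and report only boundary coordinates.

`seedoverlap` implements a hierarchical seed strategy: a selective first
pass with long seeds (`k = 16`) finds and localizes candidate overlaps,
and a second pass with shorter seeds (`k' = 12`) — viable only once a
small candidate window is fixed — pushes the boundaries out to the true
extent of the overlap. A binomial significance model decides, at every
stage, whether the observed seed count is consistent with a genuine
overlap at the assumed error rate.

## The model

Let `e` be the per-base error rate and `k` the seed length. A seed
match requires `2k` error-free bases (k on each read), so a position in
a genuine overlap of length `L` survives as a seed match with
probability

```
p = (1 - e)^(2k)
```

and the number of seed hits in the overlap is approximately binomial
with `L` trials. The pipeline keeps a candidate only if its hit count
reaches the three-sigma lower tail

```
mu - 3*sigma = L*p - 3*sqrt(L*p*(1 - p))
```

(`binomial_threshold()`). A non-positive floor means no evidence can be
rejected at that length. With the defaults (`e = 0.15`, `k = 16`),
`p ≈ 0.0055`: a 5 kb overlap is expected to retain ~28 seed hits and is
rejected below 12. The same criterion is reused with `k'` during
extension and for the final validation — the only consistent choice when
the counted objects are `k'`-mers.

### The alignment-length estimate

The criterion needs an estimate of `L` before the overlap is fully
delimited. From the selected cluster's seed bounds (`q_L`, `q_R` on the
query; `r_L`, `r_R` on the chosen reference strand) we use the chained
span plus, on each side, the smaller of the two read overhangs:

```
L = max(q_R - q_L, r_R - r_L) + min(q_L, r_L)
    + min(querySize - q_R, refSize - r_R)
```

For the dovetail configuration in which the query's right end runs past
the reference's left end this reduces exactly to
`L = r_R + querySize - q_R`. We use the configuration-symmetric form
because a pair can be detected with the roles mirrored, and applying the
one-sided formula there would project the overlap across both reads'
full lengths, roughly doubling `L` and with it the significance floor —
enough to reject most genuine mirrored overlaps.

## Pipeline stages and the choices behind them

**Storage.** Reads are packed two bits per base (`A=0, C=1, G=2, T=3`,
so complement is `3 - code`), with the reverse-complement strand
materialized alongside. Non-ACGT characters are uppercased or replaced
deterministically by `A` (and counted): the two-bit alphabet has no
fifth symbol, and a deterministic policy keeps every run reproducible.
Replacement can only destroy seeds, never invent biology: an `N`-laden
read simply contributes less evidence.

**Indexing.** Every k-mer of both strands of every reference read goes
into an occurrence map. Values occurring more than `max_kmer_count`
(10000) times are dropped as repeat noise; values occurring fewer than
`min_kmer_count` (2) times are dropped as unmatchable — in self-overlap
mode any k-mer genuinely shared by two reads necessarily occurs at
least twice in the set. In two-set mode that argument fails, so
`find_overlaps()` lowers the floor to 1 rather than silently discard
cross-set evidence.

**Matching.** Query reads are scanned in the forward direction only;
reverse-strand overlaps surface through the indexed reverse strands.
Per reference read, the strand with more raw matches wins (ties to
forward, for determinism).

**Clustering.** The sorted match array is partitioned greedily into
maximal runs in which both coordinates are non-decreasing and adjacent
matches drift off the diagonal by at most
`max_shift * max(gap_q, gap_r)`. `max_shift = 0.2` is the indel
tolerance: two neighbouring seeds 100 bp apart may disagree by 20 bp of
accumulated indels. The drift bound is applied per adjacent gap, not
cumulatively — under i.i.d. indels the drift between seeds grows with
the gap between them, which the relative form tracks; a cumulative form
would spuriously split long chains. If the query-major pass produces no
cluster that survives the significance floor, the array is re-sorted
reference-major and re-partitioned once: interleaved chains (e.g. a
repeat visited twice on one read) can separate under the other order.
The surviving cluster with the most matched query bases is carried
forward (ties: more hits, then leftmost).

**Extension.** The cluster bounds are projected outward by
`1 + max_shift` to a maximal window (`compute_max_bounds()`), `k'`-mers
are matched inside that window only (a global 12-mer index would be
enormous and useless — 12-mer hits are only informative once localized),
and candidates are consumed outward in order of proximity. A candidate
violating the drift bound is skipped; extension on a side stops when the
accumulated hits on that side fall below the `mu - 3*sigma` floor for
the span covered so far. Finally, every `k'`-mer match inside the final
region is counted once (deduplicated by position) and the criterion is
applied with `L` the larger of the two final spans; only then is the
pair reported. The reported `identity` is the seed-density estimate
`(hits / L)^(1 / (2k'))` — the inverse of the survival law — not a
DP identity; the pipeline never computes base-level alignments.

**Output.** Records are written in a 12-column M4-style dialect
(0-based half-open, forward-strand coordinates, target strand flag),
sorted by read ids; reruns are byte-identical. The `threads`
configuration field is accepted for interface compatibility but the
per-pair computation is a pure function of the pair and configuration,
so any schedule must (and does) produce identical output.

## The evaluation suite

Reported overlaps are judged against the *optimal* local alignment
(Smith-Waterman, linear gap penalties, defaults +2/−3/−5 — a common
choice for noisy long reads; the scheme is configurable because no
canonical one exists), not against a mapper's opinion. `compute_dp()`
requires the optimal alignment to be *good* — span at least
`min_align_len` (2000 bp) and identity at least 0.6, roughly the
expected identity of two 15%-error reads — and then checks the record
under three nested modes: **presence** (the pair was reported),
**length** (span within `bound_tolerance` of optimal, same direction),
**bounds** (every endpoint within `bound_tolerance * optimal span`).
`bound_tolerance` defaults to 0.2, reusing the indel tolerance: the
same physics that lets cluster seeds drift lets reported bounds drift.

Sensitivity samples true pairs (from ground truth), precision samples
reported records at the analysis floor, specificity samples
placement-disjoint pairs; all sampling is uniform without replacement
under a caller-fixed seed, so estimates are bit-reproducible. Because
one validation pass yields all three modes, the estimators return the
three fractions together (attribute `by_mode`).

The Smith-Waterman implementation finds the optimal end score-only,
the start by a score-only pass over the reversed prefixes, and traces
back only within the optimal span — full traceback matrices over two
8 kb reads would cost 64 MB each for no benefit. An independent
quadratic DP written in plain R serves as its oracle in the tests.

## The simulator

`simulate_reads()` draws placements uniformly over an i.i.d. uniform
ACGT genome, on random strands, until the target coverage is met; read
lengths are log-normal (mean 8 kb, sdlog 0.35, truncated to
[1000, 40000] — typical of recent SMRT chemistry). Errors are i.i.d.
per base at rate 0.12 with an indel-dominant mix (insertion 0.5,
deletion 0.35, substitution 0.15), matching the technology's observed
error structure under the standard assumption that its errors are
random rather than systematic. Ground truth records pre-error
placements, so true overlaps are exact interval intersections and the
expected per-read bounds are the error-free projections; the indel
drift this ignores is bounded by `error_rate * overlap length` and is
absorbed by the evaluation tolerance.

What the simulator deliberately does **not** model: repeat structure
beyond random chance, chemistry-specific error profiles, homopolymer
bias, chimeric reads, or quality values. Passing tests therefore
demonstrate the machinery is correct under the stated error model, not
that the defaults are optimal for any particular real dataset — real
genomes' repeats will cost precision, and systematic error hotspots
would break the i.i.d. survival law that calibrates the thresholds.

## Numerical choices and degenerate inputs

* Thresholds are computed in double precision directly from the printed
  formula; `e = 0` degenerates to a floor of `L` (certain evidence).
* Empty match arrays, empty files and zero-read inputs yield empty
  results, not errors; reads shorter than `k` contribute nothing.
* All tie-breaks (strand, cluster selection, alignment end cells) are
  documented and deterministic.
* Reported coordinates are 0-based half-open everywhere internally;
  reverse-strand positions flip to forward coordinates only at the
  output boundary via `pos_fwd = len - pos_rev`.

## Problem sizes used by the checks

The bundled checks simulate 200 kb genomes at 20–30x coverage
(500–800 reads) and validate sampled subsets (tens of pairs) with the
full DP — sizes chosen so the complete suite, including two end-to-end
studies, runs on a laptop-class single core in minutes while leaving
every code path exercised at realistic read lengths. The binomial model
is scale-free and the per-pair pipeline never sees the genome size, so
behaviour at these sizes is representative; only repeat content (absent
in random genomes) changes qualitatively at real-genome scale.

## Known limitations

* Only the best cluster per pair is pursued; a pair with two genuine
  overlapping arrangements (tandem duplication) yields one record.
* The identity column is a seed-density estimate with substantial
  variance on short overlaps; treat it as a rough guide, not a DP
  identity.
* The low-count filter interpretation (floor summed over strands,
  lowered to 1 in two-set mode) is a documented reading of behaviour
  that the method's description leaves open.
* Specificity sampling treats any placement intersection as a true
  overlap; pairs sharing only a genomic repeat count as
  non-overlapping, which on repeat-rich genomes makes the reported
  specificity conservative.
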