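---
title: "Calling transposable element insertions from paired-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transposable element insertions from paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescout)
library(dplyr)
```

## The problem and the model

Transposable elements (TEs) are mobile DNA sequences; new insertions are a
major source of structural variation, but their high mutual sequence
similarity defeats naive short-read mapping: a read drawn from inside a TE
body usually maps equally well to many copies.  `tescout` calls new (and
re-identifies reference) occurrences of *known*, annotated TEs using the
one piece of information that survives the repetitiveness: **paired-end
geometry**.  A fragment spanning an insertion breakpoint yields a mate-pair
with

* one read (the **anchor**) mapped uniquely, with good mapping quality,
  in the single-copy flank *outside every annotated TE*, and
* the other read mapped *inside* some annotated TE copy — wherever the
  aligner happened to put it among the near-identical copies.

The anchor localises the event; the TE-side mate names what jumped.
Because the TE-side placement is unreliable at the level of the individual
element, the mate is named at a configurable level of the TE hierarchy —
element, family, superfamily, or class — trading specificity for
reliability.  Most analyses use the superfamily level: reads cannot tell
two ATCOPIA elements apart, but "a Copia-superfamily element inserted
here" is a reliable statement.

### Clustering and population-at-once calling

All qualifying anchors are pooled **across every individual of the
population** and clustered per (chromosome, item) by single linkage with
window

$$ w \;=\; \mu_\text{insert} + k\,\sigma_\text{insert}, \qquad k = 3, $$

implemented as a sort-and-sweep (a new cluster opens where the gap between
consecutive anchors exceeds $w$), which is $O(n\log n)$ in the number of
reads and provably identical to brute-force single-linkage clustering in
one dimension.  Two anchors belong to the same event only if their
distance is explainable by the fragment-size distribution.

A cluster becomes an event once **one** individual contributes at least
`min_support` pairs (default 3).  Every other individual with at least
`rescue_min_support` pairs (default 1) in the same cluster is then marked
a carrier: an individual sequenced at low coverage borrows confidence from
the population ("rescue").  This is why calling individuals jointly beats
calling them one at a time and merging.

Each event reports:

* `loc` — the floored median anchor position.  The reported locus of a
  breakpoint cloud is not defined by first principles; the median is
  robust to one-sided anchor pileups, and downstream matching tolerates a
  $3\sigma$ window anyway.
* `read_pair_support` — pooled pairs over all carriers; `non_ref_counts`
  — the carrier count.
* `orientation` — each pair votes from strand geometry.  For an
  inner-facing (FR) library, a breakpoint-spanning pair shows anchor and
  TE-mate on *opposite* strands exactly when the inserted copy runs in
  the same direction as its annotated source copy, so opposite strands
  vote *parallel*, equal strands *inverse*; the event takes the majority,
  with ties, votes against strand-unknown source records, and all "old"
  events reported *uncertain* (with the vote counts suppressed).  This
  geometric rule is a design choice of this package, fixed by
  construction and verified against the simulator: planting a copy in its
  source orientation yields unanimous *parallel* votes, a
  reverse-complemented planting unanimous *inverse*.
* `new`/`old` — *old* iff some annotated locus of the same item (at the
  active level) contains the call or lies within the clustering window of
  it; at the superfamily level *any* Copia near *any* annotated Copia
  locus is old, because the item name is the only identity that survives.
* `len` — the length of the annotated reference copy of the
  most-supported source element in the cluster (tie broken by smallest
  `te_id`).  A "length of the event" is not observable from read pairs
  alone; this interpretation is flagged here deliberately.

### Evidence selection details

"Good quality" for the anchor is `MAPQ >= min_anchor_mapq` (default 20).
The TE-side mate has *no* MAPQ requirement — multi-mapping there is
expected and is the entire reason for hierarchy-level naming.  Overlap
rules are strict: a candidate anchor touching any TE by even 1 bp is
disqualified; a mate touching a TE by 1 bp counts as inside.  When a mate
overlaps several records, one evidence row is emitted per distinct item at
the active level, and clustering support resolves cross-item ambiguity.
Secondary, supplementary and duplicate-flagged alignments are ignored.

Two reference styles are supported.  Against an ordinary annotated
reference (`"annotated"`), TE membership is an interval query.  Against a
**virtual reference** (`"virtual"`) — TE-free chromosomes plus one contig
per annotated element, as built by `build_virtual_reference()` — a read on
a TE contig is inside that TE by construction.

## Tunable parameters

| parameter            | default | unit  | role |
|----------------------|---------|-------|------|
| `level`              | superfamily | —  | hierarchy level for naming/clustering |
| `min_anchor_mapq`    | 20      | Phred | anchor uniqueness threshold |
| `min_support`        | 3       | pairs | per-individual support to open an event |
| `rescue_min_support` | 1       | pairs | carrier floor once the event exists |
| `insert_mean`        | 300     | bp    | library fragment mean |
| `insert_sd`          | 100     | bp    | library fragment SD |
| `window_multiplier`  | 3       | —     | SDs added to the mean for the window |

`min_anchor_mapq = 20` and `min_support = 3` are package defaults chosen
for typical short-read libraries, not quantities with a single canonical
value; both are exposed everywhere (API and CLI).  The insert-size
parameters must describe the actual library; the $3\sigma$ window then
covers ~99.7% of fragment lengths.

## The simulator and what it does (not) emulate

`tescout` ships the validation harness it is tested with:

1. `build_virtual_reference()` excises every annotated TE into its own
   contig (overlapping annotations merge into one excision; base count is
   conserved exactly).
2. `plant_insertions()` re-inserts sampled elements at uniformly random
   positions of the TE-free chromosomes, on random strands (minus-strand
   plantings are reverse-complemented), recording the truth.
3. `mutate_snps()` plants exactly *n* substitution SNPs (uniform
   placement; the fixture default rate is 0.4% of the genome, the
   divergence of a typical natural accession from its reference).
4. `simulate_read_pairs()` draws `round(coverage * G / (2 * read_length))`
   fragments with Normal(`insert_mean`, `insert_sd`) lengths truncated
   below at twice the read length, inner-facing mates, and optional
   per-base substitution errors — and, crucially, emits **truth
   alignments**: every read is placed at its true origin projected onto
   the virtual reference.  Reads wholly inside a planted TE body get MAPQ
   0 (mimicking the multi-mapping an aligner reports there), flank reads
   MAPQ 60, and breakpoint-straddling reads are assigned to the side
   holding the majority of their bases.

The truth-alignment emitter is what makes the round trip aligner-free and
deterministic.  It deliberately does **not** model: indels, base-quality
profiles, chimeric fragments, reads spanning more than two planted blocks,
or any specific aligner's mismapping behaviour.  Consequently a perfect
round-trip result (below) demonstrates the *caller's* correctness on
correct alignments; error rates on real data are dominated by the aligner
and annotation quality and will be worse, particularly in pericentromeric
regions — which is why the evaluator stratifies by an
arm/pericentromere/centromere partition (approximate *A. thaliana*
boundaries ship in `inst/extdata/athaliana_regions_approx.tsv`).

A desk-scale fixture (`make_te_fixture()`) bundles all of this: a ~200 kb
two-chromosome genome, 20 annotated TE copies across 6 superfamilies
(Copia, Gypsy, Helitron, MuDR, HAT, L1), and per individual 10 planted
insertions at 20x coverage, 100 bp reads, 300±100 bp inserts.  Insertion
points keep 2 kb apart (within *and across* individuals) and 1 kb from
chromosome ends: the fixture is designed to measure recovery of
*resolvable* events, not the (real) ambiguity of two same-superfamily
insertions closer than one clustering window, which no read-pair method
can separate.

## Evaluation

`match_calls()` scores a call as correct when it names the right
superfamily within $3\sigma_\text{insert}$ of the planted position
(boundary inclusive).  Matching is greedy nearest-first and **one-to-one**
— many-to-one matching would understate false positives.  Rates follow the
printed definitions: `fp = false calls / all calls` (0 when there are no
calls), `fn = missed insertions / insertions planted`.  When truth is
per-individual, an event only counts for the individuals that carry it.

On the shipped fixture the round trip is exact (fp = fn = 0 at 20x), and
over repeated seeds the rates degrade in the expected directions: the
false-negative rate at 2x coverage exceeds the rate at 20x (at 2x a
breakpoint attracts ~2 evidence pairs on average, below `min_support`),
and the mean false-positive rate at 150 bp reads does not exceed the rate
at 50 bp.  These are computed, not asserted, by the test suite and by
`scripts/acceptance.R`.

## Diversity statistics

For population summaries, the presence/absence matrix feeds a windowed
pairwise-difference statistic: per non-overlapping window (default
20 kb), the mean over all unordered pairs of individuals of the number of
events at which they differ, normalised to 1 bp.  Events count once each,
regardless of element length, and are assigned to windows by position.
The implementation uses the equivalent frequency form
$\sum_e 2\hat p_e(1-\hat p_e)\,n/(n-1) / w$ and is tested to $10^{-12}$
against the explicit all-pairs computation.  Two individuals differing at
exactly one event in a 20 kb window give $1/20000 = 5\times10^{-5}$.

`window_correlation()` correlates two tracks (e.g. TE events vs SNPs)
over windows, *skipping any window where either track has zero events*;
with fewer than three surviving windows the correlation is reported as
undefined rather than a number.  Pearson is the default (the usual choice
for this comparison); Spearman is available where heavy-tailed window
values are a concern.

## Numerical and design choices

* Coordinates are 1-based inclusive end to end (GFF in, report out),
  carried internally by `GenomicRanges`/`IRanges`, which eliminates
  off-by-one ambiguity without a coordinate-system conversion layer.
* Clustering ties: a gap of exactly $w$ stays in one cluster; a matching
  offset of exactly $3\sigma$ counts as correct (both `<=`).
* Orientation ties (`p == i`) are *uncertain*; events against
  strand-unknown annotation records are *uncertain* by policy even though
  the vote geometry would formally still be defined.
* Determinism: every random operation takes an explicit seed and runs
  inside `withr::with_seed()`; identical seeds give byte-identical output
  files, which the test suite checks by file digest.
* Degenerate inputs: empty alignment streams, empty GFFs, clusters below
  support, zero-event call sets and header-only outputs are all
  first-class and tested.

## Worked example

```{r example, eval = FALSE}
fx <- make_te_fixture(tempfile("fx"), seed = 1)
params <- calling_params(level = "superfamily",
                         insert_mean = 300, insert_sd = 100)
ev <- lapply(names(fx$sams), function(id)
  extract_te_evidence(fx$sams[[id]], fx$annotation, params,
                      reference_style = "virtual", individual_id = id))
names(ev) <- names(fx$sams)
calls <- call_te_events(ev, fx$annotation, params)
glance(calls)
score_calls(calls, fx$truth, fx$annotation, params)

pos <- select(tidy(calls), event_id, chrom, loc)
div <- pairwise_diversity(calls$presence, pos)
autoplot(div)
```

The problem sizes used throughout the package's own validation — a 200 kb
fixture genome, 10 insertions per individual, 2–3 individuals, 5 seeds
for the trend analyses, 1000 random instances for the clustering oracle —
were chosen as the smallest scales at which every behaviour of interest
(rescue, merging, trend direction, oracle agreement) is exercised with
comfortable margins.

## Known limitations

* Only substitution errors and exact-length reads are simulated; no
  split-read evidence is used, so insertions of elements shorter than the
  read length are invisible by construction.
* Contradicting ("negative") pairs are not counted against an event.
* Absence calling at reference loci (typing which reference copies a
  sample *lacks*) is out of scope.
* The reported `len` is a property of the source annotation, not a
  measurement of the inserted copy.
* In virtual-reference style, new/old classification refers to TE-free
  coordinates; reference-copy re-identification is only meaningful in
  annotated style or via the junction table of
  `build_virtual_reference()`.
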