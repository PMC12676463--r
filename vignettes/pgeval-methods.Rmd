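---
title: "Methods: how pgeval measures a pangenome graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how pgeval measures a pangenome graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgeval)
```

`pgeval` evaluates pangenome variation graphs: sequence graphs whose
segments carry DNA and whose named paths spell out individual haplotypes
or assemblies. This vignette documents the models behind each metric, the
defaults and why they were chosen, what the synthetic generator does and
does not emulate, and the numerical corner cases.

## The graph model

A graph is GFA1 restricted to blunt ends: segment overlaps must be `0M`
or `*`. This is deliberate rather than a shortcut — the evaluation
identities the package relies on (path sequence = concatenation of
oriented segment sequences; flattened base count = total graph bp) only
hold for blunt-ended graphs, which is what the graph builders under
assessment emit. Nonzero-overlap graphs are rejected at parse time.
W (walk) lines are translated into equivalent P-lines on ingest so one
internal representation serves everything downstream.

Path names follow the PanSN convention `sample#haplotype#chrom`; the
sample is the text before the first `#`, and a path without `#` is its
own sample. All per-sample metrics (coverage, growth) group haplotype
paths by sample so a diploid sample never counts twice. Reference
backbone paths can be excluded by sample name (`exclude_samples =
"ref"`), mirroring the practice of computing growth over haplotypes only.

`flatten_graph()` emits one FASTA record per segment rather than one
concatenated record. Concatenation would create spurious k-mers spanning
segment junctions; per-segment records avoid that at the cost of missing
genuine k-mers that straddle a junction in every path (see the k-mer
section for the direction of this bias).

## k-mer completeness and duplication

The metric asks: of the k-mers that are *unambiguously single-copy in
every input assembly*, how many appear once, more than once, or not at
all in the graph? The three fractions measure redundancy (multi) and loss
(absent) introduced by graph construction.

* K-mers are **canonical**: a window is identified with the
  lexicographic minimum of itself and its reverse complement, so all
  counts are strand-independent. Windows containing `N` are skipped.
* **Universal uniqueness** means canonical count exactly 1 in each
  assembly. Absence anywhere excludes a k-mer — "maps uniquely to all
  genomes" requires that it maps at all.
* "Uniquely mapped" is implemented as *exact-match* canonical counting
  rather than alignment with a unique-hit tag. For 21-mers the two
  coincide unless an aligner tolerates mismatched seeds; exact counting
  is deterministic and needs no external aligner. This assumption is the
  package's own choice and is stated here because alignment-based
  variants of the metric do not specify mismatch handling.
* Defaults: `k = 21` (long enough that random collisions in a plant-size
  genome are negligible, short enough that SNP-adjacent windows don't
  dominate), marker presence threshold `0.8` (a marker is "present" when
  at least 80 % of its distinct k-mers occur in the target — tolerant of
  a few variant-disrupted windows while still catching truncated or
  missing genes). Both are arguments everywhere they apply.
* Because k-mers are counted within segments only, a k-mer whose only
  occurrences straddle segment boundaries is reported absent. On bubble
  graphs this inflates `fraction_absent` by at most the breakpoint
  neighborhoods, bounded by `(k-1)` windows per variant breakpoint. The
  synthetic generator's guard gap (below) keeps this effect away from
  marker k-mers entirely, which is why the planted-duplication tests can
  assert exact fractions.

`assembly_representation()` — the fraction of an assembly's distinct
canonical k-mers found in its reconstructed graph path — is a containment
measure standing in for alignment coverage of the assembly against the
graph. It is insensitive to rearrangement (k-mer sets ignore order),
which is acceptable for a representation measure but would not be for an
identity measure.

## Coverage and growth curves

Node coverage is the number of distinct samples whose paths traverse the
node. For a threshold pair `(c, q)` (integer coverage floor, quorum
fraction), a node *qualifies* in a drawn subset of `m` samples when at
least

    t(m) = max(c, ceil(q * m), 1)

of the `m` samples carry it. The ceiling reads "at least a fraction q of
the samples"; the floor of 1 makes `c = 0, q = 0` mean "any carrier"
rather than "every node". The exact rounding convention of external
growth tools is not standardized, so the ceiling convention is fixed here
and documented; tests always check against an exhaustive enumeration of
subsets, not against another tool. A small epsilon (`1e-9`) guards the
ceiling against floating-point noise in products like `0.1 * 3`.

The growth curve at subset size `m` is the expectation of the qualifying
node count over a uniformly random `m`-subset of the `n` samples. The
number of carriers drawn is hypergeometric, so

    E[count](m) = sum over nodes of P[Hyper(n, k_node, m) >= t(m)]

computed per distinct coverage level and multiplied by the node count (or
bp) at that level — O(n) distinct levels, O(n^2) tail evaluations in
total. The classical special cases are `1/0` (pangenome curve, must be
nondecreasing in `m`) and `1/1` (core curve); the identities
`curve(n; 1,1) = #nodes with coverage n` and `curve(n; 1,0) = #covered
nodes` are asserted in the tests. Monte-Carlo mode draws random sample
orderings, averages qualifying counts, and reports a standard error; the
suite checks `|MC - exact| <= 4·SE` at 2000 repetitions for all five
standard threshold pairs.

## SV benchmarking

Matching follows the conventional SV-benchmark recipe. Two records are
candidate matches when they share chromosome and type class (insertion-
like vs deletion-like — types never cross), start within `refdist` bases,
and have size similarity `min(|l1|,|l2|)/max(|l1|,|l2|) >=
min_size_sim`; for sequence-resolved insertion pairs a sequence
similarity `1 - editdist/max(len)` must also reach `min_seq_sim`
(symbolic alleles skip the criterion, as alignment-free tools do).
Defaults — refdist 500 bp, size/sequence similarity 0.7, sizemin 50 bp —
mirror the documented defaults of the Truvari benchmark so "run with
default parameters" means the same thing here.

Candidates are assigned greedily one-to-one in ascending order of
(position distance, then `1 - size similarity`, then input order) — a
deterministic tie-break. A single TP count replaces separate TP-base /
TP-call bookkeeping; on the ≤ 6-record fixtures the tests verify the
greedy TP equals the exhaustive optimal assignment, and `precision =
tp/(tp+fp)`, `recall = tp/(tp+fn)`, `f1 = 2PR/(P+R)` with zero
denominators mapping to 0.

Multi-callset merging is single-linkage clustering per chromosome (link
within `max_dist`, size similarity, same type class), which matches the
transitive behavior of SV mergers: a chain A–B–C merges even when A and C
alone would not link. Each cluster reports its exact support signature;
the intersection table is the UpSet input and its counts sum to the
cluster count by construction.

## Permutation overlap test

The question: do the variant regions a graph implies overlap a previously
reported variant set more than chance placement would? The statistic is
**count-once**: the number of *distinct truth regions* overlapped (≥ 1
shared base, half-open intervals, strand ignored) by at least one query
region. Counting distinct truth regions — rather than query regions —
follows the stated intent of counting each true variant only once; the
opposite direction (how many query regions land in truth) differs only in
which set saturates and can be obtained by swapping arguments.

Randomization re-places each query region independently, preserving its
length: a chromosome is drawn with probability proportional to its number
of valid start positions among chromosomes that fit, then the start is
uniform. Placed regions may overlap each other and the truth — no
masking, matching default randomization behavior. Query regions longer
than the longest truth region are removed first
(`max_length_filter()`): a long region overlaps by chance in proportion
to its footprint and inflates the null expectation.

The p-value is the +1-corrected empirical tail,
`p = (1 + #{perm >= obs}) / (1 + n_perm)`, so with 100 permutations the
smallest attainable value is `1/101 = 0.0099...` — exactly the value
printed when the observed overlap beats every permutation. The z-score
`(obs - mean)/sd` is reported as `NA` when the permuted values are
constant (the p-value remains valid). Calibration is tested: under a true
null the rejection rate at α = 0.05 over 200 replicate tests must fall in
the central 99 % binomial interval.

## Variant plumbing choices

* VCF positions are 1-based; all interval work converts to 0-based
  half-open in one place (`variant_regions()`).
* A sample *carries* a record when its GT contains any alt allele index;
  missing (`.`) means absent. A permissive mode accepts GT-less records
  as carried by a single named sample, for callers that emit bare sites.
* A symbolic `<DEL>` with `END` spans `pos..END` inclusive, giving
  `svlen = -(END - pos + 1)`; explicit alleles use `len(alt) - len(ref)`.
* Multiallelic splitting trims shared bases right-then-left (keeping at
  least one base and advancing `pos` on left trims), the common
  normalizer behavior; full left-alignment would additionally need the
  reference and is applied only when one is supplied.
* Classification uses the > 50 bp convention: length-changing records
  with `|svlen| >= 50` are `SV_INS`/`SV_DEL`, smaller ones `INS`/`DEL`,
  equal-length records `SNP`/`MNP`, and `SVTYPE`-tagged inversions,
  duplications and other complex types `OTHER`. Classification happens
  after trimming, so padding conventions cannot change a call.
* Filter defaults encode the standard pre-benchmark rules: recurrence
  ≥ 2 carriers, size strictly > 100 bp, repeat hits by top query
  coverage (ties: higher identity, then lexicographic subject) with an
  80 % coverage floor.

## The synthetic generator

The generator emulates, at desk scale, a multi-assembly study design:
six sample haplotypes derived from one reference by implanted variation
with controlled cross-sample sharing, and the bubble graph a
graph-construction pipeline would ideally build from them. Defaults:
2 chromosomes × 20 kb, GC 0.44 (plant-genome-like), 20 SNPs, 2
multiallelic SNP sites, 8 small indels (2–10 bp), 4+4 large
deletions/insertions and 2+2 inversions/duplications of 101–300 bp — SV
sizes start above 100 bp to match the "exceeding 100 bp" simulation rule
— and per-variant carrier counts uniform on 1..6. Every default is a
`sim_config()` argument.

Design guarantees, enforced by construction and asserted in tests:

* **Non-overlap with a guard gap** (default 22 = k+1): footprints are
  rejection-sampled so no two variants or markers come within the guard
  of each other. Real data offer no such guarantee; fixtures need it so
  the truth VCF, haplotypes and graph correspond exactly and k-mer
  fractions are exactly predictable.
* **Byte-exact conservation**: each sample's graph path spells its
  haplotype exactly, and applying the truth VCF to the reference (an
  independent code path through the VCF model) reproduces each haplotype.
* **Bubble topology**: a SNP contributes one alt segment per alt allele;
  a deletion an edge skipping the deleted segment; an insertion an extra
  segment; an inversion a reverse-orientation traversal of the reference
  segment; a tandem duplication a repeated traversal. Inversions and
  duplications are emitted with explicit alleles plus `SVTYPE`, so they
  both apply cleanly to sequence and classify as complex.
* **Single-copy markers**: markers are reference windows clear of all
  variant footprints, hence present exactly once per haplotype; a
  configurable subset is duplicated in a separate target to plant a known
  duplication signal.
* **One seed**: all randomness flows from `sim_config(seed = ...)`;
  identical configs give byte-identical bundles.

What the generator does **not** emulate: repeat landscapes and
transposable elements (real duplication signals come largely from
repeats; here duplication is planted explicitly), overlapping or nested
variation, interspersed duplications (tandem only), sequencing or
assembly error, and graph-builder artifacts such as collapsed repeats or
spurious bubbles. Passing tests therefore demonstrate correctness of the
*metrics* on graphs with known structure — not that any particular
pipeline's real-world graph is good.

## Problem sizes and numerical tolerances

The test suite runs entirely on generated data: bundles of 2 × 8–20 kb
with 18–42 variants, growth oracles on graphs of ≤ 15 nodes × ≤ 5
samples (exhaustive subset enumeration, tolerance 1e-9), matching oracles
on ≤ 6-record sets (exhaustive assignment), 200-replicate permutation
calibration with 100 permutations each, and 2000-repetition Monte-Carlo
growth checks. Duplication fractions are integer ratios and are compared
exactly; their sum-to-one identity is asserted at 1e-12. These sizes keep
the full suite in single-digit minutes while leaving every oracle
exhaustive rather than sampled.

## Known limitations

* GFA2, rGFA tags (`SN`/`SO`/`SR`), graph editing and visualization are
  out of scope; graphs must already carry path lines.
* Heaps-law growth-curve parameter fitting is not implemented; the
  package reports the curves themselves.
* The matcher handles insertion- and deletion-like classes; breakend
  algebra and genotype concordance are out of scope.
* Coordinates and counts are plain R integers/doubles; chromosomes
  beyond ~2 Gb per record set are untested territory.
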