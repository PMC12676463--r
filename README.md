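# pgeval

**Evaluation toolkit for pangenome variation graphs.**

Pangenome graphs built by different pipelines (minimizer-anchored,
all-vs-all, progressive-alignment) from the same assemblies can differ
wildly in size, redundancy and the variants they imply, and there is no
single tool that measures these differences on a common footing. `pgeval`
implements a standardized assessment battery for GFA1 variation graphs
with sample-named paths, aimed at anyone comparing graph-construction
pipelines or validating a graph before calling variants from it:

* **Graph statistics & flattening** — node/edge/path counts, total bp,
  segment-length summary; per-segment FASTA export; exact path-sequence
  reconstruction (with reverse-complement traversal).
* **k-mer completeness/duplication** — canonical 21-mers from single-copy
  marker genes (BUSCO-style CDSs) are filtered to those occurring exactly
  once in *every* input assembly; the fractions of these universal k-mers
  that are unique / multi-copy / absent in the flattened graph quantify
  sequence duplication and loss. A marker-presence screen (≥ 80 % of a
  marker's k-mers) flags missing genes, and k-mer containment of an
  assembly in its graph path measures how completely the graph represents
  the assembly.
* **Coverage & growth curves** — per-node coverage counted over distinct
  *samples* (PanSN haplotype paths grouped by the `sample#` prefix);
  pangenome growth under coverage/quorum thresholds `c/q` (the standard
  five: `1/0`, `2/0`, `1/1`, `1/0.5`, `1/0.1`). A node qualifies at subset
  size *m* when carried by at least `t(m) = max(c, ceil(q·m), 1)` of *m*
  randomly drawn samples; the exact curve is the hypergeometric
  expectation `Σ_nodes P[Hyper(n, k, m) ≥ t(m)]`, with a Monte-Carlo mode
  for cross-checking.
* **SV benchmarking** — truth-vs-call matching with Truvari-style
  defaults (refdist 500 bp, size similarity 0.7, sequence similarity 0.7
  for sequence-resolved insertions, sizemin 50 bp), greedy one-to-one
  assignment, precision/recall/F1; multi-callset single-linkage merging
  with UpSet-style intersection tables.
* **Permutation overlap test** — regioneR-style test of whether variant
  regions overlap a previously reported variant set more than expected by
  chance: count-once statistic (distinct truth regions hit), length-
  preserving randomization, +1-corrected empirical p-value
  `(1 + #{perm ≥ obs})/(1 + n_perm)` and z-score, with the
  longer-than-any-truth-variant pre-filter.
* **Variant plumbing** — minimal VCF 4.2 in/out, multiallelic splitting
  with allele trimming, the >50 bp SV classification convention,
  recurrence (≥ 2 carriers), size (> 100 bp) and repeat-hit
  (top hit, ≥ 80 % query coverage) filters.
* **Synthetic truth bundles** — a seeded generator that implants
  SNPs/indels/SVs (deletions, insertions, inversions, tandem
  duplications) with controlled cross-sample sharing into a simulated
  reference, and emits the haplotypes, the exact bubble graph with
  per-sample paths, a truth VCF and single-copy marker genes — so every
  metric above is testable against known ground truth at desk scale.

## Worked example

```r
library(pgeval)

cfg <- sim_config(seed = 42)          # 2 x 20 kb, 6 samples, 42 variants
b   <- simulate_pangenome(cfg)

graph_stats(b$graph)
#>   n_segments n_links n_paths total_bp mean_segment_len min_segment_len max_segment_len
#> 1        110     154      14    40819         371.0818               1            3300
```

The graph has 110 segments over 40.8 kb with 14 paths (6 samples plus the
reference, per chromosome). Growth and core curves over the haplotype
paths:

```r
growth_curves(b$graph, exclude_samples = "ref")[c(1:3, 13:15), ]
#>   spec m coverage_threshold quorum expected_nodes expected_bp
#> 1  1/0 1                  1      0       77.33333    39910.67
#> 2  1/0 2                  1      0       90.60000    40178.13
#> 3  1/0 3                  1      0       97.60000    40341.45
#> 13 1/1 1                  1      1       77.33333    39910.67
#> 14 1/1 2                  1      1       64.06667    39643.20
#> 15 1/1 3                  1      1       57.80000    39539.05
```

The pangenome curve (`1/0`) grows from 77.3 expected nodes for one sample
towards all 107 covered nodes, while the core curve (`1/1`) shrinks to
the 50 nodes carried by all six samples. k-mer duplication against the
bundle's marker genes, on a target in which one of the four markers was
deliberately duplicated:

```r
uni <- universal_unique_filter(extract_kmers(b$markers, 21), b$haplotypes, 21)
duplication_report(uni, b$duplication_target, 21)
#>   n_kmers_universal_unique n_unique n_multi n_absent fraction_unique fraction_multi fraction_absent
#> 1                      720      540     180        0            0.75           0.25               0
```

Exactly the planted quarter of the 720 universal marker k-mers is
multi-copy; nothing is absent. Benchmarking the truth-derived SV calls
against the truth itself is, as it must be, perfect:

```r
truth <- classify_set(split_multiallelic_set(b$truth))
match_sets(truth, truth)
#> bench_result: TP=10 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
```

## Command line

`exec/evalkit` exposes the same operations as subcommands:

```sh
evalkit simulate --seed 5 --out bundle/
evalkit stats bundle/graph.gfa --out stats.tsv
evalkit growth bundle/graph.gfa --spec 1/0 --spec 1/1 --exclude-sample ref --out growth.tsv
evalkit kmer-dup --markers bundle/markers.fa \
    --assemblies bundle/samples/s1.fa,bundle/samples/s2.fa \
    --target graph_flat.fa -k 21 --out dup.tsv
evalkit bench --calls calls.vcf --truth truth.vcf --out bench.json
evalkit permtest --query q.bed --truth t.bed --genome sizes.txt \
    --n-perm 100 --seed 7 --out permtest.json
evalkit evaluate --bundle bundle/ --seed 7 --out summary.json
```

`evaluate` chains the whole battery (stats → flatten → k-mer duplication
→ growth → benchmarking → permutation test) into one JSON summary that
embeds the run configuration.

## Limitations

Only blunt-ended GFA1 (overlaps `0M`/`*`) is supported; graphs must ship
P-lines (or W-lines) naming their paths. k-mers are counted within
segments, never across junctions, so duplication/absence fractions carry
a small, documented edge effect. The SV matcher uses a single TP count
(no separate base/call bookkeeping) and skips the sequence-similarity
criterion for symbolic alleles. See the methods vignette
(`vignettes/pgeval-methods.Rmd`) for the full model descriptions, default
choices and known limitations.
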