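Package: pgeval
Title: Evaluation Toolkit for Pangenome Variation Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized assessment of pangenome variation graphs: GFA1
    parsing with sample-named paths, graph statistics and FASTA flattening,
    exact canonical k-mer completeness and duplication metrics against
    single-copy marker genes, node-coverage histograms and pangenome
    growth/core curves under coverage and quorum thresholds (exact
    hypergeometric and Monte-Carlo modes), structural-variant benchmarking
    (precision/recall/F1) with multi-callset merging and intersection
    tables, permutation-based region-overlap testing with a count-once
    statistic, and a seeded synthetic generator that implants SNPs and
    structural variants into a simulated reference to produce haplotypes,
    a bubble graph with per-sample paths, a truth VCF and marker genes,
    so every metric is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
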