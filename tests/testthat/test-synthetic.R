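test_that("simulated references hit the requested GC content and length", {
  cfg <- sim_config(n_chrom = 2, chrom_len = 10000, gc = 0.5, seed = 81)
  set.seed(81)
  ref <- simulate_reference(cfg)
  expect_length(ref, 2)
  expect_true(all(nchar(ref) == 10000))
  gc_count <- sum(vapply(strsplit(ref, ""), function(ch) {
    sum(ch %in% c("G", "C"))
  }, numeric(1)))
  # 3 sigma binomial bound around 0.5 * 20000
  expect_true(abs(gc_count - 10000) <= 3 * sqrt(20000 * 0.25))
  # extreme GC
  set.seed(82)
  pure <- simulate_reference(sim_config(chrom_len = 1000, gc = 1, seed = 82))
  expect_false(grepl("[AT]", pure[[1]]))
})

test_that("identical configs give byte-identical bundles", {
  b1 <- small_bundle(seed = 83)
  b2 <- small_bundle(seed = 83)
  expect_identical(b1$reference, b2$reference)
  expect_identical(b1$haplotypes, b2$haplotypes)
  expect_identical(write_gfa(b1$graph), write_gfa(b2$graph))
  expect_identical(write_vcf(b1$truth), write_vcf(b2$truth))
  expect_identical(b1$markers, b2$markers)
})

test_that("zero-variant configs return the reference unchanged", {
  cfg <- sim_config(n_snp = 0, n_multiallelic_snp = 0, n_small_indel = 0,
                    n_del = 0, n_ins = 0, n_inv = 0, n_dup = 0,
                    chrom_len = 2000, seed = 84)
  set.seed(84)
  ref <- simulate_reference(cfg)
  iv <- implant_variants(ref, cfg)
  expect_length(iv$truth$records, 0)
  for (s in names(iv$haplotypes)) expect_identical(iv$haplotypes[[s]], ref)
})

test_that("a private deletion shortens only its carrier's haplotype", {
  cfg <- sim_config(n_snp = 0, n_multiallelic_snp = 0, n_small_indel = 0,
                    n_del = 1, n_ins = 0, n_inv = 0, n_dup = 0,
                    del_range = c(100L, 100L), chrom_len = 3000, n_chrom = 1,
                    n_samples = 3, carrier_weights = c(1, 0, 0), seed = 85)
  set.seed(85)
  ref <- simulate_reference(cfg)
  iv <- implant_variants(ref, cfg)
  expect_equal(iv$plan$n_carriers, 1)
  carrier <- strsplit(iv$plan$carriers, ",")[[1]]
  for (s in names(iv$haplotypes)) {
    expected <- if (s == carrier) nchar(ref) - 100 else nchar(ref)
    expect_equal(nchar(iv$haplotypes[[s]][[1]]), unname(expected))
  }
})

test_that("bubble topology of a single SNP matches the drawn construction", {
  cfg <- sim_config(n_snp = 1, n_multiallelic_snp = 0, n_small_indel = 0,
                    n_del = 0, n_ins = 0, n_inv = 0, n_dup = 0,
                    chrom_len = 500, n_chrom = 1, n_samples = 2,
                    n_markers = 0, n_dup_markers = 0,
                    carrier_weights = c(1, 0), seed = 86)
  b <- simulate_pangenome(cfg)
  # left flank, ref base, alt base, right flank
  expect_equal(graph_stats(b$graph)$n_segments, 4)
  routes <- unique(vapply(b$graph$paths, function(p) {
    paste(p$seg, collapse = ",")
  }, character(1)))
  expect_length(routes, 2)
})

test_that("every sample path spells its haplotype and truth applies exactly", {
  for (seed in c(91, 92)) {
    b <- small_bundle(seed = seed)
    for (s in names(b$haplotypes)) {
      for (chrom in names(b$reference)) {
        expect_identical(path_sequence(b$graph, paste0(s, "#1#", chrom)),
                         unname(b$haplotypes[[s]][[chrom]]))
      }
    }
    for (chrom in names(b$reference)) {
      expect_identical(path_sequence(b$graph, paste0("ref#0#", chrom)),
                       unname(b$reference[[chrom]]))
    }
    split <- split_multiallelic_set(b$truth)
    for (s in names(b$haplotypes)) {
      expect_identical(apply_variant_set(b$reference, split, s),
                       b$haplotypes[[s]])
    }
  }
})

test_that("allele-node coverage equals the designed carrier counts", {
  b <- small_bundle(seed = 93)
  cov <- node_sample_coverage(b$graph, exclude_samples = "ref")
  n <- cov$n_samples
  # insertion alt segments are traversed by exactly the designed carriers
  ins <- b$plan[b$plan$class %in% c("INS", "SMALL_INS"), ]
  for (i in seq_len(nrow(ins))) {
    rec <- Filter(function(r) r$id == ins$id[i], b$truth$records)[[1]]
    alt_seq <- substring(rec$alts[[1]], 2)
    seg_id <- names(b$graph$segments)[b$graph$segments == alt_seq]
    expect_length(seg_id, 1)
    expect_equal(unname(cov$coverage[seg_id]), ins$n_carriers[i])
  }
  # deleted segments are covered by everyone except the carriers
  dels <- b$plan[b$plan$class %in% c("DEL", "SMALL_DEL"), ]
  for (i in seq_len(nrow(dels))) {
    rec <- Filter(function(r) r$id == dels$id[i], b$truth$records)[[1]]
    del_seq <- substring(rec$ref, 2)
    seg_id <- names(b$graph$segments)[b$graph$segments == del_seq]
    if (length(seg_id) == 1) {
      expect_equal(unname(cov$coverage[seg_id]), n - dels$n_carriers[i])
    }
  }
})

test_that("markers are single-copy in every haplotype, duplication is planted", {
  b <- small_bundle(seed = 94)
  for (id in names(b$markers)) {
    for (s in names(b$haplotypes)) {
      expect_equal(oracle_kmer_count(substr(b$markers[[id]], 1, 21),
                                     b$haplotypes[[s]]), 1L)
    }
    want <- if (id %in% b$duplicated_markers) 2L else 1L
    expect_equal(oracle_kmer_count(substr(b$markers[[id]], 1, 21),
                                   b$duplication_target), want)
  }
  expect_length(b$duplicated_markers, b$config$n_dup_markers)
})

test_that("impossible capacity requests fail loudly", {
  cfg <- sim_config(chrom_len = 600, n_del = 50, del_range = c(101L, 120L),
                    seed = 95)
  set.seed(95)
  ref <- simulate_reference(cfg)
  expect_error(implant_variants(ref, cfg), "too small")
})

test_that("bundles write to disk and read back consistently", {
  b <- small_bundle(seed = 96)
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("reference.fa", "truth.vcf",
                                               "graph.gfa", "markers.fa",
                                               "dup_target.fa",
                                               "config.json")))))
  ref <- read_fasta(file.path(dir, "reference.fa"))
  expect_identical(ref, b$reference)
  g <- parse_gfa(file.path(dir, "graph.gfa"))
  expect_equal(graph_stats(g), graph_stats(b$graph))
  v <- parse_vcf(file.path(dir, "truth.vcf"))
  expect_equal(length(v), length(b$truth))
  hap1 <- read_fasta(file.path(dir, "samples", "s1.fa"))
  expect_equal(unname(hap1), unname(b$haplotypes$s1))
})
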