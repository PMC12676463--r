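toy_layout <- function() genome_layout(c(chr1 = 100000, chr2 = 80000))

sparse_truth <- function() {
  region_set(c(rep("chr1", 5), rep("chr2", 5)),
             c(1000, 5000, 9000, 13000, 17000, 2000, 6000, 10000, 14000, 18000),
             c(1300, 5300, 9300, 13300, 17300, 2300, 6300, 10300, 14300, 18300))
}

test_that("region sets validate bounds against the layout", {
  gl <- toy_layout()
  expect_error(region_set("chr1", 10, 10), "start < end")
  expect_error(region_set("chr3", 0, 10, genome = gl), "absent")
  expect_error(region_set("chr2", 0, 80001, genome = gl), "past")
  expect_error(genome_layout(c(10, 20)), "named")
  expect_error(genome_layout(c(a = 10, a = 20)), "duplicate")
})

test_that("count-once overlap counts distinct truth regions", {
  truth <- region_set("chr1", c(100, 1000), c(200, 1100))
  # three query regions piling on one truth region count once
  q1 <- region_set("chr1", c(100, 120, 150), c(110, 130, 160))
  expect_equal(count_overlaps_once(q1, truth), 1)
  # disjoint
  expect_equal(count_overlaps_once(region_set("chr1", 5000, 5100), truth), 0)
  # one query spanning both truth regions counts each once
  expect_equal(count_overlaps_once(region_set("chr1", 0, 2000), truth), 2)
  # half-open: touching at the boundary is not an overlap
  expect_equal(count_overlaps_once(region_set("chr1", 200, 300), truth), 0)
  expect_equal(count_overlaps_once(region_set("chr1", 199, 300), truth), 1)
})

test_that("count-once agrees with a naive double-loop oracle", {
  set.seed(71)
  gl <- toy_layout()
  for (i in 1:10) {
    q <- randomize_regions(region_set(rep("chr1", 30), 0, rep(500, 30) ), gl)
    t <- randomize_regions(region_set(rep("chr1", 20), 0, rep(800, 20)), gl)
    expect_equal(count_overlaps_once(q, t), oracle_overlap_once(q, t))
    expect_lte(count_overlaps_once(q, t), nrow(t))
  }
})

test_that("max-length filter removes query regions longer than any truth", {
  truth <- region_set("chr1", 0, 500)  # max truth length 500
  query <- region_set("chr1", c(0, 1000, 2000), c(501, 1500, 2400))
  kept <- max_length_filter(query, truth)
  expect_equal(kept$start, c(1000, 2000))  # the 501 bp region is dropped
  expect_equal(nrow(max_length_filter(query[0, ], truth)), 0)
  expect_error(max_length_filter(query, truth[0, ]), "empty")
})

test_that("randomization preserves lengths and places uniformly", {
  gl <- toy_layout()
  regions <- region_set(rep("chr1", 50), seq(0, 49000, 1000),
                        seq(0, 49000, 1000) + rep(c(100, 250), 25))
  r <- randomize_regions(regions, gl, seed = 5)
  expect_equal(sort(r$end - r$start), sort(regions$end - regions$start))
  expect_true(all(r$end <= gl[r$chrom]))
  # single chromosome exactly the region length -> start pinned at 0
  one <- genome_layout(c(c1 = 500))
  pin <- randomize_regions(region_set("c1", 0, 500), one, seed = 1)
  expect_equal(pin$start, 0)
  # uniform starts: chi-square over 10 bins at 10,000 draws
  big <- region_set(rep("chr1", 10000), 0, rep(100, 10000))
  placed <- randomize_regions(big, genome_layout(c(chr1 = 100000)), seed = 9)
  bins <- table(cut(placed$start, breaks = seq(0, 99901, length.out = 11),
                    include.lowest = TRUE))
  expect_gt(stats::chisq.test(as.integer(bins))$p.value, 0.001)
  expect_error(randomize_regions(region_set("chr1", 0, 99999999), gl),
               "longer than every chromosome")
})

test_that("perm_test attains the +1-corrected empirical p-value bounds", {
  gl <- toy_layout()
  truth <- sparse_truth()
  # query identical to a sparse truth: observed beats every permutation
  pt <- perm_test(truth, truth, gl, n_perm = 100, seed = 2)
  expect_equal(pt$observed, nrow(truth))
  expect_true(all(pt$perm_values < pt$observed))
  expect_equal(pt$p, 1 / 101)
  expect_equal(round(pt$p, 4), 0.0099)
  expect_gt(pt$z, 2)
  expect_length(pt$perm_values, 100)
  # zero observed with alternative 'greater' -> p = 1
  off <- region_set("chr2", 70000, 70100)
  truth1 <- region_set("chr1", 0, 100)
  pt0 <- perm_test(off, truth1, genome_layout(c(chr1 = 1000, chr2 = 80000)),
                   n_perm = 50, seed = 3)
  expect_equal(pt0$observed, 0)
  expect_equal(pt0$p, 1)
  expect_error(perm_test(truth, truth, gl, n_perm = 100), "seed")
})

test_that("identical seeds reproduce the full permutation result", {
  gl <- toy_layout()
  truth <- sparse_truth()
  a <- perm_test(truth, truth, gl, n_perm = 60, seed = 42)
  b <- perm_test(truth, truth, gl, n_perm = 60, seed = 42)
  expect_identical(a, b)
  c <- perm_test(truth, truth, gl, n_perm = 60, seed = 43)
  expect_false(identical(a$perm_values, c$perm_values))
})

test_that("constant permuted values give an undefined z but a valid p", {
  gl <- genome_layout(c(c1 = 200))
  # query covers the whole chromosome: every permutation hits everything
  query <- region_set("c1", 0, 200)
  truth <- region_set("c1", c(10, 100), c(20, 110))
  pt <- perm_test(query, truth, gl, n_perm = 20, seed = 1)
  expect_true(is.na(pt$z))
  expect_equal(pt$p, 1)  # every permuted value ties the observed
})

test_that("variant_regions maps truth SVs onto their reference footprints", {
  b <- small_bundle(seed = 72)
  svs <- size_filter(split_multiallelic_set(b$truth), 50, strict_greater = FALSE)
  regs <- variant_regions(svs)
  expect_equal(nrow(regs), length(svs))
  expect_true(all(regs$end > regs$start))
  layout <- genome_layout(b$truth$contigs)
  expect_true(all(regs$end <= unname(layout[regs$chrom])))
})
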