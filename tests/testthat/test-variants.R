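mk_record <- function(chrom = "chr1", pos, ref, alts, gt = c(s1 = "1")) {
  pgeval:::new_variant_record(chrom, pos, ref, alts, gt = gt)
}

test_that("split_multiallelic separates alleles and recodes genotypes", {
  r <- mk_record(pos = 100, ref = "A", alts = c("T", "G"),
                 gt = c(s1 = "1/1", s2 = "0/2", s3 = "./."))
  out <- split_multiallelic(r)
  expect_length(out, 2)
  expect_equal(out[[1]]$alts, "T")
  expect_equal(out[[2]]$alts, "G")
  expect_equal(out[[1]]$pos, 100)
  expect_equal(out[[1]]$gt, c(s1 = "1/1", s2 = "0/0", s3 = "./."))
  expect_equal(out[[2]]$gt, c(s1 = "0/0", s2 = "0/1", s3 = "./."))
  # biallelic input returned unchanged
  b <- mk_record(pos = 5, ref = "A", alts = "T")
  expect_length(split_multiallelic(b), 1)
  expect_equal(split_multiallelic(b)[[1]]$alts, "T")
})

test_that("allele trimming reproduces the original edit on a toy sequence", {
  # REF ATT with ALT ATTTT (insertion) and A (deletion), applied to a toy
  # carrier; the split records must reproduce the same edited sequences.
  toy <- c(chr1 = "GGGATTGGG")
  r <- mk_record(pos = 4, ref = "ATT", alts = c("ATTTT", "A"),
                 gt = c(s1 = "1", s2 = "2"))
  naive_apply <- function(seq, pos, ref, alt) {
    paste0(substr(seq, 1, pos - 1), alt,
           substr(seq, pos + nchar(ref), nchar(seq)))
  }
  want1 <- naive_apply(toy[[1]], 4, "ATT", "ATTTT")
  want2 <- naive_apply(toy[[1]], 4, "ATT", "A")
  out <- split_multiallelic(r)
  expect_lt(nchar(out[[1]]$ref), 3)  # trimming happened
  got1 <- naive_apply(toy[[1]], out[[1]]$pos, out[[1]]$ref, out[[1]]$alts[[1]])
  got2 <- naive_apply(toy[[1]], out[[2]]$pos, out[[2]]$ref, out[[2]]$alts[[1]])
  expect_equal(got1, want1)
  expect_equal(got2, want2)
  vs <- variant_set(list(r), samples = c("s1", "s2"))
  expect_length(split_multiallelic_set(vs)$records, 2)
})

test_that("classification follows the >50 bp convention and SVTYPE overrides", {
  cls <- function(...) classify_variant(mk_record(...))$vtype
  expect_equal(cls(pos = 10, ref = "A", alts = "T"), "SNP")
  expect_equal(cls(pos = 10, ref = "AC", alts = "GT"), "MNP")
  expect_equal(cls(pos = 10, ref = "A",
                   alts = paste0("A", strrep("T", 51))), "SV_INS")
  expect_equal(cls(pos = 10, ref = "A",
                   alts = paste0("A", strrep("T", 30))), "INS")
  expect_equal(cls(pos = 10, ref = paste0("A", strrep("T", 30)),
                   alts = "A"), "DEL")
  expect_equal(cls(pos = 10, ref = paste0("A", strrep("T", 49)),
                   alts = "A"), "DEL")  # 49 bp is below the cut
  expect_equal(cls(pos = 10, ref = paste0("A", strrep("T", 50)),
                   alts = "A"), "SV_DEL")
  inv <- mk_record(pos = 10, ref = "ACGT", alts = "ACGT")
  inv$svtype <- "INV"
  expect_equal(classify_variant(inv)$vtype, "OTHER")
  expect_error(classify_variant(mk_record(pos = 10, ref = "A",
                                          alts = c("T", "G"))), "biallelic")
  # invariant under shared suffix padding
  expect_equal(cls(pos = 10, ref = "AGGG", alts = "TGGG"), "SNP")
})

test_that("multiallelic sites are counted before splitting", {
  vs <- variant_set(list(
    mk_record(pos = 10, ref = "A", alts = "T"),
    mk_record(pos = 50, ref = "A", alts = c("T", "G"), gt = c(s1 = "1"))))
  expect_equal(count_multiallelic(vs), 1)
  expect_equal(count_multiallelic(split_multiallelic_set(vs)), 0)
  b <- small_bundle(seed = 51)
  expect_equal(count_multiallelic(b$truth), b$config$n_multiallelic_snp)
})

test_that("recurrence filter keeps variants shared by enough samples", {
  vs <- variant_set(list(
    mk_record(pos = 10, ref = "A", alts = "T",
              gt = c(s1 = "1", s2 = "0", s3 = "0")),
    mk_record(pos = 50, ref = "G", alts = "C",
              gt = c(s1 = "1", s2 = "1", s3 = "0"))))
  expect_equal(length(recurrence_filter(vs, 2)), 1)
  expect_equal(recurrence_filter(vs, 2)$records[[1]]$pos, 50)
  expect_equal(length(recurrence_filter(vs, 1)), 2)
  expect_error(recurrence_filter(vs, 0), "min_samples")
  # generator bookkeeping is the oracle on a synthetic truth set
  b <- small_bundle(seed = 52)
  kept <- recurrence_filter(b$truth, 2)
  expect_equal(length(kept), sum(b$plan$n_carriers >= 2))
  expect_setequal(vapply(kept$records, `[[`, character(1), "id"),
                  b$plan$id[b$plan$n_carriers >= 2])
})

test_that("size filter drops variants at or below the cut (strictly greater)", {
  vs <- variant_set(list(
    mk_record(pos = 10, ref = "A", alts = paste0("A", strrep("C", 100))),
    mk_record(pos = 500, ref = "A", alts = paste0("A", strrep("C", 101))),
    mk_record(pos = 900, ref = "A", alts = "T")))
  kept <- size_filter(vs, 100)
  expect_equal(length(kept), 1)
  expect_equal(kept$records[[1]]$pos, 500)
  expect_equal(length(size_filter(vs, 100, strict_greater = FALSE)), 2)
})

test_that("filters are idempotent and commute", {
  b <- small_bundle(seed = 53)
  vs <- split_multiallelic_set(b$truth)
  a <- size_filter(recurrence_filter(vs, 2), 100)
  bb <- recurrence_filter(size_filter(vs, 100), 2)
  ids <- function(s) vapply(s$records, `[[`, character(1), "id")
  expect_equal(ids(a), ids(bb))
  expect_equal(ids(recurrence_filter(recurrence_filter(vs, 2), 2)),
               ids(recurrence_filter(vs, 2)))
  expect_equal(ids(size_filter(size_filter(vs, 100), 100)),
               ids(size_filter(vs, 100)))
})

test_that("repeat-hit filter keeps the single best high-coverage hit", {
  hits <- data.frame(
    query = c("q1", "q1", "q2", "q3", "q3"),
    subject = c("teA", "teB", "teC", "teD", "teC"),
    pident = c(95, 90, 99, 88, 88),
    qcov = c(85, 92, 75, 90, 90))
  best <- repeat_hit_filter(hits, 80)
  expect_equal(nrow(best), 2)               # q2 dropped: best coverage 75
  expect_equal(best$subject[best$query == "q1"], "teB")  # top coverage wins
  expect_equal(best$subject[best$query == "q3"], "teC")  # tie -> subject id
  expect_equal(nrow(repeat_hit_filter(hits[0, ], 80)), 0)
  # ties on coverage break by identity first
  hits2 <- data.frame(query = "q", subject = c("a", "b"),
                      pident = c(90, 99), qcov = c(90, 90))
  expect_equal(repeat_hit_filter(hits2)$subject, "b")
  # read_hits carries extra columns through
  path <- tempfile(fileext = ".tsv")
  writeLines(c("q1\tteA\t95\t85\t100\t0", "q1\tteB\t90\t92\t100\t0"), path)
  tab <- read_hits(path)
  expect_named(tab, c("query", "subject", "pident", "qcov", "extra1", "extra2"))
  expect_equal(repeat_hit_filter(tab)$subject, "teB")
})

test_that("applying a truth set reproduces carrier haplotypes", {
  b <- small_bundle(seed = 54)
  vs <- split_multiallelic_set(b$truth)
  for (s in names(b$haplotypes)) {
    expect_identical(apply_variant_set(b$reference, vs, s),
                     b$haplotypes[[s]])
  }
  expect_error(apply_variant_set(b$reference, vs, "nobody"), "unknown sample")
})
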