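# Shared fixtures and independent brute-force oracles. Every oracle here is
# deliberately naive (string scans, exhaustive enumeration) and shares no
# code path with the package implementation it checks.

toy_gfa_lines <- function() {
  c("H\tVN:Z:1.0",
    "S\t1\tACGT",
    "S\t2\tTT",
    "L\t1\t+\t2\t+\t0M",
    "P\ts1#1#c1\t1+,2+\t*")
}

# Three-sample graph used throughout growth tests: node A on all samples,
# node B on s1 only.
toy_cov_graph <- function() {
  pangenome_graph(
    segments = c(A = "ACGT", B = "TT"),
    links = data.frame(from = "A", from_orient = "+", to = "B",
                       to_orient = "+", overlap = "0M"),
    paths = list(
      list(name = "s1#1#c", seg = c("A", "B"), orient = c("+", "+")),
      list(name = "s2#1#c", seg = "A", orient = "+"),
      list(name = "s3#1#c", seg = "A", orient = "+")))
}

# Brute-force occurrence count of a k-mer (both strands) in a sequence set,
# counting within records only, by sliding a window with substring().
oracle_kmer_count <- function(kmer, sequences) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  total <- 0L
  for (s in sequences) {
    n <- nchar(s); k <- nchar(kmer)
    if (n < k) next
    windows <- substring(s, 1:(n - k + 1), k:n)
    total <- total + sum(windows == kmer) +
      if (rc != kmer) sum(windows == rc) else 0L
  }
  total
}

# Exhaustive growth-curve oracle: average qualifying-node count over all
# m-subsets of samples, from a node x sample membership matrix.
oracle_growth <- function(membership, c_min, quorum) {
  n <- ncol(membership)
  vapply(seq_len(n), function(m) {
    t_m <- max(c_min, ceiling(quorum * m - 1e-9), 1)
    subsets <- utils::combn(n, m)
    mean(apply(subsets, 2, function(cols) {
      sum(rowSums(membership[, cols, drop = FALSE]) >= t_m)
    }))
  }, numeric(1))
}

# Exhaustive optimal one-to-one assignment: maximum number of call/truth
# pairs matchable under an eligibility matrix (rows = calls, cols = truth).
oracle_max_matching <- function(elig) {
  n_call <- nrow(elig)
  best <- 0L
  recurse <- function(ci, used_truth, count) {
    if (count + (n_call - ci + 1L) <= best) return()
    if (ci > n_call) { best <<- max(best, count); return() }
    for (ti in which(elig[ci, ] & !used_truth)) {
      used_truth[ti] <- TRUE
      recurse(ci + 1L, used_truth, count + 1L)
      used_truth[ti] <- FALSE
    }
    recurse(ci + 1L, used_truth, count)
  }
  recurse(1L, rep(FALSE, ncol(elig)), 0L)
  best
}

# Naive double-loop count-once overlap oracle over 0-based half-open regions.
oracle_overlap_once <- function(query, truth) {
  hit <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(query))) {
      if (truth$chrom[i] == query$chrom[j] &&
          truth$start[i] < query$end[j] && query$start[j] < truth$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

# Random biallelic SV set (explicit INS/DEL alleles >= 50 bp) for
# benchmarking tests; positions are spaced so records never self-collide.
rand_sv_set <- function(n = 8, seed = 1, chrom = "chr1") {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    pos <- 2000L * i + sample.int(500L, 1L)
    size <- sample(50:300, 1L)
    anchor <- sample(c("A", "C", "G", "T"), 1L)
    body <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                  collapse = "")
    if (stats::runif(1) < 0.5) {
      rec <- list(chrom = chrom, pos = pos, ref = anchor,
                  alt = paste0(anchor, body))
    } else {
      rec <- list(chrom = chrom, pos = pos, ref = paste0(anchor, body),
                  alt = anchor)
    }
    pgeval:::new_variant_record(rec$chrom, rec$pos, rec$ref, rec$alt,
                                gt = c(s1 = "1"))
  })
  classify_set(variant_set(recs, samples = "s1"))
}

# Tiny deterministic bundle for tests that do not need the default scale.
small_bundle <- function(seed = 11, ...) {
  simulate_pangenome(sim_config(chrom_len = 8000L, n_snp = 8L,
                                n_small_indel = 4L, n_del = 2L, n_ins = 2L,
                                n_inv = 1L, n_dup = 1L,
                                n_multiallelic_snp = 1L, n_markers = 3L,
                                seed = seed, ...))
}
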