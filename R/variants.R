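# Variant normalization, classification and the standard filtering rules
# applied before benchmarking: recurrence (shared by >= 2 samples), size
# (exceeding 100 bp), repeat-hit (best alignment per variant, query
# coverage >= 80%).

# Trim shared flanking bases of a ref/alt pair: right (suffix) first, then
# left (prefix, advancing pos); always keep >= 1 base on each allele.
trim_alleles <- function(pos, ref, alt) {
  if (is_symbolic(alt)) return(list(pos = pos, ref = ref, alt = alt))
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Split a multiallelic record into biallelic records
#'
#' One record per alt allele, with shared leading/trailing bases trimmed
#' (right first, then left, adjusting `pos`; at least one ref base is kept)
#' and genotypes re-coded per split allele: the focal alt becomes allele 1,
#' every other allele 0, missing stays missing.
#'
#' @param record A variant record (from a [variant_set()]).
#' @return List of biallelic variant records. Biallelic input is returned
#'   (trimmed) as a single-element list.
#' @export
split_multiallelic <- function(record) {
  stopifnot(inherits(record, "variant_record"))
  lapply(seq_along(record$alts), function(a) {
    tr <- trim_alleles(record$pos, record$ref, record$alts[[a]])
    gt <- vapply(record$gt, function(g) {
      toks <- strsplit(g, "[/|]")[[1]]
      idx <- suppressWarnings(as.integer(toks))
      recoded <- ifelse(is.na(idx), ".", ifelse(idx == a, "1", "0"))
      paste(recoded, collapse = if (grepl("|", g, fixed = TRUE)) "|" else "/")
    }, character(1))
    new_variant_record(chrom = record$chrom, pos = tr$pos, ref = tr$ref,
                       alts = tr$alt, gt = gt, id = record$id,
                       qual = record$qual, filter = record$filter,
                       svtype = record$svtype,
                       svlen = if (is_symbolic(tr$alt)) record$svlen[[a]] else NULL,
                       end = if (is_symbolic(tr$alt)) record$end else NA_integer_)
  })
}

#' Split every multiallelic record of a set
#'
#' @param set A [variant_set()].
#' @return A [variant_set()] of biallelic records.
#' @export
split_multiallelic_set <- function(set) {
  stopifnot(inherits(set, "variant_set"))
  recs <- unlist(lapply(set$records, split_multiallelic), recursive = FALSE)
  variant_set(recs, samples = set$samples, contigs = set$contigs)
}

#' Classify a biallelic variant record
#'
#' Size-based typing with the conventional >50 bp structural-variant cut:
#' equal-length alleles give `SNP` (1 bp) or `MNP`; length-changing alleles
#' give `INS`/`DEL` below the threshold and `SV_INS`/`SV_DEL` at or above
#' it; inversions, duplications and other complex types (recognized via
#' `SVTYPE`) fall in `OTHER`. Classification is applied after allele
#' trimming, so shared padding does not change the call.
#'
#' @param record A biallelic variant record.
#' @param sv_threshold Absolute length difference (bases) at which an
#'   indel becomes a structural variant. Default 50.
#' @return The record with its `vtype` field set.
#' @export
classify_variant <- function(record, sv_threshold = 50L) {
  stopifnot(inherits(record, "variant_record"))
  if (length(record$alts) != 1L) {
    stop("classify requires a biallelic record; split multiallelic sites first",
         call. = FALSE)
  }
  alt <- record$alts[[1]]
  vtype <- if (!is.na(record$svtype) &&
               record$svtype %in% c("INV", "DUP", "CNV", "BND", "TRA", "CPX")) {
    "OTHER"
  } else if (is_symbolic(alt)) {
    sv <- abs(record$svlen[[1]])
    base <- sub("^<|>$", "", alt); base <- sub(">$", "", base)
    if (base %in% c("INS")) {
      if (sv >= sv_threshold) "SV_INS" else "INS"
    } else if (base %in% c("DEL")) {
      if (sv >= sv_threshold) "SV_DEL" else "DEL"
    } else "OTHER"
  } else {
    tr <- trim_alleles(record$pos, record$ref, alt)
    dl <- nchar(tr$alt) - nchar(tr$ref)
    if (dl == 0L) {
      if (nchar(tr$ref) == 1L) "SNP" else "MNP"
    } else if (dl > 0L) {
      if (dl >= sv_threshold) "SV_INS" else "INS"
    } else {
      if (-dl >= sv_threshold) "SV_DEL" else "DEL"
    }
  }
  record$vtype <- vtype
  record
}

#' Classify every record of a (biallelic) set
#'
#' @param set A [variant_set()] of biallelic records.
#' @inheritParams classify_variant
#' @return The set with `vtype` filled on every record.
#' @export
classify_set <- function(set, sv_threshold = 50L) {
  stopifnot(inherits(set, "variant_set"))
  set$records <- lapply(set$records, classify_variant, sv_threshold = sv_threshold)
  set
}

#' Count multiallelic sites
#'
#' Number of records carrying two or more alt alleles (counted before
#' splitting).
#'
#' @param set A [variant_set()].
#' @return Integer count.
#' @export
count_multiallelic <- function(set) {
  stopifnot(inherits(set, "variant_set"))
  sum(vapply(set$records, function(r) length(r$alts), integer(1)) >= 2L)
}

#' Recurrence filter: keep variants shared by enough samples
#'
#' Retains records present (genotype carries an alt allele) in at least
#' `min_samples` samples — the rule used to drop the long tail of
#' single-genotype calls before simulation.
#'
#' @param set A [variant_set()] with genotypes.
#' @param min_samples Minimum carrier count (default 2).
#' @return Filtered [variant_set()].
#' @export
recurrence_filter <- function(set, min_samples = 2L) {
  stopifnot(inherits(set, "variant_set"))
  if (min_samples < 1L) stop("min_samples must be >= 1", call. = FALSE)
  keep <- vapply(set$records, function(r) {
    sum(record_presence(r, set$samples)) >= min_samples
  }, logical(1))
  variant_set(set$records[keep], samples = set$samples, contigs = set$contigs)
}

#' Size filter: keep variants exceeding a length cut
#'
#' Keeps records whose absolute length change exceeds `min_len` bases
#' (strictly greater by default, matching the "exceeding 100 bp" rule; set
#' `strict_greater = FALSE` for >=). SNPs and MNPs have length change 0 and
#' are dropped.
#'
#' @param set A [variant_set()].
#' @param min_len Length threshold in bases (default 100).
#' @param strict_greater Use `>` (default) rather than `>=`.
#' @return Filtered [variant_set()].
#' @export
size_filter <- function(set, min_len = 100L, strict_greater = TRUE) {
  stopifnot(inherits(set, "variant_set"))
  keep <- vapply(set$records, function(r) {
    sz <- max(abs(r$svlen), na.rm = TRUE)
    if (strict_greater) sz > min_len else sz >= min_len
  }, logical(1))
  variant_set(set$records[keep], samples = set$samples, contigs = set$contigs)
}

#' Best repeat-library hit per query with a coverage floor
#'
#' Per query, keeps the single hit with the highest query coverage (ties
#' broken by higher percent identity, then lexicographically smaller
#' subject id) and drops queries whose best coverage is below `min_qcov` —
#' the rule used to classify variants as repeat-associated with high
#' confidence.
#'
#' @param hits Data frame of alignment hits with columns `query`, `subject`,
#'   `pident`, `qcov` (additional columns are carried through), e.g. from
#'   [read_hits()].
#' @param min_qcov Minimum query coverage percentage (default 80).
#' @return Data frame with one row per retained query.
#' @export
repeat_hit_filter <- function(hits, min_qcov = 80) {
  needed <- c("query", "subject", "pident", "qcov")
  if (!all(needed %in% names(hits))) {
    stop("hits must have columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0) return(hits)
  if (any(hits$qcov < 0 | hits$qcov > 100)) {
    stop("query coverage must lie in [0, 100]", call. = FALSE)
  }
  ord <- order(hits$query, -hits$qcov, -hits$pident, hits$subject,
               method = "radix")
  best <- hits[ord, , drop = FALSE]
  best <- best[!duplicated(best$query), , drop = FALSE]
  best <- best[best$qcov >= min_qcov, , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Read a tabular alignment-hit file
#'
#' Tab-separated with no header; the first four columns are query id,
#' subject id, percent identity and query coverage, further columns are
#' kept as `extra1`, `extra2`, ...
#'
#' @param path Path to the hit table.
#' @return Data frame suitable for [repeat_hit_filter()].
#' @export
read_hits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 4) stop("hit table needs at least 4 columns", call. = FALSE)
  names(df)[1:4] <- c("query", "subject", "pident", "qcov")
  if (ncol(df) > 4) names(df)[5:ncol(df)] <- paste0("extra", seq_len(ncol(df) - 4))
  df
}

#' Apply a sample's variants to a reference genome
#'
#' Reconstructs the haplotype carried by `sample` by editing the reference
#' with every record whose genotype shows the alt allele. Alleles must be
#' explicit (sequence-resolved); records are applied right-to-left per
#' chromosome, which is exact for non-overlapping variants.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param set A biallelic [variant_set()] with explicit alleles.
#' @param sample Sample name.
#' @return Named character vector of edited chromosome sequences.
#' @export
apply_variant_set <- function(reference, set, sample) {
  stopifnot(inherits(set, "variant_set"))
  if (!(sample %in% set$samples)) {
    stop("unknown sample '", sample, "'", call. = FALSE)
  }
  out <- reference
  recs <- Filter(function(r) record_presence(r, sample) == 1L, set$records)
  if (length(recs) == 0) return(out)
  chroms <- vapply(recs, `[[`, character(1), "chrom")
  pos <- vapply(recs, `[[`, integer(1), "pos")
  for (i in order(chroms, -pos, method = "radix")) {
    r <- recs[[i]]
    if (length(r$alts) != 1L) stop("apply requires biallelic records", call. = FALSE)
    if (is_symbolic(r$alts[[1]])) {
      stop("cannot apply symbolic allele at ", r$chrom, ":", r$pos, call. = FALSE)
    }
    s <- out[[r$chrom]]
    if (substr(s, r$pos, r$pos + nchar(r$ref) - 1L) != r$ref) {
      stop("ref allele mismatch at ", r$chrom, ":", r$pos, call. = FALSE)
    }
    out[[r$chrom]] <- paste0(substr(s, 1L, r$pos - 1L), r$alts[[1]],
                             substr(s, r$pos + nchar(r$ref), nchar(s)))
  }
  out
}
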