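# Permutation test of overlap between a query region set (e.g. pangenome
# variants) and a truth region set (previously reported variants), in the
# style of regioneR's permTest/randomizeRegions/numOverlaps.
#
# Regions are 0-based half-open intervals on a named-chromosome layout.
# The statistic is "count once": the number of DISTINCT truth regions
# overlapped (>= 1 shared base) by at least one query region, so repeated
# hits on the same truth region are not overcounted.

#' Genome layout: ordered chromosome lengths
#'
#' @param lengths Named numeric vector of chromosome lengths (bases).
#' @return Named integer vector of class `genome_layout`.
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("chromosome lengths must be named", call. = FALSE)
  }
  if (anyDuplicated(names(lengths))) stop("duplicate chromosome name", call. = FALSE)
  if (any(lengths < 1)) stop("chromosome lengths must be >= 1", call. = FALSE)
  structure(setNames(as.integer(lengths), names(lengths)), class = "genome_layout")
}

#' Read a two-column chromosome-sizes ("genome") file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @return A [genome_layout()].
#' @export
read_genome_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  genome_layout(setNames(df[[2]], df[[1]]))
}

#' Construct a region set
#'
#' @param chrom Character vector of chromosome names.
#' @param start 0-based start positions.
#' @param end Exclusive end positions (`end > start`).
#' @param genome Optional [genome_layout()] for bounds checking.
#' @return Data frame of class `region_set` with columns `chrom`, `start`,
#'   `end`.
#' @export
region_set <- function(chrom = character(0), start = integer(0),
                       end = integer(0), genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("regions must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(genome)) {
    if (!all(df$chrom %in% names(genome))) {
      stop("region on a chromosome absent from the layout", call. = FALSE)
    }
    if (any(df$end > genome[df$chrom])) {
      stop("region extends past its chromosome end", call. = FALSE)
    }
  }
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file as a region set
#'
#' Uses the first three BED columns (0-based half-open, the native BED
#' convention).
#'
#' @param path Path to a BED file.
#' @param genome Optional [genome_layout()] for bounds checking.
#' @return A [region_set()].
#' @export
read_bed <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  region_set(df[[1]], df[[2]], df[[3]], genome = genome)
}

#' Write a region set as BED
#'
#' @param regions A [region_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

regions_to_granges <- function(regions, levels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(regions$chrom,
                      levels = levels %||% unique(regions$chrom)),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
}

#' Drop query regions longer than the longest truth region
#'
#' Long query regions inflate the baseline expected overlap under
#' randomization simply by their footprint, so they are removed before the
#' permutation test.
#'
#' @param query,truth [region_set()]s; `truth` must be nonempty.
#' @return Filtered query [region_set()].
#' @export
max_length_filter <- function(query, truth) {
  if (nrow(truth) == 0) stop("truth region set is empty", call. = FALSE)
  cut <- max(truth$end - truth$start)
  query[(query$end - query$start) <= cut, , drop = FALSE]
}

#' Count-once overlap statistic
#'
#' Number of distinct truth regions overlapped (sharing >= 1 base) by at
#' least one query region. Strand-free, half-open interval semantics.
#'
#' @param query,truth [region_set()]s.
#' @return Integer count in `0..nrow(truth)`.
#' @export
count_overlaps_once <- function(query, truth) {
  if (nrow(query) == 0 || nrow(truth) == 0) return(0L)
  lv <- unique(c(truth$chrom, query$chrom))
  hits <- GenomicRanges::countOverlaps(regions_to_granges(truth, lv),
                                       regions_to_granges(query, lv))
  sum(hits > 0L)
}

#' Randomly re-place regions on a genome layout
#'
#' Each region keeps its length and is placed independently: the
#' chromosome is drawn with probability proportional to the number of
#' valid start positions (length - region length + 1) among chromosomes
#' that can hold it, then the start is uniform over valid positions.
#' Placed regions may overlap each other (no masking).
#'
#' @param regions A [region_set()].
#' @param genome A [genome_layout()].
#' @param seed Optional RNG seed; when `NULL` the current RNG state is used.
#' @return A [region_set()] of the same lengths.
#' @export
randomize_regions <- function(regions, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lens <- regions$end - regions$start
  if (length(lens) > 0 && max(lens) > max(genome)) {
    stop("a region is longer than every chromosome; cannot place it",
         call. = FALSE)
  }
  chrom <- character(length(lens))
  start <- integer(length(lens))
  gl <- as.integer(genome)
  gn <- names(genome)
  for (l in unique(lens)) {  # regions of equal length share the placement law
    idx <- which(lens == l)
    slots <- gl - l + 1L
    fits <- which(slots > 0L)
    ci <- if (length(fits) == 1L) rep(fits, length(idx)) else
      sample(fits, length(idx), replace = TRUE, prob = slots[fits])
    chrom[idx] <- gn[ci]
    start[idx] <- pmin(as.integer(floor(stats::runif(length(idx)) * slots[ci])),
                       slots[ci] - 1L)
  }
  region_set(chrom, start, start + lens)
}

#' Permutation test of region-set overlap
#'
#' Compares the observed count-once overlap of `query` with `truth` to its
#' distribution over `n_perm` random re-placements of the query regions on
#' the genome layout. The +1-corrected empirical p-value is
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)` for `alternative =
#' "greater"` (mirrored for `"less"`), so the smallest attainable p at 100
#' permutations is 1/101 = 0.0099. The z-score is
#' `(observed - mean(perm)) / sd(perm)`, `NA` when the permuted values are
#' constant.
#'
#' @param query,truth [region_set()]s.
#' @param genome A [genome_layout()].
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed (required: permutations must be reproducible).
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return List of class `perm_test_result`: `observed`, `perm_values`,
#'   `mean`, `sd`, `z`, `p`, `n_perm`, `alternative`, `seed`.
#' @export
perm_test <- function(query, truth, genome, n_perm = 100L, seed,
                      alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (missing(seed) || is.null(seed)) {
    stop("perm_test requires an explicit seed", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  lv <- unique(c(truth$chrom, names(genome)))
  truth_gr <- regions_to_granges(truth, lv)
  count_vs_truth <- function(q) {
    if (nrow(q) == 0 || nrow(truth) == 0) return(0L)
    sum(GenomicRanges::countOverlaps(truth_gr, regions_to_granges(q, lv)) > 0L)
  }
  observed <- count_vs_truth(query)
  perm_values <- vapply(seq_len(n_perm), function(i) {
    count_vs_truth(randomize_regions(query, genome))
  }, integer(1))
  mu <- mean(perm_values)
  sdv <- stats::sd(perm_values)
  z <- if (!is.na(sdv) && sdv > 0) (observed - mu) / sdv else NA_real_
  p <- if (alternative == "greater") {
    (1 + sum(perm_values >= observed)) / (1 + n_perm)
  } else {
    (1 + sum(perm_values <= observed)) / (1 + n_perm)
  }
  structure(list(observed = observed, perm_values = perm_values,
                 mean = mu, sd = sdv, z = z, p = p, n_perm = n_perm,
                 alternative = alternative, seed = as.integer(seed)),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(paste0("perm_test_result: observed=%d, perm mean=%.2f sd=%.2f, ",
                     "z=%s, p=%.4f (%d permutations, alternative=%s)\n"),
              x$observed, x$mean, x$sd,
              if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
              x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Regions spanned by the variants of a set
#'
#' Converts biallelic records to 0-based half-open regions: the reference
#' footprint for deletions/inversions, a 1-bp anchor interval for
#' insertions and SNPs.
#'
#' @param set A biallelic [variant_set()].
#' @return A [region_set()].
#' @export
variant_regions <- function(set) {
  stopifnot(inherits(set, "variant_set"))
  if (length(set$records) == 0) return(region_set())
  chrom <- vapply(set$records, `[[`, character(1), "chrom")
  start <- vapply(set$records, function(r) r$pos - 1L, integer(1))
  end <- vapply(set$records, function(r) {
    if (is_symbolic(r$alts[[1]])) r$end else r$pos - 1L + nchar(r$ref)
  }, integer(1))
  region_set(chrom, start, pmax(end, start + 1L))
}
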