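# Exact canonical k-mer metrics: duplication of single-copy marker k-mers in
# a flattened graph, marker presence, and assembly representation.
#
# "Uniquely mapped" is taken as canonical-count == 1 under exact matching;
# a canonical k-mer is the lexicographic minimum of a window and its reverse
# complement, so all metrics are strand-independent. k-mers are counted
# within records only (no junction spanning), matching the per-segment
# flatten convention.

#' Count canonical k-mers of a sequence set
#'
#' Every length-`k` window of every record is canonicalized (lexicographic
#' min of the window and its reverse complement) and counted. Windows
#' containing `N` are skipped.
#'
#' @param sequences Character vector of DNA sequences (one or more records).
#' @param k K-mer length (default 21).
#' @return An object of class `kmer_counter`: list with `k` and `counts`
#'   (named integer vector, canonical k-mer -> occurrence count).
#' @export
extract_kmers <- function(sequences, k = 21L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  sequences <- vapply(as.character(sequences), check_dna, character(1))
  all_kmers <- unlist(lapply(sequences, function(s) canonical_windows(s, k)),
                      use.names = FALSE)
  counts <- if (length(all_kmers) == 0) {
    integer(0)
  } else {
    tab <- table(all_kmers)
    setNames(as.integer(tab), names(tab))
  }
  structure(list(k = k, counts = counts), class = "kmer_counter")
}

# All canonical k-mer windows of one sequence, N-windows dropped.
canonical_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(s, starts, starts + k - 1L)
  rc <- revcomp(s)
  # reverse complement of window i is window (n - k + 2 - i) of revcomp(s)
  rev_windows <- substring(rc, starts, starts + k - 1L)[rev(seq_along(starts))]
  keep <- !grepl("N", fwd, fixed = TRUE)
  pmin(fwd[keep], rev_windows[keep])
}

#' @export
print.kmer_counter <- function(x, ...) {
  cat(sprintf("kmer_counter: k=%d, %d distinct canonical k-mers (%d total)\n",
              x$k, length(x$counts), sum(x$counts)))
  invisible(x)
}

# Canonical count of a fixed set of k-mers inside a sequence set.
kmer_counts_in <- function(kmers, sequences, k) {
  counter <- extract_kmers(sequences, k)
  out <- counter$counts[kmers]
  out[is.na(out)] <- 0L
  setNames(as.integer(out), kmers)
}

#' Universal single-copy filter for marker k-mers
#'
#' Retains the marker k-mers whose canonical count is exactly 1 in every
#' input assembly; absence from any assembly, or multiplicity anywhere,
#' excludes a k-mer. These "universally unique" k-mers are the probes for
#' [duplication_report()].
#'
#' @param marker_kmers A `kmer_counter` built from marker sequences, or a
#'   character vector of canonical k-mers.
#' @param assemblies Nonempty list of sequence sets (named character
#'   vectors), one per input assembly.
#' @param k K-mer length; defaults to the counter's `k`.
#' @return Character vector of retained canonical k-mers.
#' @export
universal_unique_filter <- function(marker_kmers, assemblies, k = NULL) {
  if (inherits(marker_kmers, "kmer_counter")) {
    k <- k %||% marker_kmers$k
    kmers <- names(marker_kmers$counts)
  } else {
    kmers <- as.character(marker_kmers)
    if (is.null(k)) k <- nchar(kmers[1])
  }
  if (!is.list(assemblies) || length(assemblies) == 0) {
    stop("'assemblies' must be a nonempty list of sequence sets", call. = FALSE)
  }
  keep <- rep(TRUE, length(kmers))
  for (asm in assemblies) {
    counts <- kmer_counts_in(kmers, asm, k)
    keep <- keep & counts == 1L
    if (!any(keep)) break
  }
  kmers[keep]
}

#' Classify universal marker k-mers in a target sequence set
#'
#' Each universally unique marker k-mer is classified by its canonical count
#' summed over the target records: `unique` (count 1), `multi` (count > 1)
#' or `absent` (count 0). The multi fraction measures sequence duplication
#' in the target (e.g. a flattened pangenome graph); the absent fraction
#' measures loss.
#'
#' @param universal_kmers Nonempty character vector of canonical k-mers
#'   (from [universal_unique_filter()]).
#' @param target Sequence set to assess (e.g. [flatten_graph()] output).
#' @param k K-mer length.
#' @return A one-row data frame: `n_kmers_universal_unique`, `n_unique`,
#'   `n_multi`, `n_absent`, `fraction_unique`, `fraction_multi`,
#'   `fraction_absent` (fractions sum to 1).
#' @export
duplication_report <- function(universal_kmers, target, k = 21L) {
  universal_kmers <- as.character(universal_kmers)
  if (length(universal_kmers) == 0) {
    stop("empty universal k-mer set: duplication fractions are undefined",
         call. = FALSE)
  }
  counts <- kmer_counts_in(universal_kmers, target, k)
  n <- length(counts)
  n_unique <- sum(counts == 1L)
  n_multi <- sum(counts > 1L)
  n_absent <- sum(counts == 0L)
  data.frame(
    n_kmers_universal_unique = n,
    n_unique = n_unique, n_multi = n_multi, n_absent = n_absent,
    fraction_unique = n_unique / n,
    fraction_multi = n_multi / n,
    fraction_absent = n_absent / n)
}

#' Marker presence by shared k-mer fraction
#'
#' A marker is called present in a sample sequence when at least
#' `presence_threshold` of its distinct canonical k-mers occur (count >= 1)
#' in the sample. This is a k-mer substitute for gene lifting: markers whose
#' sequence is largely missing from a reconstructed assembly are reported
#' as missing genes.
#'
#' @param markers Named character vector of marker sequences.
#' @param sample_sequence DNA string (or sequence set) to screen.
#' @param k K-mer length.
#' @param presence_threshold Required fraction of marker k-mers, in (0, 1].
#' @return Data frame with columns `marker`, `n_kmers`, `n_present`,
#'   `fraction_present`, `status` (`"present"`/`"missing"`). Markers shorter
#'   than `k` are skipped with a warning.
#' @export
marker_presence <- function(markers, sample_sequence, k = 21L,
                            presence_threshold = 0.8) {
  if (!(presence_threshold > 0 && presence_threshold <= 1)) {
    stop("presence_threshold must be in (0, 1]", call. = FALSE)
  }
  if (is.null(names(markers))) names(markers) <- paste0("marker_", seq_along(markers))
  short <- nchar(markers) < k
  if (any(short)) {
    warning("skipping marker(s) shorter than k: ",
            paste(names(markers)[short], collapse = ", "), call. = FALSE)
    markers <- markers[!short]
  }
  sample_kmers <- names(extract_kmers(sample_sequence, k)$counts)
  rows <- lapply(names(markers), function(id) {
    mk <- unique(names(extract_kmers(markers[[id]], k)$counts))
    npres <- sum(mk %in% sample_kmers)
    frac <- if (length(mk) > 0) npres / length(mk) else 0
    data.frame(marker = id, n_kmers = length(mk), n_present = npres,
               fraction_present = frac,
               status = if (frac >= presence_threshold) "present" else "missing")
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(marker = character(0), n_kmers = integer(0),
                      n_present = integer(0), fraction_present = numeric(0),
                      status = character(0))
  }
  out
}

#' Representation of an assembly inside a graph path
#'
#' Fraction of the assembly's distinct canonical k-mers that occur in the
#' path sequence reconstructed from the graph — a k-mer containment
#' substitute for alignment coverage of the assembly against the graph.
#'
#' @param assembly Sequence set of the input assembly.
#' @param path_seq Sequence (set) reconstructed from the graph.
#' @param k K-mer length.
#' @return Proportion in \[0, 1\].
#' @export
assembly_representation <- function(assembly, path_seq, k = 21L) {
  asm_kmers <- names(extract_kmers(assembly, k)$counts)
  if (length(asm_kmers) == 0) {
    stop("assembly yields no k-mers at k=", k, call. = FALSE)
  }
  path_kmers <- names(extract_kmers(path_seq, k)$counts)
  mean(asm_kmers %in% path_kmers)
}
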