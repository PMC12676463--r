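# Truth-vs-call SV benchmarking and multi-callset merging.
#
# Matching follows the usual SV-benchmarking recipe (defaults mirror
# Truvari 4.x: refdist 500, size similarity 0.7, sequence similarity 0.7,
# sizemin 50): candidate pairs must share chromosome and type class, lie
# within refdist, and pass size (and, for sequence-resolved insertions,
# sequence) similarity; greedy one-to-one assignment in ascending
# (distance, 1 - size similarity) order. A single TP count replaces the
# separate TP-base/TP-call bookkeeping of alignment-based tools.

#' Matching parameters for SV benchmarking
#'
#' @param refdist Maximum start-position distance in bases (default 500).
#' @param min_size_sim Minimum size similarity min(l1,l2)/max(l1,l2)
#'   (default 0.7).
#' @param min_seq_sim Minimum sequence similarity, applied only when both
#'   alleles are sequence-resolved insertions (default 0.7).
#' @param sizemin Minimum |length change| for a record to enter the
#'   comparison (default 50).
#' @return List of class `match_params`.
#' @export
match_params <- function(refdist = 500L, min_size_sim = 0.7,
                         min_seq_sim = 0.7, sizemin = 50L) {
  stopifnot(refdist >= 0, sizemin >= 0,
            min_size_sim >= 0, min_size_sim <= 1,
            min_seq_sim >= 0, min_seq_sim <= 1)
  structure(list(refdist = as.integer(refdist), min_size_sim = min_size_sim,
                 min_seq_sim = min_seq_sim, sizemin = as.integer(sizemin)),
            class = "match_params")
}

# Coarse type class used for match compatibility.
type_class <- function(vtype) {
  switch(vtype,
         INS = , SV_INS = "INS",
         DEL = , SV_DEL = "DEL",
         SNP = "SNP", MNP = "MNP",
         "OTHER")
}

sv_size <- function(rec) abs(rec$svlen[[1]])

size_similarity <- function(a, b) {
  if (a == 0 && b == 0) return(1)
  min(a, b) / max(a, b)
}

# 1 - normalized edit distance between inserted sequences; NA when either
# allele is symbolic (the criterion is then skipped).
ins_seq_similarity <- function(r1, r2) {
  if (is_symbolic(r1$alts[[1]]) || is_symbolic(r2$alts[[1]])) return(NA_real_)
  s1 <- substring(r1$alts[[1]], 2L)  # drop the anchor base
  s2 <- substring(r2$alts[[1]], 2L)
  if (!nzchar(s1) && !nzchar(s2)) return(1)
  d <- utils::adist(s1, s2)[1, 1]
  1 - d / max(nchar(s1), nchar(s2))
}

bench_fields <- function(set, params, what) {
  stopifnot(inherits(set, "variant_set"))
  vt <- vapply(set$records, function(r) r$vtype %||% NA_character_, character(1))
  if (anyNA(vt)) {
    stop(what, " set has unclassified records; run classify_set() first",
         call. = FALSE)
  }
  if (any(vapply(set$records, function(r) length(r$alts), integer(1)) != 1L)) {
    stop(what, " set must be biallelic; run split_multiallelic_set() first",
         call. = FALSE)
  }
  size <- vapply(set$records, sv_size, numeric(1))
  keep <- size >= params$sizemin
  data.frame(idx = which(keep),
             chrom = vapply(set$records[keep], `[[`, character(1), "chrom"),
             pos = vapply(set$records[keep], `[[`, integer(1), "pos"),
             class = vapply(vt[keep], type_class, character(1)),
             size = size[keep], stringsAsFactors = FALSE)
}

#' Benchmark a call set against a truth set
#'
#' Greedy one-to-one matching of calls to truth records under
#' [match_params()]; matched pairs are true positives, unmatched calls
#' false positives, unmatched truth records false negatives.
#'
#' @param calls,truth Classified biallelic [variant_set()]s.
#' @param params A [match_params()].
#' @return List of class `bench_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `matches` (data frame of matched index pairs),
#'   `call_labels` and `truth_labels` (`"TP"`/`"FP"`/`"FN"` per record of
#'   the size-eligible subsets).
#' @export
match_sets <- function(calls, truth, params = match_params()) {
  cf <- bench_fields(calls, params, "calls")
  tf <- bench_fields(truth, params, "truth")
  cand <- NULL
  if (nrow(cf) > 0 && nrow(tf) > 0) {
    pairs <- expand.grid(ci = seq_len(nrow(cf)), ti = seq_len(nrow(tf)))
    ok <- cf$chrom[pairs$ci] == tf$chrom[pairs$ti] &
      cf$class[pairs$ci] == tf$class[pairs$ti] &
      abs(cf$pos[pairs$ci] - tf$pos[pairs$ti]) <= params$refdist
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs) > 0) {
      ssim <- mapply(function(ci, ti) size_similarity(cf$size[ci], tf$size[ti]),
                     pairs$ci, pairs$ti)
      pairs <- pairs[ssim >= params$min_size_sim, , drop = FALSE]
      ssim <- ssim[ssim >= params$min_size_sim]
      if (nrow(pairs) > 0) {
        qsim <- mapply(function(ci, ti) {
          if (cf$class[ci] != "INS") return(NA_real_)
          ins_seq_similarity(calls$records[[cf$idx[ci]]],
                             truth$records[[tf$idx[ti]]])
        }, pairs$ci, pairs$ti)
        drop <- !is.na(qsim) & qsim < params$min_seq_sim
        pairs <- pairs[!drop, , drop = FALSE]
        ssim <- ssim[!drop]
      }
      if (nrow(pairs) > 0) {
        dist <- abs(cf$pos[pairs$ci] - tf$pos[pairs$ti])
        ord <- order(dist, 1 - ssim, pairs$ci, pairs$ti, method = "radix")
        cand <- pairs[ord, , drop = FALSE]
      }
    }
  }
  call_matched <- rep(FALSE, nrow(cf))
  truth_matched <- rep(FALSE, nrow(tf))
  matches <- list()
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      ci <- cand$ci[r]; ti <- cand$ti[r]
      if (!call_matched[ci] && !truth_matched[ti]) {
        call_matched[ci] <- TRUE
        truth_matched[ti] <- TRUE
        matches[[length(matches) + 1L]] <-
          data.frame(call_idx = cf$idx[ci], truth_idx = tf$idx[ti])
      }
    }
  }
  tp <- sum(call_matched)
  fp <- sum(!call_matched)
  fn <- sum(!truth_matched)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    matches = if (length(matches)) do.call(rbind, matches) else
      data.frame(call_idx = integer(0), truth_idx = integer(0)),
    call_labels = ifelse(call_matched, "TP", "FP"),
    truth_labels = ifelse(truth_matched, "TP", "FN")),
    class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("bench_result: TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Clustering parameters for multi-callset merging
#'
#' @param max_dist Maximum start distance for linking two records
#'   (default 1000).
#' @param min_size_sim Minimum size similarity for linking (default 0.7).
#' @param require_same_type Link only records of the same type class
#'   (default TRUE).
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(max_dist = 1000L, min_size_sim = 0.7,
                           require_same_type = TRUE) {
  stopifnot(max_dist >= 0, min_size_sim >= 0, min_size_sim <= 1)
  structure(list(max_dist = as.integer(max_dist), min_size_sim = min_size_sim,
                 require_same_type = isTRUE(require_same_type)),
            class = "cluster_params")
}

#' Merge variant records across call sets by single-linkage clustering
#'
#' Records from all sets are pooled per chromosome and linked when they lie
#' within `max_dist`, pass size similarity, and (optionally) share a type
#' class; connected components form merged clusters, each annotated with
#' the input sets that support it.
#'
#' @param sets Named list of >= 2 classified biallelic [variant_set()]s.
#' @param params A [cluster_params()].
#' @return Data frame with one row per record: `set`, `record_idx`,
#'   `chrom`, `pos`, `class`, `size`, `cluster`.
#' @export
cluster_multisets <- function(sets, params = cluster_params()) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets))) {
    stop("'sets' must be a named list of >= 2 variant sets", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (length(s$records) == 0) return(NULL)
    data.frame(
      set = nm,
      record_idx = seq_along(s$records),
      chrom = vapply(s$records, `[[`, character(1), "chrom"),
      pos = vapply(s$records, `[[`, integer(1), "pos"),
      class = vapply(s$records, function(r) {
        if (is.na(r$vtype %||% NA_character_)) {
          stop("set '", nm, "' has unclassified records", call. = FALSE)
        }
        type_class(r$vtype)
      }, character(1)),
      size = vapply(s$records, sv_size, numeric(1)),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(set = character(0), record_idx = integer(0),
                      chrom = character(0), pos = integer(0),
                      class = character(0), size = numeric(0),
                      cluster = integer(0)))
  }
  n <- nrow(rows)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (chr in unique(rows$chrom)) {
    idx <- which(rows$chrom == chr)
    idx <- idx[order(rows$pos[idx])]
    for (a in seq_along(idx)) {
      for (b in seq_len(length(idx) - a)) {
        i <- idx[a]; j <- idx[a + b]
        if (rows$pos[j] - rows$pos[i] > params$max_dist) break
        if (params$require_same_type && rows$class[i] != rows$class[j]) next
        if (size_similarity(rows$size[i], rows$size[j]) < params$min_size_sim) next
        link(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  rows$cluster <- match(roots, unique(roots))
  rows
}

#' Intersection (UpSet) table of merged clusters
#'
#' Counts clusters per exact support signature (the sorted set of input
#' call sets contributing at least one record). Counts sum to the number
#' of clusters.
#'
#' @param clusters Data frame from [cluster_multisets()].
#' @return Data frame with columns `signature` (set names joined by `&`),
#'   `n_sets`, `n_clusters`, sorted by decreasing count.
#' @export
intersection_counts <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(data.frame(signature = character(0), n_sets = integer(0),
                      n_clusters = integer(0)))
  }
  sigs <- vapply(split(clusters$set, clusters$cluster), function(s) {
    paste(sort(unique(s)), collapse = "&")
  }, character(1))
  tab <- table(sigs)
  out <- data.frame(signature = names(tab),
                    n_sets = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    n_clusters = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n_clusters, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
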