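# Node-coverage and pangenome growth/core curves under coverage/quorum
# thresholds, in the style of Panacus.
#
# Coverage of a node = number of distinct SAMPLES whose paths traverse it
# (haplotype paths are grouped by the PanSN sample prefix, so a diploid
# sample counts once). A node "qualifies" at subset size m under threshold
# (c, q) when it is carried by at least t(m) = max(c, ceil(q*m), 1) of the
# m drawn samples. The exact growth curve is the expectation of the
# qualifying-node count over a uniformly random m-subset of samples, which
# reduces to hypergeometric tail probabilities per coverage level.

#' Per-node sample coverage of a pangenome graph
#'
#' @param graph A [pangenome_graph()] with at least one path.
#' @param exclude_samples Sample names whose paths are ignored (e.g. a
#'   reference backbone that is not a study haplotype).
#' @return An object of class `coverage_map`: list with `coverage` (named
#'   integer vector per segment), `bp` (segment lengths), `n_samples`, and
#'   `samples`.
#' @export
node_sample_coverage <- function(graph, exclude_samples = character(0)) {
  stopifnot(inherits(graph, "pangenome_graph"))
  paths <- Filter(function(p) !(p$sample %in% exclude_samples), graph$paths)
  if (length(paths) == 0) {
    stop("graph has no (non-excluded) paths; coverage is undefined", call. = FALSE)
  }
  samples <- unique(vapply(paths, `[[`, character(1), "sample"))
  ids <- names(graph$segments)
  cov <- setNames(integer(length(ids)), ids)
  for (s in samples) {
    segs <- unique(unlist(lapply(paths[vapply(paths, `[[`, character(1), "sample") == s],
                                 `[[`, "seg"), use.names = FALSE))
    cov[segs] <- cov[segs] + 1L
  }
  structure(list(coverage = cov,
                 bp = setNames(nchar(graph$segments), ids),
                 n_samples = length(samples), samples = samples),
            class = "coverage_map")
}

#' Node-coverage histogram
#'
#' Tally of nodes (and base pairs) per coverage level, including an explicit
#' 0 bin for nodes on no path.
#'
#' @param cov A `coverage_map` from [node_sample_coverage()].
#' @return Data frame with columns `coverage`, `n_nodes`, `bp`, covering
#'   levels 0..n_samples.
#' @export
coverage_histogram <- function(cov) {
  stopifnot(inherits(cov, "coverage_map"))
  levels <- 0:cov$n_samples
  n_nodes <- vapply(levels, function(l) sum(cov$coverage == l), integer(1))
  bp <- vapply(levels, function(l) sum(cov$bp[cov$coverage == l]), numeric(1))
  data.frame(coverage = levels, n_nodes = n_nodes, bp = bp)
}

# Qualification threshold at subset size m for coverage c and quorum q.
growth_threshold <- function(c_min, quorum, m) {
  pmax(c_min, ceiling(quorum * m - 1e-9), 1L)
}

#' Pangenome growth curve under a coverage/quorum threshold
#'
#' For each subset size m in 1..n_samples, the expected number of nodes
#' (and bp) qualifying among a uniformly random m-subset of samples. A node
#' with coverage k qualifies when at least `t(m) = max(c, ceil(q*m), 1)` of
#' the m drawn samples carry it; the number of carriers drawn is
#' hypergeometric, so exact mode sums `P[Hyper(n, k, m) >= t(m)]` over
#' nodes. Monte-Carlo mode averages qualifying counts over random sample
#' orderings instead.
#'
#' The classical special cases: `c=1, q=0` is the pangenome (union) curve
#' and `c=1, q=1` is the core curve.
#'
#' @param cov A `coverage_map` from [node_sample_coverage()].
#' @param coverage Integer coverage threshold c >= 0.
#' @param quorum Quorum fraction q in \[0, 1\].
#' @param mode `"exact"` (hypergeometric expectation) or `"montecarlo"`.
#' @param n_reps Number of random orderings for Monte-Carlo mode.
#' @param seed RNG seed, required for Monte-Carlo mode.
#' @return Data frame with columns `m`, `coverage_threshold`, `quorum`,
#'   `expected_nodes`, `expected_bp` (plus `mc_se`, the Monte-Carlo standard
#'   error of `expected_nodes`, in `"montecarlo"` mode).
#' @export
growth_curve <- function(cov, coverage = 1L, quorum = 0,
                         mode = c("exact", "montecarlo"),
                         n_reps = 1000L, seed = NULL) {
  stopifnot(inherits(cov, "coverage_map"))
  mode <- match.arg(mode)
  c_min <- as.integer(coverage)
  if (is.na(c_min) || c_min < 0) stop("coverage threshold must be >= 0", call. = FALSE)
  if (!(quorum >= 0 && quorum <= 1)) stop("quorum must be in [0, 1]", call. = FALSE)
  n <- cov$n_samples
  ms <- seq_len(n)
  if (c_min > n && quorum == 0) {
    warning("coverage threshold exceeds the number of samples; curve is zero",
            call. = FALSE)
  }
  if (mode == "exact") {
    exp_nodes <- exp_bp <- numeric(n)
    cov_levels <- sort(unique(cov$coverage))
    n_at <- vapply(cov_levels, function(l) sum(cov$coverage == l), numeric(1))
    bp_at <- vapply(cov_levels, function(l) sum(cov$bp[cov$coverage == l]), numeric(1))
    for (m in ms) {
      t_m <- growth_threshold(c_min, quorum, m)
      # P[X >= t] for X ~ Hypergeometric(successes k, failures n-k, draws m)
      p_qual <- stats::phyper(t_m - 1L, cov_levels, n - cov_levels, m,
                              lower.tail = FALSE)
      exp_nodes[m] <- sum(n_at * p_qual)
      exp_bp[m] <- sum(bp_at * p_qual)
    }
  } else {
    if (is.null(seed)) stop("montecarlo mode requires a seed", call. = FALSE)
    if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
    set.seed(as.integer(seed))
    t_vec <- growth_threshold(c_min, quorum, ms)
    # membership matrix: node x sample
    paths_by_sample <- cov$samples
    acc_nodes <- acc_bp <- matrix(0, nrow = n_reps, ncol = n)
    # carriers per node among first m samples of a random ordering
    memb <- attr(cov, "membership")
    if (is.null(memb)) {
      stop("coverage_map lacks per-sample membership; build it with ",
           "node_sample_coverage()", call. = FALSE)
    }
    for (r in seq_len(n_reps)) {
      ord <- sample.int(n)
      cum <- t(apply(memb[, ord, drop = FALSE], 1L, cumsum))
      qual <- sweep(cum, 2L, t_vec, ">=")
      acc_nodes[r, ] <- colSums(qual)
      acc_bp[r, ] <- colSums(qual * cov$bp)
    }
    exp_nodes <- colMeans(acc_nodes)
    exp_bp <- colMeans(acc_bp)
    mc_se <- apply(acc_nodes, 2L, stats::sd) / sqrt(n_reps)
  }
  out <- data.frame(m = ms, coverage_threshold = c_min, quorum = quorum,
                    expected_nodes = exp_nodes, expected_bp = exp_bp)
  if (mode == "montecarlo") out$mc_se <- mc_se
  out
}

#' Growth curves for a set of coverage/quorum specifications
#'
#' @param graph A [pangenome_graph()].
#' @param specs Character vector of `"c/q"` pairs, defaulting to the five
#'   standard thresholds: pangenome `1/0`, two-copy `2/0`, core `1/1`,
#'   and soft thresholds `1/0.5`, `1/0.1`.
#' @param exclude_samples Passed to [node_sample_coverage()].
#' @inheritParams growth_curve
#' @return Row-bound data frame of [growth_curve()] results, one block per
#'   spec, with a `spec` column.
#' @export
growth_curves <- function(graph, specs = c("1/0", "2/0", "1/1", "1/0.5", "1/0.1"),
                          exclude_samples = character(0),
                          mode = "exact", n_reps = 1000L, seed = NULL) {
  cov <- node_sample_coverage(graph, exclude_samples = exclude_samples)
  if (mode == "montecarlo") cov <- add_membership(cov, graph, exclude_samples)
  parsed <- parse_growth_specs(specs)
  out <- lapply(seq_len(nrow(parsed)), function(i) {
    gc <- growth_curve(cov, parsed$coverage[i], parsed$quorum[i],
                       mode = mode, n_reps = n_reps, seed = seed)
    cbind(spec = specs[i], gc)
  })
  do.call(rbind, out)
}

parse_growth_specs <- function(specs) {
  parts <- strsplit(specs, "/", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("growth spec must look like 'c/q': ", specs[bad][1], call. = FALSE)
  data.frame(coverage = as.integer(vapply(parts, `[[`, character(1), 1)),
             quorum = as.numeric(vapply(parts, `[[`, character(1), 2)))
}

# Attach the node x sample membership matrix needed by Monte-Carlo mode.
add_membership <- function(cov, graph, exclude_samples = character(0)) {
  paths <- Filter(function(p) !(p$sample %in% exclude_samples), graph$paths)
  memb <- matrix(FALSE, nrow = length(cov$coverage), ncol = cov$n_samples,
                 dimnames = list(names(cov$coverage), cov$samples))
  for (p in paths) memb[unique(p$seg), p$sample] <- TRUE
  attr(cov, "membership") <- memb
  cov
}
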