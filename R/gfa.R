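# GFA1 pangenome-graph model: parse, validate, write, summarize, flatten.
#
# A pangenome_graph holds blunt-ended GFA1 content:
#   segments: named character vector, id -> uppercase DNA sequence
#   links:    data.frame(from, from_orient, to, to_orient, overlap)
#   paths:    list of path records: list(name, sample, seg, orient)
# Only "0M"/"*" overlaps are accepted: the graph builders this toolkit
# evaluates emit blunt-ended graphs, and nonzero overlaps would break the
# identity "path sequence = concatenation of oriented segment sequences".

#' Construct a pangenome graph object
#'
#' @param segments Named character vector of segment sequences (A/C/G/T/N).
#' @param links Data frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`, `overlap`. Defaults to no links.
#' @param paths List of path records, each a list with `name` (character),
#'   `seg` (character vector of segment ids) and `orient` (matching vector of
#'   `"+"`/`"-"`). The per-path `sample` field is derived from the name
#'   (PanSN convention: text before the first `#`; names without `#` are
#'   their own sample).
#' @return An object of class `pangenome_graph`.
#' @export
pangenome_graph <- function(segments = character(0), links = empty_links(),
                            paths = list()) {
  segments <- vapply(segments, check_dna, character(1), what = "segment sequence")
  ids <- names(segments)
  if (length(segments) > 0 && (is.null(ids) || any(!nzchar(ids)))) {
    stop("every segment needs a nonempty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate segment id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (any(nchar(segments) < 1L)) {
    stop("segment sequences must have length >= 1", call. = FALSE)
  }
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  needed <- c("from", "from_orient", "to", "to_orient", "overlap")
  if (!all(needed %in% names(links))) {
    stop("links must have columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  for (col in needed) links[[col]] <- as.character(links[[col]])
  unknown <- setdiff(c(links$from, links$to), ids)
  if (length(unknown) > 0) {
    stop("link references unknown segment: ", unknown[1], call. = FALSE)
  }
  if (!all(links$overlap %in% c("0M", "*"))) {
    stop("only blunt-ended links (overlap '0M' or '*') are supported", call. = FALSE)
  }
  paths <- lapply(paths, function(p) {
    if (is.null(p$name) || !nzchar(p$name)) stop("path without a name", call. = FALSE)
    if (length(p$seg) == 0) stop("path '", p$name, "' has no steps", call. = FALSE)
    if (length(p$seg) != length(p$orient)) {
      stop("path '", p$name, "': seg/orient length mismatch", call. = FALSE)
    }
    if (!all(p$orient %in% c("+", "-"))) {
      stop("path '", p$name, "': orientation must be '+' or '-'", call. = FALSE)
    }
    miss <- setdiff(p$seg, ids)
    if (length(miss) > 0) {
      stop("path '", p$name, "' references unknown segment: ", miss[1], call. = FALSE)
    }
    list(name = p$name, sample = sample_of_path(p$name),
         seg = as.character(p$seg), orient = as.character(p$orient))
  })
  pnames <- vapply(paths, `[[`, character(1), "name")
  if (anyDuplicated(pnames)) {
    stop("duplicate path name: ", pnames[duplicated(pnames)][1], call. = FALSE)
  }
  names(paths) <- pnames
  structure(list(segments = segments, links = links, paths = paths),
            class = "pangenome_graph")
}

empty_links <- function() {
  data.frame(from = character(0), from_orient = character(0),
             to = character(0), to_orient = character(0),
             overlap = character(0), stringsAsFactors = FALSE)
}

# PanSN sample naming: "sample#haplotype#chrom" -> "sample".
sample_of_path <- function(name) sub("#.*$", "", name)

#' Parse a GFA1 graph
#'
#' Recognizes H/S/L/P lines; W (walk) lines are converted to equivalent
#' paths named `sample#haplotype#seqid`; other line types are skipped with a
#' warning. Lowercase sequence is uppercased on ingest.
#'
#' @param x Path to a GFA file, or a character vector of GFA lines.
#' @return A [pangenome_graph()].
#' @export
parse_gfa <- function(x) {
  lines <- if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(lines)]
  seg_ids <- character(0); seg_seqs <- character(0)
  link_rows <- list(); path_recs <- list()
  skipped <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    type <- f[[1]]
    if (type == "H") next
    if (type == "S") {
      if (length(f) < 3) stop("line ", i, ": malformed S line (need id and sequence)", call. = FALSE)
      if (f[2] %in% seg_ids) stop("line ", i, ": duplicate segment id '", f[2], "'", call. = FALSE)
      seg_ids <- c(seg_ids, f[2]); seg_seqs <- c(seg_seqs, f[3])
    } else if (type == "L") {
      if (length(f) < 6) stop("line ", i, ": malformed L line (need 6 fields)", call. = FALSE)
      link_rows[[length(link_rows) + 1L]] <-
        data.frame(from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
                   overlap = f[6], stringsAsFactors = FALSE)
    } else if (type == "P") {
      if (length(f) < 3) stop("line ", i, ": malformed P line (need name and steps)", call. = FALSE)
      steps <- strsplit(f[3], ",", fixed = TRUE)[[1]]
      ok <- grepl("^.+[+-]$", steps)
      if (length(steps) == 0 || !all(ok)) {
        stop("line ", i, ": malformed P-line step list", call. = FALSE)
      }
      path_recs[[length(path_recs) + 1L]] <- list(
        name = f[2],
        seg = sub("[+-]$", "", steps),
        orient = substr(steps, nchar(steps), nchar(steps)))
    } else if (type == "W") {
      if (length(f) < 7) stop("line ", i, ": malformed W line (need 7 fields)", call. = FALSE)
      walk <- f[7]
      toks <- regmatches(walk, gregexpr("[><][^><]+", walk))[[1]]
      if (length(toks) == 0) stop("line ", i, ": malformed walk string", call. = FALSE)
      path_recs[[length(path_recs) + 1L]] <- list(
        name = paste(f[2], f[3], f[4], sep = "#"),
        seg = substring(toks, 2L),
        orient = ifelse(substr(toks, 1L, 1L) == ">", "+", "-"))
    } else {
      skipped <- c(skipped, type)
    }
  }
  if (length(skipped) > 0) {
    warning("ignored GFA line type(s): ", paste(unique(skipped), collapse = ", "),
            call. = FALSE)
  }
  names(seg_seqs) <- seg_ids
  links <- if (length(link_rows) > 0) do.call(rbind, link_rows) else empty_links()
  pangenome_graph(segments = seg_seqs, links = links, paths = path_recs)
}

#' Serialize a pangenome graph to GFA1 text
#'
#' Output is deterministic: an `H` header, S lines in natural id order,
#' L lines in input order, then P lines. `parse_gfa(write_gfa(g))` is
#' structurally identical to `g`.
#'
#' @param graph A [pangenome_graph()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of GFA lines (invisibly when `path` is given).
#' @export
write_gfa <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pangenome_graph"))
  ord <- natural_order(names(graph$segments))
  out <- "H\tVN:Z:1.0"
  if (length(graph$segments) > 0) {
    out <- c(out, sprintf("S\t%s\t%s", names(graph$segments)[ord],
                          unname(graph$segments)[ord]))
  }
  if (nrow(graph$links) > 0) {
    out <- c(out, sprintf("L\t%s\t%s\t%s\t%s\t%s", graph$links$from,
                          graph$links$from_orient, graph$links$to,
                          graph$links$to_orient, graph$links$overlap))
  }
  for (p in graph$paths) {
    out <- c(out, sprintf("P\t%s\t%s\t*", p$name,
                          paste0(p$seg, p$orient, collapse = ",")))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Summary statistics of a pangenome graph
#'
#' Node, edge and path counts plus a segment-length summary. Empty graphs
#' yield zeros (mean 0 by convention).
#'
#' @param graph A [pangenome_graph()].
#' @return A one-row data frame with columns `n_segments`, `n_links`,
#'   `n_paths`, `total_bp`, `mean_segment_len`, `min_segment_len`,
#'   `max_segment_len`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "pangenome_graph"))
  lens <- nchar(graph$segments)
  n <- length(lens)
  data.frame(
    n_segments = n,
    n_links = nrow(graph$links),
    n_paths = length(graph$paths),
    total_bp = if (n > 0) sum(lens) else 0L,
    mean_segment_len = if (n > 0) mean(lens) else 0,
    min_segment_len = if (n > 0) min(lens) else 0L,
    max_segment_len = if (n > 0) max(lens) else 0L)
}

#' Reconstruct the DNA sequence spelled by a path
#'
#' Concatenates segment sequences in step order, reverse-complementing
#' segments traversed in `-` orientation.
#'
#' @param graph A [pangenome_graph()].
#' @param path_name Name of a path in the graph.
#' @return A single DNA string.
#' @export
path_sequence <- function(graph, path_name) {
  stopifnot(inherits(graph, "pangenome_graph"))
  p <- graph$paths[[path_name]]
  if (is.null(p)) stop("no path named '", path_name, "' in graph", call. = FALSE)
  pieces <- unname(graph$segments[p$seg])
  neg <- p$orient == "-"
  if (any(neg)) pieces[neg] <- revcomp(pieces[neg])
  paste(pieces, collapse = "")
}

#' Flatten a graph to per-segment FASTA records
#'
#' One record per segment (id = segment id), ordered by natural sort of ids.
#' Segments are kept as separate records rather than concatenated, so no
#' spurious k-mers spanning segment junctions are created downstream.
#'
#' @param graph A [pangenome_graph()].
#' @param path Optional FASTA output path.
#' @return Named character vector of segment sequences (the FASTA records).
#' @export
flatten_graph <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pangenome_graph"))
  recs <- graph$segments[natural_order(names(graph$segments))]
  if (!is.null(path)) {
    write_fasta(recs, path)
    return(invisible(recs))
  }
  recs
}

#' @export
print.pangenome_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf("pangenome_graph: %d segments (%d bp), %d links, %d paths\n",
              s$n_segments, s$total_bp, s$n_links, s$n_paths))
  if (length(x$paths) > 0) {
    cat("  samples:", paste(unique(vapply(x$paths, `[[`, character(1), "sample")),
                            collapse = ", "), "\n")
  }
  invisible(x)
}
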