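# Synthetic variation-graph generator: a random reference, haplotypes with
# implanted SNPs/indels/SVs under a controlled sharing model, the matching
# bubble graph with one path per sample plus a reference path, a truth VCF,
# and single-copy marker genes with an optional planted duplication.
#
# Variants are placed non-overlapping with a guard gap (default k+1 = 22)
# so that bubble construction is well-defined, truth/graph correspondence
# is exact, and k-mer windows of distinct variants never interact. All
# randomness flows from the single seed in the config.

#' Configuration for the synthetic pangenome generator
#'
#' Defaults emulate the evaluated study design at desk scale: six sample
#' haplotypes over a two-chromosome reference, structural variants
#' exceeding 100 bp, and per-variant carrier counts drawn uniformly over
#' 1..n_samples.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_len Chromosome length in bases (default 20000).
#' @param gc GC content of the simulated reference (default 0.44).
#' @param n_samples Number of sample haplotypes (default 6).
#' @param n_snp,n_multiallelic_snp,n_small_indel,n_del,n_ins,n_inv,n_dup
#'   Variant counts per class (biallelic SNPs, multiallelic SNP sites,
#'   2-10 bp indels, large deletions, large insertions, inversions, tandem
#'   duplications).
#' @param small_indel_range,del_range,ins_range,inv_range,dup_range
#'   Length ranges (bases) per class; SV ranges default to 101-300 so every
#'   SV exceeds the 100 bp simulation cut.
#' @param carrier_weights Optional weight vector over carrier counts
#'   1..n_samples (default uniform).
#' @param guard_gap Minimum spacing between variant footprints (default 22,
#'   i.e. k+1 for the default k = 21).
#' @param n_markers,marker_len,n_dup_markers Marker-gene count, length and
#'   number of markers duplicated in the duplication target.
#' @param seed Mandatory RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_len = 20000L, gc = 0.44,
                       n_samples = 6L,
                       n_snp = 20L, n_multiallelic_snp = 2L,
                       n_small_indel = 8L, n_del = 4L, n_ins = 4L,
                       n_inv = 2L, n_dup = 2L,
                       small_indel_range = c(2L, 10L),
                       del_range = c(101L, 300L), ins_range = c(101L, 300L),
                       inv_range = c(101L, 250L), dup_range = c(101L, 250L),
                       carrier_weights = NULL, guard_gap = 22L,
                       n_markers = 4L, marker_len = 200L, n_dup_markers = 1L,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed", call. = FALSE)
  stopifnot(n_chrom >= 1, chrom_len >= 100, gc >= 0, gc <= 1, n_samples >= 1,
            n_snp >= 0, n_multiallelic_snp >= 0, n_small_indel >= 0,
            n_del >= 0, n_ins >= 0, n_inv >= 0, n_dup >= 0, guard_gap >= 1,
            n_markers >= 0, marker_len >= 1, n_dup_markers <= n_markers)
  if (n_multiallelic_snp > 0 && n_samples < 2) {
    stop("multiallelic sites need >= 2 samples", call. = FALSE)
  }
  if (!is.null(carrier_weights) && length(carrier_weights) != n_samples) {
    stop("carrier_weights must have length n_samples", call. = FALSE)
  }
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
              gc = gc, n_samples = as.integer(n_samples),
              n_snp = as.integer(n_snp),
              n_multiallelic_snp = as.integer(n_multiallelic_snp),
              n_small_indel = as.integer(n_small_indel),
              n_del = as.integer(n_del), n_ins = as.integer(n_ins),
              n_inv = as.integer(n_inv), n_dup = as.integer(n_dup),
              small_indel_range = as.integer(small_indel_range),
              del_range = as.integer(del_range), ins_range = as.integer(ins_range),
              inv_range = as.integer(inv_range), dup_range = as.integer(dup_range),
              carrier_weights = carrier_weights, guard_gap = as.integer(guard_gap),
              n_markers = as.integer(n_markers), marker_len = as.integer(marker_len),
              n_dup_markers = as.integer(n_dup_markers), seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Simulate a random reference genome
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (as inside [simulate_pangenome()], which seeds once).
#' @return Named character vector `chr1`, `chr2`, ... of DNA sequences with
#'   expected GC content `config$gc`.
#' @export
simulate_reference <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  setNames(vapply(seq_len(config$n_chrom), function(i) {
    paste(sample(names(probs), config$chrom_len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1)), paste0("chr", seq_len(config$n_chrom)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Reserve a non-overlapping footprint of interior width w on some
# chromosome; returns list(chrom, start0) or errors after max_tries.
place_footprint <- function(w, reference, occupied, guard, max_tries = 2000L) {
  lens <- nchar(reference)
  for (try in seq_len(max_tries)) {
    ci <- sample.int(length(reference), 1L, prob = lens)
    len <- lens[[ci]]
    lo <- 2L + guard
    hi <- len - w - 2L - guard
    if (hi < lo) next
    start0 <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    iv <- c(start0 - guard, start0 + w + guard)
    occ <- occupied[[ci]]
    clash <- length(occ) > 0 && any(iv[1] < occ[, 2] & occ[, 1] < iv[2])
    if (!clash) {
      return(list(chrom_idx = ci, start0 = start0, reserve = iv))
    }
  }
  stop("genome too small for the requested variant/marker counts ",
       "(no free footprint after ", max_tries, " placement attempts)",
       call. = FALSE)
}

#' Implant variants into a reference, producing haplotypes and a truth set
#'
#' Variant footprints are placed by rejection sampling with a guard gap so
#' no two variants (or their k-mer neighborhoods) overlap. Carriers per
#' variant are drawn from the config's sharing model. Every allele is
#' sequence-explicit; inversions and duplications additionally carry
#' `SVTYPE` so they classify as complex (`OTHER`).
#'
#' @param reference Named character vector from [simulate_reference()].
#' @param config A [sim_config()].
#' @param seed Optional seed (see [simulate_reference()]).
#' @return List: `haplotypes` (named character vector per sample), `truth`
#'   (a [variant_set()] with per-sample genotypes), `plan` (bookkeeping
#'   data frame: class, chrom, coordinates, size, carrier count),
#'   `occupied` (per-chromosome reserved intervals, for marker placement).
#' @export
implant_variants <- function(reference, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  samples <- paste0("s", seq_len(config$n_samples))
  occupied <- rep(list(matrix(numeric(0), ncol = 2)), length(reference))
  guard <- config$guard_gap
  classes <- c(rep("SNP", config$n_snp),
               rep("MSNP", config$n_multiallelic_snp),
               rep("SMALL_INDEL", config$n_small_indel),
               rep("DEL", config$n_del), rep("INS", config$n_ins),
               rep("INV", config$n_inv), rep("DUP", config$n_dup))
  if (length(classes) > 1) classes <- sample(classes)
  draw_size <- function(range) range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
  draw_carriers <- function(min_c = 1L) {
    w <- config$carrier_weights %||% rep(1, config$n_samples)
    choices <- seq(min_c, config$n_samples)
    k <- if (length(choices) == 1L) choices else
      sample(choices, 1L, prob = w[choices])
    sort(sample(samples, k))
  }
  other_bases <- function(b, n) sample(setdiff(c("A", "C", "G", "T"), b), n)
  plan_rows <- list(); records <- list()
  edits <- list()  # per record id: list(chrom, start0, end0, repl (per alt))
  for (vi in seq_along(classes)) {
    cls <- classes[[vi]]
    size <- switch(cls,
                   SNP = 1L, MSNP = 1L,
                   SMALL_INDEL = draw_size(config$small_indel_range),
                   DEL = draw_size(config$del_range),
                   INS = draw_size(config$ins_range),
                   INV = draw_size(config$inv_range),
                   DUP = draw_size(config$dup_range))
    indel_kind <- if (cls == "SMALL_INDEL") sample(c("ins", "del"), 1L) else NA
    w <- switch(cls, SNP = 1L, MSNP = 1L,
                SMALL_INDEL = if (indel_kind == "del") size else 0L,
                DEL = size, INS = 0L, INV = size, DUP = size)
    spot <- place_footprint(w, reference, occupied, guard)
    ci <- spot$chrom_idx; s0 <- spot$start0
    occupied[[ci]] <- rbind(occupied[[ci]], spot$reserve)
    chrom <- names(reference)[[ci]]
    seq_at <- function(a, b) substr(reference[[ci]], a, b)  # 1-based inclusive
    carriers <- draw_carriers(if (cls == "MSNP") 2L else 1L)
    gt <- setNames(rep("0", length(samples)), samples)
    if (cls == "SNP") {
      refb <- seq_at(s0 + 1L, s0 + 1L)
      altb <- other_bases(refb, 1L)
      rec <- new_variant_record(chrom, s0 + 1L, refb, altb, gt = gt)
      ed <- list(start0 = s0, end0 = s0 + 1L, repl = altb)
      gt[carriers] <- "1"
    } else if (cls == "MSNP") {
      refb <- seq_at(s0 + 1L, s0 + 1L)
      alts <- other_bases(refb, 2L)
      rec <- new_variant_record(chrom, s0 + 1L, refb, alts, gt = gt)
      # split carriers into two nonempty allele groups
      g1_n <- sample.int(length(carriers) - 1L, 1L)
      g1 <- carriers[seq_len(g1_n)]
      g2 <- setdiff(carriers, g1)
      gt[g1] <- "1"; gt[g2] <- "2"
      ed <- list(start0 = s0, end0 = s0 + 1L, repl = alts, groups = list(g1, g2))
    } else if (cls %in% c("DEL", "SMALL_INDEL") &&
               (cls == "DEL" || indel_kind == "del")) {
      anchor <- seq_at(s0, s0)
      ref <- seq_at(s0, s0 + size)  # anchor + deleted bases
      rec <- new_variant_record(chrom, s0, ref, anchor, gt = gt)
      ed <- list(start0 = s0, end0 = s0 + size, repl = "")
      gt[carriers] <- "1"
      cls <- if (cls == "SMALL_INDEL") "SMALL_DEL" else cls
    } else if (cls %in% c("INS", "SMALL_INDEL")) {
      anchor <- seq_at(s0, s0)
      ins <- rand_dna(size)
      rec <- new_variant_record(chrom, s0, anchor, paste0(anchor, ins), gt = gt)
      ed <- list(start0 = s0, end0 = s0, repl = ins)
      gt[carriers] <- "1"
      cls <- if (cls == "SMALL_INDEL") "SMALL_INS" else cls
    } else if (cls == "INV") {
      unit <- seq_at(s0 + 1L, s0 + size)
      rec <- new_variant_record(chrom, s0 + 1L, unit, revcomp(unit), gt = gt,
                                svtype = "INV")
      ed <- list(start0 = s0, end0 = s0 + size, repl = revcomp(unit))
      gt[carriers] <- "1"
    } else if (cls == "DUP") {
      unit <- seq_at(s0 + 1L, s0 + size)
      anchor <- seq_at(s0 + size, s0 + size)  # last base of the unit
      rec <- new_variant_record(chrom, s0 + size, anchor, paste0(anchor, unit),
                                gt = gt, svtype = "DUP")
      ed <- list(start0 = s0 + size, end0 = s0 + size, repl = unit)
      gt[carriers] <- "1"
    }
    rec$gt <- gt
    rec$id <- sprintf("var_%03d", vi)
    records[[vi]] <- rec
    ed$chrom <- chrom
    ed$carriers <- carriers
    ed$gt <- gt
    edits[[vi]] <- ed
    plan_rows[[vi]] <- data.frame(
      id = rec$id, class = cls, chrom = chrom, pos = rec$pos, size = size,
      n_carriers = length(carriers),
      carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
  }
  # haplotype = reference edited right-to-left with this sample's alleles,
  # chromosome-structured (named vector chrom -> sequence)
  haplotypes <- lapply(samples, function(s) {
    out <- reference
    for (chrom in names(reference)) {
      seq <- reference[[chrom]]
      here <- Filter(function(e) e$chrom == chrom && s %in% e$carriers, edits)
      if (length(here) > 0) {
        ord <- order(vapply(here, `[[`, numeric(1), "start0"), decreasing = TRUE)
        for (e in here[ord]) {
          repl <- if (length(e$repl) > 1L) {
            e$repl[[if (s %in% e$groups[[1]]) 1L else 2L]]
          } else e$repl
          seq <- paste0(substr(seq, 1L, e$start0), repl,
                        substr(seq, e$end0 + 1L, nchar(seq)))
        }
      }
      out[[chrom]] <- seq
    }
    out
  })
  names(haplotypes) <- samples
  truth <- variant_set(records, samples = samples,
                       contigs = setNames(nchar(reference), names(reference)))
  list(haplotypes = haplotypes, truth = truth,
       plan = do.call(rbind, plan_rows), occupied = occupied)
}

#' Build the bubble variation graph implied by a truth set
#'
#' The reference is segmented at every variant breakpoint; each variant
#' contributes a bubble: SNP sites get one alt segment per alt base,
#' deletions an edge skipping the deleted segment, insertions an extra
#' segment, inversions a reverse-orientation traversal of the reference
#' segment, tandem duplications a repeated traversal. One path per sample
#' (named `sample#1#chrom`) plus a reference path (`ref#0#chrom`) per
#' chromosome; every path spells its haplotype exactly.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param truth A [variant_set()] with explicit alleles and per-sample
#'   genotypes, variants non-overlapping (as produced by
#'   [implant_variants()]).
#' @return A [pangenome_graph()].
#' @export
build_bubble_graph <- function(reference, truth) {
  stopifnot(inherits(truth, "variant_set"))
  samples <- truth$samples
  # describe each record as a site on the reference
  sites_by_chrom <- setNames(vector("list", length(reference)), names(reference))
  for (r in truth$records) {
    alt1 <- r$alts[[1]]
    if (any(is_symbolic(r$alts))) {
      stop("bubble construction needs sequence-explicit alleles", call. = FALSE)
    }
    kind <- if (!is.na(r$svtype) && r$svtype == "INV") "inv"
      else if (!is.na(r$svtype) && r$svtype == "DUP") "dup"
      else if (all(nchar(r$alts) == 1L) && nchar(r$ref) == 1L) "snp"
      else if (nchar(r$ref) > nchar(alt1)) "del"
      else "ins"
    site <- switch(kind,
      snp = list(kind = "snp", a = r$pos - 1L, b = r$pos, alts = r$alts),
      del = list(kind = "del", a = r$pos, b = r$pos + nchar(r$ref) - 1L),
      ins = list(kind = "ins", a = r$pos, b = r$pos,
                 seq = substring(alt1, 2L)),
      inv = list(kind = "inv", a = r$pos - 1L, b = r$pos - 1L + nchar(r$ref)),
      dup = list(kind = "dup", a = r$pos - nchar(alt1) + 1L, b = r$pos))
    site$gt <- r$gt
    if (kind == "del" && alt1 != substr(r$ref, 1L, 1L)) {
      stop("deletion records must be anchored (alt = first ref base)", call. = FALSE)
    }
    sites_by_chrom[[r$chrom]] <- c(sites_by_chrom[[r$chrom]], list(site))
  }
  # allele of a sample at a site: 0 = ref, j = alts[j]
  allele_of <- function(site, s) {
    g <- site$gt[[s]] %||% "0"
    a <- suppressWarnings(max(as.integer(strsplit(g, "[/|]")[[1]]), na.rm = TRUE))
    if (!is.finite(a)) 0L else a
  }
  seg_seqs <- character(0)
  next_id <- 1L
  new_seg <- function(seq) {
    id <- as.character(next_id)
    next_id <<- next_id + 1L
    seg_seqs[[id]] <<- seq
    id
  }
  path_recs <- list()
  for (chrom in names(reference)) {
    seq <- reference[[chrom]]
    len <- nchar(seq)
    sites <- sites_by_chrom[[chrom]]
    if (length(sites) > 1) {
      sites <- sites[order(vapply(sites, `[[`, integer(1), "a"))]
    }
    cuts <- sort(unique(c(0L, len,
                          unlist(lapply(sites, function(s) c(s$a, s$b))))))
    # chunk segments between consecutive cuts
    chunk_start <- cuts[-length(cuts)]
    chunk_end <- cuts[-1]
    keep <- chunk_end > chunk_start
    chunk_start <- chunk_start[keep]; chunk_end <- chunk_end[keep]
    chunk_id <- vapply(seq_along(chunk_start), function(i) {
      new_seg(substr(seq, chunk_start[i] + 1L, chunk_end[i]))
    }, character(1))
    # variant roles: interval sites map to the chunk starting at their 'a';
    # insertion sites attach to their cut point
    role <- vector("list", length(chunk_start))   # interval site per chunk
    alt_segs <- list()
    ins_at <- list()                              # cut point -> ins sites
    for (site in sites) {
      if (site$kind == "ins") {
        key <- as.character(site$a)
        site$seg <- new_seg(site$seq)
        ins_at[[key]] <- c(ins_at[[key]], list(site))
      } else {
        ci <- which(chunk_start == site$a & chunk_end == site$b)
        if (length(ci) != 1L) {
          stop("internal error: variant interval does not align to a chunk ",
               "(overlapping truth variants?)", call. = FALSE)
        }
        if (site$kind == "snp") {
          site$alt_seg <- vapply(site$alts, new_seg, character(1))
        }
        role[[ci]] <- site
      }
    }
    walk <- function(who) {  # who: sample name or NA for the reference path
      seg <- character(0); orient <- character(0)
      emit <- function(id, o = "+") {
        seg <<- c(seg, id); orient <<- c(orient, o)
      }
      for (i in seq_along(chunk_start)) {
        key <- as.character(chunk_start[i])
        for (site in ins_at[[key]] %||% list()) {
          if (!is.na(who) && allele_of(site, who) >= 1L) emit(site$seg)
        }
        site <- role[[i]]
        a <- if (is.null(site) || is.na(who)) 0L else allele_of(site, who)
        if (is.null(site) || a == 0L) {
          emit(chunk_id[i])
        } else if (site$kind == "snp") {
          emit(site$alt_seg[[a]])
        } else if (site$kind == "del") {
          # skip the deleted segment
        } else if (site$kind == "inv") {
          emit(chunk_id[i], "-")
        } else if (site$kind == "dup") {
          emit(chunk_id[i]); emit(chunk_id[i])
        }
      }
      list(seg = seg, orient = orient)
    }
    ref_walk <- walk(NA)
    path_recs[[length(path_recs) + 1L]] <-
      list(name = paste0("ref#0#", chrom), seg = ref_walk$seg,
           orient = ref_walk$orient)
    for (s in samples) {
      w <- walk(s)
      path_recs[[length(path_recs) + 1L]] <-
        list(name = paste0(s, "#1#", chrom), seg = w$seg, orient = w$orient)
    }
  }
  # links = consecutive step pairs over all paths, deduplicated
  link_keys <- character(0); link_rows <- list()
  for (p in path_recs) {
    n <- length(p$seg)
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      key <- paste(p$seg[i], p$orient[i], p$seg[i + 1L], p$orient[i + 1L])
      if (!(key %in% link_keys)) {
        link_keys <- c(link_keys, key)
        link_rows[[length(link_rows) + 1L]] <-
          data.frame(from = p$seg[i], from_orient = p$orient[i],
                     to = p$seg[i + 1L], to_orient = p$orient[i + 1L],
                     overlap = "0M", stringsAsFactors = FALSE)
      }
    }
  }
  pangenome_graph(
    segments = seg_seqs,
    links = if (length(link_rows)) do.call(rbind, link_rows) else empty_links(),
    paths = path_recs)
}

#' Implant single-copy marker genes, optionally planting duplications
#'
#' Markers are windows of the reference placed clear of every variant
#' footprint (plus guard gap), so each marker occurs exactly once in every
#' haplotype. Markers named in `duplicate` additionally appear a second
#' time in the returned duplication target, giving a known planted
#' duplication for [duplication_report()].
#'
#' @param reference Named character vector of chromosome sequences.
#' @param occupied Per-chromosome reserved intervals from
#'   [implant_variants()] (0-based, guard included); `NULL` for none.
#' @param n_markers Number of markers.
#' @param marker_len Marker length (bases); must be >= k for k-mer use.
#' @param duplicate Character vector of marker ids (e.g. `"marker_02"`) or
#'   an integer count of markers to duplicate in the target.
#' @param guard_gap Spacing kept around markers (default 22).
#' @param seed Optional seed (see [simulate_reference()]).
#' @return List: `markers` (named character vector), `positions` (data
#'   frame marker/chrom/start0), `duplicated` (ids), `target` (the
#'   reference records plus one extra record per duplicated marker).
#' @export
implant_markers <- function(reference, occupied = NULL, n_markers = 4L,
                            marker_len = 200L, duplicate = 0L,
                            guard_gap = 22L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(occupied)) {
    occupied <- rep(list(matrix(numeric(0), ncol = 2)), length(reference))
  }
  markers <- character(0); rows <- list()
  for (i in seq_len(n_markers)) {
    spot <- place_footprint(marker_len, reference, occupied, guard_gap)
    ci <- spot$chrom_idx; s0 <- spot$start0
    occupied[[ci]] <- rbind(occupied[[ci]], spot$reserve)
    id <- sprintf("marker_%02d", i)
    markers[[id]] <- substr(reference[[ci]], s0 + 1L, s0 + marker_len)
    rows[[i]] <- data.frame(marker = id, chrom = names(reference)[[ci]],
                            start0 = s0, stringsAsFactors = FALSE)
  }
  dup_ids <- if (is.numeric(duplicate)) {
    names(markers)[seq_len(duplicate)]
  } else {
    stopifnot(all(duplicate %in% names(markers)))
    duplicate
  }
  target <- reference
  for (id in dup_ids) target[[paste0("dup_", id)]] <- markers[[id]]
  list(markers = markers,
       positions = if (length(rows)) do.call(rbind, rows) else
         data.frame(marker = character(0), chrom = character(0),
                    start0 = integer(0)),
       duplicated = dup_ids, target = target)
}

#' Simulate a complete truth bundle
#'
#' Seeds the RNG once from the config and chains
#' [simulate_reference()], [implant_variants()], [build_bubble_graph()]
#' and [implant_markers()]. The bundle satisfies, by construction, the
#' conservation guarantees the test-suite checks: each sample path in the
#' graph spells that sample's haplotype byte-exactly, and applying the
#' truth variants to the reference reproduces every haplotype.
#'
#' @param config A [sim_config()].
#' @return List of class `truth_bundle`: `config`, `reference`,
#'   `haplotypes` (per sample, chromosome-structured), `truth`, `graph`,
#'   `plan`, `markers`, `marker_positions`, `duplicated_markers`,
#'   `duplication_target`.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reference <- simulate_reference(config)
  iv <- implant_variants(reference, config)
  graph <- build_bubble_graph(reference, iv$truth)
  mk <- implant_markers(reference, occupied = iv$occupied,
                        n_markers = config$n_markers,
                        marker_len = config$marker_len,
                        duplicate = config$n_dup_markers,
                        guard_gap = config$guard_gap)
  structure(list(config = config, reference = reference,
                 haplotypes = iv$haplotypes, truth = iv$truth, graph = graph,
                 plan = iv$plan, markers = mk$markers,
                 marker_positions = mk$positions,
                 duplicated_markers = mk$duplicated,
                 duplication_target = mk$target),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf(paste0("truth_bundle: %d chrom x %d bp, %d samples, ",
                     "%d truth variants, %d markers (seed %d)\n"),
              x$config$n_chrom, x$config$chrom_len, x$config$n_samples,
              length(x$truth$records), length(x$markers), x$config$seed))
  invisible(x)
}

#' Write a truth bundle to disk
#'
#' Emits `reference.fa`, `samples/<sample>.fa`, `truth.vcf`, `graph.gfa`,
#' `markers.fa`, `dup_target.fa` and `config.json` under `dir`.
#'
#' @param bundle A `truth_bundle` from [simulate_pangenome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$reference, file.path(dir, "reference.fa"))
  for (s in names(bundle$haplotypes)) {
    hap <- bundle$haplotypes[[s]]
    names(hap) <- paste0(s, "#1#", names(hap))
    write_fasta(hap, file.path(dir, "samples", paste0(s, ".fa")))
  }
  write_vcf(bundle$truth, file.path(dir, "truth.vcf"))
  write_gfa(bundle$graph, file.path(dir, "graph.gfa"))
  write_fasta(bundle$markers, file.path(dir, "markers.fa"))
  write_fasta(bundle$duplication_target, file.path(dir, "dup_target.fa"))
  cfg <- unclass(bundle$config)
  cfg$carrier_weights <- cfg$carrier_weights %||% NA
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
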