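# Minimal VCF 4.2 ingest/emit around the variant_record/variant_set model.
#
# A variant_record is a list: chrom, pos (1-based), id, ref, alts (character
# vector), qual, filter, svtype (NA or e.g. "INV"/"DUP"), svlen (numeric,
# one per alt; alt minus ref length for explicit alleles, from SVLEN/END
# for symbolic ones), end (1-based inclusive), gt (named character vector,
# sample -> GT string), vtype (NA until classified).
#
# A symbolic <DEL> spans pos..END inclusive, so svlen = -(END - pos + 1).

new_variant_record <- function(chrom, pos, ref, alts, gt = character(0),
                               id = ".", qual = ".", filter = ".",
                               svtype = NA_character_, svlen = NULL,
                               end = NA_integer_, vtype = NA_character_) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be >= 1", call. = FALSE)
  if (!nzchar(ref)) stop("ref allele must be nonempty", call. = FALSE)
  alts <- as.character(alts)
  if (length(alts) < 1L) stop("record needs at least one alt allele", call. = FALSE)
  if (is.null(svlen)) {
    svlen <- vapply(alts, function(a) {
      if (is_symbolic(a)) NA_real_ else nchar(a) - nchar(ref)
    }, numeric(1), USE.NAMES = FALSE)
  }
  if (any(is_symbolic(alts) & is.na(svlen))) {
    stop("symbolic allele without a resolvable SVLEN/END at ", chrom, ":", pos,
         call. = FALSE)
  }
  if (is.na(end)) end <- pos + max(nchar(ref) - 1L, 0L)
  structure(list(chrom = as.character(chrom), pos = pos, id = id,
                 ref = toupper(ref), alts = toupper(alts), qual = qual,
                 filter = filter, svtype = svtype, svlen = as.numeric(svlen),
                 end = as.integer(end), gt = gt, vtype = vtype),
            class = "variant_record")
}

is_symbolic <- function(a) grepl("^<.+>$", a)

#' Construct a variant set
#'
#' @param records List of variant records.
#' @param samples Character vector of sample names (derived from records'
#'   genotype columns when omitted).
#' @param contigs Optional named vector of contig lengths.
#' @return Object of class `variant_set`, records sorted by (chrom, pos).
#' @export
variant_set <- function(records = list(), samples = NULL, contigs = NULL) {
  if (is.null(samples)) {
    samples <- unique(unlist(lapply(records, function(r) names(r$gt)),
                             use.names = FALSE)) %||% character(0)
  }
  if (length(records) > 0) {
    chroms <- vapply(records, `[[`, character(1), "chrom")
    pos <- vapply(records, `[[`, integer(1), "pos")
    records <- records[order(chroms, pos, method = "radix")]
  }
  structure(list(records = records, samples = samples, contigs = contigs),
            class = "variant_set")
}

#' @export
length.variant_set <- function(x) length(x$records)

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d records, %d samples\n",
              length(x$records), length(x$samples)))
  invisible(x)
}

# Per-sample presence of a record: GT contains >= 1 alt allele index;
# missing "." counts as absent.
record_presence <- function(rec, samples = names(rec$gt)) {
  vapply(samples, function(s) {
    g <- rec$gt[[s]] %||% "."
    toks <- strsplit(g, "[/|]")[[1]]
    as.integer(any(suppressWarnings(as.integer(toks)) >= 1L, na.rm = TRUE))
  }, integer(1))
}

#' Per-sample presence matrix of a variant set
#'
#' @param set A [variant_set()].
#' @return Integer matrix, records x samples, entries 0/1.
#' @export
presence_matrix <- function(set) {
  stopifnot(inherits(set, "variant_set"))
  m <- t(vapply(set$records, record_presence, integer(length(set$samples)),
                samples = set$samples))
  if (length(set$records) == 1L) m <- matrix(m, nrow = 1L,
                                             dimnames = list(NULL, set$samples))
  m
}

parse_info_field <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(list())
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[[2]] else TRUE)
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  vals
}

#' Parse a VCF 4.2 stream
#'
#' Honors GT in FORMAT and SVTYPE/SVLEN/END in INFO for symbolic alleles.
#' Input lacking a `#CHROM` header is a format error; unsorted records are
#' sorted with a warning. With `permissive = TRUE`, records without
#' FORMAT/sample columns are accepted as carried by the single sample
#' `sample_name` (presence = 1).
#'
#' @param x Path to a VCF file or character vector of VCF lines.
#' @param permissive Accept GT-less records as present in `sample_name`.
#' @param sample_name Sample used for GT-less records in permissive mode.
#' @return A [variant_set()].
#' @export
parse_vcf <- function(x, permissive = FALSE, sample_name = "SAMPLE") {
  lines <- if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(lines)]
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1L) stop("VCF format error: missing #CHROM header line",
                                call. = FALSE)
  contigs <- parse_contig_header(lines[startsWith(lines, "##contig")])
  hdr <- strsplit(lines[[hdr_i]], "\t", fixed = TRUE)[[1]]
  samples <- if (length(hdr) > 9) hdr[10:length(hdr)] else character(0)
  if (length(samples) == 0 && permissive) samples <- sample_name
  body <- lines[-seq_len(hdr_i)]
  body <- body[!startsWith(body, "#")]
  records <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop("VCF format error at record ", i, ": fewer than 8 fields", call. = FALSE)
    }
    info <- parse_info_field(f[[8]])
    pos <- as.integer(f[[2]])
    alts <- strsplit(f[[5]], ",", fixed = TRUE)[[1]]
    end <- if (!is.null(info$END)) as.integer(info$END) else NA_integer_
    svlen <- NULL
    if (any(is_symbolic(alts))) {
      svlen <- vapply(seq_along(alts), function(j) {
        if (!is_symbolic(alts[[j]])) return(nchar(alts[[j]]) - nchar(f[[4]]))
        if (!is.null(info$SVLEN)) {
          sl <- as.numeric(strsplit(info$SVLEN, ",", fixed = TRUE)[[1]])
          return(sl[min(j, length(sl))])
        }
        if (!is.na(end)) {
          span <- end - pos + 1L
          return(if (identical(info$SVTYPE, "DEL") || alts[[j]] == "<DEL>")
            -span else span)
        }
        NA_real_
      }, numeric(1))
    }
    gt <- character(0)
    if (length(f) >= 10 && length(hdr) > 9) {
      fmt <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fmt)
      if (!is.na(gi)) {
        gt <- vapply(f[10:length(f)], function(col) {
          strsplit(col, ":", fixed = TRUE)[[1]][gi]
        }, character(1), USE.NAMES = FALSE)
        names(gt) <- samples
      }
    } else if (permissive) {
      gt <- setNames("1", sample_name)
    }
    new_variant_record(chrom = f[[1]], pos = pos, ref = f[[4]], alts = alts,
                       gt = gt, id = f[[3]], qual = f[[6]], filter = f[[7]],
                       svtype = if (is.null(info$SVTYPE)) NA_character_ else info$SVTYPE,
                       svlen = svlen, end = if (is.na(end)) NA_integer_ else end)
  })
  if (length(records) > 1) {
    chroms <- vapply(records, `[[`, character(1), "chrom")
    pos <- vapply(records, `[[`, integer(1), "pos")
    ord <- order(chroms, pos, method = "radix")
    if (!identical(ord, seq_along(records))) {
      warning("VCF records were not coordinate-sorted; sorting", call. = FALSE)
    }
  }
  variant_set(records, samples = samples, contigs = contigs)
}

parse_contig_header <- function(lines) {
  if (length(lines) == 0) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', "\\1", lines)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", lines)))
  setNames(lens, ids)
}

#' Write a variant set as VCF 4.2
#'
#' Round-trip stable with [parse_vcf()] on records this module emits.
#'
#' @param set A [variant_set()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of VCF lines (invisibly when `path` is given).
#' @export
write_vcf <- function(set, path = NULL) {
  stopifnot(inherits(set, "variant_set"))
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">',
           '##INFO=<ID=SVLEN,Number=A,Type=Integer,Description="Signed length difference of alt vs ref">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(set$contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(set$contigs),
                          as.integer(set$contigs)))
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(set$samples) > 0) cols <- c(cols, "FORMAT", set$samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  rows <- vapply(set$records, function(r) {
    info <- character(0)
    if (!is.na(r$svtype)) info <- c(info, paste0("SVTYPE=", r$svtype))
    if (any(is_symbolic(r$alts))) {
      info <- c(info, paste0("SVLEN=", paste(as.integer(r$svlen), collapse = ",")),
                paste0("END=", r$end))
    }
    fields <- c(r$chrom, r$pos, r$id, r$ref, paste(r$alts, collapse = ","),
                r$qual, r$filter, if (length(info)) paste(info, collapse = ";") else ".")
    if (length(set$samples) > 0) {
      gts <- vapply(set$samples, function(s) r$gt[[s]] %||% ".", character(1))
      fields <- c(fields, "GT", gts)
    }
    paste(fields, collapse = "\t")
  }, character(1))
  out <- c(hdr, rows)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
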