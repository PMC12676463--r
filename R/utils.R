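#' @importFrom methods is
#' @importFrom stats setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character DNA (A/C/G/T/N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Natural (alphanumeric-aware) ordering: digit runs compare numerically, so
# segment ids "2" < "10" and "s2" < "s10".
natural_order <- function(x) {
  keys <- vapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    toks <- regmatches(s, gregexpr("\\d+|\\D+", s))[[1]]
    dig <- grepl("^\\d+$", toks)
    toks[dig] <- sprintf("%030d", as.numeric(toks[dig]))
    paste(toks, collapse = "")
  }, character(1))
  order(keys, method = "radix")
}

# Uppercase and validate a DNA alphabet restricted to A/C/G/T/N.
check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T/N (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  x
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector as 60-column wrapped FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
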