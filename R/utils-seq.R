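#' @importFrom methods is
#' @importFrom stats dnorm kmeans rbinom runif rnorm cmdscale median setNames
#' @importFrom utils read.delim write.table write.csv packageVersion
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()]
#' accepting plain strings (case preserved as upper case, `N` allowed).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Generate random DNA
#'
#' Uniform i.i.d. bases; used by the synthetic-data generators. Consumes the
#' R RNG stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param n integer vector of sequence lengths.
#' @return character vector of DNA strings, one per element of `n`.
#' @export
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

## split a string into single characters
chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

## GC fraction of a string (N ignored in denominator)
gc_fraction <- function(seq) {
  b <- chars(seq)
  b <- b[b != "N"]
  if (length(b) == 0L) return(NA_real_)
  mean(b %in% c("G", "C"))
}

## length of the longest homopolymer run (N runs excluded)
longest_homopolymer <- function(seq) {
  b <- chars(seq)
  r <- rle(b)
  r$lengths <- r$lengths[r$values != "N"]
  if (length(r$lengths) == 0L) return(0L)
  max(r$lengths)
}

## longest perfect dinucleotide tandem (in bases, e.g. "ATATAT" -> 6)
longest_dinuc_run <- function(seq) {
  b <- chars(seq)
  n <- length(b)
  if (n < 4L) return(0L)
  best <- 0L
  run <- 2L
  for (i in 3:n) {
    if (b[i] == b[i - 2L] && b[i] != "N") run <- run + 1L else run <- 2L
    if (run > best) best <- run
  }
  if (best < 4L) 0L else best
}

## assert a sequence uses only ACGTN
check_alphabet <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", toupper(seq))) {
    stop(what, " contains characters outside ACGTN", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file as a named character vector
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## deterministic stable order helper: order by multiple keys, ties broken by id
order_by <- function(..., decreasing = logical(0)) {
  keys <- list(...)
  stopifnot(length(decreasing) %in% c(0L, length(keys)))
  if (length(decreasing) == 0L) decreasing <- rep(FALSE, length(keys))
  keys <- Map(function(k, d) if (d) -xtfrm(k) else xtfrm(k), keys, decreasing)
  do.call(order, keys)
}
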