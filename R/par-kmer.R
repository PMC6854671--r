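#' Build a canonical k-mer index
#'
#' Indexes all k-mers occurring at least `min_occurrence` times across the
#' input sequences. K-mers are strand-collapsed to their canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement), so
#' membership queries are strand symmetric, which matches the behaviour of a
#' hybridisation probe. K-mers containing `N` are never indexed. Typical
#' settings mirror a dual-evidence setup: `min_occurrence = 1` on genome
#' assemblies and `min_occurrence = 5` on a ~5x read subset.
#'
#' @param sequences named character vector of sequences (or a file path to a
#'   FASTA, read via [read_fasta()]).
#' @param k k-mer size (default 17; must be >= 11).
#' @param min_occurrence minimum total occurrence count for membership.
#' @param source label, `"assembly"` or `"reads"` (metadata only).
#' @return object of class `kmer_index`.
#' @export
kmer_index <- function(sequences, k = 17L, min_occurrence = 1L,
                       source = c("assembly", "reads")) {
  source <- match.arg(source)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  if (k < 11L) stop("k must be >= 11", call. = FALSE)
  if (length(sequences) == 0L) stop("no sequences supplied", call. = FALSE)
  kmers <- unlist(lapply(unname(sequences), function(s) {
    s <- toupper(s)
    if (nchar(s) < k) {
      warning("sequence shorter than k contributes no k-mers", call. = FALSE)
      return(character(0))
    }
    extract_kmers(s, k)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  kmers <- canonical_kmers(kmers)
  counts <- table(kmers)
  members <- sort(names(counts)[counts >= min_occurrence])
  structure(list(k = as.integer(k), min_occurrence = as.integer(min_occurrence),
                 source = source, members = members),
            class = "kmer_index")
}

## all positional k-mers of a single sequence
extract_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## canonical (strand-collapsed) form of each k-mer
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(kmers)
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d source=%s min_occ=%d members=%d\n",
              x$k, x$source, x$min_occurrence, length(x$members)))
  invisible(x)
}

#' Query k-mer membership
#'
#' @param index a [kmer_index()].
#' @param kmers character vector of k-mers (any strand, any case).
#' @return logical vector.
#' @export
has_kmer <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  bad <- nchar(kmers) != index$k
  out <- canonical_kmers(toupper(kmers)) %in% index$members
  out[bad] <- FALSE
  out
}

#' Annotate regions of a sequence not covered by other lines' k-mers
#'
#' A position of `target` is covered when at least one k-mer window
#' overlapping it is a member of the other-line indexes (`combine = "any"`:
#' membership in any index marks coverage; `combine = "all"` requires every
#' index). Maximal runs of uncovered positions of length >= `min_len` are the
#' presence/absence regions (PARs) suitable for internal probe design.
#' Windows containing `N` are treated as absent from the indexes (they can
#' still be covered by overlapping windows).
#'
#' @param target a single sequence (character scalar).
#' @param others a [kmer_index()] or list of them (all with the same `k`).
#' @param k k-mer size; defaults to the indexes' `k`.
#' @param min_len minimum PAR length (default 35 bp).
#' @param combine `"any"` (default) or `"all"`; how evidence from multiple
#'   indexes is merged per window.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `length`; sorted and disjoint. Zero rows when fully covered.
#' @export
annotate_uncovered_regions <- function(target, others, k = NULL, min_len = 35L,
                                       combine = c("any", "all")) {
  combine <- match.arg(combine)
  if (inherits(others, "kmer_index")) others <- list(others)
  stopifnot(length(others) >= 1L, all(vapply(others, inherits, logical(1), "kmer_index")))
  ks <- vapply(others, `[[`, integer(1), "k")
  if (is.null(k)) k <- ks[1]
  if (any(ks != k)) stop("all indexes must share the same k", call. = FALSE)
  target <- toupper(target)
  L <- nchar(target)
  if (L < k) stop("target shorter than k", call. = FALSE)
  wins <- extract_kmers(target, k)
  memb <- vapply(others, function(ix) has_kmer(ix, wins), logical(length(wins)))
  if (is.null(dim(memb))) memb <- matrix(memb, ncol = length(others))
  covered_win <- if (combine == "any") rowSums(memb) > 0L else rowSums(memb) == length(others)
  starts <- which(covered_win)
  covered <- if (length(starts)) {
    IRanges::reduce(IRanges::IRanges(start = starts, width = k))
  } else IRanges::IRanges()
  uncovered <- IRanges::setdiff(IRanges::IRanges(1L, L), covered)
  uncovered <- uncovered[IRanges::width(uncovered) >= min_len]
  data.frame(start = IRanges::start(uncovered) - 1L,
             end = IRanges::end(uncovered),
             length = IRanges::width(uncovered))
}

#' Subtract repeat intervals from PARs
#'
#' Interval set-difference; fragments shorter than `min_len` after
#' subtraction are discarded. Both interval sets are 0-based half-open on
#' the same sequence.
#'
#' @param pars data.frame with `start`, `end` columns (e.g. from
#'   [annotate_uncovered_regions()]).
#' @param repeats data.frame with `start`, `end` columns (e.g. RepeatMasker
#'   intervals read with [read_bed()]).
#' @param min_len minimum surviving fragment length (default 35 bp).
#' @return data.frame with `start`, `end`, `length`; sorted and disjoint.
#' @export
subtract_repeats <- function(pars, repeats, min_len = 35L) {
  as_ir <- function(df, what) {
    if (nrow(df) == 0L) return(IRanges::IRanges())
    if (any(df$end <= df$start)) stop("malformed ", what, " interval (end <= start)", call. = FALSE)
    IRanges::IRanges(start = df$start + 1L, end = df$end)
  }
  out <- IRanges::setdiff(as_ir(pars, "PAR"), as_ir(repeats, "repeat"))
  out <- out[IRanges::width(out) >= min_len]
  data.frame(start = IRanges::start(out) - 1L, end = IRanges::end(out),
             length = IRanges::width(out))
}

#' Read a BED file (first three columns)
#'
#' @param path BED path (0-based half-open, as per the format).
#' @return data.frame with `seq_id`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  data.frame(seq_id = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]))
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open); an optional `name` column becomes BED column 4.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, intersect(c("seq_id", "start", "end", "name"),
                                names(intervals)), drop = FALSE]
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as GFF3
#'
#' Coordinates are converted to GFF's 1-based inclusive convention.
#'
#' @param intervals data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open internally).
#' @param path output path.
#' @param type feature type string (default `"region"`).
#' @param source source column string.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(intervals, path, type = "region", source = "indelchip") {
  lines <- "##gff-version 3"
  if (nrow(intervals) > 0L) {
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t.\t.\t.",
                              intervals$seq_id, source, type,
                              intervals$start + 1L, intervals$end))
  }
  writeLines(lines, path)
  invisible(path)
}
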