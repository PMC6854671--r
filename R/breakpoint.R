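#' Construct an InDel variant record
#'
#' An InDel is a sequence (>= 100 bp for discovery-derived events) present at
#' a locus in one line and absent at the same locus in another. The record
#' stores the carrier-side coordinates, the event sequence, the short
#' non-homologous fragment that may replace it in the other line, and both
#' flanking sequences shared by the two lines.
#'
#' Coordinates are 0-based half-open on the carrier sequence; `end - start`
#' must equal `nchar(deleted_seq)` for anchored variants.
#'
#' @param id variant identifier.
#' @param kind `"deletion_vs_ref"` (sequence carried by the reference) or
#'   `"insertion_vs_ref"` (sequence carried by the alternative line).
#' @param chrom carrier sequence name.
#' @param start,end 0-based half-open coordinates on the carrier.
#' @param deleted_seq the event sequence (present in one line only).
#' @param inserted_fragment short non-homologous fragment found in place of
#'   `deleted_seq` in the non-carrier line; may be `""`.
#' @param left_flank,right_flank flanking sequences shared by both lines
#'   (>= 50 bp when available).
#' @param source_line line in which the event was discovered.
#' @param min_len minimum event length enforced (100 bp for discovery-derived
#'   variants; set to 0 to construct shorter toys).
#' @return an object of class `indel_variant`.
#' @export
indel_variant <- function(id, kind = c("deletion_vs_ref", "insertion_vs_ref"),
                          chrom = "chr1", start = 0L, end = NULL,
                          deleted_seq, inserted_fragment = "",
                          left_flank, right_flank,
                          source_line = NA_character_, min_len = 100L) {
  kind <- match.arg(kind)
  deleted_seq <- toupper(deleted_seq)
  inserted_fragment <- toupper(inserted_fragment)
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  for (s in c(deleted_seq, inserted_fragment, left_flank, right_flank)) {
    check_alphabet(s)
  }
  if (nchar(deleted_seq) < min_len) {
    stop("deleted_seq shorter than ", min_len, " bp", call. = FALSE)
  }
  if (is.null(end)) end <- start + nchar(deleted_seq)
  if (end - start != nchar(deleted_seq)) {
    stop("end - start must equal nchar(deleted_seq)", call. = FALSE)
  }
  structure(
    list(id = as.character(id), kind = kind, chrom = chrom,
         start = as.integer(start), end = as.integer(end),
         deleted_seq = deleted_seq, inserted_fragment = inserted_fragment,
         left_flank = left_flank, right_flank = right_flank,
         source_line = source_line),
    class = "indel_variant")
}

#' @export
print.indel_variant <- function(x, ...) {
  cat(sprintf("<indel_variant> %s (%s) %s:%d-%d len=%d insert=%d\n",
              x$id, x$kind, x$chrom, x$start, x$end,
              nchar(x$deleted_seq), nchar(x$inserted_fragment)))
  invisible(x)
}

## longest common prefix length of two strings; case-insensitive, stops at N
lcp_len <- function(a, b) {
  a <- chars(a); b <- chars(b)
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  same <- a[seq_len(n)] == b[seq_len(n)] & a[seq_len(n)] != "N" & b[seq_len(n)] != "N"
  if (all(same)) n else which.min(same) - 1L
}

## longest common suffix length
lcs_len <- function(a, b) lcp_len(paste(rev(chars(a)), collapse = ""),
                                  paste(rev(chars(b)), collapse = ""))

#' Classify an InDel breakpoint
#'
#' Breakpoints fall into four types depending on whether a microhomology
#' (a short sequence present once in the reference and duplicated at both
#' extremities of the junction in the carrier) and/or a short non-homologous
#' inserted fragment is observed:
#' type I: no microhomology, no insert; type II: microhomology only;
#' type III: insert only; type IV: both. Events of type II/IV with
#' microhomology longer than 5 bp are flagged as excluded from probe design.
#'
#' Microhomology is scanned on both sides -- the longest common prefix of the
#' event sequence with the right flank, and the longest common suffix with
#' the left flank -- and the maximum is taken. The scan is case-insensitive
#' and terminates at `N`.
#'
#' @param v an [indel_variant()].
#' @param max_design_mh microhomology length above which type II/IV events
#'   are excluded from design (default 5 bp).
#' @return an object of class `breakpoint_class` with fields `type_code`
#'   (`"I"`..`"IV"`), `microhomology_len`, `insert_len`, `design_excluded`.
#' @export
classify_breakpoint <- function(v, max_design_mh = 5L) {
  stopifnot(inherits(v, "indel_variant"))
  if (nchar(v$deleted_seq) == 0L) stop("deleted_seq is empty", call. = FALSE)
  if (nchar(v$left_flank) == 0L || nchar(v$right_flank) == 0L) {
    stop("flanks must be non-empty", call. = FALSE)
  }
  m_right <- lcp_len(v$deleted_seq, v$right_flank)
  m_left <- lcs_len(v$deleted_seq, v$left_flank)
  ## the homology run must be bounded by the flank: if it consumes the whole
  ## (shorter) flank we cannot know the true length
  if (m_right == nchar(v$right_flank) && nchar(v$right_flank) < nchar(v$deleted_seq)) {
    stop("right flank shorter than microhomology search window", call. = FALSE)
  }
  if (m_left == nchar(v$left_flank) && nchar(v$left_flank) < nchar(v$deleted_seq)) {
    stop("left flank shorter than microhomology search window", call. = FALSE)
  }
  m <- max(m_right, m_left)
  i <- nchar(v$inserted_fragment)
  type <- if (m == 0L && i == 0L) "I"
          else if (m > 0L && i == 0L) "II"
          else if (m == 0L && i > 0L) "III"
          else "IV"
  structure(
    list(type_code = type, microhomology_len = as.integer(m),
         insert_len = as.integer(i),
         design_excluded = type %in% c("II", "IV") && m > max_design_mh),
    class = "breakpoint_class")
}

#' Design a breakpoint (BP) probe pair
#'
#' A BP probe is a 35 bp sequence read off the allele lacking the event
#' (left flank, then inserted fragment if any, then right flank), centred on
#' the junction base. The assay is discriminative only when the base at the
#' interrogated position differs between the presence allele (first base of
#' the event sequence) and the absence allele (first base after the
#' junction). For junctions inside a microhomology the interrogated position
#' is shifted one base at a time, at most `max_shift` times, until a
#' discriminative position is found; if none exists within the window the
#' design fails.
#'
#' @param v an [indel_variant()].
#' @param bp its [classify_breakpoint()] result.
#' @param max_shift maximum junction shift attempted (default 5).
#' @param probe_len probe length (default 35; must be odd).
#' @return a data.frame with two rows (FW and REV probes: columns `probe_id`,
#'   `indel_id`, `ptype`, `strand`, `seq`, `shift`, `interrogated`), or an
#'   object of class `design_failure` with a `reason` field.
#' @export
design_bp_probe <- function(v, bp = classify_breakpoint(v), max_shift = 5L,
                            probe_len = 35L) {
  stopifnot(inherits(v, "indel_variant"), inherits(bp, "breakpoint_class"))
  if (bp$design_excluded) {
    stop("variant is excluded from design (microhomology > 5 bp)", call. = FALSE)
  }
  if (probe_len %% 2L == 0L) stop("probe_len must be odd", call. = FALSE)
  half <- (probe_len - 1L) %/% 2L
  absence <- paste0(v$left_flank, v$inserted_fragment, v$right_flank)
  after <- paste0(v$inserted_fragment, v$right_flank) # absence allele past the junction
  del <- chars(v$deleted_seq)
  aft <- chars(after)
  shift <- NA_integer_
  for (s in 0:max_shift) {
    if (s + 1L > length(del) || s + 1L > length(aft)) break
    a <- del[s + 1L]; b <- aft[s + 1L]
    if (a != b && a != "N" && b != "N") { shift <- s; break }
  }
  if (is.na(shift)) {
    return(structure(list(reason = "not_possible",
                          detail = "no discriminative position within shift window"),
                     class = "design_failure"))
  }
  centre <- nchar(v$left_flank) + shift + 1L # 1-based on the absence allele
  if (centre - half < 1L || centre + half > nchar(absence)) {
    stop("flanks too short for a ", probe_len, " bp junction probe", call. = FALSE)
  }
  fw <- substr(absence, centre - half, centre + half)
  data.frame(
    probe_id = paste0(v$id, "_BP_", c("FW", "REV")),
    indel_id = v$id,
    ptype = "BP",
    strand = c("FW", "REV"),
    seq = c(fw, revcomp(fw)),
    shift = shift,
    interrogated = half + 1L,
    stringsAsFactors = FALSE)
}

#' @export
print.design_failure <- function(x, ...) {
  cat("<design_failure>", x$reason, "-", x$detail, "\n")
  invisible(x)
}

#' Test whether an object is a design failure
#' @param x object returned by [design_bp_probe()].
#' @return logical scalar.
#' @export
is_design_failure <- function(x) inherits(x, "design_failure")
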