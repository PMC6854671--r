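#' Probe design configuration
#'
#' Thresholds governing probe scoring, filtering and windowed selection.
#' Defaults follow the published selection policy: probes are *recommended*
#' at score >= 0.6 with no expected flanking polymorphism, *neutral* at
#' score >= 0.4 with fewer than 3 flanking polymorphisms all at least 21 bp
#' from the interrogated base; internal candidates must have > 70% of their
#' footprint inside a PAR and pass reference hit filters (<= 1 hit for
#' deletion probes, 0 for insertion probes, < 3 for BP probes); windowed
#' selection tiles PARs with 75, then 50, then 25 bp windows, retrying when
#' fewer than 4 probes are selected.
#'
#' @param thr_recommended,thr_neutral score thresholds.
#' @param max_flank_polys_neutral flanking polymorphism count must be
#'   strictly below this for the neutral class.
#' @param min_poly_distance minimum distance (bp) of a tolerated flanking
#'   polymorphism from the interrogated base.
#' @param flank_window flank width (bp) used for 16-mer hit counting.
#' @param hit_kmer k used for hit counting (16).
#' @param max_hits_deletion_probe,max_hits_insertion_probe,max_hits_bp_probe
#'   reference genome hit caps (BP cap is strict: hits must be `< 3`,
#'   i.e. `<= max_hits_bp_probe`).
#' @param min_par_overlap strict lower bound on the in-PAR fraction of the
#'   probe footprint.
#' @param window_sizes decreasing window sizes for iterative selection.
#' @param min_probes_per_indel retry threshold for windowed selection.
#' @return list of class `design_config`.
#' @export
design_config <- function(thr_recommended = 0.6, thr_neutral = 0.4,
                          max_flank_polys_neutral = 3L, min_poly_distance = 21L,
                          flank_window = 30L, hit_kmer = 16L,
                          max_hits_deletion_probe = 1L,
                          max_hits_insertion_probe = 0L,
                          max_hits_bp_probe = 2L,
                          min_par_overlap = 0.70,
                          window_sizes = c(75L, 50L, 25L),
                          min_probes_per_indel = 4L) {
  stopifnot(all(diff(window_sizes) < 0), thr_recommended > thr_neutral)
  structure(as.list(environment()), class = "design_config")
}

#' Multiplicity-aware genome k-mer counts
#'
#' Counts every canonical k-mer of a genome; used as the lookup for 16-mer
#' hit counting. Counting is strand-collapsed so a probe window matches the
#' genome regardless of orientation.
#'
#' @param genome named character vector of sequences (or FASTA path).
#' @param k k-mer size (default 16).
#' @return object of class `kmer_counts` (environment-backed hash).
#' @export
genome_kmer_counts <- function(genome, k = 16L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  kmers <- unlist(lapply(unname(genome), function(s) extract_kmers(toupper(s), k)),
                  use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  kmers <- canonical_kmers(kmers)
  tab <- table(kmers)
  env <- new.env(parent = emptyenv(), size = length(tab) * 2L)
  for (i in seq_along(tab)) assign(names(tab)[i], as.integer(tab[[i]]), envir = env)
  structure(list(k = as.integer(k), counts = env), class = "kmer_counts")
}

## vectorised count lookup (0 for absent or N-containing windows)
kmer_count_lookup <- function(counts, kmers) {
  stopifnot(inherits(counts, "kmer_counts"))
  kmers <- canonical_kmers(toupper(kmers))
  out <- integer(length(kmers))
  ok <- !grepl("N", kmers, fixed = TRUE)
  out[ok] <- vapply(kmers[ok], function(km) {
    v <- get0(km, envir = counts$counts, ifnotfound = 0L)
    v
  }, integer(1))
  out
}

#' 16-mer hit count of a probe
#'
#' Sums, over all 16 bp windows fully contained in the flanking regions on
#' either side of the interrogated base (up to `flank_window` bp per side),
#' the occurrence count of the window in the genome. Windows containing `N`
#' contribute 0. High values indicate expected non-specific binding.
#'
#' @param probe_seq probe sequence (character scalar).
#' @param counts a [genome_kmer_counts()] index (k must equal
#'   `cfg$hit_kmer`).
#' @param interrogated 1-based position of the interrogated base within
#'   `probe_seq` (default: centre).
#' @param cfg a [design_config()].
#' @return integer hit count.
#' @export
count_16mer_hits <- function(probe_seq, counts,
                             interrogated = (nchar(probe_seq) + 1L) %/% 2L,
                             cfg = design_config()) {
  probe_seq <- toupper(probe_seq)
  check_alphabet(probe_seq, "probe")
  if (counts$k != cfg$hit_kmer) stop("index k does not match cfg$hit_kmer", call. = FALSE)
  k <- cfg$hit_kmer
  left <- substr(probe_seq, max(1L, interrogated - cfg$flank_window), interrogated - 1L)
  right <- substr(probe_seq, interrogated + 1L,
                  min(nchar(probe_seq), interrogated + cfg$flank_window))
  wins <- c(extract_kmers(left, k), extract_kmers(right, k))
  if (length(wins) == 0L) return(0L)
  sum(kmer_count_lookup(counts, wins))
}

#' Count full-length probe hits on a genome
#'
#' Occurrences of the probe (either strand, exact match) across all
#' sequences of a genome.
#'
#' @param probe_seq probe sequence.
#' @param genome named character vector of sequences (or FASTA path).
#' @return integer number of hits.
#' @export
count_genome_hits <- function(probe_seq, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  subject <- Biostrings::DNAStringSet(toupper(unname(genome)))
  p <- Biostrings::DNAString(toupper(probe_seq))
  fw <- sum(Biostrings::vcountPattern(p, subject))
  rv <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), subject))
  as.integer(fw + rv)
}

#' Score a probe and classify its designability
#'
#' The published pipeline scores probes with a proprietary random-forest
#' "p-convert" model; this package substitutes a transparent surrogate with
#' identical thresholds and classification semantics. The surrogate is
#'
#' \deqn{score = max(0, 1 - 0.35 p_{GC} - 0.25 p_{HP} - 0.15 p_{DI} - 0.25 p_{16})}
#'
#' with \eqn{p_{GC} = |GC - 0.45| / 0.55}, \eqn{p_{HP} = \min(1, \max(0,
#' HP - 2) / 8)} for the longest homopolymer run HP, \eqn{p_{DI}} the
#' fraction of the probe covered by its longest perfect dinucleotide tandem,
#' and \eqn{p_{16} = \min(1, \max(0, hit16 / W - 1) / 9)} the normalised
#' excess of the 16-mer hit count over the window count W (a unique probe
#' has hit16 = W). All four penalties are monotone in the underlying defect.
#'
#' Classification: `not_possible` when the interrogated base is `N` or the
#' longest homopolymer is >= 10; `recommended` when score >= 0.6 and no
#' flanking polymorphism is expected; `neutral` when score >= 0.4, fewer
#' than 3 flanking polymorphisms, all at distance >= 21 bp from the
#' interrogated base; otherwise `not_recommended`.
#'
#' @param probe_seq probe sequence (ACGTN).
#' @param hit16 16-mer hit count from [count_16mer_hits()] (NA to skip the
#'   non-specific-binding penalty).
#' @param poly_distances distances (bp) of known flanking polymorphisms from
#'   the interrogated base; `integer(0)` when none are known.
#' @param interrogated 1-based interrogated position (default centre).
#' @param cfg a [design_config()].
#' @return list with `score` (in `[0, 1]`) and `classification`.
#' @export
score_probe <- function(probe_seq, hit16 = NA_integer_,
                        poly_distances = integer(0),
                        interrogated = (nchar(probe_seq) + 1L) %/% 2L,
                        cfg = design_config()) {
  probe_seq <- toupper(probe_seq)
  check_alphabet(probe_seq, "probe")
  n <- nchar(probe_seq)
  hp <- longest_homopolymer(probe_seq)
  if (substr(probe_seq, interrogated, interrogated) == "N" || hp >= 10L) {
    return(list(score = 0, classification = "not_possible"))
  }
  gc <- gc_fraction(probe_seq)
  p_gc <- abs(gc - 0.45) / 0.55
  p_hp <- min(1, max(0, hp - 2L) / 8)
  p_di <- longest_dinuc_run(probe_seq) / n
  p_16 <- 0
  if (!is.na(hit16)) {
    ## windows actually available for a probe of this length
    w_avail <- length(extract_kmers(substr(probe_seq, 1, interrogated - 1L), cfg$hit_kmer)) +
      length(extract_kmers(substr(probe_seq, interrogated + 1L, n), cfg$hit_kmer))
    if (w_avail > 0L) p_16 <- min(1, max(0, hit16 / w_avail - 1) / 9)
  }
  score <- max(0, 1 - 0.35 * p_gc - 0.25 * p_hp - 0.15 * p_di - 0.25 * p_16)
  np <- length(poly_distances)
  classification <-
    if (score >= cfg$thr_recommended && np == 0L) "recommended"
    else if (score >= cfg$thr_neutral && np < cfg$max_flank_polys_neutral &&
             (np == 0L || all(poly_distances >= cfg$min_poly_distance))) "neutral"
    else "not_recommended"
  list(score = score, classification = classification)
}

#' Enumerate internal (MONO/OTV) probe candidates along PARs
#'
#' Tiles each PAR of an InDel's internal sequence with probe-length windows
#' at the given step, computes the in-PAR overlap fraction, hit counts and
#' the surrogate score, and returns a candidate table ready for
#' [filter_candidates()] / [select_windowed()].
#'
#' @param indel_id identifier used in probe ids.
#' @param indel_seq internal sequence of the InDel.
#' @param pars data.frame of PAR intervals (`start`, `end`, 0-based
#'   half-open, relative to `indel_seq`).
#' @param genome named character vector: the reference genome used for hit
#'   filtering (for deletion probes this contains the event; for insertion
#'   probes it does not).
#' @param kind `"deletion_vs_ref"` or `"insertion_vs_ref"` (controls which
#'   hit cap applies downstream).
#' @param ptype `"MONO"` or `"OTV"`.
#' @param counts16 optional [genome_kmer_counts()] (k = 16) for hit16; built
#'   from `genome` when NULL.
#' @param step candidate spacing in bp (default 5).
#' @param probe_len probe length (default 35).
#' @param snp_positions for OTV probes, 0-based positions (relative to
#'   `indel_seq`) of known SNPs; candidates are centred on them and `step`
#'   is ignored.
#' @param cfg a [design_config()].
#' @return data.frame of candidates (`probe_id`, `indel_id`, `ptype`,
#'   `strand`, `seq`, `position`, `par_overlap_frac`, `genome_hits`,
#'   `hit16`, `score`, `classification`, `kind`).
#' @export
tile_candidates <- function(indel_id, indel_seq, pars, genome,
                            kind = c("deletion_vs_ref", "insertion_vs_ref"),
                            ptype = c("MONO", "OTV"), counts16 = NULL,
                            step = 5L, probe_len = 35L,
                            snp_positions = NULL, cfg = design_config()) {
  kind <- match.arg(kind)
  ptype <- match.arg(ptype)
  indel_seq <- toupper(indel_seq)
  L <- nchar(indel_seq)
  if (is.null(counts16)) counts16 <- genome_kmer_counts(genome, cfg$hit_kmer)
  starts <- integer(0)
  if (ptype == "OTV") {
    if (is.null(snp_positions) || length(snp_positions) == 0L) {
      return(empty_candidates())
    }
    half <- (probe_len - 1L) %/% 2L
    starts <- snp_positions - half
    starts <- starts[starts >= 0L & starts + probe_len <= L]
  } else if (nrow(pars) > 0L) {
    for (r in seq_len(nrow(pars))) {
      s0 <- pars$start[r]
      s1 <- pars$end[r] - probe_len
      if (s1 >= s0) starts <- c(starts, seq(s0, s1, by = step))
    }
  }
  starts <- sort(unique(starts))
  if (length(starts) == 0L) return(empty_candidates())
  par_ir <- if (nrow(pars) > 0L) {
    IRanges::IRanges(start = pars$start + 1L, end = pars$end)
  } else IRanges::IRanges()
  rows <- lapply(starts, function(s0) {
    seq <- substr(indel_seq, s0 + 1L, s0 + probe_len)
    if (grepl("N", seq, fixed = TRUE)) return(NULL)
    probe_ir <- IRanges::IRanges(start = s0 + 1L, width = probe_len)
    ov <- sum(IRanges::width(IRanges::intersect(probe_ir, par_ir))) / probe_len
    hits <- count_genome_hits(seq, genome)
    h16 <- count_16mer_hits(seq, counts16, cfg = cfg)
    sc <- score_probe(seq, hit16 = h16, cfg = cfg)
    data.frame(probe_id = sprintf("%s_%s_%06d", indel_id, ptype, s0),
               indel_id = indel_id, ptype = ptype, strand = "FW",
               seq = seq, position = s0, par_overlap_frac = ov,
               genome_hits = hits, hit16 = h16, score = sc$score,
               classification = sc$classification, kind = kind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_candidates() else out
}

empty_candidates <- function() {
  data.frame(probe_id = character(0), indel_id = character(0),
             ptype = character(0), strand = character(0), seq = character(0),
             position = integer(0), par_overlap_frac = numeric(0),
             genome_hits = integer(0), hit16 = integer(0), score = numeric(0),
             classification = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

## hit cap for one candidate row
hit_cap <- function(ptype, kind, cfg) {
  ifelse(ptype == "BP", cfg$max_hits_bp_probe,
         ifelse(kind == "insertion_vs_ref", cfg$max_hits_insertion_probe,
                cfg$max_hits_deletion_probe))
}

#' Filter probe candidates by class, hits and PAR overlap
#'
#' Internal (OTV/MONO) candidates are kept when classified `recommended` or
#' `neutral`, within the reference hit cap (<= 1 for deletion probes, 0 for
#' insertion probes) and with strictly more than `min_par_overlap` of their
#' footprint in PARs. BP candidates are kept regardless of score as long as
#' they have fewer than 3 reference hits.
#'
#' @param cands candidate data.frame (see [tile_candidates()]; BP rows from
#'   [design_bp_probe()] may be bound in, with `par_overlap_frac` and
#'   `classification` columns added).
#' @param cfg a [design_config()].
#' @return the retained rows.
#' @export
filter_candidates <- function(cands, cfg = design_config()) {
  if (nrow(cands) == 0L) return(cands)
  cap <- hit_cap(cands$ptype, cands$kind, cfg)
  keep_hits <- cands$genome_hits <= cap
  is_bp <- cands$ptype == "BP"
  keep_class <- is_bp | cands$classification %in% c("recommended", "neutral")
  keep_par <- is_bp | cands$par_overlap_frac > cfg$min_par_overlap
  cands[keep_hits & keep_class & keep_par, , drop = FALSE]
}

## windows tiling one PAR at width w; last partial window kept
par_windows <- function(par_start, par_end, w) {
  starts <- seq(par_start, par_end - 1L, by = w)
  data.frame(start = starts, end = pmin(starts + w, par_end))
}

#' Windowed selection of MONO probes
#'
#' Tiles each PAR of an InDel with fixed-size windows (last partial window
#' kept) and keeps the best-scoring candidate per window, ties broken by
#' probe id. A candidate belongs to every window its footprint overlaps, so
#' trailing windows shorter than a probe remain targetable; per-window
#' winners are unioned (a probe best in two adjacent windows counts once).
#' When fewer than `min_probes_per_indel` probes are selected, the
#' selection is redone with the next (smaller) window size; the final
#' iteration's selection is returned even if still short.
#'
#' @param cands filtered candidate rows for a single InDel.
#' @param pars data.frame of PAR intervals for the same InDel.
#' @param cfg a [design_config()].
#' @return list with `selected` (candidate rows) and `window_size` used.
#' @export
select_windowed <- function(cands, pars, cfg = design_config()) {
  if (nrow(cands) == 0L || nrow(pars) == 0L) {
    return(list(selected = cands[0, , drop = FALSE], window_size = NA_integer_))
  }
  plen <- nchar(cands$seq)
  sel <- cands[0, , drop = FALSE]
  used <- NA_integer_
  for (w in cfg$window_sizes) {
    picked <- integer(0)
    for (r in seq_len(nrow(pars))) {
      wins <- par_windows(pars$start[r], pars$end[r], w)
      for (q in seq_len(nrow(wins))) {
        in_win <- which(cands$position < wins$end[q] &
                          cands$position + plen > wins$start[q])
        if (length(in_win) == 0L) next
        ord <- order_by(cands$score[in_win], cands$probe_id[in_win],
                        decreasing = c(TRUE, FALSE))
        picked <- c(picked, in_win[ord[1]])
      }
    }
    picked <- sort(unique(picked))
    sel <- cands[picked, , drop = FALSE]
    used <- w
    if (nrow(sel) >= cfg$min_probes_per_indel) break
  }
  list(selected = sel, window_size = used)
}

#' Rescue InDels left untargeted by the first selection
#'
#' For InDels with zero selected probes, re-runs windowed selection among
#' their `not_recommended` candidates that still pass the hit and PAR
#' overlap filters. InDels with no surviving candidate at all remain
#' untargeted and are reported.
#'
#' @param selected data.frame of already-selected probes (all InDels).
#' @param all_cands data.frame of all candidates (all InDels).
#' @param pars_by_indel named list of PAR data.frames keyed by indel id.
#' @param indel_ids character vector of all InDel ids in the design.
#' @param cfg a [design_config()].
#' @return list with `selected` (input plus rescued rows) and `untargeted`
#'   (ids with no probe even after rescue).
#' @export
rescue_untargeted <- function(selected, all_cands, pars_by_indel, indel_ids,
                              cfg = design_config()) {
  targeted <- unique(selected$indel_id)
  todo <- setdiff(indel_ids, targeted)
  rescued <- list()
  still <- character(0)
  for (id in todo) {
    cand <- all_cands[all_cands$indel_id == id &
                        all_cands$classification == "not_recommended", , drop = FALSE]
    if (nrow(cand) > 0L) {
      cap <- hit_cap(cand$ptype, cand$kind, cfg)
      cand <- cand[cand$genome_hits <= cap &
                     (cand$ptype == "BP" | cand$par_overlap_frac > cfg$min_par_overlap), ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0L) { still <- c(still, id); next }
    pars <- pars_by_indel[[id]]
    if (is.null(pars) || nrow(pars) == 0L) { still <- c(still, id); next }
    res <- select_windowed(cand, pars, cfg)
    if (nrow(res$selected) == 0L) still <- c(still, id)
    else rescued[[id]] <- res$selected
  }
  list(selected = rbind(selected, do.call(rbind, unname(rescued))),
       untargeted = still)
}

#' Collapse exact-sequence duplicate probes
#'
#' Keeps, per distinct sequence, the highest-scoring carrier; ties are
#' broken by the lexicographically smaller probe id. Order of the result is
#' deterministic (by probe id).
#'
#' @param selected data.frame of selected probes with `seq`, `score`,
#'   `probe_id` columns.
#' @return deduplicated data.frame.
#' @export
dedupe_probes <- function(selected) {
  if (nrow(selected) <= 1L) return(selected)
  ord <- order_by(selected$seq, selected$score, selected$probe_id,
                  decreasing = c(FALSE, TRUE, FALSE))
  x <- selected[ord, , drop = FALSE]
  x <- x[!duplicated(x$seq), , drop = FALSE]
  x[order(x$probe_id), , drop = FALSE]
}

#' Write / read a probe manifest TSV
#'
#' @param manifest probe data.frame.
#' @param path TSV path.
#' @return `path` (writer, invisibly) or the manifest data.frame (reader).
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
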