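#' Synthetic-data configuration
#'
#' States the world the generators emulate: genomes are a shared random
#' backbone interrupted by planted InDel events of all four breakpoint
#' types; array signals are bivariate-normal clusters in (contrast,
#' intensity) space laid out like a real two-channel assay -- presence
#' clusters at high intensity and strong contrast, the off-target (absence)
#' cluster at low intensity and neutral contrast, hemizygous midway.
#'
#' @param n_indels number of planted events.
#' @param indel_size_range event length range in bp (default 100-10,000,
#'   echoing the published 37 bp - 129.7 kbp spectrum at desk scale).
#' @param spacer_range length range of the shared backbone between events.
#' @param breakpoint_type_mix named probabilities for types I-IV.
#' @param microhomology_len_range microhomology length range for types
#'   II/IV (default 1-5 bp, the designable range).
#' @param insert_len_range non-homologous fragment length range for types
#'   III/IV (default 1-50 bp).
#' @param deletion_fraction fraction of events carried by the reference
#'   (the rest are insertions relative to it).
#' @param repeat_fraction fraction of events whose interior contains a copy
#'   of a backbone repeat (breaks the "whole event is one PAR" property).
#' @param flank_len flank length recorded per variant (default 100 bp).
#' @param n_samples number of samples for genotype/signal generation.
#' @param presence_freq_range per-event presence allele frequency range.
#' @param cluster_geometry named list of `c(con_mean, con_sd, int_mean,
#'   int_sd)` per call state; see Details for defaults.
#' @param probe_error_rate probability that a probe x sample presence state
#'   is flipped before signal generation.
#' @param dropout_rate probability of a missing signal.
#' @return list of class `synthetic_config`.
#' @details Default cluster geometry: presence (`AA`/`BB`) at intensity
#'   10 (SD 0.3) and contrast +/-1.5 (SD 0.2); `AB` at presence intensity,
#'   contrast 0 (SD 0.2); absence (`OO`) at intensity 7 (SD 0.4), contrast
#'   0 (SD 0.5); hemizygous (`OA`/`OB`) midway at intensity 8.5 (SD 0.35),
#'   contrast +/-0.75 (SD 0.3).
#' @export
synthetic_config <- function(n_indels = 20L,
                             indel_size_range = c(100L, 10000L),
                             spacer_range = c(300L, 600L),
                             breakpoint_type_mix = c(I = 0.05, II = 0.53,
                                                     III = 0.42, IV = 0.002),
                             microhomology_len_range = c(1L, 5L),
                             insert_len_range = c(1L, 50L),
                             deletion_fraction = 0.37,
                             repeat_fraction = 0,
                             flank_len = 100L,
                             n_samples = 100L,
                             presence_freq_range = c(0.1, 0.9),
                             cluster_geometry = default_cluster_geometry(),
                             probe_error_rate = 0,
                             dropout_rate = 0) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1,
            probe_error_rate >= 0, probe_error_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            spacer_range[1] >= flank_len)
  mix <- breakpoint_type_mix / sum(breakpoint_type_mix)
  cfg <- as.list(environment())
  cfg$breakpoint_type_mix <- mix
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_cluster_geometry <- function() {
  list(AA = c(con_mean = 1.5, con_sd = 0.2, int_mean = 10, int_sd = 0.3),
       BB = c(con_mean = -1.5, con_sd = 0.2, int_mean = 10, int_sd = 0.3),
       AB = c(con_mean = 0, con_sd = 0.2, int_mean = 10, int_sd = 0.3),
       OA = c(con_mean = 0.75, con_sd = 0.3, int_mean = 8.5, int_sd = 0.35),
       OB = c(con_mean = -0.75, con_sd = 0.3, int_mean = 8.5, int_sd = 0.35),
       OO = c(con_mean = 0, con_sd = 0.5, int_mean = 7, int_sd = 0.4))
}

rint <- function(range) if (range[1] >= range[2]) range[1] else sample(range[1]:range[2], 1L)

## pick a base different from all bases in `avoid`
other_base <- function(avoid) sample(setdiff(BASES, toupper(avoid)), 1L)

#' Generate a reference and an alternative genome with planted InDels
#'
#' Both genomes share a random backbone; each planted event inserts its
#' sequence into the carrier genome only, with the junction engineered to
#' the requested breakpoint type: type II/IV events duplicate the chosen
#' microhomology at both extremities of the junction (the event sequence
#' begins with the same bases as the right flank); type III/IV events place
#' a short non-homologous fragment in the non-carrier at the junction.
#' Accidental homology at the engineered junction is excluded by
#' construction, so [classify_breakpoint()] recovers the planted type and
#' microhomology length exactly for non-repetitive events.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   (cfg, seed)).
#' @return list with `reference` and `alt` (named character vectors, one
#'   chromosome each), `variants` (list of [indel_variant()]), `truth`
#'   (data.frame: id, kind, type, microhomology_len, insert_len, length,
#'   carrier_start, carrier_end, has_repeat) and `repeats` (data.frame of
#'   planted repeat intervals relative to each event's sequence).
#' @export
generate_genomes <- function(cfg = synthetic_config(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  n <- cfg$n_indels
  ref_parts <- character(0); alt_parts <- character(0)
  ref_pos <- 0L; alt_pos <- 0L
  variants <- vector("list", n)
  truth <- vector("list", n)
  repeats <- list()
  repeat_motif <- random_dna(200L)
  ## seed the repeat motif into the shared backbone so that other-line
  ## k-mer indexes cover it
  lead <- paste0(random_dna(rint(cfg$spacer_range)), repeat_motif,
                 random_dna(50L))
  ref_parts <- alt_parts <- lead
  ref_pos <- alt_pos <- nchar(lead)
  spacers <- random_dna(vapply(seq_len(n), function(i) rint(cfg$spacer_range),
                               integer(1)))
  ## the piece immediately left of each event is always shared backbone of
  ## at least spacer_range[1] >= flank_len bases
  prev_tail <- substr(lead, nchar(lead) - cfg$flank_len + 1L, nchar(lead))
  if (n > 0L) for (i in seq_len(n)) {
    type <- sample(names(cfg$breakpoint_type_mix), 1L,
                   prob = cfg$breakpoint_type_mix)
    kind <- if (runif(1) < cfg$deletion_fraction) "deletion_vs_ref" else "insertion_vs_ref"
    m <- if (type %in% c("II", "IV")) rint(cfg$microhomology_len_range) else 0L
    ins_len <- if (type %in% c("III", "IV")) rint(cfg$insert_len_range) else 0L
    len <- rint(cfg$indel_size_range)
    R <- spacers[i]
    ## event sequence: prefix = microhomology copied from the right flank
    body <- random_dna(len - m)
    S <- paste0(substr(R, 1L, m), body)
    has_repeat <- runif(1) < cfg$repeat_fraction &&
      nchar(S) >= nchar(repeat_motif) + 2L * (m + 10L)
    if (has_repeat) {
      at <- max(m + 10L, (nchar(S) - nchar(repeat_motif)) %/% 2L)
      S <- substr(paste0(substr(S, 1L, at), repeat_motif,
                         substr(S, at + nchar(repeat_motif) + 1L, nchar(S))),
                  1L, len)
      repeats[[length(repeats) + 1L]] <-
        data.frame(id = sprintf("IND%04d", i), start = at,
                   end = min(at + nchar(repeat_motif), len))
    }
    ## no accidental prefix extension past m
    if (substr(S, m + 1L, m + 1L) == substr(R, m + 1L, m + 1L)) {
      S <- paste0(substr(S, 1L, m), other_base(substr(R, m + 1L, m + 1L)),
                  substr(S, m + 2L, nchar(S)))
    }
    ## no suffix homology with the left flank
    L_last <- substr(prev_tail, nchar(prev_tail), nchar(prev_tail))
    if (substr(S, nchar(S), nchar(S)) == L_last) {
      S <- paste0(substr(S, 1L, nchar(S) - 1L), other_base(L_last))
    }
    FRAG <- if (ins_len > 0L) random_dna(ins_len) else ""
    carrier_is_ref <- kind == "deletion_vs_ref"
    carrier_start <- if (carrier_is_ref) ref_pos else alt_pos
    ## carrier gets S, the other line gets FRAG, then both share R
    if (carrier_is_ref) {
      ref_parts <- c(ref_parts, S, R); alt_parts <- c(alt_parts, FRAG, R)
      ref_pos <- ref_pos + nchar(S) + nchar(R)
      alt_pos <- alt_pos + nchar(FRAG) + nchar(R)
    } else {
      alt_parts <- c(alt_parts, S, R); ref_parts <- c(ref_parts, FRAG, R)
      alt_pos <- alt_pos + nchar(S) + nchar(R)
      ref_pos <- ref_pos + nchar(FRAG) + nchar(R)
    }
    left_flank_seq <- prev_tail
    prev_tail <- substr(R, nchar(R) - cfg$flank_len + 1L, nchar(R))
    v <- indel_variant(
      id = sprintf("IND%04d", i), kind = kind, chrom = "chr1",
      start = carrier_start, deleted_seq = S, inserted_fragment = FRAG,
      left_flank = left_flank_seq,
      right_flank = substr(R, 1L, cfg$flank_len),
      source_line = if (carrier_is_ref) "ref" else "alt", min_len = 0L)
    variants[[i]] <- v
    truth[[i]] <- data.frame(
      id = v$id, kind = kind, type = type, microhomology_len = m,
      insert_len = ins_len, length = nchar(S),
      carrier_start = carrier_start, carrier_end = carrier_start + nchar(S),
      has_repeat = has_repeat, stringsAsFactors = FALSE)
  }
  list(reference = c(chr1 = paste(ref_parts, collapse = "")),
       alt = c(chr1 = paste(alt_parts, collapse = "")),
       variants = variants,
       truth = do.call(rbind, truth),
       repeats = if (length(repeats)) do.call(rbind, repeats) else
         data.frame(id = character(0), start = integer(0), end = integer(0)))
}

#' Generate per-sample genotype states for planted events
#'
#' Draws, per event, a presence allele frequency from
#' `cfg$presence_freq_range`, then per sample a presence/absence state
#' (inbred panel: homozygous present or absent).
#'
#' @param cfg a [synthetic_config()].
#' @param n_indels number of events (rows).
#' @param seed integer seed.
#' @return character matrix (events x samples) over `{present, absent}`.
#' @export
generate_genotypes <- function(cfg = synthetic_config(), n_indels = cfg$n_indels,
                               seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  p <- runif(n_indels, cfg$presence_freq_range[1], cfg$presence_freq_range[2])
  m <- matrix("absent", n_indels, cfg$n_samples,
              dimnames = list(sprintf("IND%04d", seq_len(n_indels)),
                              sprintf("S%03d", seq_len(cfg$n_samples))))
  pres <- matrix(runif(n_indels * cfg$n_samples), n_indels) < p
  m[pres] <- "present"
  m
}

#' Generate two-channel array signals from true call states
#'
#' Each sample's (contrast, intensity) pair is drawn from the bivariate
#' normal of its true cluster (see [synthetic_config()] geometry). With
#' probability `probe_error_rate` the presence state is flipped first
#' (present-type states become `OO` and vice versa, mimicking a probe
#' genotyping error); with probability `dropout_rate` the signal is
#' missing.
#'
#' @param states character matrix (probes x samples) over
#'   `{AA, AB, BB, OA, OB, OO}`.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `contrast` and `intensity` matrices, `truth` (the
#'   input states) and `observed_state` (states after planted errors; the
#'   cluster each signal was actually drawn from).
#' @export
generate_signals <- function(states, cfg = synthetic_config(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  stopifnot(is.matrix(states))
  geom <- cfg$cluster_geometry
  obs <- states
  if (cfg$probe_error_rate > 0) {
    flip <- matrix(runif(length(states)), nrow(states)) < cfg$probe_error_rate
    present_like <- states %in% c("AA", "AB", "BB")
    obs[flip & present_like] <- "OO"
    obs[flip & states == "OO"] <- "AA"
  }
  con <- matrix(NA_real_, nrow(states), ncol(states), dimnames = dimnames(states))
  int <- con
  for (st in names(geom)) {
    sel <- obs == st
    nsel <- sum(sel)
    if (nsel == 0L) next
    g <- geom[[st]]
    con[sel] <- rnorm(nsel, g[["con_mean"]], g[["con_sd"]])
    int[sel] <- rnorm(nsel, g[["int_mean"]], g[["int_sd"]])
  }
  if (cfg$dropout_rate > 0) {
    drop <- matrix(runif(length(states)), nrow(states)) < cfg$dropout_rate
    con[drop] <- NA_real_
    int[drop] <- NA_real_
  }
  list(contrast = con, intensity = int, truth = states, observed_state = obs)
}

#' Generate a direct multi-probe presence-call panel
#'
#' Bypasses the clustering layer: per (line, event) a true presence state
#' is drawn, then each of `k_probes` probe calls independently flips with
#' probability `e`. Used to exercise the consensus layer at the published
#' simulation design (362 lines x 10,000 events).
#'
#' @param n_lines,n_indels panel dimensions.
#' @param k_probes probes per event.
#' @param e per-probe error rate.
#' @param seed integer seed.
#' @param presence_freq presence probability of the true state
#'   (default 0.5).
#' @return list with `calls` (probe-row matrix, `(n_indels * k_probes)` x
#'   `n_lines`, values `"AA"`/`"OO"`), `probe_indel` (row -> event id map)
#'   and `truth` (event x line matrix over `{present, absent}`).
#' @export
generate_multiprobe_panel <- function(n_lines, n_indels, k_probes, e, seed,
                                      presence_freq = 0.5) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("IND%05d", seq_len(n_indels))
  samples <- sprintf("L%03d", seq_len(n_lines))
  truth_present <- matrix(runif(n_indels * n_lines) < presence_freq,
                          n_indels, n_lines, dimnames = list(ids, samples))
  probe_indel <- rep(ids, each = k_probes)
  tp <- truth_present[probe_indel, , drop = FALSE]
  flip <- matrix(runif(length(tp)) < e, nrow(tp))
  observed <- xor(tp, flip)
  calls <- matrix(ifelse(observed, "AA", "OO"), nrow(tp),
                  dimnames = list(sprintf("%s_P%02d", probe_indel,
                                          rep(seq_len(k_probes), n_indels)),
                                  samples))
  truth <- matrix(ifelse(truth_present, "present", "absent"),
                  n_indels, dimnames = dimnames(truth_present))
  list(calls = calls, probe_indel = probe_indel, truth = truth)
}
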