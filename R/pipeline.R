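#' Pipeline configuration
#'
#' Bundles the per-module configurations, the output directory and the
#' seed. Can be written to / read from JSON so that runs are reproducible
#' from a single file.
#'
#' @param outdir output directory (created on demand).
#' @param seed integer seed driving every stochastic stage.
#' @param synthetic,design,calling,markers lists of arguments forwarded to
#'   [synthetic_config()], [design_config()], [calling_config()],
#'   [marker_filter_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, synthetic = list(),
                            design = list(), calling = list(),
                            markers = list()) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, design = design, calling = calling,
                 markers = markers),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON path with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

artifact_paths <- function(outdir) {
  list(reference = file.path(outdir, "reference.fa"),
       alt = file.path(outdir, "alt.fa"),
       variants = file.path(outdir, "variants.vcf"),
       truth = file.path(outdir, "truth.tsv"),
       genotypes = file.path(outdir, "genotypes.tsv"),
       pars = file.path(outdir, "pars.bed"),
       manifest = file.path(outdir, "manifest.tsv"),
       signals = file.path(outdir, "signals.tsv"),
       calls = file.path(outdir, "calls.tsv"),
       probesets = file.path(outdir, "probeset_report.tsv"),
       consensus = file.path(outdir, "consensus.tsv"),
       freqdiff = file.path(outdir, "freqdiff01.tsv"),
       kinship = file.path(outdir, "kinship.csv"),
       pcoa = file.path(outdir, "pcoa.csv"),
       provenance = file.path(outdir, "provenance.json"))
}

need_artifact <- function(paths, keys, stage, produced_by) {
  for (k in keys) {
    if (!file.exists(paths[[k]])) {
      stop(sprintf("stage '%s' requires artifact '%s' produced by stage '%s'",
                   stage, basename(paths[[k]]), produced_by), call. = FALSE)
    }
  }
}

log_counts <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(sprintf("%s=%s", names(c(...)),
                                                  c(...)), collapse = " ")))
}

#' Run the design -> call -> consensus -> diversity pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' fixture. Stages: `"simulate"` (genomes, variants, genotypes),
#' `"design"` (PARs + probe manifest), `"call"` (signals + cluster calls),
#' `"consensus"` (per-event consensus and FreqDiff01), `"diversity"`
#' (marker filters, kinship, PCoA). Every run writes a provenance record
#' (seed, package version, stages). A missing upstream artifact raises an
#' error naming the stage that produces it. Runs with the same
#' configuration and seed produce identical artifacts.
#'
#' @param cfg a [pipeline_config()] (or path to its JSON form).
#' @param stages subset of the stage names above (default: all).
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "design", "call",
                                         "consensus", "diversity")) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(cfg$outdir)
  scfg <- do.call(synthetic_config, cfg$synthetic)
  dcfg <- do.call(design_config, cfg$design)
  ccfg <- do.call(calling_config, cfg$calling)
  mcfg <- do.call(marker_filter_config, cfg$markers)

  if ("simulate" %in% stages) {
    sim <- generate_genomes(scfg, seed = cfg$seed)
    write_fasta(sim$reference, paths$reference)
    write_fasta(sim$alt, paths$alt)
    write_indel_vcf(sim$variants, paths$variants)
    write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    geno <- generate_genotypes(scfg, nrow(sim$truth), seed = cfg$seed + 1L)
    write.table(data.frame(indel_id = rownames(geno), geno,
                           check.names = FALSE),
                paths$genotypes, sep = "\t", quote = FALSE, row.names = FALSE)
    log_counts("simulate", n_indels = nrow(sim$truth),
               ref_bp = nchar(sim$reference), alt_bp = nchar(sim$alt))
  }

  if ("design" %in% stages) {
    need_artifact(paths, c("reference", "alt", "variants"), "design", "simulate")
    ref <- read_fasta(paths$reference)
    alt <- read_fasta(paths$alt)
    variants <- read_indel_vcf(paths$variants)
    manifest <- design_probes(variants, ref, alt, cfg = dcfg,
                              par_bed = paths$pars)
    write_manifest(manifest, paths$manifest)
    log_counts("design", probes = nrow(manifest),
               indels_targeted = length(unique(manifest$indel_id)))
  }

  if ("call" %in% stages) {
    need_artifact(paths, c("manifest", "genotypes"), "call", "design")
    manifest <- read_manifest(paths$manifest)
    gdf <- read.delim(paths$genotypes, check.names = FALSE)
    geno <- as.matrix(gdf[, -1, drop = FALSE])
    rownames(geno) <- gdf$indel_id
    states <- probe_truth_states(manifest, geno)
    sig <- generate_signals(states, scfg, seed = cfg$seed + 2L)
    write_signals(sig, paths$signals)
    calls <- call_signal_matrix(sig, manifest, ccfg, seed = cfg$seed + 3L)
    write_calls(calls, paths$calls)
    qc <- sample_qc(calls, ccfg)
    report <- do.call(rbind, lapply(rownames(calls), function(pid) {
      ptype <- manifest$ptype[match(pid, manifest$probe_id)]
      cls <- classify_probeset(calls[pid, qc$pass], ptype, cfg = ccfg)
      data.frame(probe_id = pid, ptype = ptype, category = cls$category,
                 call_rate = cls$metrics$call_rate,
                 het_freq = cls$metrics$het_freq)
    }))
    write.table(report, paths$probesets, sep = "\t", quote = FALSE,
                row.names = FALSE)
    log_counts("call", probes = nrow(calls),
               samples_pass_qc = sum(qc$pass), samples_fail_qc = sum(!qc$pass))
  }

  if ("consensus" %in% stages) {
    need_artifact(paths, "calls", "consensus", "call")
    need_artifact(paths, "manifest", "consensus", "design")
    calls <- read_calls(paths$calls)
    manifest <- read_manifest(paths$manifest)
    probe_indel <- manifest$indel_id[match(rownames(calls), manifest$probe_id)]
    ct <- consensus_table(calls, probe_indel)
    write.table(data.frame(indel_id = rownames(ct$consensus), ct$consensus,
                           check.names = FALSE),
                paths$consensus, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(indel_id = names(ct$freq_diff01),
                           freq_diff01 = ct$freq_diff01),
                paths$freqdiff, sep = "\t", quote = FALSE, row.names = FALSE)
    log_counts("consensus", indels = nrow(ct$consensus),
               mean_freqdiff01 = signif(mean(ct$freq_diff01, na.rm = TRUE), 3))
  }

  if ("diversity" %in% stages) {
    need_artifact(paths, "consensus", "diversity", "consensus")
    cdf <- read.delim(paths$consensus, check.names = FALSE)
    cons <- as.matrix(cdf[, -1, drop = FALSE])
    dos <- matrix(c(present = 1, absent = 0, missing = NA)[cons],
                  nrow(cons), dimnames = list(cdf$indel_id, colnames(cons)))
    kept <- filter_markers(dos, mcfg)
    if (nrow(kept) == 0L) stop("no markers pass the diversity filters", call. = FALSE)
    K <- ibd_kinship(kept)
    write.csv(as.matrix(unclass(K)), paths$kinship, row.names = TRUE)
    pc <- pcoa(kinship_distance(K), n_axes = 2L)
    write.csv(data.frame(sample_id = rownames(pc$coords), pc$coords),
              paths$pcoa, row.names = FALSE)
    log_counts("diversity", markers_in = nrow(dos), markers_kept = nrow(kept))
  }

  prov <- list(package = "indelchip",
               version = as.character(packageVersion("indelchip")),
               seed = cfg$seed, stages = stages,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Design probes for a set of variants (high-level)
#'
#' End-to-end design for one reference/alternative genome pair: BP probes
#' from the junctions (designable breakpoints only), PAR detection inside
#' each event against the other line's 17-mer index, MONO candidate tiling,
#' scoring, filtering, windowed selection with the <4-probe retry, rescue
#' of untargeted events, and duplicate removal.
#'
#' @param variants list of [indel_variant()].
#' @param reference,alt named character vectors of genome sequences.
#' @param cfg a [design_config()].
#' @param k_par k-mer size for PAR detection (default 17).
#' @param par_bed optional path: write detected PARs as BED
#'   (event-relative coordinates).
#' @return probe manifest data.frame.
#' @export
design_probes <- function(variants, reference, alt, cfg = design_config(),
                          k_par = 17L, par_bed = NULL) {
  idx_ref <- kmer_index(reference, k = k_par, min_occurrence = 1L)
  idx_alt <- kmer_index(alt, k = k_par, min_occurrence = 1L)
  counts_ref <- genome_kmer_counts(reference, cfg$hit_kmer)
  all_cands <- list()
  bp_rows <- list()
  pars_by_indel <- list()
  par_records <- list()
  for (v in variants) {
    bp <- classify_breakpoint(v)
    if (!bp$design_excluded) {
      pr <- design_bp_probe(v, bp)
      if (!is_design_failure(pr)) {
        pr$position <- pr$shift
        pr$par_overlap_frac <- NA_real_
        pr$genome_hits <- vapply(pr$seq, count_genome_hits, integer(1),
                                 genome = reference)
        pr$hit16 <- NA_integer_
        pr$score <- NA_real_
        pr$classification <- "bp"
        pr$kind <- v$kind
        bp_rows[[v$id]] <- pr[, names(empty_candidates())]
      }
    }
    ## PARs: parts of the event sequence not covered by the other line
    other_idx <- if (v$kind == "deletion_vs_ref") idx_alt else idx_ref
    if (nchar(v$deleted_seq) >= k_par) {
      pars <- annotate_uncovered_regions(v$deleted_seq, other_idx, k = k_par)
      ## hit filtering is against the line NOT carrying the event for
      ## insertions (no hit expected) and the reference for deletions
      cands <- tile_candidates(v$id, v$deleted_seq, pars,
                               genome = reference, kind = v$kind,
                               ptype = "MONO", counts16 = counts_ref, cfg = cfg)
      pars_by_indel[[v$id]] <- pars
      if (nrow(pars) > 0L) {
        par_records[[v$id]] <- data.frame(seq_id = v$id, start = pars$start,
                                          end = pars$end)
      }
      all_cands[[v$id]] <- cands
    }
  }
  if (!is.null(par_bed)) {
    pr <- do.call(rbind, unname(par_records))
    if (is.null(pr)) pr <- data.frame(seq_id = character(0), start = integer(0),
                                      end = integer(0))
    write_bed(pr, par_bed)
  }
  cands <- do.call(rbind, c(unname(all_cands), list(empty_candidates())))
  kept <- filter_candidates(cands, cfg)
  sel_list <- lapply(split(kept, kept$indel_id), function(ci) {
    select_windowed(ci, pars_by_indel[[ci$indel_id[1]]], cfg)$selected
  })
  selected <- do.call(rbind, c(unname(sel_list), list(empty_candidates())))
  resc <- rescue_untargeted(selected, cands, pars_by_indel,
                            indel_ids = vapply(variants, `[[`, character(1), "id"),
                            cfg = cfg)
  bp_all <- do.call(rbind, c(unname(bp_rows), list(empty_candidates())))
  bp_kept <- bp_all[bp_all$genome_hits <= cfg$max_hits_bp_probe, , drop = FALSE]
  manifest <- dedupe_probes(rbind(resc$selected, bp_kept))
  rownames(manifest) <- NULL
  manifest
}

## truth call state per manifest probe from event-level genotypes:
## BP probes are codominant (presence -> AA on FW / BB on REV strand,
## absence -> OO); internal probes hybridise only when present (AA vs OO)
probe_truth_states <- function(manifest, genotypes) {
  states <- matrix("OO", nrow(manifest), ncol(genotypes),
                   dimnames = list(manifest$probe_id, colnames(genotypes)))
  for (i in seq_len(nrow(manifest))) {
    g <- genotypes[manifest$indel_id[i], ]
    present <- g == "present"
    lab <- if (manifest$ptype[i] == "BP" && manifest$strand[i] == "REV") "BB" else "AA"
    states[i, present] <- lab
  }
  states
}

## fit + call every probe of a signal matrix according to its type
call_signal_matrix <- function(signals, manifest, cfg = calling_config(),
                               seed = 1L) {
  con <- signals$contrast; int <- signals$intensity
  calls <- matrix("NoCall", nrow(con), ncol(con), dimnames = dimnames(con))
  for (i in seq_len(nrow(con))) {
    pid <- rownames(con)[i]
    ptype <- manifest$ptype[match(pid, manifest$probe_id)]
    model <- fit_clusters(con[i, ], int[i, ], cfg = cfg, seed = seed + i)
    calls[i, ] <- switch(
      ptype,
      BP = call_bp(model, con[i, ], int[i, ], cfg),
      OTV = call_otv(model, con[i, ], int[i, ], cfg),
      as.vector(call_mono_hom2otv(model, con[i, ], int[i, ],
                                  calling_config(inbred_penalty = 16L))))
  }
  calls
}
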