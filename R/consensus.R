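#' Map array calls to presence dosages
#'
#' Converts the 7-state call alphabet to presence of the InDel sequence:
#' `AA`/`AB`/`BB` -> 1 (present), `OO` -> 0 (absent), `OA`/`OB` -> 0.5
#' (hemizygous, one copy present), `NoCall`/`NA` -> `NA` (missing).
#'
#' @param calls character vector or matrix of calls.
#' @return numeric object of the same shape with values in
#'   `{0, 0.5, 1, NA}`.
#' @export
presence_code <- function(calls) {
  map <- c(AA = 1, AB = 1, BB = 1, OO = 0, OA = 0.5, OB = 0.5, NoCall = NA)
  out <- map[calls]
  if (is.matrix(calls)) out <- matrix(out, nrow(calls), ncol(calls),
                                      dimnames = dimnames(calls))
  unname_if_vector(out, calls)
}

unname_if_vector <- function(out, template) {
  if (!is.matrix(template)) out <- unname(out)
  out
}

#' Average presence frequency across probes
#'
#' Mean presence dosage over the non-missing probes of one InDel for one
#' sample (hemizygous counts 0.5); `NA` when every probe is missing.
#'
#' @param dosages numeric vector of presence dosages (see
#'   [presence_code()]).
#' @return numeric scalar in `[0, 1]` or `NA`.
#' @export
presence_frequency <- function(dosages) {
  if (all(is.na(dosages))) return(NA_real_)
  mean(dosages, na.rm = TRUE)
}

#' Consensus presence genotype from the average frequency
#'
#' Assigns the most frequent presence allele: `present` when the frequency
#' exceeds 0.5, `absent` below 0.5, and `missing` on an exact tie (0.5) or
#' when the frequency itself is missing. Treating ties as missing (rather
#' than errors) is what makes the 2-probe consensus error equal
#' P(both probes wrong).
#'
#' @param freq presence frequency (numeric vector allowed).
#' @return character vector over `{present, absent, missing}`.
#' @export
consensus_genotype <- function(freq) {
  out <- rep("missing", length(freq))
  out[!is.na(freq) & freq > 0.5] <- "present"
  out[!is.na(freq) & freq < 0.5] <- "absent"
  out
}

#' Fraction of samples with an inconsistent probe set (FreqDiff01)
#'
#' For one InDel across samples: the fraction of samples whose defined
#' average presence frequency is neither 0 nor 1, i.e. at least one probe
#' disagrees with the others. Samples with no defined frequency are
#' excluded from the denominator.
#'
#' @param freqs numeric vector of per-sample presence frequencies.
#' @return numeric scalar in `[0, 1]` (`NaN` when no frequency is defined).
#' @export
freq_diff01 <- function(freqs) {
  def <- !is.na(freqs)
  mean(freqs[def] != 0 & freqs[def] != 1)
}

#' Consensus table for a call matrix
#'
#' Applies [presence_frequency()] and [consensus_genotype()] per
#' (InDel, sample) and [freq_diff01()] per InDel.
#'
#' @param calls character matrix of probe calls (probes x samples).
#' @param probe_indel character vector mapping each probe (row) to its
#'   InDel id.
#' @return list with `freq` (InDel x sample matrix), `consensus` (character
#'   matrix) and `freq_diff01` (named numeric vector per InDel).
#' @export
consensus_table <- function(calls, probe_indel) {
  stopifnot(is.matrix(calls), length(probe_indel) == nrow(calls))
  dos <- presence_code(calls)
  ids <- unique(probe_indel)
  freq <- matrix(NA_real_, length(ids), ncol(calls),
                 dimnames = list(ids, colnames(calls)))
  for (i in seq_along(ids)) {
    rows <- dos[probe_indel == ids[i], , drop = FALSE]
    freq[i, ] <- apply(rows, 2, presence_frequency)
  }
  cons <- matrix(consensus_genotype(freq), nrow(freq), ncol(freq),
                 dimnames = dimnames(freq))
  list(freq = freq, consensus = cons,
       freq_diff01 = apply(freq, 1, freq_diff01))
}

#' Simulate multi-probe consensus genotyping error
#'
#' For each of `n_lines * n_indels` observations and each combination of
#' probe count `k` and per-probe error rate `e`, the number of erroneous
#' probes is a binomial draw (`k` trials, success probability `e`); the
#' consensus assigns the most frequent presence allele, exact ties being
#' missing. Reported per (k, e): the consensus error rate (erroneous
#' consensus calls / all observations -- ties are missing, never errors),
#' the missing (tie) rate, and the mean FreqDiff01 (observations with at
#' least one erroneous probe but not all).
#'
#' Closed forms used as test oracles: error = P(X > k/2), missing =
#' P(X = k/2), FreqDiff01 = 1 - (1-e)^k - e^k for X ~ Binomial(k, e).
#'
#' @param k integer vector of probe counts (2..50 in the published design).
#' @param e numeric vector of per-probe error rates.
#' @param n_lines,n_indels simulation design (defaults 362 and 10,000).
#' @param seed integer seed (mandatory).
#' @return data.frame keyed by (`k`, `e`) with columns
#'   `consensus_error_rate`, `missing_rate`, `freq_diff01`, `n_obs`.
#' @export
simulate_probe_errors <- function(k, e, n_lines = 362L, n_indels = 10000L,
                                  seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(all(e >= 0), all(e <= 1), all(k >= 1))
  set.seed(seed)
  n <- as.numeric(n_lines) * as.numeric(n_indels)
  grid <- expand.grid(k = as.integer(k), e = as.numeric(e),
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    kk <- grid$k[i]; ee <- grid$e[i]
    wrong <- rbinom(n, kk, ee)
    data.frame(k = kk, e = ee,
               consensus_error_rate = sum(wrong > kk / 2) / n,
               missing_rate = sum(2L * wrong == kk) / n,
               freq_diff01 = mean(wrong > 0L & wrong < kk),
               n_obs = n)
  })
  do.call(rbind, res)
}

#' Concordance between two presence matrices
#'
#' Fraction of equal entries among entries non-missing in both matrices;
#' optionally stratified (e.g. by probe type or genotype class). Symmetric
#' in its two arguments.
#'
#' @param a,b matrices (or vectors) of identical shape; `NA` = missing.
#' @param strata optional factor/character object of the same shape; one
#'   rate per level is returned in addition to the overall rate.
#' @return named numeric vector: `overall`, then one element per stratum.
#' @export
concordance <- function(a, b, strata = NULL) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  out <- c(overall = if (any(ok)) mean(a[ok] == b[ok]) else NA_real_)
  if (!is.null(strata)) {
    for (lv in sort(unique(as.vector(strata[ok])))) {
      sel <- ok & strata == lv
      out[lv] <- mean(a[sel] == b[sel])
    }
  }
  out
}

#' Genotyping-by-sequencing presence matrix from probe alignment
#'
#' A probe is called present in a line when its sequence aligns to that
#' line's assembly with less than `max_mismatch_frac` mismatches
#' (<= floor(0.05 * 35) = 1 mismatch for a 35 bp probe, either strand, no
#' indels), otherwise absent. Probes spanning unassembled gaps therefore
#' come out absent -- the false-absent mechanism of draft assemblies.
#'
#' @param probe_seqs named character vector of probe sequences.
#' @param assemblies named list: one named character vector of sequences
#'   (or FASTA path) per line.
#' @param max_mismatch_frac maximum mismatch fraction (default 0.05).
#' @return numeric matrix (probes x lines) of 1 (present) / 0 (absent).
#' @export
gbs_from_probe_alignment <- function(probe_seqs, assemblies,
                                     max_mismatch_frac = 0.05) {
  lines <- names(assemblies)
  out <- matrix(0, length(probe_seqs), length(assemblies),
                dimnames = list(names(probe_seqs), lines))
  for (ln in lines) {
    genome <- assemblies[[ln]]
    if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
      genome <- read_fasta(genome)
    }
    subject <- Biostrings::DNAStringSet(toupper(unname(genome)))
    for (i in seq_along(probe_seqs)) {
      p <- Biostrings::DNAString(toupper(probe_seqs[[i]]))
      mm <- floor(max_mismatch_frac * length(p))
      hit <- sum(Biostrings::vcountPattern(p, subject, max.mismatch = mm)) +
        sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p),
                                      subject, max.mismatch = mm))
      if (hit > 0) out[i, ln] <- 1
    }
  }
  out
}

#' Mendelian consistency of F1 calls against parental BP calls
#'
#' Predicts F1 genotypes from the two parents (present x present ->
#' present, absent x absent -> absent, present x absent -> hemizygous) and
#' compares with the observed F1 calls. Probes with missing or hemizygous
#' parental calls are excluded.
#'
#' @param parent1,parent2,f1 presence dosage vectors (one entry per probe,
#'   values 0 / 0.5 / 1 / NA as from [presence_code()]).
#' @return list with `overall`, `homozygous` and `hemizygous` consistency
#'   rates and `n_used` probes.
#' @export
mendelian_check <- function(parent1, parent2, f1) {
  stopifnot(length(parent1) == length(parent2),
            length(parent1) == length(f1))
  usable <- !is.na(parent1) & !is.na(parent2) &
    parent1 %in% c(0, 1) & parent2 %in% c(0, 1) & !is.na(f1)
  predicted <- (parent1 + parent2) / 2
  hom <- usable & (predicted %in% c(0, 1))
  hemi <- usable & predicted == 0.5
  rate <- function(sel) if (any(sel)) mean(f1[sel] == predicted[sel]) else NA_real_
  list(overall = rate(usable), homozygous = rate(hom),
       hemizygous = rate(hemi), n_used = sum(usable))
}
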