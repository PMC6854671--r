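# Independent oracles used across the suite. These deliberately use naive
# loops / closed forms rather than the package's own code paths.

# brute-force longest common prefix, stopping at N, case-insensitive
oracle_lcp <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- 0L
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i] || a[i] == "N") break
    n <- n + 1L
  }
  n
}

oracle_lcs <- function(a, b) {
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  oracle_lcp(rev1(a), rev1(b))
}

# canonicalise k-mers in one vectorised Biostrings call (string plumbing
# only; the coverage logic under test below stays naive)
oracle_canonical <- function(kms) {
  if (length(kms) == 0L) return(kms)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kms)))
  pmin(kms, rc)
}

# per-position brute-force PAR scan: position p (1-based) of target is
# covered iff some k-window overlapping p is present (canonically) in any
# of the others' k-mer string sets
oracle_uncovered <- function(target, other_kmer_sets, k, min_len = 35L) {
  target <- toupper(target)
  L <- nchar(target)
  nw <- L - k + 1L
  wins <- oracle_canonical(substring(target, 1:nw, k:L))
  win_cov <- Reduce(`|`, lapply(other_kmer_sets, function(s) wins %in% s))
  pos_cov <- logical(L)
  for (i in seq_len(nw)) if (win_cov[i]) pos_cov[i:(i + k - 1L)] <- TRUE
  runs <- rle(pos_cov)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(start = integer(0), end = integer(0))
  for (j in seq_along(runs$values)) {
    if (!runs$values[j] && runs$lengths[j] >= min_len) {
      out <- rbind(out, data.frame(start = starts[j] - 1L, end = ends[j]))
    }
  }
  out
}

# canonical k-mer set of one sequence
oracle_kmer_set <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  kms <- substring(seq, 1:n, k:(n + k - 1L))
  kms <- kms[!grepl("N", kms)]
  unique(oracle_canonical(kms))
}

# exact consensus-error / missing / FreqDiff01 closed forms for X~Bin(k,e)
oracle_consensus_error <- function(k, e) {
  j <- 0:k
  p <- dbinom(j, k, e)
  sum(p[j > k / 2])
}
oracle_missing_rate <- function(k, e) {
  if (k %% 2L == 1L) return(0)
  dbinom(k / 2L, k, e)
}
oracle_freqdiff01 <- function(k, e) 1 - (1 - e)^k - e^k

# naive kinship: direct double loop over the estimator's definition
oracle_kinship <- function(X, p = rowMeans(X, na.rm = TRUE)) {
  use <- p > 0 & p < 1 & !is.na(p)
  X <- X[use, , drop = FALSE]; p <- p[use]
  n <- ncol(X)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    K[i, j] <- mean((X[ok, i] - p[ok]) * (X[ok, j] - p[ok]) /
                      (p[ok] * (1 - p[ok])))
  }
  K
}

other_base_for_test <- function(b) setdiff(c("A", "C", "G", "T"), toupper(b))[1]

# random indel_variant with planted homology for property tests
random_planted_variant <- function(id, type = sample(c("I", "II", "III", "IV"), 1),
                                   m_range = 1:5, len = 120L, flank = 60L) {
  m <- if (type %in% c("II", "IV")) sample(m_range, 1L) else 0L
  i_len <- if (type %in% c("III", "IV")) sample(1:30, 1L) else 0L
  right <- indelchip::random_dna(flank)
  left <- indelchip::random_dna(flank)
  body <- indelchip::random_dna(len - m)
  s <- paste0(substr(right, 1, m), body)
  bpos <- m + 1L
  if (substr(s, bpos, bpos) == substr(right, bpos, bpos)) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(right, bpos, bpos))[1]
    s <- paste0(substr(s, 1, m), alt, substr(s, m + 2L, nchar(s)))
  }
  if (substr(s, nchar(s), nchar(s)) == substr(left, flank, flank)) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(left, flank, flank))[1]
    s <- paste0(substr(s, 1, nchar(s) - 1L), alt)
  }
  list(v = indel_variant(id = id, kind = "deletion_vs_ref",
                         deleted_seq = s,
                         inserted_fragment = if (i_len) indelchip::random_dna(i_len) else "",
                         left_flank = left, right_flank = right, min_len = 0L),
       type = type, m = m, i = i_len)
}
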