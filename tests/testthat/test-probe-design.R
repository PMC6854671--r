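# brute-force occurrence count of a substring in a genome (both strands)
oracle_substring_count <- function(pat, genome) {
  count_fixed <- function(p, s) {
    n <- 0L; from <- 1L
    repeat {
      hit <- regexpr(p, substr(s, from, nchar(s)), fixed = TRUE)
      if (hit == -1L) break
      n <- n + 1L
      from <- from + hit
    }
    n
  }
  sum(vapply(genome, function(s) {
    count_fixed(pat, s) + count_fixed(pat, revcomp(s))
  }, integer(1)))
}

test_that("count_16mer_hits equals the brute-force window count", {
  set.seed(31)
  genome <- c(chr1 = random_dna(10000))
  counts <- genome_kmer_counts(genome, 16)
  # probe lifted from the genome: every window hits at least its own locus
  probe <- substr(genome, 501, 535)
  h <- count_16mer_hits(probe, counts)
  wins <- c(substring(substr(probe, 1, 17), 1:2, 16:17),
            substring(substr(probe, 19, 35), 1:2, 16:17))
  expect_equal(h, sum(vapply(wins, oracle_substring_count, integer(1),
                             genome = genome)))
  expect_gte(h, 4L) # 4 windows, each with >= 1 hit

  # probe from a triplicated segment: every window counts 3
  seg <- random_dna(60)
  g3 <- c(chr1 = paste0(random_dna(100), seg, random_dna(100), seg,
                        random_dna(100), seg, random_dna(100)))
  c3 <- genome_kmer_counts(g3, 16)
  p3 <- substr(seg, 10, 44)
  expect_equal(count_16mer_hits(p3, c3), 4L * 3L)

  # probe absent from the genome
  expect_equal(count_16mer_hits(random_dna(35), counts), 0L)
  # windows containing N contribute 0: N in the left flank silences both
  # left windows, leaving only the right-flank windows
  pN <- paste0(substr(probe, 1, 4), "N", substr(probe, 6, 35))
  right_wins <- substring(substr(probe, 19, 35), 1:2, 16:17)
  expect_equal(count_16mer_hits(pN, counts),
               sum(vapply(right_wins, oracle_substring_count, integer(1),
                          genome = genome)))
})

test_that("count_genome_hits counts both strands", {
  set.seed(32)
  seg <- random_dna(35)
  genome <- c(chr1 = paste0(random_dna(50), seg, random_dna(50), revcomp(seg),
                            random_dna(50)))
  expect_equal(count_genome_hits(seg, genome), 2L)
  expect_equal(count_genome_hits(random_dna(35), genome), 0L)
})

test_that("score_probe classification follows the published thresholds", {
  set.seed(33)
  cfg <- design_config()
  # a benign random probe with no flank polymorphism is recommended
  repeat {
    p <- random_dna(35)
    s <- score_probe(p)
    if (s$score >= 0.6) break
  }
  expect_equal(s$classification, "recommended")
  # same score but polymorphisms at tolerated distances -> neutral
  s2 <- score_probe(p, poly_distances = c(25L, 30L))
  expect_equal(s2$classification, "neutral")
  # a polymorphism closer than 21 bp demotes to not_recommended
  s3 <- score_probe(p, poly_distances = c(10L))
  expect_equal(s3$classification, "not_recommended")
  # 3 polymorphisms exceed the neutral cap
  s4 <- score_probe(p, poly_distances = c(25L, 28L, 30L))
  expect_equal(s4$classification, "not_recommended")
  # degenerate homopolymer is not designable
  expect_equal(score_probe(strrep("A", 35))$classification, "not_possible")
  # N at the interrogated base is not designable
  pn <- paste0(substr(p, 1, 17), "N", substr(p, 19, 35))
  expect_equal(score_probe(pn)$classification, "not_possible")
  expect_error(score_probe("XYZ"), "ACGTN")
  # score is monotone in the hit16 excess
  expect_gte(score_probe(p, hit16 = 4L)$score, score_probe(p, hit16 = 40L)$score)
})

test_that("filter_candidates applies class, hit and PAR-overlap rules per probe type", {
  base <- empty_candidates()
  row <- function(ptype, kind, hits, class, par = 0.9, id = "p") {
    data.frame(probe_id = id, indel_id = "i", ptype = ptype, strand = "FW",
               seq = strrep("A", 35), position = 0L, par_overlap_frac = par,
               genome_hits = hits, hit16 = 4L, score = 0.5,
               classification = class, kind = kind)
  }
  cands <- rbind(
    row("MONO", "deletion_vs_ref", 2L, "recommended", id = "del2hits"),
    row("MONO", "deletion_vs_ref", 1L, "recommended", id = "del1hit"),
    row("OTV", "insertion_vs_ref", 1L, "recommended", id = "ins1hit"),
    row("OTV", "insertion_vs_ref", 0L, "neutral", id = "ins0hit"),
    row("BP", "deletion_vs_ref", 1L, "not_recommended", id = "bp1hit"),
    row("BP", "deletion_vs_ref", 3L, "not_recommended", id = "bp3hits"),
    row("MONO", "deletion_vs_ref", 0L, "recommended", par = 0.6, id = "par60"),
    row("MONO", "deletion_vs_ref", 0L, "not_recommended", id = "notrec"))
  kept <- filter_candidates(cands, design_config())
  expect_setequal(kept$probe_id, c("del1hit", "ins0hit", "bp1hit"))
})

test_that("windowed selection reproduces hand-enumerated window counts and the retry rule", {
  cfg <- design_config()
  cand_at <- function(pos, scores) {
    set.seed(34)
    data.frame(probe_id = sprintf("c%04d", pos), indel_id = "i1", ptype = "MONO",
               strand = "FW", seq = random_dna(rep(35, length(pos))),
               position = pos, par_overlap_frac = 1, genome_hits = 1L,
               hit16 = 4L, score = scores,
               classification = "recommended", kind = "deletion_vs_ref")
  }
  # 400 bp PAR, candidates every 5 bp with scores decreasing along the PAR:
  # 6 windows at 75 bp (last one partial), each won by its leftmost
  # overlapping candidate -> starts 0, 45, 120, 195, 270, 345; no retry.
  pos <- seq(0L, 365L, by = 5L)
  dense <- cand_at(pos, 0.9 - 0.0005 * pos)
  res <- select_windowed(dense, data.frame(start = 0L, end = 400L), cfg)
  expect_equal(res$window_size, 75L)
  expect_equal(res$selected$position, c(0L, 45L, 120L, 195L, 270L, 345L))

  # 160 bp PAR, candidates at 0/45/90/125 with decreasing scores:
  # 75 bp pass -> 3 windows -> bests {0, 45, 125} (< 4) -> retried at
  # 50 bp -> 4 windows -> bests {0, 45, 90, 125}: the <4 retry stops.
  four <- cand_at(c(0L, 45L, 90L, 125L), c(0.9, 0.8, 0.7, 0.6))
  res2 <- select_windowed(four, data.frame(start = 0L, end = 160L), cfg)
  expect_equal(res2$window_size, 50L)
  expect_equal(res2$selected$position, c(0L, 45L, 90L, 125L))

  # 60 bp PAR with two sparse candidates: the 25 bp iteration is reached
  # and returns both ({0} wins [0,25) and [25,50), {25} wins [50,60)).
  sparse <- cand_at(c(0L, 25L), c(0.8, 0.7))
  res3 <- select_windowed(sparse, data.frame(start = 0L, end = 60L), cfg)
  expect_equal(res3$window_size, 25L)
  expect_equal(nrow(res3$selected), 2L)

  # ties break on the lexicographically smaller probe_id
  tied <- cand_at(seq(0L, 65L, by = 5L), 0.7)
  res4 <- select_windowed(tied, data.frame(start = 0L, end = 100L), cfg)
  expect_equal(res4$selected$probe_id[1], "c0000")
})

test_that("rescue targets only probe-less InDels and dedupe keeps best carriers", {
  sel <- data.frame(probe_id = "kept", indel_id = "i1", ptype = "MONO",
                    strand = "FW", seq = strrep("C", 35), position = 0L,
                    par_overlap_frac = 1, genome_hits = 0L, hit16 = 0L,
                    score = 0.8, classification = "recommended",
                    kind = "deletion_vs_ref")
  cands <- rbind(sel, data.frame(
    probe_id = c("r1", "r2"), indel_id = "i2", ptype = "MONO", strand = "FW",
    seq = c(strrep("G", 35), strrep("T", 35)), position = c(0L, 40L),
    par_overlap_frac = 1, genome_hits = 0L, hit16 = 0L, score = c(0.35, 0.3),
    classification = "not_recommended", kind = "deletion_vs_ref"))
  pars <- list(i1 = data.frame(start = 0L, end = 80L),
               i2 = data.frame(start = 0L, end = 80L))
  out <- rescue_untargeted(sel, cands, pars, indel_ids = c("i1", "i2", "i3"))
  expect_true(all(c("r1", "r2") %in% out$selected$probe_id))
  expect_equal(out$untargeted, "i3")
  # already-targeted InDel is unchanged
  expect_equal(sum(out$selected$indel_id == "i1"), 1L)

  # dedupe: identical sequences collapse to the higher score
  dup <- rbind(sel, transform(sel, probe_id = "dup", score = 0.5))
  dd <- dedupe_probes(dup)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$probe_id, "kept")
  # tie on score -> lexicographically smaller id
  tie <- rbind(transform(sel, probe_id = "zzz"), transform(sel, probe_id = "aaa"))
  expect_equal(dedupe_probes(tie)$probe_id, "aaa")
  # all unique -> unchanged
  uniq <- rbind(sel, transform(sel, probe_id = "other", seq = strrep("T", 35)))
  expect_equal(nrow(dedupe_probes(uniq)), 2L)
})

test_that("tile_candidates computes PAR overlap and respects N-free probes", {
  set.seed(35)
  genome <- c(chr1 = random_dna(3000))
  indel_seq <- substr(genome, 1001, 1400) # 400 bp, present once in genome
  pars <- data.frame(start = 50L, end = 250L)
  cands <- tile_candidates("i1", indel_seq, pars, genome,
                           kind = "deletion_vs_ref", ptype = "MONO", step = 10L)
  expect_true(all(cands$position >= 50 & cands$position + 35 <= 250))
  expect_true(all(cands$par_overlap_frac == 1))
  expect_true(all(cands$genome_hits == 1L))
  expect_true(all(nchar(cands$seq) == 35L))
  # selection end-to-end keeps only candidates passing every exhaustive assertion
  kept <- filter_candidates(cands, design_config())
  sel <- select_windowed(kept, pars, design_config())
  expect_true(all(sel$selected$par_overlap_frac > 0.70))
  expect_true(all(sel$selected$genome_hits <= 1L))
})

test_that("probe count tracks cumulated PAR length rather than InDel length", {
  set.seed(36)
  genome <- c(chr1 = random_dna(2000))
  cfg <- design_config()
  n_sel <- function(indel_len, par_len) {
    indel_seq <- random_dna(indel_len)
    pars <- data.frame(start = 0L, end = par_len)
    cands <- tile_candidates(sprintf("i%d_%d", indel_len, par_len), indel_seq,
                             pars, genome, kind = "deletion_vs_ref",
                             ptype = "MONO", step = 5L)
    kept <- filter_candidates(cands, cfg)
    nrow(select_windowed(kept, pars, cfg)$selected)
  }
  # same InDel length, growing PARs -> non-decreasing probe counts
  counts <- vapply(c(100L, 300L, 600L), function(pl) n_sel(800L, pl), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
  # larger InDel with the same PAR does not get more probes
  expect_equal(n_sel(2000L, 150L), n_sel(400L, 150L))
})
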