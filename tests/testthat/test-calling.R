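# draw one probe's signals from named cluster states using the package
# geometry; returns contrast/intensity vectors plus the truth states
draw_signals <- function(states, seed, geom = default_cluster_geometry()) {
  set.seed(seed)
  con <- int <- numeric(length(states))
  for (st in unique(states)) {
    g <- geom[[st]]
    sel <- states == st
    con[sel] <- rnorm(sum(sel), g[["con_mean"]], g[["con_sd"]])
    int[sel] <- rnorm(sum(sel), g[["int_mean"]], g[["int_sd"]])
  }
  list(con = con, int = int)
}

test_that("fit_clusters recovers well-separated components and flags thin data", {
  states <- rep(c("AA", "OO"), c(60, 40))
  s <- draw_signals(states, 41)
  model <- fit_clusters(s$con, s$int, seed = 7)
  expect_equal(model$k, 2L)
  # means within 0.5 SD of the generating truth
  ints <- sort(model$means[, "intensity"])
  expect_lt(abs(ints[1] - 7), 0.5 * 0.4)
  expect_lt(abs(ints[2] - 10), 0.5 * 0.3)

  # all samples at one point -> a single component
  one <- fit_clusters(rep(1.5, 20), rep(10, 20), seed = 7)
  expect_equal(one$k, 1L)

  # < 10 usable samples -> insufficient
  thin <- fit_clusters(rnorm(5), rnorm(5), seed = 7)
  expect_true(thin$insufficient)
  expect_equal(call_bp(thin, rnorm(5), rnorm(5)), rep("NoCall", 5))
})

test_that("call_bp labels presence/absence/hemizygous clusters and NoCalls ambiguity", {
  states <- c(rep("AA", 50), rep("BB", 40), rep("OO", 30))
  s <- draw_signals(states, 42)
  model <- fit_clusters(s$con, s$int, seed = 3)
  calls <- call_bp(model, s$con, s$int)
  expect_gte(mean(calls == states), 0.995)

  # hemizygous cluster at intermediate intensity -> OA
  states2 <- c(rep("AA", 50), rep("OA", 25), rep("OO", 30))
  s2 <- draw_signals(states2, 43)
  model2 <- fit_clusters(s2$con, s2$int, seed = 3)
  calls2 <- call_bp(model2, s2$con, s2$int)
  expect_gte(mean(calls2 == states2), 0.95)

  # a sample on the posterior decision boundary between two clusters is
  # NoCall (posterior ~0.5 < confidence threshold)
  s3 <- draw_signals(rep(c("AA", "BB"), c(30, 30)), 44)
  m3 <- fit_clusters(s3$con, s3$int, seed = 3)
  mid_int <- mean(m3$means[, "intensity"])
  logdiff <- function(x) {
    d <- vapply(1:2, function(j) {
      log(m3$weights[j]) + dnorm(x, m3$means[j, 1], m3$sds[j, 1], log = TRUE) +
        dnorm(mid_int, m3$means[j, 2], m3$sds[j, 2], log = TRUE)
    }, numeric(1))
    d[1] - d[2]
  }
  boundary <- uniroot(logdiff, sort(m3$means[, 1]))$root
  expect_equal(call_bp(m3, boundary, mid_int), "NoCall")

  # missing signals are NoCall
  expect_equal(call_bp(m3, c(NA, 1.5), c(10, NA)), c("NoCall", "NoCall"))
})

test_that("call_otv relabels a low-intensity AB cluster as OO and keeps true AB", {
  # OO cluster sits at AB-like contrast but 3 intensity units below
  states <- c(rep("AA", 40), rep("BB", 40), rep("OO", 30))
  s <- draw_signals(states, 45)
  model <- fit_clusters(s$con, s$int, seed = 5)
  calls <- call_otv(model, s$con, s$int)
  expect_gte(mean(calls == states), 0.995)
  expect_true("OO" %in% calls)

  # genuine AB at homozygous intensity is retained
  states2 <- c(rep("AA", 40), rep("BB", 40), rep("AB", 20))
  s2 <- draw_signals(states2, 46)
  model2 <- fit_clusters(s2$con, s2$int, seed = 5)
  calls2 <- call_otv(model2, s2$con, s2$int, calling_config(inbred_penalty = 0L))
  expect_gte(mean(calls2 == states2), 0.95)
  expect_false("OO" %in% calls2)

  # four clusters: all four labels emitted
  states4 <- c(rep("AA", 40), rep("BB", 40), rep("AB", 20), rep("OO", 30))
  s4 <- draw_signals(states4, 47)
  model4 <- fit_clusters(s4$con, s4$int, seed = 5,
                         cfg = calling_config(inbred_penalty = 0L))
  calls4 <- call_otv(model4, s4$con, s4$int, calling_config(inbred_penalty = 0L))
  expect_setequal(intersect(unique(calls4), c("AA", "AB", "BB", "OO")),
                  c("AA", "AB", "BB", "OO"))
  expect_gte(mean(calls4 == states4), 0.95)
})

test_that("Hom2OTV recalls the lower-intensity homozygous cluster as OO", {
  # two clusters at the same contrast, 3-unit (>= 6 SD) intensity gap
  states <- rep(c("AA", "OO"), c(60, 40))
  geom <- default_cluster_geometry()
  geom$AA[["con_mean"]] <- 0 # monomorphic probes have contrast-neutral presence
  s <- draw_signals(states, 48, geom)
  model <- fit_clusters(s$con, s$int, seed = 9)
  calls <- call_mono_hom2otv(model, s$con, s$int)
  expect_equal(attr(calls, "status"), "hom2otv")
  expect_gte(mean(calls == states), 0.995)

  # two clusters separated mainly in contrast: an unexpected SNP, no OO
  snp_states <- rep(c("AA", "BB"), c(50, 50))
  s2 <- draw_signals(snp_states, 49)
  model2 <- fit_clusters(s2$con, s2$int, seed = 9)
  calls2 <- call_mono_hom2otv(model2, s2$con, s2$int)
  expect_equal(attr(calls2, "status"), "snp_like")
  expect_false("OO" %in% calls2)

  # a single tight cluster is monomorphic: no OO emitted
  s3 <- draw_signals(rep("AA", 50), 50)
  model3 <- fit_clusters(s3$con, s3$int, seed = 9)
  calls3 <- call_mono_hom2otv(model3, s3$con, s3$int)
  expect_equal(attr(calls3, "status"), "monomorphic")
  expect_false("OO" %in% calls3)

  # the caller never emits AB (property over random mixtures)
  set.seed(51)
  for (rep_i in 1:20) {
    sts <- sample(c("AA", "BB", "OO"), 60, replace = TRUE)
    ss <- draw_signals(sts, 51 + rep_i)
    mm <- fit_clusters(ss$con, ss$int, seed = rep_i)
    cc <- call_mono_hom2otv(mm, ss$con, ss$int)
    expect_false("AB" %in% cc)
  }
})

test_that("calling is invariant to swapping channel labels (AA <-> BB)", {
  states <- c(rep("AA", 50), rep("BB", 40), rep("OO", 30))
  s <- draw_signals(states, 52)
  model <- fit_clusters(s$con, s$int, seed = 11)
  calls <- call_bp(model, s$con, s$int)
  # swapping channels negates contrast
  model_sw <- fit_clusters(-s$con, s$int, seed = 11)
  calls_sw <- call_bp(model_sw, -s$con, s$int)
  swap <- c(AA = "BB", BB = "AA", AB = "AB", OA = "OB", OB = "OA",
            OO = "OO", NoCall = "NoCall")
  expect_equal(unname(swap[calls]), calls_sw)
})

test_that("increasing the inbred penalty never increases AB calls", {
  states <- c(rep("AA", 45), rep("BB", 45), rep("AB", 10))
  s <- draw_signals(states, 53)
  n_ab <- vapply(c(0L, 4L, 8L, 16L), function(pen) {
    cfg <- calling_config(inbred_penalty = pen)
    model <- fit_clusters(s$con, s$int, cfg = cfg, seed = 13)
    sum(call_otv(model, s$con, s$int, cfg) == "AB")
  }, numeric(1))
  expect_true(all(diff(n_ab) <= 0))
  # at the full penalty the small middle cluster is effectively absorbed
  expect_lte(n_ab[4], n_ab[1])
})

test_that("classify_probeset assigns the documented categories", {
  cfg <- calling_config()
  # clean polymorphic BP probe
  states <- c(rep("AA", 50), rep("OO", 50))
  s <- draw_signals(states, 54)
  model <- fit_clusters(s$con, s$int, seed = 15)
  calls <- call_bp(model, s$con, s$int)
  expect_equal(classify_probeset(calls, "BP", model, cfg)$category,
               "PolyHighResolution")
  # low call rate
  lowcr <- c(rep("AA", 70), rep("NoCall", 30))
  expect_equal(classify_probeset(lowcr, "BP", cfg = cfg)$category,
               "CallRateBelowThreshold")
  # single cluster -> MonoHighResolution
  expect_equal(classify_probeset(rep("AA", 100), "BP", cfg = cfg)$category,
               "MonoHighResolution")
  # AB without second homozygote class -> NoMinorHom
  nmh <- c(rep("AA", 90), rep("AB", 10))
  expect_equal(classify_probeset(nmh, "OTV", cfg = cfg)$category,
               "NoMinorHom")
  # three homozygote classes incl. off-target -> OTV
  otv <- c(rep("AA", 40), rep("BB", 40), rep("OO", 20))
  expect_equal(classify_probeset(otv, "OTV", cfg = cfg)$category, "OTV")
  # excess heterozygosity on an inbred panel
  het <- c(rep("AA", 60), rep("AB", 40))
  expect_equal(classify_probeset(het, "OTV", cfg = cfg)$category,
               "UnexpectedHeterozygosity")
  # Hom2OTV status propagates
  h2 <- structure(c(rep("AA", 60), rep("OO", 40)), status = "hom2otv")
  expect_equal(classify_probeset(h2, "MONO", cfg = cfg)$category, "Hom2OTV")
})

test_that("sample_qc fails samples below 90% call rate and errors when none pass", {
  calls <- matrix("AA", 100, 3, dimnames = list(NULL, c("good", "edge", "bad")))
  calls[1:5, "edge"] <- "NoCall"   # 95% -> pass
  calls[1:15, "bad"] <- "NoCall"   # 85% -> fail
  qc <- sample_qc(calls)
  expect_equal(qc$pass, c(TRUE, TRUE, FALSE))
  expect_equal(qc$call_rate[3], 0.85)
  all_bad <- matrix("NoCall", 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(sample_qc(all_bad), "no samples pass")
})

test_that("signal and call matrices round-trip through their TSV formats", {
  set.seed(55)
  sig <- list(contrast = matrix(rnorm(6), 2, 3,
                                dimnames = list(c("p1", "p2"), c("s1", "s2", "s3"))),
              intensity = matrix(rnorm(6), 2, 3,
                                 dimnames = list(c("p1", "p2"), c("s1", "s2", "s3"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signals(sig, f)
  back <- read_signals(f)
  expect_equal(back$contrast, sig$contrast)
  expect_equal(back$intensity, sig$intensity)

  calls <- matrix(c("AA", "OO", "NoCall", "AB", "BB", "OA"), 2, 3,
                  dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, f2)
  expect_equal(read_calls(f2), calls)
})
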