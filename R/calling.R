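#' Calling configuration
#'
#' Parameters of the two-channel cluster callers. The inbred penalty scales
#' the prior weight of the heterozygous component (0 = fully heterozygous
#' prior, 16 = completely homozygous); it is implemented as a down-weighting
#' factor `2^(-penalty/4)`, a documented surrogate for the vendor's
#' unpublished mechanism. `het_so_cut`, `het_v_maf_cut` and `ab_vary_z_cut`
#' carry the published names and default cut values with transparent
#' formulas (see [classify_probeset()]). `hom2otv_gap_sd` is the minimum
#' intensity separation (in pooled within-cluster SDs) for the
#' two-homozygous-cluster relabelling of monomorphic probes.
#'
#' @param inbred_penalty integer in `[0, 16]`; 4 for the BP/OTV relabel
#'   pass, 16 for the MONO high pass.
#' @param sample_callrate_min sample QC threshold (default 0.9).
#' @param marker_callrate_min probe-level call-rate surrogate used by probe
#'   classification (default 0.97).
#' @param het_so_cut heterozygous size-offset cut (default -0.3): an
#'   AB-labelled cluster sitting more than this far below the mean
#'   homozygous intensity is relabelled off-target (OO).
#' @param het_v_maf_cut,ab_vary_z_cut retained vendor cut values (1.9, 2.6)
#'   applied to the het-frequency-vs-MAF and het intensity-variance z
#'   surrogates.
#' @param hom2otv_gap_sd intensity gap, in pooled within-cluster SDs,
#'   required to call two homozygous-looking clusters a presence/absence
#'   pair (default 3).
#' @param confidence posterior probability below which a sample is NoCall
#'   (default 0.85; must be in (0.5, 1)).
#' @param contrast_tol contrast magnitude below which a component is
#'   considered contrast-neutral (AB or OO like; default 0.5).
#' @param max_het_rate heterozygous call frequency above which a probeset is
#'   flagged UnexpectedHeterozygosity on an inbred panel (default 0.15).
#' @return list of class `calling_config`.
#' @export
calling_config <- function(inbred_penalty = 4L, sample_callrate_min = 0.9,
                           marker_callrate_min = 0.97, het_so_cut = -0.3,
                           het_v_maf_cut = 1.9, ab_vary_z_cut = 2.6,
                           hom2otv_gap_sd = 3, confidence = 0.85,
                           contrast_tol = 0.5, max_het_rate = 0.15) {
  stopifnot(inbred_penalty >= 0, inbred_penalty <= 16,
            confidence > 0.5, confidence < 1)
  structure(as.list(environment()), class = "calling_config")
}

SD_FLOOR <- 0.02

## diagonal-covariance Gaussian mixture log-likelihood
mixture_loglik <- function(x, y, weights, means, sds) {
  dens <- vapply(seq_along(weights), function(j) {
    weights[j] * dnorm(x, means[j, 1], sds[j, 1]) *
      dnorm(y, means[j, 2], sds[j, 2])
  }, numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, ncol = length(weights))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

#' Fit a cluster model to one probe's two-channel signals
#'
#' Fits a mixture of up to `max_components` bivariate (diagonal covariance)
#' Gaussian components to the (contrast, intensity) summaries of one probe
#' across samples. Components are seeded with k-means (deterministic given
#' `seed`) and the number of components is chosen by BIC. Samples with
#' missing signal are ignored during fitting.
#'
#' @param contrast,intensity numeric vectors (one value per sample).
#' @param max_components maximum number of components (default 4).
#' @param cfg a [calling_config()].
#' @param seed integer seed controlling the k-means initialisation.
#' @return object of class `cluster_model`: fields `k`, `weights`, `means`
#'   (k x 2, columns contrast/intensity), `sds` (k x 2), `n`,
#'   `insufficient` (TRUE when < 10 usable samples, in which case the probe
#'   is to be flagged CallRateBelowThreshold).
#' @export
fit_clusters <- function(contrast, intensity, max_components = 4L,
                         cfg = calling_config(), seed = 1L) {
  stopifnot(length(contrast) == length(intensity))
  ok <- is.finite(contrast) & is.finite(intensity)
  x <- contrast[ok]; y <- intensity[ok]
  n <- length(x)
  if (n < 10L) {
    return(structure(list(k = 0L, weights = numeric(0),
                          means = matrix(numeric(0), 0, 2),
                          sds = matrix(numeric(0), 0, 2),
                          n = n, insufficient = TRUE),
                     class = "cluster_model"))
  }
  X <- cbind(x, y)
  n_distinct <- nrow(unique(X))
  best <- NULL
  best_bic <- Inf
  for (k in seq_len(min(max_components, n_distinct))) {
    cl <- if (k == 1L) rep(1L, n) else {
      set.seed(seed + k)
      tryCatch(kmeans(X, centers = k, nstart = 5L, iter.max = 50L)$cluster,
               error = function(e) NULL)
    }
    if (is.null(cl)) next
    means <- matrix(0, k, 2); sds <- matrix(SD_FLOOR, k, 2)
    w <- numeric(k)
    for (j in seq_len(k)) {
      sel <- cl == j
      w[j] <- mean(sel)
      means[j, ] <- colMeans(X[sel, , drop = FALSE])
      if (sum(sel) > 1L) {
        sds[j, ] <- pmax(apply(X[sel, , drop = FALSE], 2, stats::sd), SD_FLOOR)
      }
    }
    ll <- mixture_loglik(x, y, w, means, sds)
    bic <- -2 * ll + (6 * k - 1) * log(n)
    if (bic < best_bic) {
      best_bic <- bic
      best <- list(k = k, weights = w, means = means, sds = sds,
                   n = n, insufficient = FALSE)
    }
  }
  colnames(best$means) <- colnames(best$sds) <- c("contrast", "intensity")
  structure(best, class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d n=%d%s\n", x$k, x$n,
              if (isTRUE(x$insufficient)) " (insufficient data)" else ""))
  if (x$k > 0L) {
    df <- data.frame(weight = round(x$weights, 3),
                     contrast = round(x$means[, 1], 3),
                     intensity = round(x$means[, 2], 3))
    print(df)
  }
  invisible(x)
}

## posterior membership matrix (n x k) under component weights w
component_posteriors <- function(model, contrast, intensity, weights = model$weights) {
  k <- model$k
  dens <- vapply(seq_len(k), function(j) {
    weights[j] * dnorm(contrast, model$means[j, 1], model$sds[j, 1]) *
      dnorm(intensity, model$means[j, 2], model$sds[j, 2])
  }, numeric(length(contrast)))
  if (is.null(dim(dens))) dens <- matrix(dens, ncol = k)
  tot <- rowSums(dens)
  dens / pmax(tot, 1e-300)
}

## down-weight the heterozygous (interior-contrast, presence-intensity)
## component by 2^(-penalty/4); returns adjusted, renormalised weights
apply_inbred_penalty <- function(model, labels, cfg) {
  w <- model$weights
  het <- which(labels == "AB")
  if (length(het) > 0L && cfg$inbred_penalty > 0) {
    w[het] <- w[het] * 2^(-cfg$inbred_penalty / 4)
    w <- w / sum(w)
  }
  w
}

## pooled within-cluster intensity SD
pooled_int_sd <- function(model) {
  sqrt(sum(model$weights * model$sds[, 2]^2) / sum(model$weights))
}

## geometric component labelling shared by the three callers.
## mode "bp": low cluster -> OO, interior intensities -> OA/OB, presence
##   by contrast sign (interior contrast -> AB).
## mode "otv": low clusters -> OO, presence -> AA/AB/BB by contrast.
label_components <- function(model, cfg, mode = c("bp", "otv")) {
  mode <- match.arg(mode)
  k <- model$k
  con <- model$means[, 1]; int <- model$means[, 2]
  labels <- character(k)
  sign_label <- function(ci) {
    if (ci > cfg$contrast_tol) "AA" else if (ci < -cfg$contrast_tol) "BB" else "AB"
  }
  if (k == 1L) {
    l <- sign_label(con[1])
    return(if (l == "AB") "AA" else l) # single contrast-neutral cluster: presence
  }
  gap <- cfg$hom2otv_gap_sd * pooled_int_sd(model)
  low <- int < max(int) - gap
  if (all(low == FALSE)) {
    ## no off-target level: plain contrast labelling
    return(vapply(con, sign_label, character(1)))
  }
  ## presence level
  labels[!low] <- vapply(con[!low], sign_label, character(1))
  ## off-target level: the lowest component is OO; interior intensities are
  ## hemizygous for BP probes (signed by contrast), OO for OTV probes
  low_idx <- which(low)
  oo <- low_idx[which.min(int[low_idx])]
  labels[oo] <- "OO"
  inter <- setdiff(low_idx, oo)
  if (length(inter) > 0L) {
    labels[inter] <- if (mode == "bp") {
      ifelse(con[inter] >= 0, "OA", "OB")
    } else "OO"
  }
  labels
}

## shared assignment step: max-posterior component, NoCall below confidence
assign_calls <- function(model, labels, contrast, intensity, cfg) {
  calls <- rep("NoCall", length(contrast))
  ok <- is.finite(contrast) & is.finite(intensity)
  if (!any(ok)) return(calls)
  w <- apply_inbred_penalty(model, labels, cfg)
  post <- component_posteriors(model, contrast[ok], intensity[ok], weights = w)
  best <- max.col(post, ties.method = "first")
  conf <- post[cbind(seq_len(nrow(post)), best)]
  lab <- labels[best]
  lab[conf < cfg$confidence] <- "NoCall"
  calls[ok] <- lab
  calls
}

#' Call genotypes from a BP (breakpoint) probe
#'
#' BP probes behave like codominant SNP assays: at least two clusters are
#' expected, homozygous presence (`AA`/`BB`, high intensity) and absence
#' (`OO`, low intensity, contrast-neutral). A cluster at intermediate
#' intensity is hemizygous (`OA`/`OB` by contrast sign). Samples whose
#' maximum posterior is below the confidence threshold are `NoCall`.
#'
#' @param model a [fit_clusters()] result.
#' @param contrast,intensity per-sample signals.
#' @param cfg a [calling_config()] (inbred penalty applies to the AB
#'   component, default 4).
#' @return character vector of calls over
#'   `{AA, AB, BB, OA, OB, OO, NoCall}`.
#' @export
call_bp <- function(model, contrast, intensity, cfg = calling_config()) {
  stopifnot(inherits(model, "cluster_model"))
  if (isTRUE(model$insufficient)) return(rep("NoCall", length(contrast)))
  labels <- label_components(model, cfg, mode = "bp")
  assign_calls(model, labels, contrast, intensity, cfg)
}

#' Call genotypes from an OTV (internal polymorphic) probe
#'
#' Standard SNP labelling (`AA`/`AB`/`BB` by contrast) with an off-target
#' pass: a putative `AB` cluster sitting markedly below the homozygous
#' clusters in intensity (size offset below `het_so_cut`) is relabelled
#' `OO`, as are clusters at the distinct low-intensity level. Four clusters
#' (`AA`, `AB`, `BB`, `OO`) can therefore all be emitted.
#'
#' @inheritParams call_bp
#' @return character vector of calls over `{AA, AB, BB, OO, NoCall}`.
#' @export
call_otv <- function(model, contrast, intensity, cfg = calling_config()) {
  stopifnot(inherits(model, "cluster_model"))
  if (isTRUE(model$insufficient)) return(rep("NoCall", length(contrast)))
  labels <- label_components(model, cfg, mode = "otv")
  ## het size-offset pass: AB clusters far below the homozygous mean
  ## intensity are miscalled off-target samples
  hom <- labels %in% c("AA", "BB")
  if (any(labels == "AB") && any(hom)) {
    hom_int <- mean(model$means[hom, 2])
    for (j in which(labels == "AB")) {
      if (model$means[j, 2] - hom_int < cfg$het_so_cut) labels[j] <- "OO"
    }
  }
  assign_calls(model, labels, contrast, intensity, cfg)
}

#' Call presence/absence from a MONO probe (Hom2OTV)
#'
#' MONO probes interrogate putatively monomorphic sites inside the InDel,
#' so only two clusters are expected, separated in intensity only: presence
#' (upper) and absence (lower, off-target). When the fitted model has two
#' homozygous-looking components whose separation is primarily in intensity
#' (|dIntensity| > |dContrast|) and at least `hom2otv_gap_sd` pooled SDs
#' wide, the lower-intensity cluster is recalled as `OO` and the upper as
#' presence (`AA`). A single cluster is monomorphic (all presence). Two
#' clusters separated mainly in contrast indicate an unexpected SNP and are
#' labelled like an OTV probe instead. Heterozygous calls are never emitted.
#'
#' @inheritParams call_bp
#' @param cfg a [calling_config()]; the MONO pass uses the high inbred
#'   penalty (16) by default.
#' @return character vector of calls over `{AA, BB, OO, NoCall}` with a
#'   `status` attribute: `"hom2otv"`, `"monomorphic"`, `"snp_like"` or
#'   `"unexpected"`.
#' @export
call_mono_hom2otv <- function(model, contrast, intensity,
                              cfg = calling_config(inbred_penalty = 16L)) {
  stopifnot(inherits(model, "cluster_model"))
  if (isTRUE(model$insufficient)) {
    out <- rep("NoCall", length(contrast))
    attr(out, "status") <- "insufficient"
    return(out)
  }
  k <- model$k
  status <- "unexpected"
  if (k == 1L) {
    labels <- "AA"
    status <- "monomorphic"
  } else if (k == 2L) {
    d_int <- abs(diff(model$means[, 2]))
    d_con <- abs(diff(model$means[, 1]))
    if (d_int >= cfg$hom2otv_gap_sd * pooled_int_sd(model) && d_int > d_con) {
      labels <- c("AA", "OO")[order(order(-model$means[, 2]))]
      status <- "hom2otv"
    } else {
      labels <- ifelse(model$means[, 1] >= 0, "AA", "BB")
      if (labels[1] == labels[2]) labels[which.min(model$means[, 1])] <- "BB"
      status <- "snp_like"
    }
  } else {
    labels <- label_components(model, cfg, mode = "otv")
    labels[labels == "AB"] <- "NoCall" # never emit heterozygous calls
    status <- "unexpected"
  }
  out <- assign_calls(model, labels, contrast, intensity, cfg)
  attr(out, "status") <- status
  out
}

#' Classify a probeset from its calls
#'
#' Reduced 8-category surrogate of the vendor's 14-category probeset
#' taxonomy, decided in order: `CallRateBelowThreshold` (probe call rate
#' below `marker_callrate_min`, or too few samples to fit),
#' `UnexpectedHeterozygosity` (AB frequency above `max_het_rate` on an
#' inbred panel), `Hom2OTV` (MONO probe relabelled by the intensity pass),
#' `OTV` (off-target cluster alongside both SNP homozygote classes),
#' `PolyHighResolution` (at least two homozygote-class clusters, each with
#' at least 2 samples), `NoMinorHom` (AB present without a second
#' homozygote class), `MonoHighResolution` (a single class), else `Other`.
#'
#' @param calls character vector of calls for one probe.
#' @param ptype `"BP"`, `"OTV"` or `"MONO"`.
#' @param model optional [fit_clusters()] model (used for separation
#'   metrics).
#' @param cfg a [calling_config()].
#' @param status optional status attribute from [call_mono_hom2otv()].
#' @return list with `category` and `metrics` (call rate, cluster count,
#'   het frequency, cluster separation in pooled SDs).
#' @export
classify_probeset <- function(calls, ptype = c("BP", "OTV", "MONO"),
                              model = NULL, cfg = calling_config(),
                              status = attr(calls, "status")) {
  ptype <- match.arg(ptype)
  called <- calls[calls != "NoCall" & !is.na(calls)]
  call_rate <- length(called) / length(calls)
  tab <- table(called)
  het_freq <- if (length(called)) sum(calls == "AB") / length(called) else 0
  sep <- NA_real_
  if (!is.null(model) && model$k > 1L) {
    d <- as.matrix(stats::dist(model$means))
    sep <- min(d[upper.tri(d)]) / max(pooled_int_sd(model), SD_FLOOR)
  }
  hom_classes <- intersect(names(tab)[tab >= 2L], c("AA", "BB", "OO"))
  category <-
    if ((!is.null(model) && isTRUE(model$insufficient)) ||
        call_rate < cfg$marker_callrate_min) "CallRateBelowThreshold"
    else if (het_freq > cfg$max_het_rate) "UnexpectedHeterozygosity"
    else if (identical(status, "hom2otv")) "Hom2OTV"
    else if (all(c("AA", "BB", "OO") %in% hom_classes)) "OTV"
    else if (length(hom_classes) >= 2L) "PolyHighResolution"
    else if ("AB" %in% names(tab) && length(hom_classes) == 1L) "NoMinorHom"
    else if (length(tab) == 1L) "MonoHighResolution"
    else "Other"
  list(category = category,
       metrics = list(call_rate = call_rate, n_classes = length(tab),
                      het_freq = het_freq, separation_sd = sep))
}

#' Per-sample call-rate quality control
#'
#' Samples with a call rate below the threshold (default 0.9) are flagged
#' failed and should be excluded from probeset classification.
#'
#' @param calls matrix of calls (probes x samples), `"NoCall"`/`NA` for
#'   missing.
#' @param cfg a [calling_config()].
#' @return data.frame with `sample_id`, `call_rate`, `pass`. Errors when no
#'   sample passes.
#' @export
sample_qc <- function(calls, cfg = calling_config()) {
  stopifnot(is.matrix(calls))
  rate <- colMeans(calls != "NoCall" & !is.na(calls))
  out <- data.frame(sample_id = colnames(calls), call_rate = rate,
                    pass = rate >= cfg$sample_callrate_min,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(out$pass)) stop("no samples pass QC", call. = FALSE)
  out
}

#' Read / write per-probe signal tables
#'
#' Long TSV with columns `probe_id`, `sample_id`, `contrast`, `intensity`;
#' converted to/from a pair of probes x samples matrices.
#'
#' @param signals list with `contrast` and `intensity` matrices (dimnames =
#'   probes, samples).
#' @param path TSV path.
#' @return the path (writer) or a `signals` list (reader).
#' @export
write_signals <- function(signals, path) {
  con <- signals$contrast; int <- signals$intensity
  df <- data.frame(probe_id = rep(rownames(con), times = ncol(con)),
                   sample_id = rep(colnames(con), each = nrow(con)),
                   contrast = as.vector(con), intensity = as.vector(int))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  probes <- unique(df$probe_id); samples <- unique(df$sample_id)
  con <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
  int <- con
  idx <- cbind(match(df$probe_id, probes), match(df$sample_id, samples))
  con[idx] <- df$contrast
  int[idx] <- df$intensity
  list(contrast = con, intensity = int)
}

#' Read / write call matrices
#'
#' TSV with probes as rows (first column `probe_id`) and samples as columns.
#'
#' @param calls character matrix (probes x samples).
#' @param path TSV path.
#' @return the path (writer) or the call matrix (reader).
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(probe_id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}
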