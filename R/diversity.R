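#' Marker filter configuration
#'
#' Quality thresholds for diversity markers: missing data rate below 20%,
#' heterozygous (hemizygous dosage) rate below 15%, minor allele frequency
#' above 5%. Markers are treated as bi-allelic present/absent.
#'
#' @param max_missing,max_het,min_maf thresholds in (0, 1).
#' @return list of class `marker_filter_config`.
#' @export
marker_filter_config <- function(max_missing = 0.20, max_het = 0.15,
                                 min_maf = 0.05) {
  stopifnot(max_missing > 0, max_missing < 1, max_het > 0, max_het < 1,
            min_maf > 0, min_maf < 1)
  structure(list(max_missing = max_missing, max_het = max_het,
                 min_maf = min_maf), class = "marker_filter_config")
}

#' Filter markers on missingness, heterozygosity and MAF
#'
#' @param genotypes numeric matrix of presence dosages (markers x samples,
#'   values 0 / 0.5 / 1 / NA).
#' @param cfg a [marker_filter_config()].
#' @return the retained rows of `genotypes`.
#' @export
filter_markers <- function(genotypes, cfg = marker_filter_config()) {
  stopifnot(is.matrix(genotypes))
  miss <- rowMeans(is.na(genotypes))
  het <- rowMeans(genotypes == 0.5, na.rm = TRUE)
  het[is.nan(het)] <- 0
  p <- rowMeans(genotypes, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- miss < cfg$max_missing & het < cfg$max_het & maf > cfg$min_maf
  keep[is.na(keep)] <- FALSE
  genotypes[keep, , drop = FALSE]
}

#' Pick the single best probe per InDel
#'
#' Ranks probes by call rate (descending), then concordance (descending),
#' then score (descending), with a deterministic tie-break on probe id, and
#' keeps the top-ranked probe of each InDel.
#'
#' @param metrics data.frame with columns `probe_id`, `indel_id`,
#'   `call_rate`, `concordance`, `score` (missing metric columns are
#'   treated as constant).
#' @return the selected rows, one per InDel, ordered by `indel_id`.
#' @export
best_probe_per_indel <- function(metrics) {
  stopifnot(all(c("probe_id", "indel_id") %in% names(metrics)))
  get_or0 <- function(col) if (col %in% names(metrics)) metrics[[col]] else rep(0, nrow(metrics))
  ord <- order_by(metrics$indel_id, get_or0("call_rate"), get_or0("concordance"),
                  get_or0("score"), metrics$probe_id,
                  decreasing = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  x <- metrics[ord, , drop = FALSE]
  x[!duplicated(x$indel_id), , drop = FALSE]
}

#' Genomic (IBD-type) kinship from presence dosages
#'
#' Astle-Balding genomic kinship: for lines i, j and markers m with
#' presence frequency `p_m`,
#' \deqn{K_{ij} = \frac{1}{M_{ij}} \sum_m \frac{(x_{im} - p_m)(x_{jm} - p_m)}{p_m (1 - p_m)}}
#' computed pairwise-complete over missing entries; markers fixed in the
#' panel (`p_m` of 0 or 1) are skipped. Invariant to swapping the
#' present/absent labels of any marker.
#'
#' @param genotypes numeric matrix of dosages (markers x samples, values
#'   0 / 0.5 / 1 / NA).
#' @param freqs optional vector of marker presence frequencies; estimated
#'   from the data when NULL.
#' @return object of class `kinship_matrix`: the n x n symmetric estimate
#'   with a `markers_used` attribute.
#' @export
ibd_kinship <- function(genotypes, freqs = NULL) {
  stopifnot(is.matrix(genotypes))
  if (is.null(freqs)) freqs <- rowMeans(genotypes, na.rm = TRUE)
  usable <- !is.na(freqs) & freqs > 0 & freqs < 1
  X <- genotypes[usable, , drop = FALSE]
  p <- freqs[usable]
  if (nrow(X) == 0L) stop("no polymorphic markers", call. = FALSE)
  Z <- (X - p) / sqrt(p * (1 - p))
  obs <- !is.na(Z)
  Z[!obs] <- 0
  M <- crossprod(obs * 1) # pairwise-complete marker counts
  K <- crossprod(Z) / pmax(M, 1)
  K[M == 0] <- NA_real_
  structure(K, class = c("kinship_matrix", class(K)),
            markers_used = nrow(X))
}

#' Kinship to normalised dissimilarity
#'
#' Computes `1 - K` rescaled to `[0, 1]` with a zero diagonal, suitable as
#' input for [pcoa()].
#'
#' @param K kinship matrix (e.g. [ibd_kinship()]).
#' @return symmetric dissimilarity matrix.
#' @export
kinship_distance <- function(K) {
  D <- 1 - unclass(K)
  D <- D - min(D, na.rm = TRUE)
  mx <- max(D, na.rm = TRUE)
  if (mx > 0) D <- D / mx
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Double-centres `-D^2 / 2` and eigendecomposes (via [stats::cmdscale()]).
#' Axes are ordered by eigenvalue; only axes with positive eigenvalues are
#' returned, with a warning when the input is not Euclidean-embeddable
#' (negative eigenvalues present).
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @param n_axes number of axes requested (default 2).
#' @return list with `coords` (n x axes matrix), `eigenvalues` (all of
#'   them) and `prop_explained` (over positive eigenvalues).
#' @export
pcoa <- function(D, n_axes = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  fit <- suppressWarnings(cmdscale(D, k = min(n_axes, n - 1L), eig = TRUE))
  ev <- fit$eig
  if (any(ev < -sqrt(.Machine$double.eps) * max(abs(ev)))) {
    warning("distance matrix is not Euclidean; axes restricted to positive eigenvalues",
            call. = FALSE)
  }
  coords <- fit$points
  pos <- which(ev[seq_len(ncol(coords))] > 0)
  coords <- coords[, pos, drop = FALSE]
  if (ncol(coords) > 0L) colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = ev,
       prop_explained = ev[pos] / sum(ev[ev > 0]))
}
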