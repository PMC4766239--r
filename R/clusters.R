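# Five-cluster scheme and cluster-level synchrony.
#
# The 19 scalp channels are grouped into five clusters mirroring the cerebral
# lobes. Bivariate markers are evaluated between the first two principal
# components of each cluster (all four PC combinations), static and dynamic
# canonical correlations directly between the clusters' channels; a
# channel-pair-averaging alternative is provided for comparison.

#' Electrode clusters
#'
#' Fixed channel groups: Anterior (FP1, FP2, F3, F4), Temporal/Left (F7, T7,
#' P7), Central (FZ, C3, CZ, C4, PZ), Temporal/Right (F8, T8, P8) and
#' Posterior (P3, P4, O1, O2). These constants are immutable; pass an
#' explicit override list to the driver functions to change them.
#'
#' @format Named list of channel-label vectors.
#' @export
CLUSTERS <- list(
  Anterior      = c("FP1", "FP2", "F3", "F4"),
  TemporalLeft  = c("F7", "T7", "P7"),
  Central       = c("FZ", "C3", "CZ", "C4", "PZ"),
  TemporalRight = c("F8", "T8", "P8"),
  Posterior     = c("P3", "P4", "O1", "O2")
)

#' All unordered cluster pairs
#'
#' @param clusters cluster definition list (default [CLUSTERS]).
#' @return Two-column character matrix of the 10 unordered pairs.
#' @export
cluster_pairs <- function(clusters = CLUSTERS) {
  t(utils::combn(names(clusters), 2))
}

#' Per-cluster principal components
#'
#' PCA on the pooled lag-0 covariance of a cluster's channels across a
#' subject's segments (segments are mean-centered individually). Component
#' signs are fixed so the largest-magnitude loading is positive. Pooling over
#' segments keeps the component meaning stable across the recording.
#'
#' @param segs a [segment_set()] containing the cluster's channels.
#' @param cluster cluster name or channel-label vector.
#' @param clusters cluster definition list used to resolve a name.
#' @return List with `scores` (per segment, 2 x samples matrix of PC1/PC2
#'   projections), `varfrac` (explained-variance fractions of the first two
#'   components), `loadings` (channels x 2).
#' @export
cluster_pcs <- function(segs, cluster, clusters = CLUSTERS) {
  chans <- if (is.character(cluster) && length(cluster) == 1L &&
               cluster %in% names(clusters)) clusters[[cluster]] else cluster
  sub <- segset_channels(segs, chans)
  g0 <- sample_covariance(sub, 0L, method = "direct")$gamma[, , 1]
  e <- eigen(g0, symmetric = TRUE)
  v <- e$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {
    top <- which.max(abs(v[, k]))
    if (v[top, k] < 0) v[, k] <- -v[, k]
  }
  varfrac <- e$values[1:2] / sum(e$values)
  scores <- lapply(sub$segments, function(m) {
    s <- t(v) %*% (m - rowMeans(m))
    rownames(s) <- c("PC1", "PC2")
    s
  })
  list(scores = scores, varfrac = varfrac, loadings = v)
}

# PC series of all clusters as a list of 10 x T segment matrices with labels
# "<Cluster>.PC1"/"<Cluster>.PC2", plus the per-cluster variance fractions
subject_pcs <- function(segs, clusters = CLUSTERS) {
  out <- lapply(names(clusters), function(cl) cluster_pcs(segs, cl, clusters))
  names(out) <- names(clusters)
  labels <- as.vector(vapply(names(clusters),
                             function(cl) paste0(cl, c(".PC1", ".PC2")),
                             character(2)))
  nseg <- length(segs$segments)
  pcseg <- lapply(seq_len(nseg), function(i) {
    m <- do.call(rbind, lapply(out, function(o) o$scores[[i]]))
    rownames(m) <- labels
    m
  })
  varfrac <- t(vapply(out, function(o) o$varfrac, numeric(2)))
  colnames(varfrac) <- c("PC1", "PC2")
  list(segments = pcseg, labels = labels, varfrac = varfrac)
}

#' Explained variance of the first two cluster components
#'
#' Convenience wrapper returning, per cluster, the cumulative variance
#' fraction captured by PC1 + PC2 — the homogeneity condition under which the
#' two-PC synchrony scheme is justified.
#'
#' @inheritParams cluster_pcs
#' @return Named numeric vector of cumulative two-PC variance fractions.
#' @export
two_pc_variance <- function(segs, clusters = CLUSTERS) {
  vapply(names(clusters), function(cl)
    sum(cluster_pcs(segs, cl, clusters)$varfrac), numeric(1))
}

MARKER_NAMES <- c("C", "pC", "nPhi", "G", "cG", "rho", "drho", "cMI")
PC_COMBOS <- c("1-1", "1-2", "2-1", "2-2")
TIME_DOMAIN <- "time-domain"

# subset a cov_seq to channel indices
subcov <- function(cov, idx) {
  structure(list(gamma = cov$gamma[idx, idx, , drop = FALSE],
                 n = length(idx), max_lag = cov$max_lag,
                 labels = cov$labels[idx], nobs = cov$nobs),
            class = "cov_seq")
}

#' All synchrony markers of one subject
#'
#' Computes the requested markers between cluster pairs from one subject's
#' preprocessed segments. Bivariate markers (C, pC, nPhi, G, cG, cMI) are
#' evaluated for every combination of the first two PCs of the two clusters;
#' static and dynamic canonical correlations are computed directly between
#' the clusters' channels (combo `"direct"`). Partial coherence and
#' conditional Granger causality condition on the first two PCs of *all*
#' clusters. Frequency-domain markers are band-averaged over
#' delta/theta/alpha/beta0; the rest are time-domain.
#'
#' @param segs a [segment_set()] from [preprocess_pipeline()].
#' @param markers subset of `c("C","pC","nPhi","G","cG","rho","drho","cMI")`.
#' @param pairs two-column matrix of cluster-name pairs (default all 10).
#' @param bands band names for the frequency-domain markers.
#' @param config a [spectral_config()].
#' @param ar_max_order maximum AR order for the Granger fits.
#' @param cmi_normalization normalization of [cross_mutual_info()].
#' @param clusters cluster definitions.
#' @return Data.frame with columns `marker`, `pair`, `band`, `direction`
#'   (`"sym"`, `"fwd"` = first-named -> second-named cluster, or `"rev"`),
#'   `combo`, `value`; the per-cluster two-PC variance fractions are attached
#'   as attribute `"varfrac"`.
#' @export
subject_markers <- function(segs, markers = MARKER_NAMES,
                            pairs = cluster_pairs(clusters),
                            bands = names(frequency_bands()),
                            config = spectral_config(),
                            ar_max_order = 10,
                            cmi_normalization = "maes",
                            clusters = CLUSTERS) {
  markers <- match.arg(markers, MARKER_NAMES, several.ok = TRUE)
  rate <- segs$rate
  pcs <- subject_pcs(segs, clusters)
  pci <- function(cl, k) match(paste0(cl, ".PC", k), pcs$labels)

  spec <- ginv <- NULL
  if (any(markers %in% c("C", "pC", "nPhi"))) {
    pcov <- sample_covariance(pcs$segments, config$truncation)
    spec <- lag_window_spectrum(pcov, config, rate)
    if ("pC" %in% markers) ginv <- inverse_spectrum(spec)
  }
  arcov <- if (any(markers %in% c("G", "cG")))
    sample_covariance(pcs$segments, ar_max_order, method = "direct") else NULL
  fit_all <- if ("cG" %in% markers) fit_ar(arcov, max_order = ar_max_order) else NULL
  chan_spec <- NULL
  if ("drho" %in% markers) {
    ccov <- sample_covariance(segs, config$truncation)
    chan_spec <- lag_window_spectrum(ccov, config, rate)
  }
  gamma0 <- if ("rho" %in% markers)
    sample_covariance(segs, 0L, method = "direct") else NULL
  pc_concat <- if ("cMI" %in% markers)
    do.call(cbind, pcs$segments) else NULL

  rows <- list()
  add <- function(marker, pair, band, direction, combo, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      marker = marker, pair = pair, band = band, direction = direction,
      combo = combo, value = value, stringsAsFactors = FALSE)

  for (p in seq_len(nrow(pairs))) {
    A <- pairs[p, 1]; B <- pairs[p, 2]
    pr <- paste(A, B, sep = "-")
    for (combo in PC_COMBOS) {
      k <- as.integer(substr(combo, 1, 1))
      l <- as.integer(substr(combo, 3, 3))
      ia <- pci(A, k); ib <- pci(B, l)
      if ("C" %in% markers) for (b in bands)
        add("C", pr, b, "sym", combo, coherence(spec, ia, ib, b))
      if ("pC" %in% markers) for (b in bands)
        add("pC", pr, b, "sym", combo,
            partial_coherence(spec, ia, ib, b, ginv = ginv))
      if ("nPhi" %in% markers) for (b in bands)
        add("nPhi", pr, b, "sym", combo, phase_shift(spec, ia, ib, b))
      if ("G" %in% markers) {
        g <- fit_ar(subcov(arcov, c(ia, ib)), max_order = ar_max_order)
        add("G", pr, TIME_DOMAIN, "fwd", combo, sqrt(sum(g$A[2, 1, ]^2)))
        add("G", pr, TIME_DOMAIN, "rev", combo, sqrt(sum(g$A[1, 2, ]^2)))
      }
      if ("cG" %in% markers) {
        cg <- conditional_granger(fit_all, ia, ib)
        add("cG", pr, TIME_DOMAIN, "fwd", combo, cg$value)
        add("cG", pr, TIME_DOMAIN, "rev", combo, cg$reverse)
      }
      if ("cMI" %in% markers)
        add("cMI", pr, TIME_DOMAIN, "sym", combo,
            cross_mutual_info(pc_concat[pci(A, k), ], pc_concat[pci(B, l), ],
                              normalization = cmi_normalization))
    }
    if ("rho" %in% markers)
      add("rho", pr, TIME_DOMAIN, "sym", "direct",
          canonical_corr(gamma0, clusters[[A]], clusters[[B]])$norm)
    if ("drho" %in% markers) for (b in bands)
      add("drho", pr, b, "sym", "direct",
          dynamic_canonical_corr(chan_spec,
                                 match(clusters[[A]], chan_spec$labels),
                                 match(clusters[[B]], chan_spec$labels), b))
  }
  out <- do.call(rbind, rows)
  attr(out, "varfrac") <- pcs$varfrac
  out
}

#' Candidate PC-combination values for one marker and cluster pair
#'
#' The four (PC_k of A, PC_l of B) candidate values among which the
#' cohort-level selection of [select_best_combo()] chooses. Canonical
#' correlations bypass PCA and are rejected here.
#'
#' @inheritParams subject_markers
#' @param marker one bivariate marker name.
#' @param pair character vector of two cluster names.
#' @return Data.frame of candidate rows (4 per band for symmetric markers, 8
#'   for directed ones).
#' @export
marker_combinations <- function(segs, marker, pair, ...) {
  if (marker %in% c("rho", "drho"))
    stop("canonical correlations are computed directly between clusters; ",
         "use subject_markers() (combo \"direct\")")
  subject_markers(segs, markers = marker,
                  pairs = matrix(pair, 1), ...)
}

#' Cohort-level selection of the best PC combination
#'
#' For every (marker, pair, band, direction) key, fits the quadratic severity
#' regression once per PC combination across the cohort and keeps the
#' combination maximizing R^2 (ties broken in lexicographic combo order).
#' Because the selection uses the MMSE outcome it is optimistically biased;
#' compare with the fixed-combo path for an honest reference.
#'
#' @param tbl marker table with columns `subject`, `marker`, `pair`, `band`,
#'   `direction`, `combo`, `value` (PC-combination rows only).
#' @param cohort cohort data.frame as from [generate_cohort()].
#' @param ... passed to [quadratic_regression()].
#' @return Data.frame with one row per key: the selected combo, its `r2`, and
#'   provenance `"pca_best"`; all candidate R^2 values are attached as
#'   attribute `"candidates"`.
#' @export
select_best_combo <- function(tbl, cohort, ...) {
  tbl <- tbl[tbl$combo %in% PC_COMBOS, , drop = FALSE]
  if (!nrow(tbl)) stop("no PC-combination rows in `tbl`")
  keys <- unique(tbl[, c("marker", "pair", "band", "direction")])
  cand_list <- list()
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- merge(tbl, k)
    combos <- sort(unique(sub$combo))
    r2 <- vapply(combos, function(cm) {
      s <- sub[sub$combo == cm, ]
      y <- s$value[match(cohort$id, s$subject)]
      if (anyNA(y) || stats::sd(y) == 0) return(NA_real_)
      quadratic_regression(y, cohort, ...)$r_squared
    }, numeric(1))
    cand_list[[i]] <<- data.frame(k, combo = combos, r2 = r2,
                                  row.names = NULL)
    if (all(is.na(r2))) return(NULL)
    best <- combos[which.max(r2)]  # which.max takes the first maximum: ties
                                   # resolve in lexicographic combo order
    data.frame(k, combo = best, r2 = max(r2, na.rm = TRUE),
               provenance = "pca_best", row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "candidates") <- do.call(rbind, cand_list)
  res
}

#' Channel-pair-averaged marker between two clusters
#'
#' The averaging alternative to the PC scheme: the marker is computed between
#' every channel of one cluster and every channel of the other and the values
#' are averaged (e.g. 16 pairs for Anterior-Posterior). Partial coherence and
#' conditional Granger causality condition on all 19 channels.
#'
#' @inheritParams subject_markers
#' @param marker one bivariate marker name.
#' @param pair character vector of two cluster names.
#' @param band band name for frequency-domain markers.
#' @return One-row data.frame with provenance `"channel_average"`; directed
#'   markers yield two rows.
#' @export
channel_average_marker <- function(segs, marker, pair,
                                   band = "alpha",
                                   config = spectral_config(),
                                   ar_max_order = 10,
                                   cmi_normalization = "maes",
                                   clusters = CLUSTERS) {
  marker <- match.arg(marker, setdiff(MARKER_NAMES, c("rho", "drho")))
  A <- clusters[[pair[1]]]; B <- clusters[[pair[2]]]
  pr <- paste(pair, collapse = "-")
  rate <- segs$rate
  grid <- expand.grid(a = A, b = B, stringsAsFactors = FALSE)
  row1 <- function(band, direction, value)
    data.frame(marker = marker, pair = pr, band = band,
               direction = direction, combo = NA_character_, value = value,
               provenance = "channel_average", stringsAsFactors = FALSE)

  if (marker %in% c("C", "pC", "nPhi")) {
    ccov <- sample_covariance(segs, config$truncation)
    spec <- lag_window_spectrum(ccov, config, rate)
    ginv <- if (marker == "pC") inverse_spectrum(spec) else NULL
    vals <- mapply(function(a, b) switch(marker,
      C = coherence(spec, a, b, band),
      pC = partial_coherence(spec, a, b, band, ginv = ginv),
      nPhi = phase_shift(spec, a, b, band)),
      grid$a, grid$b)
    return(row1(band, "sym", mean(vals)))
  }
  if (marker == "G") {
    acov <- sample_covariance(segs, ar_max_order, method = "direct")
    vals <- mapply(function(a, b) {
      f <- fit_ar(subcov(acov, match(c(a, b), segs$labels)),
                  max_order = ar_max_order)
      c(fwd = sqrt(sum(f$A[2, 1, ]^2)), rev = sqrt(sum(f$A[1, 2, ]^2)))
    }, grid$a, grid$b)
    return(rbind(row1(TIME_DOMAIN, "fwd", mean(vals["fwd", ])),
                 row1(TIME_DOMAIN, "rev", mean(vals["rev", ]))))
  }
  if (marker == "cG") {
    fit <- fit_ar(sample_covariance(segs, ar_max_order, method = "direct"),
                  max_order = ar_max_order)
    vals <- mapply(function(a, b) {
      cg <- conditional_granger(fit, a, b)
      c(fwd = cg$value, rev = cg$reverse)
    }, grid$a, grid$b)
    return(rbind(row1(TIME_DOMAIN, "fwd", mean(vals["fwd", ])),
                 row1(TIME_DOMAIN, "rev", mean(vals["rev", ]))))
  }
  # cMI on concatenated segments
  cc <- do.call(cbind, segs$segments)
  vals <- mapply(function(a, b)
    cross_mutual_info(cc[match(a, segs$labels), ], cc[match(b, segs$labels), ],
                      normalization = cmi_normalization),
    grid$a, grid$b)
  row1(TIME_DOMAIN, "sym", mean(vals))
}
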