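# Methylation QC chain, fixed order: detection filtering -> M-values (when
# starting from intensities) -> KNN imputation -> empirical-Bayes
# batch/position adjustment -> 3-IQR trimming -> probe blacklists ->
# reference-based cell-type deconvolution.

#' M-value transform of probe intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))`. The additive offset
#' (default 1) keeps the ratio defined at zero intensities.
#'
#' @param meth_intensity,unmeth_intensity non-negative intensities
#'   (vectors or matrices of equal shape).
#' @param offset positive additive offset (default 1).
#' @return M-values with the shape of the inputs.
#' @export
mvalue_transform <- function(meth_intensity, unmeth_intensity, offset = 1) {
  stopifnot(offset > 0)
  if (any(meth_intensity < 0, na.rm = TRUE) ||
      any(unmeth_intensity < 0, na.rm = TRUE)) {
    stop("negative intensity")
  }
  log2((meth_intensity + offset) / (unmeth_intensity + offset))
}

#' Detection-based probe and sample filtering
#'
#' A call fails when its detection p-value exceeds `detection_p_max`.
#' Probes with call rate strictly below `probe_call_rate_min` are dropped
#' first, then samples with call rate (over the retained probes) strictly
#' below `sample_call_rate_min`; failed calls that survive both filters
#' become missing.
#'
#' @param m M-value matrix (probes x samples).
#' @param detection_p detection p-value matrix, co-indexed with `m`.
#' @param probe_call_rate_min default 0.95.
#' @param sample_call_rate_min default 0.99.
#' @param detection_p_max default 1e-16.
#' @return List with the filtered matrix `m` and a `report` of dropped
#'   probe/sample IDs and the number of calls set missing.
#' @export
detection_filter <- function(m, detection_p, probe_call_rate_min = 0.95,
                             sample_call_rate_min = 0.99,
                             detection_p_max = 1e-16) {
  stopifnot(all(dim(m) == dim(detection_p)))
  fails <- detection_p > detection_p_max
  probe_cr <- rowMeans(!fails)
  drop_probe <- probe_cr < probe_call_rate_min
  m2 <- m[!drop_probe, , drop = FALSE]
  f2 <- fails[!drop_probe, , drop = FALSE]
  sample_cr <- colMeans(!f2)
  drop_sample <- sample_cr < sample_call_rate_min
  m3 <- m2[, !drop_sample, drop = FALSE]
  f3 <- f2[, !drop_sample, drop = FALSE]
  m3[f3] <- NA_real_
  list(m = m3, report = list(
    probes_dropped_detection = rownames(m)[drop_probe],
    samples_dropped_call_rate = colnames(m2)[drop_sample],
    calls_set_missing = sum(f3)
  ))
}

#' K-nearest-neighbour imputation of a probe matrix
#'
#' For each probe with missing entries, the `k` nearest probes by
#' Euclidean distance over co-observed samples (normalized by the number
#' of co-observed columns) are located once; a missing entry is imputed
#' as the unweighted mean of those neighbours' observed values in that
#' sample, skipping neighbours missing there, with the probe's own row
#' mean as fallback when no neighbour value remains. Observed entries are
#' never altered; the procedure is deterministic (distance ties break by
#' row order).
#'
#' @param m numeric matrix, probes in rows; every probe needs at least
#'   one observed value.
#' @param k number of neighbours (default 10).
#' @return The completed matrix.
#' @export
knn_impute <- function(m, k = 10L) {
  if (k < 1) stop("k must be >= 1")
  if (!anyNA(m)) return(m)
  no_obs <- rowSums(!is.na(m)) == 0
  if (any(no_obs)) {
    stop("probe(s) with no observed value: ",
         paste(rownames(m)[no_obs], collapse = ", "))
  }
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  row_means <- rowSums(m0) / rowSums(obs)
  need <- which(rowSums(!obs) > 0)
  out <- m
  for (i in need) {
    # normalized squared distance to every other probe over co-observed cols
    co <- obs & rep(obs[i, ], each = nrow(m))
    diff <- m0 - rep(m0[i, ], each = nrow(m))
    diff[!co] <- 0
    n_co <- rowSums(co)
    d2 <- rowSums(diff^2) / n_co
    d2[n_co == 0] <- Inf
    d2[i] <- Inf
    ord <- order(d2)
    nbr <- ord[seq_len(min(k, sum(is.finite(d2[ord]))))]
    for (j in which(!obs[i, ])) {
      vals <- m[nbr, j]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals) > 0) mean(vals) else row_means[i]
    }
  }
  out
}

#' Empirical-Bayes batch/position adjustment
#'
#' Removes technical factor effects from a complete M-value matrix with a
#' parametric location-scale model: each probe is standardized to its
#' pooled mean and variance; per factor level, location shifts (normal
#' prior) and scale factors (inverse-gamma prior) are estimated and
#' shrunk by method-of-moments empirical Bayes; values are adjusted and
#' the pooled scale restored. Each probe is then recentred so its pooled
#' mean is preserved exactly. When both `batch` and `position` are given
#' the adjustment is applied sequentially (batch first). A factor with a
#' single level leaves the matrix unchanged; a level with fewer than two
#' samples is an error.
#'
#' @param m complete numeric matrix (probes x samples).
#' @param batch factor/vector of batch labels, length `ncol(m)`.
#' @param position optional second technical factor.
#' @return The adjusted matrix.
#' @export
eb_batch_adjust <- function(m, batch, position = NULL) {
  stopifnot(!anyNA(m), length(batch) == ncol(m))
  out <- .eb_adjust_one(m, batch)
  if (!is.null(position)) {
    stopifnot(length(position) == ncol(m))
    out <- .eb_adjust_one(out, position)
  }
  out
}

.eb_adjust_one <- function(m, f) {
  f <- as.factor(f)
  if (nlevels(f) < 2) return(m)
  tab <- table(f)
  if (any(tab < 2)) {
    stop("technical factor level(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  G <- nrow(m)
  alpha <- rowMeans(m)
  sig2 <- rowMeans((m - alpha)^2)
  sig <- sqrt(pmax(sig2, 1e-12))
  z <- (m - alpha) / sig

  z_adj <- z
  for (lev in levels(f)) {
    idx <- which(f == lev)
    nb <- length(idx)
    zb <- z[, idx, drop = FALSE]
    gam_hat <- rowMeans(zb)
    del_hat <- rowSums((zb - gam_hat)^2) / (nb - 1)

    # normal prior on the location, variance by method of moments with the
    # estimation noise subtracted (collapses to full pooling when the
    # between-probe spread is pure noise)
    gam_bar <- mean(gam_hat)
    tau2 <- max(0, var(gam_hat) - mean(del_hat) / nb)

    # inverse-gamma prior on the scale by method of moments
    V <- mean(del_hat); S <- var(del_hat)
    if (!is.finite(S) || S < 1e-12) {
      a_pr <- Inf; b_pr <- Inf
    } else {
      a_pr <- (2 * S + V^2) / S
      b_pr <- (V * S + V^3) / S
    }

    gam_star <- gam_hat
    del_star <- del_hat
    for (it in seq_len(100)) {
      g_new <- (nb * tau2 * gam_hat + del_star * gam_bar) /
        (nb * tau2 + del_star)
      ss <- rowSums((zb - g_new)^2)
      d_new <- if (is.finite(a_pr)) {
        (b_pr + 0.5 * ss) / (nb / 2 + a_pr - 1)
      } else rep(V, G)
      if (max(abs(g_new - gam_star), abs(d_new - del_star)) < 1e-10) {
        gam_star <- g_new; del_star <- d_new; break
      }
      gam_star <- g_new; del_star <- d_new
    }
    z_adj[, idx] <- (zb - gam_star) / sqrt(pmax(del_star, 1e-12))
  }
  out <- alpha + sig * z_adj
  # preserve each probe's pooled mean exactly
  out + (alpha - rowMeans(out))
}

#' Trim per-probe outliers by the IQR rule
#'
#' Values strictly outside `[Q1 - factor*IQR, Q3 + factor*IQR]` (quartiles
#' by linear interpolation, single pass) are set missing.
#'
#' @param m numeric matrix, probes in rows.
#' @param factor fence width in IQRs (default 3).
#' @return List with the trimmed matrix `m` and `n_trimmed`.
#' @export
iqr_trim <- function(m, factor = 3) {
  stopifnot(factor > 0)
  n_trim <- 0L
  for (i in seq_len(nrow(m))) {
    q <- quantile(m[i, ], c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                  type = 7)
    iqr <- q[2] - q[1]
    out <- !is.na(m[i, ]) & (m[i, ] < q[1] - factor * iqr |
                               m[i, ] > q[2] + factor * iqr)
    n_trim <- n_trim + sum(out)
    m[i, out] <- NA_real_
  }
  list(m = m, n_trimmed = n_trim)
}

#' Remove blacklisted probes
#'
#' Drops probes on sex chromosomes and probes on the supplied SNP-overlap
#' or cross-reactivity blacklists (set semantics: a probe on several lists
#' is removed and counted once).
#'
#' @param m M-value matrix (probes x samples).
#' @param cpg_info probe annotation (`id`, `chrom`).
#' @param snp_probes,cross_reactive character vectors of probe IDs.
#' @param sex_chromosomes chromosome labels treated as sex chromosomes.
#' @return List with the filtered matrix `m`, the matching `cpg_info` and
#'   the dropped IDs.
#' @export
blacklist_filter <- function(m, cpg_info, snp_probes = character(),
                             cross_reactive = character(),
                             sex_chromosomes = c("chrX", "chrY", "X", "Y")) {
  ids <- rownames(m)
  chrom <- cpg_info$chrom[match(ids, cpg_info$id)]
  drop <- ids %in% union(snp_probes, cross_reactive) |
    chrom %in% sex_chromosomes
  list(m = m[!drop, , drop = FALSE],
       cpg_info = cpg_info[cpg_info$id %in% ids[!drop], , drop = FALSE],
       probes_dropped = ids[drop])
}

#' Reference-based cell-type deconvolution
#'
#' Estimates the seven cord-blood cell-type proportions of each sample by
#' non-negative least squares against a cell-type reference matrix
#' (`||R w - m||^2` s.t. `w >= 0`, solved by Lawson-Hanson NNLS via
#' pracma), then rescales the weights to sum to one. Per sample, only
#' reference probes observed in that sample enter the fit.
#'
#' @param m M-value matrix (probes x samples) containing the reference
#'   probes.
#' @param reference reference matrix (probes x cell types) of cell-type
#'   mean M-values, no missing entries.
#' @return Matrix of proportions (samples x cell types), rows summing to
#'   one.
#' @export
estimate_cell_proportions <- function(m, reference) {
  stopifnot(!anyNA(reference))
  probes <- intersect(rownames(reference), rownames(m))
  if (length(probes) < ncol(reference)) {
    stop("fewer reference probes present than cell types")
  }
  R <- reference[probes, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) stop("reference matrix is rank-deficient")
  X <- m[probes, , drop = FALSE]
  W <- t(apply(X, 2, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < ncol(R)) stop("too few observed reference probes in a sample")
    w <- pracma::lsqnonneg(R[ok, , drop = FALSE], x[ok])$x
    if (sum(w) <= 0) rep(1 / ncol(R), ncol(R)) else w / sum(w)
  }))
  dimnames(W) <- list(colnames(m), colnames(reference))
  W
}

#' Run the full methylation QC chain
#'
#' Detection filter, KNN imputation, empirical-Bayes batch/position
#' adjustment, IQR trimming, blacklist filtering and cell-type
#' deconvolution, in that fixed order.
#'
#' @param m M-value matrix (probes x samples).
#' @param detection_p detection p-value matrix.
#' @param batch,position technical factor vectors, named by sample ID
#'   (samples dropped by the detection filter are handled by name).
#' @param cpg_info probe annotation.
#' @param reference optional cell-type reference matrix.
#' @param snp_probes,cross_reactive blacklist probe IDs.
#' @param config an [analysis_config()].
#' @return List with the cleaned matrix `m`, `cpg_info`,
#'   `cell_proportions` (when a reference is given) and the QC `report`.
#' @export
qc_methylation <- function(m, detection_p, batch = NULL, position = NULL,
                           cpg_info = NULL, reference = NULL,
                           snp_probes = character(),
                           cross_reactive = character(),
                           config = analysis_config()) {
  det <- detection_filter(m, detection_p,
                          probe_call_rate_min = config$probe_call_rate_min,
                          sample_call_rate_min = config$sample_call_rate_min_meth,
                          detection_p_max = config$detection_p_max)
  m <- knn_impute(det$m, k = config$knn_k)
  if (!is.null(batch)) {
    keep <- colnames(m)
    b <- batch[match(keep, names(batch))]
    p <- if (is.null(position)) NULL else position[match(keep, names(position))]
    m <- eb_batch_adjust(m, b, p)
  }
  tr <- iqr_trim(m, factor = config$iqr_factor)
  m <- tr$m
  if (!is.null(cpg_info)) {
    bl <- blacklist_filter(m, cpg_info, snp_probes, cross_reactive)
    m <- bl$m
    cpg_info <- bl$cpg_info
    dropped_bl <- bl$probes_dropped
  } else {
    dropped_bl <- character()
  }
  cells <- if (!is.null(reference)) estimate_cell_proportions(m, reference)
  list(m = m, cpg_info = cpg_info, cell_proportions = cells,
       report = list(
         probes_dropped_detection = det$report$probes_dropped_detection,
         samples_dropped_call_rate = det$report$samples_dropped_call_rate,
         probes_dropped_blacklist = dropped_bl,
         values_trimmed_count = tr$n_trimmed,
         imputed_count = det$report$calls_set_missing
       ))
}
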