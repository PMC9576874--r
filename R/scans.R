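# Association scans: SNP-telomere association (step 1), cis-mQTL mapping
# with moderated inference and Bonferroni control (step 2), replication
# lookup against a reference mQTL table, and SNP-x-CpG interaction
# scanning with the multicollinearity exclusion (step 4).

#' Enumerate cis SNP-CpG pairs
#'
#' All same-chromosome SNP-CpG pairs with `|cpg_pos - snp_pos| <=
#' window_bp` (boundary inclusive). Distance is signed as CpG position
#' minus SNP position.
#'
#' @param snp_info data frame `id`, `chrom`, `pos`.
#' @param cpg_info data frame `id`, `chrom`, `pos`.
#' @param window_bp cis half-window in bp.
#' @return Data frame `snp_id`, `cpg_id`, `distance_bp`, ordered by SNP
#'   then CpG input order.
#' @export
enumerate_cis_pairs <- function(snp_info, cpg_info, window_bp = 500000L) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snp_info)),
            all(c("id", "chrom", "pos") %in% names(cpg_info)))
  snp <- data.frame(snp_id = snp_info$id, chrom = snp_info$chrom,
                    snp_pos = snp_info$pos,
                    snp_ord = seq_len(nrow(snp_info)))
  cpg <- data.frame(cpg_id = cpg_info$id, chrom = cpg_info$chrom,
                    cpg_pos = cpg_info$pos,
                    cpg_ord = seq_len(nrow(cpg_info)))
  mg <- merge(snp, cpg, by = "chrom")
  mg$distance_bp <- mg$cpg_pos - mg$snp_pos
  mg <- mg[abs(mg$distance_bp) <= window_bp, ]
  mg <- mg[order(mg$snp_ord, mg$cpg_ord), ]
  rownames(mg) <- NULL
  mg[, c("snp_id", "cpg_id", "distance_bp")]
}

# coded SNP vector or NULL when constant/untestable
.coded_or_null <- function(dosage, coding) {
  x <- code_genotypes(dosage, coding)
  if (isTRUE(attr(x, "constant"))) NULL else as.numeric(x)
}

.base_covs <- function(ds, adjust_covariates) {
  if (adjust_covariates) {
    if (is.null(ds$covariates)) stop("dataset has no covariates to adjust for")
    ds$covariates
  } else NULL
}

#' SNP-telomere length association scan
#'
#' One covariate-adjusted OLS of the T/S ratio on each coded SNP
#' (complete cases per SNP); nominal significance at `alpha`.
#'
#' @param ds a [study_dataset()] (QC'd).
#' @param coding `"dominant"` or `"additive"`.
#' @param config an [analysis_config()].
#' @param adjust_covariates adjust for the covariate design (default
#'   `TRUE`).
#' @return Data frame: `snp_id`, `coding`, `beta` (T/S per coded unit),
#'   `se`, `t`, `p`, `n`, `significant`, `untestable`.
#' @export
scan_tl_snp <- function(ds, coding = c("dominant", "additive"),
                        config = analysis_config(),
                        adjust_covariates = TRUE) {
  coding <- match.arg(coding)
  covs <- .base_covs(ds, adjust_covariates)
  tl <- ds$phenotype
  rows <- lapply(seq_len(nrow(ds$geno)), function(i) {
    id <- ds$snp_info$id[i]
    x <- code_genotypes(ds$geno[i, ], coding)
    ok <- !is.na(x) & !is.na(tl)
    xs <- x[ok]
    if (length(unique(xs)) < 2) {
      return(data.frame(snp_id = id, coding = coding, beta = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        n = sum(ok), significant = FALSE,
                        untestable = TRUE))
    }
    X <- build_design(if (is.null(covs)) NULL else covs[ok, , drop = FALSE],
                      extra = list(snp = xs))
    fit <- fit_ols(X, tl[ok])
    k <- match("snp", colnames(X))
    data.frame(snp_id = id, coding = coding,
               beta = fit$coefficients[k], se = fit$se[k], t = fit$t[k],
               p = fit$p[k], n = fit$n,
               significant = fit$p[k] < config$alpha, untestable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Matrix-response OLS of several CpGs on one shared design; returns
# per-response beta/se/s2 for the last ("snp") column.
.fit_snp_block <- function(X, Y) {
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  o <- order(qx$pivot)
  xtx_inv <- xtx_inv[o, o, drop = FALSE]
  k <- match("snp", colnames(X))
  c_snp <- xtx_inv[k, k]
  list(beta = beta[k, ], s2 = s2, c_snp = c_snp, df = df)
}

#' cis-mQTL scan with empirical-Bayes moderated inference
#'
#' For every cis SNP-CpG pair, fits the CpG M-value on the coded SNP with
#' the covariate design; residual variances are moderated across all
#' pairs ([ebayes_moderate()]) and Bonferroni control is applied over the
#' total number of tested pairs. The significant set requires, by
#' default, Bonferroni significance under both the dominant and the
#' additive coding (`rule = "both"`); `rule = "either"` relaxes to the
#' union.
#'
#' @param ds a [study_dataset()] (QC'd; complete methylation enables the
#'   fast grouped fit).
#' @param config an [analysis_config()].
#' @param codings codings to scan (default both).
#' @param rule `"both"` or `"either"` for combining codings.
#' @param moderate apply variance moderation (default `TRUE`; `FALSE`
#'   gives ordinary OLS t-tests).
#' @param adjust_covariates adjust for the covariate design.
#' @return An object of class `mqtl_scan`: `results` (one row per pair
#'   per coding with `beta`, `se`, `t` (moderated when requested), `p`,
#'   `df`, `n`, `bonferroni_significant`), `significant_pairs`,
#'   `m` (tested pairs), `threshold`, and per-coding `moderation`
#'   hyperparameters.
#' @export
scan_mqtl <- function(ds, config = analysis_config(),
                      codings = c("dominant", "additive"),
                      rule = c("both", "either"), moderate = TRUE,
                      adjust_covariates = TRUE) {
  rule <- match.arg(rule)
  codings <- match.arg(codings, several.ok = TRUE)
  pairs <- enumerate_cis_pairs(ds$snp_info, ds$cpg_info,
                               config$cis_window_bp)
  m_tests <- nrow(pairs)
  if (m_tests == 0) {
    return(structure(list(results = NULL, significant_pairs = NULL,
                          m = 0L, threshold = NA_real_), class = "mqtl_scan"))
  }
  covs <- .base_covs(ds, adjust_covariates)
  moderation <- list()
  all_res <- list()

  for (coding in codings) {
    beta <- se <- tval <- s2 <- cs <- rep(NA_real_, m_tests)
    df <- nn <- rep(NA_integer_, m_tests)
    for (sid in unique(pairs$snp_id)) {
      sel <- which(pairs$snp_id == sid)
      x <- .coded_or_null(ds$geno[sid, ], coding)
      if (is.null(x)) next
      Y <- t(ds$meth[pairs$cpg_id[sel], , drop = FALSE])
      ok_x <- !is.na(x)
      complete <- !anyNA(Y[ok_x, , drop = FALSE])
      X <- build_design(if (is.null(covs)) NULL
                        else covs[ok_x, , drop = FALSE],
                        extra = list(snp = x[ok_x]))
      if (complete) {
        fb <- .fit_snp_block(X, Y[ok_x, , drop = FALSE])
        beta[sel] <- fb$beta
        s2[sel] <- fb$s2
        cs[sel] <- fb$c_snp
        df[sel] <- fb$df
        nn[sel] <- sum(ok_x)
      } else {
        for (j in seq_along(sel)) {
          y <- Y[, j]
          ok <- ok_x & !is.na(y)
          if (sum(ok) < ncol(X) + 1 || length(unique(x[ok])) < 2) next
          Xj <- build_design(if (is.null(covs)) NULL
                             else covs[ok, , drop = FALSE],
                             extra = list(snp = x[ok]))
          fit <- fit_ols(Xj, y[ok])
          k <- match("snp", colnames(Xj))
          beta[sel[j]] <- fit$coefficients[k]
          s2[sel[j]] <- fit$s2
          cs[sel[j]] <- fit$cov_unscaled[k, k]
          df[sel[j]] <- fit$df
          nn[sel[j]] <- fit$n
        }
      }
    }
    tested <- !is.na(beta)
    if (moderate && sum(tested) >= 10) {
      mod <- ebayes_moderate(s2[tested], df[tested])
      moderation[[coding]] <- mod[c("d0", "s0_sq")]
      s2_use <- s2
      s2_use[tested] <- mod$s2_post
      df_use <- df + mod$d0
    } else {
      s2_use <- s2
      df_use <- df
    }
    se <- sqrt(s2_use * cs)
    tval <- beta / se
    pval <- 2 * pt(-abs(tval), df = df_use)
    bf <- bonferroni(pval, alpha = config$alpha, m = m_tests)
    all_res[[coding]] <- data.frame(
      pairs, coding = coding, n = nn, df = df, beta = beta, se = se,
      t = tval, p = pval, bonferroni_significant = bf$flags
    )
  }

  results <- do.call(rbind, all_res)
  rownames(results) <- NULL
  key <- function(df) paste(df$snp_id, df$cpg_id, sep = "\r")
  flags <- lapply(all_res, function(r) key(r)[r$bonferroni_significant])
  sig_keys <- if (rule == "both") Reduce(intersect, flags)
              else Reduce(union, flags)
  sig <- pairs[key(pairs) %in% sig_keys, , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(results = results, significant_pairs = sig, m = m_tests,
                 threshold = config$alpha / m_tests, rule = rule,
                 moderation = moderation), class = "mqtl_scan")
}

#' @export
print.mqtl_scan <- function(x, ...) {
  cat("mqtl_scan:", x$m, "cis pairs tested, Bonferroni threshold",
      format(x$threshold, digits = 3), "\n")
  cat("  significant pairs (rule =", x$rule, "):",
      if (is.null(x$significant_pairs)) 0 else nrow(x$significant_pairs),
      "\n")
  invisible(x)
}

#' Compare significant mQTLs with a reference table
#'
#' Matches each significant SNP-CpG pair against a reference mQTL table
#' and classifies it as `replicated_concordant` (pair present, same
#' effect direction), `replicated_discordant` (pair present, opposite
#' direction) or `novel`.
#'
#' @param scan an `mqtl_scan` (or a data frame of pairs with a `beta`
#'   column).
#' @param reference data frame `snp_id`, `cpg_id`, `beta` (reference
#'   effect; only its sign is used). Unique pairs.
#' @param coding which coding's effect signs to compare (default
#'   dominant).
#' @return List with `table` (per-pair status) and `summary` (counts).
#' @export
compare_to_reference <- function(scan, reference,
                                 coding = "dominant") {
  if (inherits(scan, "mqtl_scan")) {
    sig <- scan$significant_pairs
    res <- scan$results
    res <- res[res$coding == coding, ]
    sig <- merge(sig, res[, c("snp_id", "cpg_id", "beta")],
                 by = c("snp_id", "cpg_id"), sort = FALSE)
  } else {
    sig <- scan
  }
  if (is.null(sig) || nrow(sig) == 0) {
    return(list(table = NULL,
                summary = c(replicated_concordant = 0L,
                            replicated_discordant = 0L, novel = 0L)))
  }
  if (!is.null(reference) && nrow(reference) > 0) {
    stopifnot(!anyDuplicated(paste(reference$snp_id, reference$cpg_id)))
    mg <- merge(sig, reference, by = c("snp_id", "cpg_id"),
                suffixes = c("", "_ref"), all.x = TRUE, sort = FALSE)
  } else {
    mg <- sig
    mg$beta_ref <- NA_real_
  }
  mg$status <- ifelse(is.na(mg$beta_ref), "novel",
                      ifelse(sign(mg$beta) == sign(mg$beta_ref),
                             "replicated_concordant",
                             "replicated_discordant"))
  counts <- table(factor(mg$status, levels = c("replicated_concordant",
                                               "replicated_discordant",
                                               "novel")))
  list(table = mg, summary = c(counts))
}

#' SNP-x-CpG interaction scan
#'
#' Fits, for every cis pair not Bonferroni-significant in the mQTL scan
#' (those are excluded because genotype-methylation independence cannot
#' be assumed), the telomere model with an additive-coded SNP, the CpG
#' M-value, their product, and the covariate design. The interaction
#' coefficient is Bonferroni-controlled over the interaction universe;
#' the SNP main effect is separately Bonferroni-controlled over the
#' number of SNPs.
#'
#' @param ds a [study_dataset()] (QC'd).
#' @param mqtl_significant data frame `snp_id`, `cpg_id` of pairs to
#'   exclude (e.g. `scan_mqtl(...)$significant_pairs`), or `NULL`.
#' @param config an [analysis_config()].
#' @param adjust_covariates adjust for the covariate design.
#' @param m_snp_main Bonferroni denominator for the SNP main effect
#'   (default: number of distinct SNPs in the dataset).
#' @return An object of class `interaction_scan`: `results` (per pair:
#'   `beta12`, `se12`, `p12`, `beta_snp`, `p_snp`, `beta_cpg`, `p_cpg`,
#'   `n`, Bonferroni flags `significant_interaction` /
#'   `significant_snp_main`), `m` (universe size), `threshold`.
#' @export
scan_interaction <- function(ds, mqtl_significant = NULL,
                             config = analysis_config(),
                             adjust_covariates = TRUE,
                             m_snp_main = NULL) {
  pairs <- enumerate_cis_pairs(ds$snp_info, ds$cpg_info,
                               config$cis_window_bp)
  if (!is.null(mqtl_significant) && nrow(mqtl_significant) > 0) {
    key <- paste(pairs$snp_id, pairs$cpg_id)
    drop <- key %in% paste(mqtl_significant$snp_id, mqtl_significant$cpg_id)
    pairs <- pairs[!drop, , drop = FALSE]
  }
  m_tests <- nrow(pairs)
  if (is.null(m_snp_main)) m_snp_main <- length(unique(ds$snp_info$id))
  covs <- .base_covs(ds, adjust_covariates)
  tl <- ds$phenotype

  rows <- lapply(seq_len(m_tests), function(i) {
    sid <- pairs$snp_id[i]; cid <- pairs$cpg_id[i]
    x <- as.numeric(ds$geno[sid, ])
    mcpg <- ds$meth[cid, ]
    ok <- !is.na(x) & !is.na(mcpg) & !is.na(tl)
    out <- data.frame(snp_id = sid, cpg_id = cid,
                      distance_bp = pairs$distance_bp[i],
                      beta12 = NA_real_, se12 = NA_real_, p12 = NA_real_,
                      beta_snp = NA_real_, p_snp = NA_real_,
                      beta_cpg = NA_real_, p_cpg = NA_real_,
                      n = sum(ok), untestable = TRUE)
    if (length(unique(x[ok])) < 2 || length(unique(mcpg[ok])) < 2) return(out)
    X <- build_design(if (is.null(covs)) NULL else covs[ok, , drop = FALSE],
                      extra = list(snp = x[ok], cpg = mcpg[ok],
                                   snp_cpg = x[ok] * mcpg[ok]))
    fit <- fit_ols(X, tl[ok])
    ks <- match(c("snp", "cpg", "snp_cpg"), colnames(X))
    out$beta12 <- fit$coefficients[ks[3]]
    out$se12 <- fit$se[ks[3]]
    out$p12 <- fit$p[ks[3]]
    out$beta_snp <- fit$coefficients[ks[1]]
    out$p_snp <- fit$p[ks[1]]
    out$beta_cpg <- fit$coefficients[ks[2]]
    out$p_cpg <- fit$p[ks[2]]
    out$untestable <- FALSE
    out
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  bf12 <- bonferroni(results$p12, alpha = config$alpha, m = m_tests)
  bfs <- bonferroni(results$p_snp, alpha = config$alpha, m = m_snp_main)
  results$significant_interaction <- bf12$flags
  results$significant_snp_main <- bfs$flags
  structure(list(results = results, m = m_tests,
                 threshold = bf12$threshold, m_snp_main = m_snp_main),
            class = "interaction_scan")
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat("interaction_scan:", x$m, "pairs tested, Bonferroni threshold",
      format(x$threshold, digits = 3), "\n")
  cat("  significant interactions:",
      sum(x$results$significant_interaction, na.rm = TRUE), "\n")
  invisible(x)
}
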