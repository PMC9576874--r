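# Mediation of the SNP-telomere association through CpG methylation
# (step 3): candidate selection, product-of-coefficients estimation of
# direct/indirect/total effects, and bootstrap-percentile inference.
# In linear models without treatment-mediator interaction the product
# estimator coincides with the causal-mediation ACME, so no simulation
# machinery is needed.

#' Select mediation candidates from the mQTL scan
#'
#' For each CpG involved in a Bonferroni-significant mQTL, fits the
#' telomere phenotype on the CpG plus covariates (marginally, without the
#' SNP, unless `include_snp`); pairs whose CpG is nominally associated
#' with telomere length (p < `alpha`) become mediation candidates. A CpG
#' significant with k SNPs yields k candidates.
#'
#' @param scan an `mqtl_scan` result (or a data frame of significant
#'   pairs `snp_id`, `cpg_id`, optionally with a `p` column as `mqtl_p`).
#' @param ds a [study_dataset()].
#' @param config an [analysis_config()].
#' @param include_snp also adjust the screen for the (dominant-coded)
#'   SNP (default `FALSE`, the marginal screen).
#' @param adjust_covariates adjust for the covariate design.
#' @return Data frame `snp_id`, `cpg_id`, `cpg_tl_beta`, `cpg_tl_p`,
#'   restricted to candidates.
#' @export
select_candidates <- function(scan, ds, config = analysis_config(),
                              include_snp = FALSE,
                              adjust_covariates = TRUE) {
  sig <- if (inherits(scan, "mqtl_scan")) scan$significant_pairs else scan
  if (is.null(sig) || nrow(sig) == 0) {
    return(data.frame(snp_id = character(), cpg_id = character(),
                      cpg_tl_beta = numeric(), cpg_tl_p = numeric()))
  }
  covs <- .base_covs(ds, adjust_covariates)
  tl <- ds$phenotype
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    cid <- sig$cpg_id[i]
    mcpg <- ds$meth[cid, ]
    ok <- !is.na(mcpg) & !is.na(tl)
    ex <- list(cpg = mcpg[ok])
    if (include_snp) {
      x <- code_genotypes(ds$geno[sig$snp_id[i], ], "dominant")
      ok <- ok & !is.na(x)
      ex <- list(cpg = mcpg[ok], snp = x[ok])
    }
    X <- build_design(if (is.null(covs)) NULL else covs[ok, , drop = FALSE],
                      extra = ex)
    fit <- fit_ols(X, tl[ok])
    k <- match("cpg", colnames(X))
    data.frame(snp_id = sig$snp_id[i], cpg_id = cid,
               cpg_tl_beta = fit$coefficients[k], cpg_tl_p = fit$p[k])
  })
  out <- do.call(rbind, rows)
  out <- out[out$cpg_tl_p < config$alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build the complete-case model matrices for one SNP-CpG mediation pair.
.mediation_matrices <- function(ds, snp_id, cpg_id, coding,
                                adjust_covariates) {
  covs <- .base_covs(ds, adjust_covariates)
  x <- code_genotypes(ds$geno[snp_id, ], coding)
  mcpg <- ds$meth[cpg_id, ]
  tl <- ds$phenotype
  ok <- !is.na(x) & !is.na(mcpg) & !is.na(tl)
  x <- as.numeric(x[ok]); mcpg <- mcpg[ok]; tl <- tl[ok]
  if (length(unique(x)) < 2) stop("constant coded SNP: ", snp_id)
  if (length(unique(mcpg)) < 2) stop("constant CpG: ", cpg_id)
  C <- build_design(if (is.null(covs)) NULL else covs[ok, , drop = FALSE],
                    extra = list(snp = x))
  k_snp <- match("snp", colnames(C))
  Xo <- cbind(C, cpg = mcpg)
  list(Xm = C, Xo = Xo, mediator = mcpg, tl = tl, snp = x,
       k_snp = k_snp, k_cpg = ncol(Xo), n = length(tl))
}

.mediation_point <- function(mm) {
  a <- .lm.fit(mm$Xm, mm$mediator)$coefficients[mm$k_snp]
  co <- .lm.fit(mm$Xo, mm$tl)$coefficients
  de <- co[mm$k_snp]
  b <- co[mm$k_cpg]
  ie <- a * b
  te <- de + ie
  prop <- if (!is.na(de) && !is.na(ie) && sign(de) == sign(ie) && te != 0) {
    ie / te
  } else NA_real_
  c(a = unname(a), b = unname(b), de = unname(de), ie = unname(ie),
    te = unname(te), prop_mediated = unname(prop))
}

#' Point estimates of a mediation decomposition
#'
#' Product-of-coefficients estimation on the pair of linear models:
#' the mediator model (CpG M-value on the dominant-coded SNP plus
#' covariates) gives the SNP-to-CpG path `a`; the outcome model (T/S on
#' SNP, CpG and covariates) gives the direct effect `de` (c') and the
#' CpG-to-telomere path `b`. The indirect effect is `ie = a * b`, the
#' total effect `te = de + ie`, and the proportion mediated `ie / te` is
#' reported only when `de` and `ie` share a sign.
#'
#' @param ds a [study_dataset()].
#' @param snp_id,cpg_id the pair.
#' @param coding SNP coding (default dominant).
#' @param adjust_covariates adjust for the covariate design.
#' @return Named numeric vector `a`, `b`, `de`, `ie`, `te`,
#'   `prop_mediated` (`NA` under opposite signs).
#' @export
fit_mediation <- function(ds, snp_id, cpg_id, coding = "dominant",
                          adjust_covariates = TRUE) {
  mm <- .mediation_matrices(ds, snp_id, cpg_id, coding, adjust_covariates)
  .mediation_point(mm)
}

#' Bootstrap-percentile inference for a mediation pair
#'
#' Resamples individuals with replacement `n_boot` times, refits both
#' mediation models per replicate, and reports 2.5/97.5 percentile
#' confidence intervals (linear interpolation) and the symmetric
#' two-sided bootstrap p-value `2 min(P(est <= 0), P(est >= 0))` for each
#' effect. Replicates with a degenerate design (resampled constant SNP or
#' CpG) are redrawn and counted; more than 10% degenerate draws is an
#' error. The proportion-mediated distribution uses only replicates where
#' direct and indirect effects share a sign (their number is reported).
#' Deterministic under `seed`.
#'
#' @param ds a [study_dataset()].
#' @param snp_id,cpg_id the pair.
#' @param n_boot bootstrap replicates (>= 100; study default 1,000).
#' @param seed integer seed.
#' @param coding SNP coding (default dominant).
#' @param adjust_covariates adjust for the covariate design.
#' @return An object of class `mediation_result`: point `estimates`,
#'   `ci` (2.5/97.5 percentiles per effect), `boot_p`, `prop_ci`,
#'   `prop_p`, `n_same_sign`, `n_degenerate`, `n_boot`, `seed`, `n`.
#' @export
bootstrap_mediation <- function(ds, snp_id, cpg_id, n_boot = 1000L,
                                seed = 1L, coding = "dominant",
                                adjust_covariates = TRUE) {
  stopifnot(n_boot >= 100)
  mm <- .mediation_matrices(ds, snp_id, cpg_id, coding, adjust_covariates)
  point <- .mediation_point(mm)
  n <- mm$n
  eff <- c("a", "b", "de", "ie", "te")
  boot <- matrix(NA_real_, n_boot, 6,
                 dimnames = list(NULL, c(eff, "prop_mediated")))
  n_degenerate <- 0L
  max_degenerate <- ceiling(0.1 * n_boot)
  withr::with_seed(seed, {
    for (r in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(mm$snp[idx])) >= 2 &&
            length(unique(mm$mediator[idx])) >= 2) break
        n_degenerate <- n_degenerate + 1L
        if (n_degenerate > max_degenerate) {
          stop("more than 10% of bootstrap replicates degenerate; ",
               "data too sparse for pair ", snp_id, "-", cpg_id)
        }
      }
      mr <- list(Xm = mm$Xm[idx, , drop = FALSE],
                 Xo = mm$Xo[idx, , drop = FALSE],
                 mediator = mm$mediator[idx], tl = mm$tl[idx],
                 k_snp = mm$k_snp, k_cpg = mm$k_cpg)
      boot[r, ] <- .mediation_point(mr)
    }
  })
  ci <- t(apply(boot[, eff], 2, quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7))
  colnames(ci) <- c("lower", "upper")
  boot_p <- vapply(eff, function(e) {
    x <- boot[, e]
    min(1, 2 * min(mean(x <= 0), mean(x >= 0)))
  }, numeric(1))
  same <- !is.na(boot[, "prop_mediated"])
  prop_ci <- if (any(same)) {
    quantile(boot[same, "prop_mediated"], c(0.025, 0.975), names = FALSE,
             type = 7)
  } else c(NA_real_, NA_real_)
  prop_p <- if (any(same)) {
    x <- boot[same, "prop_mediated"]
    min(1, 2 * min(mean(x <= 0), mean(x >= 0)))
  } else NA_real_
  structure(list(
    snp_id = snp_id, cpg_id = cpg_id, estimates = point, ci = ci,
    boot_p = boot_p, prop_ci = prop_ci, prop_p = prop_p,
    n_same_sign = sum(same), n_degenerate = n_degenerate,
    n_boot = n_boot, seed = seed, n = n, boot = boot
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("mediation_result:", x$snp_id, "->", x$cpg_id, "-> T/S, n =", x$n,
      ",", x$n_boot, "bootstrap replicates\n")
  tab <- data.frame(estimate = x$estimates[c("a", "b", "de", "ie", "te")],
                    x$ci, boot_p = x$boot_p)
  print(tab)
  pm <- x$estimates["prop_mediated"]
  if (!is.na(pm)) {
    cat(sprintf("  proportion mediated: %.2f (p = %.2g, %d same-sign replicates)\n",
                pm, x$prop_p, x$n_same_sign))
  } else {
    cat("  proportion mediated undefined (direct and indirect effects have opposite signs)\n")
  }
  invisible(x)
}

#' Run the full four-step analysis
#'
#' Convenience wrapper: SNP-telomere association under both codings
#' (step 1), the cis-mQTL scan (step 2), mediation candidate selection
#' and bootstrap inference (step 3), and the SNP-x-CpG interaction scan
#' with the mQTL-pair exclusion (step 4).
#'
#' @param ds a QC'd [study_dataset()].
#' @param config an [analysis_config()].
#' @param adjust_covariates adjust all models for the covariate design.
#' @return List with `association` (both codings), `mqtl`, `candidates`,
#'   `mediation` (one `mediation_result` per candidate pair) and
#'   `interaction`.
#' @export
run_analysis <- function(ds, config = analysis_config(),
                         adjust_covariates = TRUE) {
  assoc <- rbind(
    scan_tl_snp(ds, "dominant", config, adjust_covariates),
    scan_tl_snp(ds, "additive", config, adjust_covariates)
  )
  mqtl <- scan_mqtl(ds, config, adjust_covariates = adjust_covariates)
  cand <- select_candidates(mqtl, ds, config,
                            adjust_covariates = adjust_covariates)
  med <- lapply(seq_len(nrow(cand)), function(i) {
    bootstrap_mediation(ds, cand$snp_id[i], cand$cpg_id[i],
                        n_boot = config$n_boot, seed = config$seed,
                        adjust_covariates = adjust_covariates)
  })
  names(med) <- if (nrow(cand)) paste(cand$snp_id, cand$cpg_id, sep = "-")
  ia <- scan_interaction(ds, mqtl$significant_pairs, config,
                         adjust_covariates = adjust_covariates)
  list(association = assoc, mqtl = mqtl, candidates = cand,
       mediation = med, interaction = ia)
}
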