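# Genotype QC chain, applied in the fixed order: SNP/sample call-rate
# filters, imputation of residual missingness, then MAF and
# Hardy-Weinberg filters. Thresholds are strict inequalities: a feature is
# dropped only when its statistic is strictly below (or, for HWE p,
# strictly below) the configured minimum.

#' Filter SNPs and samples by call rate
#'
#' SNPs whose non-missing fraction is strictly below `snp_call_rate_min`
#' are dropped first; then samples whose call rate over the retained SNPs
#' is strictly below `sample_call_rate_min` are dropped.
#'
#' @param geno_list list with `geno` dosage matrix and `info` data frame
#'   (as from [read_genotypes()]).
#' @param snp_call_rate_min minimum SNP call rate (default 0.95).
#' @param sample_call_rate_min minimum sample call rate (default 0.90).
#' @return List with filtered `geno`, `info` and a `report` holding the
#'   dropped IDs and per-SNP call rates.
#' @export
filter_call_rates <- function(geno_list, snp_call_rate_min = 0.95,
                              sample_call_rate_min = 0.90) {
  geno <- geno_list$geno
  snp_cr <- rowMeans(!is.na(geno))
  drop_snp <- snp_cr < snp_call_rate_min
  if (all(drop_snp)) stop("all SNPs dropped by the call-rate filter")
  geno2 <- geno[!drop_snp, , drop = FALSE]
  sample_cr <- colMeans(!is.na(geno2))
  drop_sample <- sample_cr < sample_call_rate_min
  geno3 <- geno2[, !drop_sample, drop = FALSE]
  info <- geno_list$info[!drop_snp, , drop = FALSE]
  info$maf <- .observed_maf(geno3)
  list(
    geno = geno3, info = info,
    report = list(
      snps_dropped_call_rate = rownames(geno)[drop_snp],
      samples_dropped_call_rate = colnames(geno2)[drop_sample],
      snp_call_rate = snp_cr, sample_call_rate = sample_cr
    )
  )
}

.observed_maf <- function(geno) {
  apply(geno, 1, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    sum(d) / (2 * length(d))
  })
}

#' Impute missing genotypes from the empirical genotype distribution
#'
#' Each missing dosage is drawn from the SNP's observed genotype
#' frequency distribution. This is a deliberately simple scheme for a
#' sparse candidate-SNP panel without a surrounding haplotype scaffold
#' (no LD information is available to a reference-based imputer here).
#' Deterministic under `seed`.
#'
#' @param geno_list list with `geno` and `info`.
#' @param seed integer seed.
#' @return The list with `geno` complete and `info$maf` refreshed.
#' @export
impute_genotypes <- function(geno_list, seed = 1L) {
  geno <- geno_list$geno
  full_miss <- rowSums(!is.na(geno)) == 0
  if (any(full_miss)) {
    stop("SNP(s) with no observed genotype: ",
         paste(rownames(geno)[full_miss], collapse = ", "))
  }
  withr::with_seed(seed, {
    for (i in seq_len(nrow(geno))) {
      miss <- is.na(geno[i, ])
      if (!any(miss)) next
      obs <- geno[i, !miss]
      tab <- tabulate(obs + 1L, nbins = 3L)
      geno[i, miss] <- sample(0:2, sum(miss), replace = TRUE,
                              prob = tab / sum(tab))
    }
  })
  info <- geno_list$info
  info$maf <- .observed_maf(geno)
  list(geno = geno, info = info, report = geno_list$report)
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype
#' counts against the HWE-expected counts (p^2, 2pq, q^2 at the observed
#' allele frequency), without continuity correction. Monomorphic input
#' (allele frequency 0 or 1) is defined as chi2 = 0, p = 1.
#'
#' @param n_major_hom,n_het,n_minor_hom genotype counts (vectorized).
#' @return Data frame with columns `chi2` and `p`.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: chi2 = 0, p = 1
#' @export
hwe_test <- function(n_major_hom, n_het, n_minor_hom) {
  n0 <- as.numeric(n_major_hom); n1 <- as.numeric(n_het)
  n2 <- as.numeric(n_minor_hom)
  n <- n0 + n1 + n2
  stopifnot(all(n > 0))
  p <- (2 * n0 + n1) / (2 * n)
  q <- 1 - p
  chi2 <- numeric(length(n))
  poly <- p > 0 & p < 1
  if (any(poly)) {
    e0 <- n[poly] * p[poly]^2
    e1 <- n[poly] * 2 * p[poly] * q[poly]
    e2 <- n[poly] * q[poly]^2
    chi2[poly] <- (n0[poly] - e0)^2 / e0 + (n1[poly] - e1)^2 / e1 +
      (n2[poly] - e2)^2 / e2
  }
  pval <- ifelse(poly, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  data.frame(chi2 = chi2, p = pval)
}

#' Filter SNPs by minor-allele frequency and Hardy-Weinberg equilibrium
#'
#' A SNP is retained iff `maf >= maf_min` and HWE p `>= hwe_p_min`
#' (removal uses the strict inequalities of the filter definitions).
#' Requires complete dosages (run after [impute_genotypes()]).
#'
#' @param geno_list list with complete `geno` and `info`.
#' @param maf_min MAF threshold (default 0.01).
#' @param hwe_p_min HWE p-value threshold (default 0.05).
#' @return List with filtered `geno`, `info` and a `report` with the
#'   dropped IDs and the per-SNP maf/HWE tables.
#' @export
filter_maf_hwe <- function(geno_list, maf_min = 0.01, hwe_p_min = 0.05) {
  geno <- geno_list$geno
  stopifnot(!anyNA(geno))
  maf <- .observed_maf(geno)
  counts <- t(apply(geno, 1, function(d) tabulate(d + 1L, nbins = 3L)))
  hwe <- hwe_test(counts[, 1], counts[, 2], counts[, 3])
  drop_maf <- maf < maf_min
  drop_hwe <- hwe$p < hwe_p_min
  keep <- !drop_maf & !drop_hwe
  info <- geno_list$info[keep, , drop = FALSE]
  info$maf <- maf[keep]
  list(
    geno = geno[keep, , drop = FALSE], info = info,
    report = c(geno_list$report, list(
      snps_dropped_maf = rownames(geno)[drop_maf],
      snps_dropped_hwe = rownames(geno)[drop_hwe],
      maf = setNames(maf, rownames(geno)),
      hwe = cbind(data.frame(id = rownames(geno)), hwe)
    ))
  )
}

#' Run the full genotype QC chain
#'
#' Call-rate filters, then empirical imputation, then MAF/HWE filters, in
#' that fixed order.
#'
#' @param geno_list list with `geno` and `info`.
#' @param config an [analysis_config()].
#' @return As [filter_maf_hwe()]: filtered complete genotypes plus the
#'   cumulative QC report.
#' @export
qc_genotypes <- function(geno_list, config = analysis_config()) {
  out <- filter_call_rates(geno_list,
                           snp_call_rate_min = config$snp_call_rate_min,
                           sample_call_rate_min = config$sample_call_rate_min_geno)
  out <- impute_genotypes(out, seed = config$seed)
  filter_maf_hwe(out, maf_min = config$maf_min, hwe_p_min = config$hwe_p_min)
}

#' Code genotypes for regression
#'
#' Dominant coding maps dosage \{0, 1, 2\} to a minor-allele carrier
#' indicator \{0, 1, 1\}; additive coding is the identity on the dosage.
#'
#' @param dosage numeric dosage vector in \{0, 1, 2\} (NA allowed).
#' @param coding `"dominant"` or `"additive"`.
#' @return Numeric coded vector; a constant result carries attribute
#'   `constant = TRUE` (unusable as a regressor).
#' @export
code_genotypes <- function(dosage, coding = c("dominant", "additive")) {
  coding <- match.arg(coding)
  out <- if (coding == "dominant") pmin(dosage, 1) else as.numeric(dosage)
  if (length(unique(out[!is.na(out)])) < 2) attr(out, "constant") <- TRUE
  out
}

#' Pairwise linkage-disequilibrium r-squared matrix
#'
#' Squared Pearson correlations of minor-allele dosages across SNPs
#' (pairwise complete observations). A constant SNP has its row and
#' column set to `NA`.
#'
#' @param geno dosage matrix (SNPs x samples).
#' @return Symmetric numeric matrix with unit diagonal (for polymorphic
#'   SNPs) and entries in [0, 1].
#' @export
ld_r2_matrix <- function(geno) {
  stopifnot(nrow(geno) >= 2)
  r <- suppressWarnings(cor(t(geno), use = "pairwise.complete.obs"))
  r2 <- r^2
  const <- apply(geno, 1, function(d) {
    length(unique(d[!is.na(d)])) < 2
  })
  r2[const, ] <- NA_real_
  r2[, const] <- NA_real_
  d <- diag(r2)
  d[!const] <- 1
  diag(r2) <- d
  r2
}
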