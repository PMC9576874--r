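# Small fixture builders used across the suite. Everything is generated
# in code at test time.

# A minimal genotype bundle (k SNPs on one chromosome).
toy_geno <- function(dosages, ids = paste0("rs", seq_len(nrow(dosages))),
                     chrom = "chr1",
                     pos = seq(1e6, by = 1e4, length.out = nrow(dosages))) {
  rownames(dosages) <- ids
  colnames(dosages) <- paste0("S", seq_len(ncol(dosages)))
  list(geno = dosages,
       info = data.frame(id = ids, chrom = chrom, pos = pos,
                         major = "A", minor = "G",
                         maf = apply(dosages, 1, function(d) {
                           d <- d[!is.na(d)]
                           sum(d) / (2 * length(d))
                         })))
}

# A covariate-free single-SNP / single-CpG dataset built directly from
# the structural model: M = a_dom * 1{dosage>0} + N(0, sd_m),
# TL = c_dom * 1{dosage>0} + b * M + beta12 * dosage * M + N(0, tl_sd).
toy_pair_dataset <- function(n = 500, maf = 0.3, a = 0, b = 0, c_dom = 0,
                             beta12 = 0, sd_m = 1, tl_sd = 0.2,
                             tl_mean = 1.03) {
  dose <- rbinom(n, 2, maf)
  dom <- as.numeric(dose > 0)
  m <- a * dom + rnorm(n, 0, sd_m)
  tl <- tl_mean + c_dom * dom + b * m + beta12 * dose * m +
    rnorm(n, 0, tl_sd)
  ids <- paste0("S", seq_len(n))
  geno <- matrix(as.integer(dose), nrow = 1,
                 dimnames = list("rs1", ids))
  meth <- matrix(m, nrow = 1, dimnames = list("cg00000001", ids))
  study_dataset(
    geno = geno,
    snp_info = data.frame(id = "rs1", chrom = "chr1", pos = 1000000L,
                          major = "A", minor = "G",
                          maf = sum(dose) / (2 * n)),
    meth = meth,
    cpg_info = data.frame(id = "cg00000001", chrom = "chr1",
                          pos = 1010000L),
    covariates = NULL, phenotype = tl, sample_ids = ids
  )
}

# Brute-force O(n*m) oracle for cis-pair enumeration.
brute_cis_pairs <- function(snp_info, cpg_info, window_bp) {
  out <- NULL
  for (i in seq_len(nrow(snp_info))) {
    for (j in seq_len(nrow(cpg_info))) {
      if (snp_info$chrom[i] == cpg_info$chrom[j] &&
          abs(cpg_info$pos[j] - snp_info$pos[i]) <= window_bp) {
        out <- rbind(out, data.frame(
          snp_id = snp_info$id[i], cpg_id = cpg_info$id[j],
          distance_bp = cpg_info$pos[j] - snp_info$pos[i]))
      }
    }
  }
  out
}

# Direct-formula HWE oracle: Pearson chi-square from expected counts.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n0 + n1) / (2 * n)
  q <- 1 - p
  if (p == 0 || p == 1) return(c(chi2 = 0, p = 1))
  e <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n0, n1, n2) - e)^2 / e)
  c(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
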