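test_that("cis-pair enumeration is boundary-inclusive and chromosome-aware", {
  snp <- data.frame(id = "rs1", chrom = "chr1", pos = 1000000L)
  cpg <- data.frame(id = paste0("cg", 1:5),
                    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                    pos = c(500000L, 499999L, 1500000L, 1500001L, 1000000L))
  pairs <- enumerate_cis_pairs(snp, cpg, 500000L)
  expect_setequal(pairs$cpg_id, c("cg1", "cg3"))
  expect_equal(pairs$distance_bp[pairs$cpg_id == "cg1"], -500000)
  expect_equal(pairs$distance_bp[pairs$cpg_id == "cg3"], 500000)
})

test_that("cis-pair enumeration equals the brute-force double loop", {
  set.seed(31)
  for (trial in 1:50) {
    snp <- data.frame(id = paste0("rs", 1:20),
                      chrom = sample(paste0("chr", 1:3), 20, TRUE),
                      pos = sample.int(3e6, 20))
    cpg <- data.frame(id = paste0("cg", 1:60),
                      chrom = sample(paste0("chr", 1:3), 60, TRUE),
                      pos = sample.int(3e6, 60))
    w <- sample(c(1e5, 5e5, 1e6), 1)
    got <- enumerate_cis_pairs(snp, cpg, w)
    want <- brute_cis_pairs(snp, cpg, w)
    key <- function(d) if (is.null(d)) character() else
      sort(paste(d$snp_id, d$cpg_id, d$distance_bp))
    expect_identical(key(got), key(want))
  }
})

test_that("SNP-telomere scan reduces to the simple-regression closed form without covariates", {
  set.seed(32)
  ds <- toy_pair_dataset(n = 300, maf = 0.3, c_dom = 0.1)
  res <- scan_tl_snp(ds, "dominant", adjust_covariates = FALSE)
  g <- as.numeric(ds$geno[1, ] > 0)
  slope <- cov(ds$phenotype, g) / var(g)
  expect_equal(res$beta, slope, tolerance = 1e-10)

  res_add <- scan_tl_snp(ds, "additive", adjust_covariates = FALSE)
  slope_add <- cov(ds$phenotype, as.numeric(ds$geno[1, ])) /
    var(as.numeric(ds$geno[1, ]))
  expect_equal(res_add$beta, slope_add, tolerance = 1e-10)
})

test_that("dominant and additive codings coincide up to factor 2 without heterozygotes", {
  set.seed(33)
  ds <- toy_pair_dataset(n = 200, maf = 0.3, c_dom = 0.2)
  ds$geno[1, ] <- ifelse(ds$geno[1, ] > 0, 2L, 0L)   # dosage in {0, 2}
  dom <- scan_tl_snp(ds, "dominant", adjust_covariates = FALSE)
  add <- scan_tl_snp(ds, "additive", adjust_covariates = FALSE)
  expect_equal(dom$beta, 2 * add$beta, tolerance = 1e-10)
  expect_equal(dom$p, add$p, tolerance = 1e-10)
})

test_that("a constant coded genotype is reported untestable", {
  set.seed(34)
  ds <- toy_pair_dataset(n = 100)
  ds$geno[1, ] <- 0L
  res <- scan_tl_snp(ds, "dominant", adjust_covariates = FALSE)
  expect_true(res$untestable)
  expect_true(is.na(res$beta))
})

test_that("under the null the SNP-telomere scan rejects at the nominal rate", {
  set.seed(35)
  hits <- replicate(400, {
    ds <- toy_pair_dataset(n = 100)
    scan_tl_snp(ds, "dominant", adjust_covariates = FALSE)$significant
  })
  rate <- mean(hits)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("the mQTL scan without moderation reproduces per-pair OLS exactly", {
  set.seed(36)
  sim <- simulate_study(simulation_config(
    n_samples = 120, snp_spec = default_snp_spec()[1:3, ],
    cpg_spec = default_cpg_spec(default_snp_spec()[1:3, ], 4),
    include_cells = FALSE, n_batches = 1L, missing_rate_geno = 0,
    missing_rate_meth = 0, seed = 37))
  ds <- sim$dataset
  scan <- scan_mqtl(ds, codings = "additive", moderate = FALSE,
                    adjust_covariates = FALSE)
  r <- scan$results
  for (i in seq_len(nrow(r))) {
    x <- as.numeric(ds$geno[r$snp_id[i], ])
    y <- ds$meth[r$cpg_id[i], ]
    f <- fit_ols(cbind("(Intercept)" = 1, snp = x), y)
    expect_equal(r$beta[i], unname(f$coefficients["snp"]), tolerance = 1e-10)
    expect_equal(r$p[i], unname(f$p["snp"]), tolerance = 1e-10)
  }
  # window-edge pairs are part of the tested universe
  expect_equal(scan$m, nrow(enumerate_cis_pairs(ds$snp_info, ds$cpg_info,
                                                500000L)))
})

test_that("an injected cis-mQTL is detected and requires both codings by default", {
  spec <- default_snp_spec()[1:2, ]
  spec$maf <- c(0.3, 0.25)
  cpg <- default_cpg_spec(spec, 6)
  cfg <- simulation_config(
    n_samples = 500, snp_spec = spec, cpg_spec = cpg,
    mqtl_effects = data.frame(snp_id = spec$id[1], cpg_id = cpg$id[1],
                              beta = 0.5),
    include_cells = FALSE, n_batches = 1L, missing_rate_geno = 0,
    missing_rate_meth = 0, seed = 38)
  sim <- simulate_study(cfg)
  scan <- scan_mqtl(sim$dataset, adjust_covariates = FALSE)
  expect_true(any(scan$significant_pairs$snp_id == spec$id[1] &
                    scan$significant_pairs$cpg_id == cpg$id[1]))
  # the significant set is the intersection of the per-coding flag sets
  r <- scan$results
  key <- paste(r$snp_id, r$cpg_id)
  both <- intersect(key[r$coding == "dominant" & r$bonferroni_significant],
                    key[r$coding == "additive" & r$bonferroni_significant])
  expect_setequal(paste(scan$significant_pairs$snp_id,
                        scan$significant_pairs$cpg_id), both)
})

test_that("replication lookup classifies concordant, discordant and novel pairs", {
  sig <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                    cpg_id = c("cgA", "cgB", "cgC"),
                    beta = c(0.5, -0.4, 0.2))
  ref <- data.frame(snp_id = c("rs1", "rs2"), cpg_id = c("cgA", "cgB"),
                    beta = c(0.3, 0.6))
  out <- compare_to_reference(sig, ref)
  st <- setNames(out$table$status, out$table$snp_id)
  expect_identical(unname(st["rs1"]), "replicated_concordant")
  expect_identical(unname(st["rs2"]), "replicated_discordant")
  expect_identical(unname(st["rs3"]), "novel")
  expect_equal(unname(out$summary), c(1L, 1L, 1L))

  out_empty <- compare_to_reference(sig, NULL)
  expect_true(all(out_empty$table$status == "novel"))
})

test_that("mQTL-significant pairs are excluded from the interaction universe", {
  set.seed(39)
  sim <- simulate_study(simulation_config(
    n_samples = 150, snp_spec = default_snp_spec()[1:2, ],
    cpg_spec = default_cpg_spec(default_snp_spec()[1:2, ], 4),
    include_cells = FALSE, n_batches = 1L, missing_rate_geno = 0,
    missing_rate_meth = 0, seed = 40))
  ds <- sim$dataset
  excl <- data.frame(snp_id = ds$snp_info$id[1],
                     cpg_id = ds$cpg_info$id[1])
  ia <- scan_interaction(ds, excl, adjust_covariates = FALSE)
  expect_false(any(ia$results$snp_id == excl$snp_id &
                     ia$results$cpg_id == excl$cpg_id))
  all_pairs <- enumerate_cis_pairs(ds$snp_info, ds$cpg_info, 500000L)
  expect_equal(ia$m, nrow(all_pairs) - 1L)
})

test_that("under the null the interaction test rejects at the nominal rate", {
  set.seed(41)
  pv <- replicate(2000, {
    ds <- toy_pair_dataset(n = 200)
    scan_interaction(ds, adjust_covariates = FALSE)$results$p12
  })
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("mQTL detection power is monotone in effect size", {
  set.seed(42)
  spec <- default_snp_spec()[1, ]; spec$maf <- 0.3
  cpg <- default_cpg_spec(spec, 2)
  hit_rate <- vapply(c(0.1, 0.25, 0.5), function(b) {
    hits <- vapply(1:30, function(r) {
      cfg <- simulation_config(
        n_samples = 150, snp_spec = spec, cpg_spec = cpg,
        mqtl_effects = data.frame(snp_id = spec$id, cpg_id = cpg$id[1],
                                  beta = b),
        include_cells = FALSE, n_batches = 1L, missing_rate_geno = 0,
        missing_rate_meth = 0, sigma_cpg = 0.5,
        seed = 1000 + r + round(b * 10000))
      sim <- simulate_study(cfg)
      scan <- scan_mqtl(sim$dataset, codings = "additive", rule = "either",
                        adjust_covariates = FALSE)
      nrow(scan$significant_pairs) > 0 &&
        any(scan$significant_pairs$cpg_id == cpg$id[1])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(hit_rate) >= -0.1))
  expect_gt(hit_rate[3], hit_rate[1])
})
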