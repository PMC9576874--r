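test_that("mediation point estimates follow the product decomposition exactly", {
  # exact-fit construction: the mediator's residual variation is made
  # orthogonal to the SNP so both model fits are exact:
  # M = 0.5 dom + e (e _|_ dom), TL = 0.1 dom + 0.4 M
  set.seed(51)
  ds <- toy_pair_dataset(n = 200, maf = 0.3, tl_sd = 0)
  dom <- as.numeric(ds$geno[1, ] > 0)
  e <- stats::resid(stats::lm(rnorm(200) ~ dom))
  ds$meth[1, ] <- 0.5 * dom + e
  ds$phenotype <- 0.1 * dom + 0.4 * ds$meth[1, ]
  est <- fit_mediation(ds, "rs1", "cg00000001", adjust_covariates = FALSE)
  expect_equal(unname(est["a"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(est["b"]), 0.4, tolerance = 1e-10)
  expect_equal(unname(est["de"]), 0.1, tolerance = 1e-10)
  expect_equal(unname(est["ie"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(est["te"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(est["prop_mediated"]), 2 / 3, tolerance = 1e-10)

  # null mediator path: b = 0 means ie = 0 and te = de
  ds2 <- toy_pair_dataset(n = 300, maf = 0.3, a = 0.6, sd_m = 1, tl_sd = 0)
  dom2 <- as.numeric(ds2$geno[1, ] > 0)
  ds2$phenotype <- 1 + 0.25 * dom2
  est2 <- fit_mediation(ds2, "rs1", "cg00000001", adjust_covariates = FALSE)
  expect_equal(unname(est2["ie"]), 0, tolerance = 1e-10)
  expect_equal(unname(est2["te"]), unname(est2["de"]), tolerance = 1e-10)

  # opposite-sign effects leave the proportion mediated undefined
  ds3 <- toy_pair_dataset(n = 200, maf = 0.3, tl_sd = 0)
  dom3 <- as.numeric(ds3$geno[1, ] > 0)
  e3 <- stats::resid(stats::lm(rnorm(200) ~ dom3))
  ds3$meth[1, ] <- 0.5 * dom3 + e3
  ds3$phenotype <- -0.1 * dom3 + 0.2 * ds3$meth[1, ]   # de = -0.1, ie = +0.1
  est3 <- fit_mediation(ds3, "rs1", "cg00000001", adjust_covariates = FALSE)
  expect_lt(unname(est3["de"]), 0)
  expect_gt(unname(est3["ie"]), 0)
  expect_true(is.na(est3["prop_mediated"]))
})

test_that("product-method IE equals difference-method IE on random fixtures", {
  set.seed(52)
  for (trial in 1:50) {
    ds <- toy_pair_dataset(n = 150, maf = runif(1, 0.2, 0.4),
                           a = rnorm(1, 0, 0.5), b = rnorm(1, 0, 0.3),
                           c_dom = rnorm(1, 0, 0.2))
    est <- fit_mediation(ds, "rs1", "cg00000001", adjust_covariates = FALSE)
    dom <- as.numeric(ds$geno[1, ] > 0)
    total_fit <- fit_ols(cbind("(Intercept)" = 1, snp = dom), ds$phenotype)
    ie_diff <- unname(total_fit$coefficients["snp"]) - unname(est["de"])
    expect_equal(unname(est["ie"]), ie_diff, tolerance = 1e-10)
    expect_equal(unname(est["te"]), unname(est["de"] + est["ie"]),
                 tolerance = 1e-12)
  }
})

test_that("candidate selection keeps only nominally telomere-associated CpGs", {
  expect_equal(nrow(select_candidates(
    data.frame(snp_id = character(), cpg_id = character()),
    toy_pair_dataset(50))), 0)

  set.seed(53)
  # cg linked to TL (b = 0.3) -> candidate; null cg -> excluded
  ds <- toy_pair_dataset(n = 400, maf = 0.3, a = 0.8, b = 0.3)
  null_cpg <- matrix(rnorm(400), nrow = 1,
                     dimnames = list("cg00000002", colnames(ds$meth)))
  ds$meth <- rbind(ds$meth, null_cpg)
  ds$cpg_info <- rbind(ds$cpg_info,
                       data.frame(id = "cg00000002", chrom = "chr1",
                                  pos = 1020000L))
  sig <- data.frame(snp_id = c("rs1", "rs1"),
                    cpg_id = c("cg00000001", "cg00000002"))
  cand <- select_candidates(sig, ds, adjust_covariates = FALSE)
  expect_true("cg00000001" %in% cand$cpg_id)
  expect_false("cg00000002" %in% cand$cpg_id)
})

test_that("bootstrap inference is seed-deterministic and respects the decomposition per replicate", {
  set.seed(54)
  ds <- toy_pair_dataset(n = 250, maf = 0.3, a = 0.8, b = 0.25, c_dom = 0.1)
  r1 <- bootstrap_mediation(ds, "rs1", "cg00000001", n_boot = 200,
                            seed = 99, adjust_covariates = FALSE)
  r2 <- bootstrap_mediation(ds, "rs1", "cg00000001", n_boot = 200,
                            seed = 99, adjust_covariates = FALSE)
  expect_identical(r1$ci, r2$ci)
  expect_identical(r1$boot_p, r2$boot_p)
  # the identity te = de + ie holds inside every bootstrap replicate
  expect_equal(r1$boot[, "te"], r1$boot[, "de"] + r1$boot[, "ie"],
               tolerance = 1e-12)
  # the proportion mediated is populated only for same-sign replicates
  same <- !is.na(r1$boot[, "prop_mediated"])
  expect_identical(same, sign(r1$boot[, "de"]) == sign(r1$boot[, "ie"]))
  expect_identical(r1$n_same_sign, sum(same))
  expect_true(all(r1$ci[, "lower"] <= r1$ci[, "upper"]))
})

test_that("sparse resamples trip the degeneracy guard", {
  set.seed(55)
  ds <- toy_pair_dataset(n = 30, maf = 0.3)
  ds$geno[1, ] <- c(1L, rep(0L, 29))   # single carrier
  expect_error(
    bootstrap_mediation(ds, "rs1", "cg00000001", n_boot = 100, seed = 1,
                        adjust_covariates = FALSE),
    "degenerate")
})

test_that("the end-to-end wrapper recovers an injected mediation path", {
  spec <- default_snp_spec()[1, ]; spec$maf <- 0.3
  cpg <- default_cpg_spec(spec, 3)
  cfg <- simulation_config(
    n_samples = 400, snp_spec = spec, cpg_spec = cpg,
    mediation_paths = data.frame(snp_id = spec$id, cpg_id = cpg$id[1],
                                 a = 0.9, b = 0.25, c_prime = 0.05),
    include_cells = FALSE, n_batches = 1L, missing_rate_geno = 0,
    missing_rate_meth = 0, sigma_cpg = 0.3, seed = 56)
  sim <- simulate_study(cfg)
  res <- run_analysis(sim$dataset, analysis_config(n_boot = 200),
                      adjust_covariates = FALSE)
  expect_true(nrow(res$candidates) >= 1)
  key <- paste(res$candidates$snp_id, res$candidates$cpg_id)
  expect_true(paste(spec$id, cpg$id[1]) %in% key)
  mr <- res$mediation[[paste(spec$id, cpg$id[1], sep = "-")]]
  expect_s3_class(mr, "mediation_result")
  expect_lt(mr$boot_p[["ie"]], 0.05)
  # the mediated pair is excluded from the interaction universe
  expect_false(any(res$interaction$results$snp_id == spec$id &
                     res$interaction$results$cpg_id == cpg$id[1]))
})
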