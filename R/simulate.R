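# Synthetic cohort generator. Emulates the study's data structure -- a few
# dozen candidate SNPs under HWE, cis CpG methylation with mQTL effects,
# seven-component cord-blood cell mixtures, batch/position technical
# effects, detection failures and missingness, ten covariates drawn to the
# reference cohort margins, and a T/S-ratio telomere phenotype with
# direct, CpG-mediated and SNP-x-CpG interaction effects -- with every
# generative parameter retained as ground truth.

#' Default candidate SNP panel
#'
#' The 26 ageing/telomere-length candidate SNPs of the study design, with
#' their genomic positions and major/minor alleles. Minor-allele
#' frequencies are synthetic defaults (the study's observed frequencies
#' are deposited externally and not bundled): a fixed, documented spread
#' over (0.1, 0.5).
#'
#' @return Data frame `id`, `chrom`, `pos`, `major`, `minor`, `maf`.
#' @export
default_snp_spec <- function() {
  spec <- data.frame(
    id = c("rs1475398", "rs1343981", "rs10493379", "rs6669117", "rs4452212",
           "rs10496799", "rs11125529", "rs10936599", "rs16847897", "rs40184",
           "rs2841505", "rs911847", "rs3757354", "rs2371208", "rs9419958",
           "rs9420907", "rs511744", "rs17653722", "rs4764600", "rs4570625",
           "rs1386494", "rs2535913", "rs3027234", "rs412658", "rs107251",
           "rs755017"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2",
              "chr3", "chr3", "chr5", "chr6", "chr6", "chr6", "chr7",
              "chr10", "chr10", "chr11", "chr12", "chr12", "chr12",
              "chr12", "chr14", "chr17", "chr19", "chr19", "chr20"),
    pos = c(65517574L, 65579645L, 65580244L, 65595389L, 136258421L,
            139261401L, 54248729L, 169774313L, 169850328L, 1394962L,
            13571363L, 159647936L, 16235386L, 82708543L, 103916188L,
            103916707L, 219089L, 52193734L, 6492814L, 71938143L,
            71958763L, 72948525L, 8232774L, 22176638L, 4176088L,
            63790269L),
    major = c("G", "A", "G", "T", "G", "T", "C", "C", "G", "C", "T", "G",
              "C", "G", "C", "A", "C", "G", "C", "G", "C", "G", "C", "C",
              "C", "A"),
    minor = c("C", "G", "A", "C", "A", "C", "A", "T", "C", "T", "G", "A",
              "T", "T", "T", "C", "T", "T", "G", "T", "T", "A", "T", "T",
              "T", "G")
  )
  spec$maf <- rep(c(0.12, 0.22, 0.31, 0.38, 0.45, 0.27, 0.18, 0.34,
                    0.41, 0.25, 0.15, 0.29, 0.36, 0.47, 0.20, 0.33,
                    0.43, 0.13, 0.26, 0.39, 0.17, 0.30, 0.44, 0.21,
                    0.35, 0.28), length.out = nrow(spec))
  spec
}

#' Default CpG panel in cis of a SNP panel
#'
#' Places `n_per_snp` CpG probes at fixed offsets inside the +/-`window_bp`
#' neighbourhood of each SNP, with sequential cg-prefixed IDs.
#'
#' @param snp_spec SNP specification data frame (`id`, `chrom`, `pos`).
#' @param n_per_snp probes per SNP (default 8).
#' @param window_bp cis half-window in bp (default 500,000).
#' @return Data frame `id`, `chrom`, `pos`.
#' @export
default_cpg_spec <- function(snp_spec, n_per_snp = 8L,
                             window_bp = 500000L) {
  offs <- round(seq(-0.9, 0.9, length.out = n_per_snp) * window_bp)
  rows <- do.call(rbind, lapply(seq_len(nrow(snp_spec)), function(i) {
    data.frame(chrom = snp_spec$chrom[i],
               pos = pmax(1L, snp_spec$pos[i] + offs))
  }))
  rows <- rows[!duplicated(rows[, c("chrom", "pos")]), ]
  data.frame(id = sprintf("cg%08d", seq_len(nrow(rows))),
             chrom = rows$chrom, pos = rows$pos)
}

#' Simulation configuration
#'
#' Defines a synthetic cohort: sample size, SNP/CpG panels, generative
#' mQTL effects, mediation paths (a: SNP to CpG in M-units per minor
#' allele; b: CpG to telomere length in T/S per M-unit; c': direct SNP
#' effect in T/S per allele), SNP-x-CpG interaction coefficients, the
#' telomere baseline (T/S 1.03 +/- 0.20), a seven-component Dirichlet cell
#' mixture, batch/position technical effects, detection failures and
#' missingness.
#'
#' @param n_samples cohort size (default 281).
#' @param snp_spec data frame `id`, `chrom`, `pos`, `major`, `minor`,
#'   `maf` (maf in (0, 0.5]).
#' @param cpg_spec data frame `id`, `chrom`, `pos`.
#' @param mqtl_effects data frame `snp_id`, `cpg_id`, `beta` (M-value per
#'   minor allele); pairs must lie within the cis window.
#' @param mediation_paths data frame `snp_id`, `cpg_id`, `a`, `b`,
#'   `c_prime`.
#' @param interaction_terms data frame `snp_id`, `cpg_id`, `beta12` (T/S
#'   per allele x M-unit).
#' @param covariate_effects optional named numeric vector of telomere
#'   coefficients on numeric covariate columns (default none: covariates
#'   carry no signal so the marginal T/S calibration holds).
#' @param tl_mean,tl_sd telomere baseline mean and residual SD (T/S).
#' @param cell_dirichlet_alpha 7 Dirichlet concentrations (cord-blood-like
#'   mixture, granulocyte-dominated).
#' @param sigma_cpg per-CpG residual SD on the M scale.
#' @param n_batches,n_positions technical factor sizes (1 disables).
#' @param batch_shift_sd,batch_scale_sd SDs of the per-(probe, level)
#'   location shift and log scale factor.
#' @param detection_fail_rate probability a call fails detection.
#' @param missing_rate_geno,missing_rate_meth missingness rates in [0, 1).
#' @param include_cells when `FALSE`, methylation is generated without the
#'   cell-mixture component (pure effect + noise; covariate cell columns
#'   are then constant 1/7).
#' @param n_ref_probes deconvolution reference probes (>= 14 for
#'   identifiability of 7 cell types).
#' @param cis_window_bp cis window used to validate effect pairs.
#' @param seed integer seed.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 281L,
                              snp_spec = default_snp_spec(),
                              cpg_spec = default_cpg_spec(snp_spec),
                              mqtl_effects = NULL,
                              mediation_paths = NULL,
                              interaction_terms = NULL,
                              covariate_effects = NULL,
                              tl_mean = 1.03,
                              tl_sd = 0.20,
                              cell_dirichlet_alpha = c(
                                nRBC = 1.8, Gran = 16.5, Mono = 2.4,
                                NK = 0.9, Bcell = 1.5, CD4T = 4.5,
                                CD8T = 2.4),
                              sigma_cpg = 0.2,
                              n_batches = 2L,
                              n_positions = 8L,
                              batch_shift_sd = 0.2,
                              batch_scale_sd = 0.1,
                              detection_fail_rate = 0.002,
                              missing_rate_geno = 0.02,
                              missing_rate_meth = 0.01,
                              include_cells = TRUE,
                              n_ref_probes = 98L,
                              cis_window_bp = 500000L,
                              seed = 1L) {
  stopifnot(
    n_samples >= 2,
    all(snp_spec$maf > 0), all(snp_spec$maf <= 0.5),
    !anyDuplicated(snp_spec$id), !anyDuplicated(cpg_spec$id),
    tl_sd > 0, sigma_cpg >= 0,
    length(cell_dirichlet_alpha) == 7, all(cell_dirichlet_alpha > 0),
    n_batches >= 1, n_positions >= 1,
    missing_rate_geno >= 0, missing_rate_geno < 1,
    missing_rate_meth >= 0, missing_rate_meth < 1,
    detection_fail_rate >= 0, detection_fail_rate < 1
  )
  check_pairs <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    if (!all(df$snp_id %in% snp_spec$id)) stop(what, ": unknown SNP ID")
    if (!all(df$cpg_id %in% cpg_spec$id)) stop(what, ": unknown CpG ID")
    si <- match(df$snp_id, snp_spec$id)
    ci <- match(df$cpg_id, cpg_spec$id)
    same <- snp_spec$chrom[si] == cpg_spec$chrom[ci]
    dist <- abs(cpg_spec$pos[ci] - snp_spec$pos[si])
    bad <- !same | dist > cis_window_bp
    if (any(bad)) {
      stop(what, ": pair(s) outside the cis window: ",
           paste(df$snp_id[bad], df$cpg_id[bad], sep = "-", collapse = ", "))
    }
  }
  check_pairs(mqtl_effects, "mqtl_effects")
  check_pairs(mediation_paths, "mediation_paths")
  check_pairs(interaction_terms, "interaction_terms")
  structure(list(
    n_samples = as.integer(n_samples), snp_spec = snp_spec,
    cpg_spec = cpg_spec, mqtl_effects = mqtl_effects,
    mediation_paths = mediation_paths,
    interaction_terms = interaction_terms,
    covariate_effects = covariate_effects,
    tl_mean = tl_mean, tl_sd = tl_sd,
    cell_dirichlet_alpha = cell_dirichlet_alpha, sigma_cpg = sigma_cpg,
    n_batches = as.integer(n_batches), n_positions = as.integer(n_positions),
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    detection_fail_rate = detection_fail_rate,
    missing_rate_geno = missing_rate_geno,
    missing_rate_meth = missing_rate_meth,
    include_cells = isTRUE(include_cells),
    n_ref_probes = as.integer(n_ref_probes),
    cis_window_bp = as.integer(cis_window_bp),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Derive per-stage seeds from the config seed; NA means "draw from the
# ambient RNG stream" (callers seed one stream for a whole experiment).
.sub_seed <- function(seed, k) {
  if (is.na(seed)) return(NA_integer_)
  (as.integer(seed) + 104729L * k) %% 2147483587L
}

.with_seed_maybe <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) code else withr::with_seed(seed, code)
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, dosages are i.i.d. Binomial(2, maf) draws (HWE by
#' construction, so downstream HWE filtering is calibrated); missing calls
#' are masked uniformly at random at `missing_rate_geno`.
#'
#' @param cfg a [simulation_config()].
#' @param seed seed (default derived from `cfg$seed`).
#' @return List with `geno` (observed dosage matrix, `NA` where masked),
#'   `info` (SNP table with observed `maf`) and `true_geno` (pre-masking
#'   dosages, ground truth).
#' @export
simulate_genotypes <- function(cfg, seed = .sub_seed(cfg$seed, 1L)) {
  .with_seed_maybe(seed, {
    n <- cfg$n_samples
    spec <- cfg$snp_spec
    true <- t(vapply(spec$maf, function(m) rbinom(n, 2L, m),
                     integer(n)))
    dimnames(true) <- list(spec$id, sprintf("S%04d", seq_len(n)))
    geno <- true
    if (cfg$missing_rate_geno > 0) {
      mask <- matrix(runif(length(geno)) < cfg$missing_rate_geno,
                     nrow = nrow(geno))
      geno[mask] <- NA_integer_
    }
    out <- .orient_minor(geno, spec[, c("id", "chrom", "pos", "major", "minor")])
    list(geno = out$geno, info = out$info, true_geno = true)
  })
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Simulate cord-blood methylation with cell mixtures and mQTL effects
#'
#' Per sample, true cell proportions are Dirichlet draws; each probe's
#' latent M-value is its cell-type reference row times the sample's
#' proportions, plus any generative mQTL / mediation `a` effects times the
#' true dosage, plus Gaussian noise. Dedicated reference probes with
#' well-separated cell-specific means (a synthetic reference, not a
#' published one) are appended for deconvolution. Batch and position add
#' per-(probe, level) location shifts and scale factors; a detection-p
#' matrix marks simulated call failures; observed values are masked at
#' `missing_rate_meth`.
#'
#' @param cfg a [simulation_config()].
#' @param geno result of [simulate_genotypes()] (uses `true_geno`).
#' @param seed seed (default derived from `cfg$seed`).
#' @return List with `meth` (observed M-values incl. reference probes),
#'   `cpg_info`, `reference` (probe x cell-type reference means, or `NULL`
#'   when `include_cells = FALSE`), `detection_p`, `batch` (data frame
#'   `sample_id`, `batch`, `position`) and `truth` (cell proportions `W`,
#'   latent pre-batch complete matrix `m_latent`, per-probe cell means).
#' @export
simulate_methylation <- function(cfg, geno,
                                 seed = .sub_seed(cfg$seed, 2L)) {
  .with_seed_maybe(seed, {
    n <- cfg$n_samples
    samples <- colnames(geno$true_geno)
    cpg <- cfg$cpg_spec
    n_cpg <- nrow(cpg)

    if (cfg$include_cells) {
      W <- .rdirichlet(n, cfg$cell_dirichlet_alpha)
      colnames(W) <- cell_types()
      rownames(W) <- samples
      base <- rnorm(n_cpg, 0, 1.5)
      cell_means <- base + matrix(rnorm(n_cpg * 7, 0, 0.15), n_cpg, 7)
      n_ref <- cfg$n_ref_probes
      ref_type <- rep_len(seq_len(7), n_ref)
      ref_means <- matrix(-2, n_ref, 7) + matrix(rnorm(n_ref * 7, 0, 0.1),
                                                 n_ref, 7)
      ref_means[cbind(seq_len(n_ref), ref_type)] <-
        2 + rnorm(n_ref, 0, 0.1)
      all_means <- rbind(cell_means, ref_means)
      ids <- c(cpg$id, sprintf("refcg%05d", seq_len(n_ref)))
      info <- rbind(cpg,
                    data.frame(id = ids[-seq_len(n_cpg)], chrom = "chrR",
                               pos = seq_len(n_ref)))
      m_latent <- all_means %*% t(W)
      reference <- all_means[-seq_len(n_cpg), , drop = FALSE]
      dimnames(reference) <- list(ids[-seq_len(n_cpg)], cell_types())
    } else {
      W <- matrix(1 / 7, n, 7, dimnames = list(samples, cell_types()))
      all_means <- NULL
      ids <- cpg$id
      info <- cpg
      m_latent <- matrix(0, n_cpg, n)
      reference <- NULL
    }
    dimnames(m_latent) <- list(ids, samples)
    colnames(info) <- c("id", "chrom", "pos")

    eff <- rbind(
      if (!is.null(cfg$mqtl_effects) && nrow(cfg$mqtl_effects) > 0) {
        data.frame(snp_id = cfg$mqtl_effects$snp_id,
                   cpg_id = cfg$mqtl_effects$cpg_id,
                   beta = cfg$mqtl_effects$beta)
      },
      if (!is.null(cfg$mediation_paths) && nrow(cfg$mediation_paths) > 0) {
        data.frame(snp_id = cfg$mediation_paths$snp_id,
                   cpg_id = cfg$mediation_paths$cpg_id,
                   beta = cfg$mediation_paths$a)
      }
    )
    if (!is.null(eff) && nrow(eff) > 0) {
      for (i in seq_len(nrow(eff))) {
        m_latent[eff$cpg_id[i], ] <- m_latent[eff$cpg_id[i], ] +
          eff$beta[i] * geno$true_geno[eff$snp_id[i], ]
      }
    }
    if (cfg$sigma_cpg > 0) {
      m_latent <- m_latent + matrix(rnorm(length(m_latent), 0, cfg$sigma_cpg),
                                    nrow = nrow(m_latent))
    }

    batch <- sample(rep_len(seq_len(cfg$n_batches), n))
    position <- sample(rep_len(seq_len(cfg$n_positions), n))
    m_obs <- m_latent
    add_factor_effect <- function(m, f, shift_sd, scale_sd) {
      if (length(unique(f)) < 2 || (shift_sd == 0 && scale_sd == 0)) return(m)
      alpha <- rowMeans(m)
      for (lev in unique(f)) {
        idx <- which(f == lev)
        gam <- rnorm(nrow(m), 0, shift_sd)
        del <- exp(rnorm(nrow(m), 0, scale_sd))
        m[, idx] <- alpha + del * (m[, idx, drop = FALSE] - alpha) + gam
      }
      m
    }
    m_obs <- add_factor_effect(m_obs, batch, cfg$batch_shift_sd,
                               cfg$batch_scale_sd)
    m_obs <- add_factor_effect(m_obs, position, cfg$batch_shift_sd / 2,
                               cfg$batch_scale_sd / 2)

    detp <- matrix(runif(length(m_obs), 0, 1e-20), nrow = nrow(m_obs),
                   dimnames = dimnames(m_obs))
    if (cfg$detection_fail_rate > 0) {
      fail <- matrix(runif(length(detp)) < cfg$detection_fail_rate,
                     nrow = nrow(detp))
      detp[fail] <- 0.5
    }
    if (cfg$missing_rate_meth > 0) {
      mask <- matrix(runif(length(m_obs)) < cfg$missing_rate_meth,
                     nrow = nrow(m_obs))
      m_obs[mask] <- NA_real_
    }

    list(meth = m_obs, cpg_info = info, reference = reference,
         detection_p = detp,
         batch = data.frame(sample_id = samples, batch = batch,
                            position = position),
         truth = list(W = W, m_latent = m_latent, cell_means = all_means))
  })
}

#' Simulate covariates from the reference cohort margins
#'
#' Draws the ten study covariates independently from the marginal
#' distributions of the reference cohort (binary and multinomial
#' categorical draws at the printed frequencies; Gaussian draws at the
#' printed mean/SD). Joint dependence between covariates is not modelled.
#' Cell-proportion columns are taken from the supplied mixture matrix.
#'
#' @param cfg a [simulation_config()].
#' @param W cell-proportion matrix (samples x 7).
#' @param seed seed (default derived from `cfg$seed`).
#' @return Covariate data frame (rownames = sample IDs).
#' @export
simulate_covariates <- function(cfg, W, seed = .sub_seed(cfg$seed, 3L)) {
  .with_seed_maybe(seed, {
    n <- cfg$n_samples
    mg <- cohort_margins()
    num <- mg$numeric
    getn <- function(v) {
      i <- match(v, num$variable)
      rnorm(n, num$mean[i], num$sd[i])
    }
    rcat <- function(counts, levels) {
      factor(sample(levels, n, replace = TRUE, prob = counts / sum(counts)),
             levels = levels)
    }
    lv <- .covariate_levels()
    covs <- data.frame(
      sex = rbinom(n, 1, mg$counts$sex[["male"]] / mg$n),
      gestational_age = getn("gestational_age"),
      ethnicity = rbinom(n, 1, mg$counts$ethnicity[["non_European"]] / mg$n),
      birth_weight = getn("birth_weight"),
      pregnancy_complications =
        rbinom(n, 1, mg$counts$pregnancy_complications[["yes"]] / mg$n),
      pre_pregnancy_bmi = getn("pre_pregnancy_bmi"),
      parity = rcat(mg$counts$parity, lv$parity),
      education = rcat(mg$counts$education, lv$education),
      smoking = rcat(mg$counts$smoking, lv$smoking),
      paternal_age = getn("paternal_age")
    )
    cells <- as.data.frame(W)
    names(cells) <- .cell_cols()
    covs <- cbind(covs, cells)
    rownames(covs) <- rownames(W)
    covs
  })
}

#' Simulate the telomere phenotype
#'
#' Realizes the structural model: T/S = baseline + direct SNP effects
#' (c' x dosage) + CpG effects (b x latent M) + interaction effects
#' (beta12 x dosage x latent M) + optional covariate effects + Gaussian
#' noise with SD `tl_sd`. Mediation paths contribute through their `a`
#' effects (already embedded in the methylation) and their `b`/`c_prime`
#' here, so each path's true total effect is c' + a*b.
#'
#' @param cfg a [simulation_config()].
#' @param geno result of [simulate_genotypes()].
#' @param meth result of [simulate_methylation()] (uses latent M-values).
#' @param covariates covariate data frame (only used when
#'   `cfg$covariate_effects` is set).
#' @param seed seed (default derived from `cfg$seed`).
#' @return List with `tl` (named numeric vector) and `truth` (per-path
#'   true direct/indirect/total effects).
#' @export
simulate_phenotype <- function(cfg, geno, meth, covariates = NULL,
                               seed = .sub_seed(cfg$seed, 4L)) {
  .with_seed_maybe(seed, {
    n <- cfg$n_samples
    tl <- rep(cfg$tl_mean, n)
    dose <- geno$true_geno
    M <- meth$truth$m_latent
    paths <- cfg$mediation_paths
    if (!is.null(paths) && nrow(paths) > 0) {
      for (i in seq_len(nrow(paths))) {
        tl <- tl + paths$c_prime[i] * dose[paths$snp_id[i], ] +
          paths$b[i] * M[paths$cpg_id[i], ]
      }
    }
    ia <- cfg$interaction_terms
    if (!is.null(ia) && nrow(ia) > 0) {
      for (i in seq_len(nrow(ia))) {
        tl <- tl + ia$beta12[i] * dose[ia$snp_id[i], ] * M[ia$cpg_id[i], ]
      }
    }
    ce <- cfg$covariate_effects
    if (!is.null(ce) && length(ce) > 0) {
      stopifnot(!is.null(covariates), all(names(ce) %in% names(covariates)))
      for (nm in names(ce)) {
        tl <- tl + ce[[nm]] * as.numeric(covariates[[nm]])
      }
    }
    tl <- tl + rnorm(n, 0, cfg$tl_sd)
    names(tl) <- colnames(dose)
    truth <- NULL
    if (!is.null(paths) && nrow(paths) > 0) {
      truth <- data.frame(snp_id = paths$snp_id, cpg_id = paths$cpg_id,
                          a = paths$a, b = paths$b, de = paths$c_prime,
                          ie = paths$a * paths$b,
                          te = paths$c_prime + paths$a * paths$b)
    }
    list(tl = tl, truth = truth)
  })
}

#' Simulate a complete study
#'
#' Runs the full generator chain (genotypes, methylation, covariates,
#' phenotype) under one seed and, when `out_dir` is given, writes the
#' bundle in all standard formats (genotype TSV and VCF, methylation and
#' detection-p TSV, BED manifests, covariate/phenotype TSV, cell
#' reference TSV, batch table, ground truth JSON).
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional output directory (created if needed).
#' @return List with `dataset` (a [study_dataset()]), `truth` (ground
#'   truth list), `reference`, `detection_p`, `batch` and, when written,
#'   `paths`.
#' @examples
#' sim <- simulate_study(simulation_config(n_samples = 50, seed = 7))
#' length(validate_dataset(sim$dataset)) == 0
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  geno <- simulate_genotypes(cfg)
  meth <- simulate_methylation(cfg, geno)
  covs <- simulate_covariates(cfg, meth$truth$W)
  phen <- simulate_phenotype(cfg, geno, meth, covs)

  ds <- study_dataset(
    geno = geno$geno, snp_info = geno$info,
    meth = meth$meth, cpg_info = meth$cpg_info,
    covariates = covs, phenotype = phen$tl,
    sample_ids = colnames(geno$geno)
  )
  truth <- list(
    seed = cfg$seed,
    true_geno = geno$true_geno,
    cell_proportions = meth$truth$W,
    m_latent = meth$truth$m_latent,
    mqtl_effects = cfg$mqtl_effects,
    mediation = phen$truth,
    interaction_terms = cfg$interaction_terms,
    tl_mean = cfg$tl_mean, tl_sd = cfg$tl_sd
  )
  out <- list(dataset = ds, truth = truth, reference = meth$reference,
              detection_p = meth$detection_p, batch = meth$batch)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_genotypes(list(geno = geno$geno, info = geno$info), p("genotypes.tsv"))
    write_genotypes_vcf(list(geno = geno$geno, info = geno$info),
                        p("genotypes.vcf"))
    write_methylation(meth$meth, p("methylation.tsv"))
    write_methylation(meth$detection_p, p("detection_p.tsv"))
    write_manifest(geno$info[, c("id", "chrom", "pos")], p("snp_manifest.bed"))
    write_manifest(meth$cpg_info, p("cpg_manifest.bed"))
    write_covariates(covs, p("covariates.tsv"))
    write_phenotype(phen$tl, p("phenotype.tsv"))
    if (!is.null(meth$reference)) {
      write_methylation(meth$reference, p("cell_reference.tsv"))
    }
    write.table(meth$batch, p("batch.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(truth, p("truth.json"), digits = NA,
                         auto_unbox = TRUE, matrix = "rowmajor")
    out$paths <- p(c("genotypes.tsv", "genotypes.vcf", "methylation.tsv",
                     "detection_p.tsv", "snp_manifest.bed",
                     "cpg_manifest.bed", "covariates.tsv", "phenotype.tsv",
                     "batch.tsv", "truth.json"))
  }
  out
}
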