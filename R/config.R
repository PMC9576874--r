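#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one flat object.
#' Defaults are the study-design values: a +/-0.5 Mb cis window, nominal
#' alpha 0.05, 1,000 bootstrap replicates, SNP call rate 95%, genotype
#' sample call rate 90%, MAF 0.01, HWE p 0.05, probe call rate 95%,
#' detection p 1e-16, methylation sample call rate 99%, KNN K = 10 and a
#' 3-IQR outlier fence.
#'
#' @param cis_window_bp cis window half-width in base pairs.
#' @param alpha nominal significance level.
#' @param n_boot bootstrap replicates for mediation inference.
#' @param snp_call_rate_min SNPs with a lower non-missing fraction are dropped.
#' @param sample_call_rate_min_geno samples with a lower genotype call rate
#'   (over retained SNPs) are dropped.
#' @param maf_min SNPs with minor-allele frequency below this are dropped.
#' @param hwe_p_min SNPs with a Hardy-Weinberg chi-squared p below this are
#'   dropped.
#' @param probe_call_rate_min methylation probes with a lower call rate
#'   (detection p at or below `detection_p_max`) are dropped.
#' @param detection_p_max a methylation call fails when its detection
#'   p-value exceeds this.
#' @param sample_call_rate_min_meth samples with a lower methylation call
#'   rate are dropped.
#' @param knn_k number of neighbour probes for KNN imputation.
#' @param iqr_factor outlier fence in inter-quartile ranges beyond Q1/Q3.
#' @param seed integer seed used by stochastic steps (genotype imputation,
#'   bootstrap) unless overridden per call.
#'
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$cis_window_bp
#' @export
analysis_config <- function(cis_window_bp = 500000L,
                            alpha = 0.05,
                            n_boot = 1000L,
                            snp_call_rate_min = 0.95,
                            sample_call_rate_min_geno = 0.90,
                            maf_min = 0.01,
                            hwe_p_min = 0.05,
                            probe_call_rate_min = 0.95,
                            detection_p_max = 1e-16,
                            sample_call_rate_min_meth = 0.99,
                            knn_k = 10L,
                            iqr_factor = 3,
                            seed = 1L) {
  cfg <- list(
    cis_window_bp = as.integer(cis_window_bp),
    alpha = alpha,
    n_boot = as.integer(n_boot),
    snp_call_rate_min = snp_call_rate_min,
    sample_call_rate_min_geno = sample_call_rate_min_geno,
    maf_min = maf_min,
    hwe_p_min = hwe_p_min,
    probe_call_rate_min = probe_call_rate_min,
    detection_p_max = detection_p_max,
    sample_call_rate_min_meth = sample_call_rate_min_meth,
    knn_k = as.integer(knn_k),
    iqr_factor = iqr_factor,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$cis_window_bp >= 0,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$n_boot >= 1,
    cfg$snp_call_rate_min >= 0, cfg$snp_call_rate_min <= 1,
    cfg$sample_call_rate_min_geno >= 0, cfg$sample_call_rate_min_geno <= 1,
    cfg$maf_min >= 0, cfg$maf_min <= 0.5,
    cfg$hwe_p_min >= 0, cfg$hwe_p_min <= 1,
    cfg$probe_call_rate_min >= 0, cfg$probe_call_rate_min <= 1,
    cfg$detection_p_max > 0, cfg$detection_p_max < 1,
    cfg$sample_call_rate_min_meth >= 0, cfg$sample_call_rate_min_meth <= 1,
    cfg$knn_k >= 1,
    cfg$iqr_factor > 0
  )
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' The file is a flat key-value mapping; keys absent from the file keep
#' their defaults, unknown keys are an error.
#'
#' @param path file path.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param cfg an `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
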