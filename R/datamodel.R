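#' Cord-blood cell types used throughout the package
#'
#' The seven nucleated cell populations of a cord-blood deconvolution:
#' nucleated red blood cells, granulocytes, monocytes, natural killer
#' cells, B cells, CD4+ T cells and CD8+ T cells.
#'
#' @return Character vector of the seven cell-type labels.
#' @export
cell_types <- function() {
  c("nRBC", "Gran", "Mono", "NK", "Bcell", "CD4T", "CD8T")
}

.cell_cols <- function() paste0("cell_", cell_types())

#' Declared levels of the categorical covariates
#' @keywords internal
.covariate_levels <- function() {
  list(
    parity = c("primiparous", "secundiparous", "multiparous"),
    education = c("none", "high_school", "college_3yr", "university"),
    smoking = c("never", "former", "smoker")
  )
}

.covariate_numeric <- function() {
  c("sex", "gestational_age", "ethnicity", "birth_weight",
    "pregnancy_complications", "pre_pregnancy_bmi", "paternal_age")
}

#' Assemble an aligned study dataset
#'
#' Bundles genotypes, methylation, covariates and the telomere phenotype
#' with a single shared sample ordering. Components are stored as:
#' a SNP-by-sample dosage matrix plus a SNP annotation table, a
#' probe-by-sample M-value matrix plus a probe annotation table, a
#' covariate data frame, and a positive T/S-ratio vector.
#'
#' @param geno integer matrix of minor-allele dosages (SNPs x samples,
#'   values 0/1/2 or `NA`), rownames = SNP IDs.
#' @param snp_info data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `major`, `minor`, `maf`, one row per SNP in `geno` order.
#' @param meth numeric matrix of M-values (probes x samples), rownames =
#'   probe IDs.
#' @param cpg_info data frame with columns `id`, `chrom`, `pos`, one row
#'   per probe in `meth` order.
#' @param covariates data frame of per-sample covariates: `sex`,
#'   `gestational_age`, `ethnicity`, `birth_weight`,
#'   `pregnancy_complications`, `pre_pregnancy_bmi`, `parity`, `education`,
#'   `smoking`, `paternal_age` and the seven `cell_*` proportion columns.
#'   May be `NULL` for covariate-free designs.
#' @param phenotype numeric vector of T/S ratios, one per sample.
#' @param sample_ids character vector of sample IDs in component order.
#'
#' @return An object of class `study_dataset`.
#' @seealso [validate_dataset()]
#' @export
study_dataset <- function(geno, snp_info, meth, cpg_info, covariates,
                          phenotype, sample_ids) {
  n <- length(sample_ids)
  stopifnot(
    is.matrix(geno), ncol(geno) == n, nrow(geno) == nrow(snp_info),
    is.matrix(meth), ncol(meth) == n, nrow(meth) == nrow(cpg_info),
    is.null(covariates) || nrow(covariates) == n,
    length(phenotype) == n
  )
  structure(
    list(
      geno = geno, snp_info = as.data.frame(snp_info),
      meth = meth, cpg_info = as.data.frame(cpg_info),
      covariates = if (is.null(covariates)) NULL else as.data.frame(covariates),
      phenotype = as.numeric(phenotype),
      sample_ids = as.character(sample_ids)
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", length(x$sample_ids), "samples,",
      nrow(x$geno), "SNPs,", nrow(x$meth), "CpG probes\n")
  cat("  covariates:", if (is.null(x$covariates)) "none"
      else paste(ncol(x$covariates), "columns"), "\n")
  invisible(x)
}

#' Validate a study dataset
#'
#' Checks every structural invariant of a [study_dataset()] and returns a
#' report instead of raising: component sample counts agree, SNP/probe IDs
#' are unique, dosages lie in \{0, 1, 2, NA\}, stored minor-allele
#' frequencies match the dosage-recomputed values (to 1e-12) and do not
#' exceed 0.5, M-values are finite where observed, coordinates are
#' positive, categorical covariates use the declared levels, cell
#' proportions are non-negative and sum to one (to 1e-6) per sample, and
#' the T/S phenotype is strictly positive.
#'
#' @param ds a `study_dataset`.
#' @return Character vector of violation messages; empty when the dataset
#'   is valid.
#' @export
validate_dataset <- function(ds) {
  v <- character()
  n <- length(ds$sample_ids)
  if (ncol(ds$geno) != n) v <- c(v, sprintf(
    "genotypes: %d samples, expected %d", ncol(ds$geno), n))
  if (ncol(ds$meth) != n) v <- c(v, sprintf(
    "methylation: %d samples, expected %d", ncol(ds$meth), n))
  if (!is.null(ds$covariates) && nrow(ds$covariates) != n) v <- c(v, sprintf(
    "covariates: %d samples, expected %d", nrow(ds$covariates), n))
  if (length(ds$phenotype) != n) v <- c(v, sprintf(
    "phenotype: %d samples, expected %d", length(ds$phenotype), n))

  if (anyDuplicated(ds$snp_info$id)) v <- c(v, "duplicate SNP IDs")
  if (anyDuplicated(ds$cpg_info$id)) v <- c(v, "duplicate CpG probe IDs")
  if (any(ds$snp_info$pos < 1) || any(ds$cpg_info$pos < 1)) {
    v <- c(v, "coordinates must be 1-based positive integers")
  }

  bad <- !(ds$geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) v <- c(v, "dosages outside {0, 1, 2, NA}")

  if (!is.null(ds$snp_info$maf) && ncol(ds$geno) == n) {
    maf_obs <- apply(ds$geno, 1, function(d) {
      d <- d[!is.na(d)]
      if (length(d) == 0) return(NA_real_)
      sum(d) / (2 * length(d))
    })
    off <- which(!is.na(maf_obs) &
                   abs(maf_obs - ds$snp_info$maf) > 1e-12)
    if (length(off) > 0) v <- c(v, sprintf(
      "stored maf disagrees with dosages for SNP(s): %s",
      paste(ds$snp_info$id[off], collapse = ", ")))
    if (any(ds$snp_info$maf > 0.5 + 1e-12)) {
      v <- c(v, "maf above 0.5: minor allele not oriented")
    }
  }

  if (any(!is.na(ds$meth) & !is.finite(ds$meth))) {
    v <- c(v, "non-finite M-values present")
  }

  if (!is.null(ds$covariates)) {
    lv <- .covariate_levels()
    for (col in names(lv)) {
      if (col %in% names(ds$covariates)) {
        vals <- as.character(ds$covariates[[col]])
        if (!all(vals %in% lv[[col]])) v <- c(v, sprintf(
          "covariate '%s' has levels outside %s", col,
          paste(lv[[col]], collapse = "/")))
      }
    }
    cc <- intersect(.cell_cols(), names(ds$covariates))
    if (length(cc) == length(.cell_cols())) {
      W <- as.matrix(ds$covariates[, cc])
      if (any(W < 0)) v <- c(v, "negative cell proportions")
      s <- rowSums(W)
      off <- which(abs(s - 1) > 1e-6)
      if (length(off) > 0) v <- c(v, sprintf(
        "cell proportions do not sum to 1 for sample(s): %s",
        paste(ds$sample_ids[off], collapse = ", ")))
    }
  }

  if (any(!is.na(ds$phenotype) & ds$phenotype <= 0)) {
    v <- c(v, "non-positive T/S ratio in phenotype")
  }
  v
}

#' Reference cohort margins
#'
#' Marginal characteristics of the 281-pair birth cohort the synthetic
#' generator is calibrated to: per-category counts for the categorical
#' covariates and mean/SD for the continuous ones (telomere length as T/S
#' ratio 1.03 +/- 0.20). These margins drive covariate simulation and the
#' descriptive-statistics summaries.
#'
#' @return A list with elements `n` (cohort size), `counts` (named list of
#'   per-level count vectors) and `numeric` (data frame of mean/SD rows).
#' @export
cohort_margins <- function() {
  list(
    n = 281L,
    counts = list(
      sex = c(female = 139L, male = 142L),
      ethnicity = c(European = 263L, non_European = 18L),
      education = c(none = 16L, high_school = 80L, college_3yr = 148L,
                    university = 37L),
      smoking = c(never = 205L, former = 43L, smoker = 33L),
      parity = c(primiparous = 145L, secundiparous = 105L,
                 multiparous = 31L),
      pregnancy_complications = c(no = 233L, yes = 48L)
    ),
    numeric = data.frame(
      variable = c("birth_weight", "gestational_age", "tl_ts_ratio",
                   "maternal_age", "pre_pregnancy_bmi", "paternal_age"),
      mean = c(3.38, 39.03, 1.03, 30.11, 24.03, 32.48),
      sd = c(0.48, 1.64, 0.20, 4.17, 4.21, 4.99)
    )
  )
}

#' Descriptive percentages from cohort margins
#'
#' Recomputes per-category percentages from the categorical counts of a
#' margins object, rounded to one decimal as conventionally reported in a
#' cohort characteristics table. Each category's percentage is
#' 100 * count / total over its variable.
#'
#' @param margins a margins list as returned by [cohort_margins()].
#' @param digits decimals to round to (default 1).
#' @return Named list (per variable) of named numeric percentage vectors.
#' @examples
#' margin_percentages()$ethnicity
#' @export
margin_percentages <- function(margins = cohort_margins(), digits = 1) {
  lapply(margins$counts, function(cnt) {
    round(100 * cnt / sum(cnt), digits)
  })
}
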