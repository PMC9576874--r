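# File readers/writers. One dialect throughout: tab-separated, header row,
# "NA" as the missing token. Coordinates are 1-based inclusive internally;
# BED manifests are the only 0-based surface and are converted at the
# boundary.

.geno_meta_cols <- c("id", "chrom", "pos", "major", "minor")

#' Read genotype dosages
#'
#' Reads per-sample minor-allele dosages from either the package's TSV
#' dialect (columns `id`, `chrom`, `pos`, `major`, `minor`, then one dosage
#' column per sample) or a VCF with GT calls (biallelic records only, via
#' vcfR). Dosages are oriented so the stored allele is the observed minor
#' allele: when the counted allele's sample frequency exceeds 0.5 the
#' dosages are flipped (`2 - d`) and the allele labels swapped; an exact
#' 0.5 tie keeps the file's alternate allele as minor. `maf` is populated
#' from the non-missing dosages.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A list with `geno` (integer matrix SNPs x samples, `NA` for
#'   missing) and `info` (data frame `id`, `chrom`, `pos`, `major`,
#'   `minor`, `maf`).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") .read_genotypes_tsv(path) else .read_genotypes_vcf(path)
}

.read_genotypes_tsv <- function(path) {
  stopifnot(file.exists(path))
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) {
    stop("malformed genotype TSV: line(s) ",
         paste(which(nf != nf[1]), collapse = ", "),
         " have a different field count")
  }
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, colClasses = "character")
  if (!all(.geno_meta_cols %in% names(tab)[seq_len(5)])) {
    stop("genotype TSV must start with columns: ",
         paste(.geno_meta_cols, collapse = ", "))
  }
  samples <- names(tab)[-seq_len(5)]
  dos <- as.matrix(tab[, samples, drop = FALSE])
  bad <- matrix(!(dos %in% c("0", "1", "2")) & !is.na(dos),
                nrow = nrow(dos))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed dosage token '%s' at line %d (SNP %s)",
                 dos[bad][1], idx[1] + 1L, tab$id[idx[1]]))
  }
  geno <- matrix(suppressWarnings(as.integer(dos)), nrow = nrow(tab),
                 dimnames = list(tab$id, samples))
  info <- data.frame(id = tab$id, chrom = tab$chrom,
                     pos = as.integer(tab$pos),
                     major = tab$major, minor = tab$minor)
  .orient_minor(geno, info)
}

.read_genotypes_vcf <- function(path) {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic VCF record(s) rejected: ",
         paste(fix[multi, "ID"], collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
  count_alt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!all(alleles %in% c("0", "1"))) return(NA_integer_)
    sum(alleles == "1")
  }
  geno <- apply(gt, c(1, 2), count_alt)
  rownames(geno) <- fix[, "ID"]
  info <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     major = fix[, "REF"], minor = fix[, "ALT"])
  .orient_minor(geno, info)
}

# Orient dosages to minor-allele counts; populate maf. The dosage column
# entering here counts `info$minor`; flip when its frequency is > 0.5.
.orient_minor <- function(geno, info) {
  freq <- apply(geno, 1, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(0)
    sum(d) / (2 * length(d))
  })
  flip <- freq > 0.5
  if (any(flip)) {
    geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
    tmp <- info$major[flip]
    info$major[flip] <- info$minor[flip]
    info$minor[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  info$maf <- freq
  list(geno = geno, info = info)
}

#' Write genotype dosages
#'
#' `write_genotypes()` emits the TSV dialect read by [read_genotypes()];
#' `write_genotypes_vcf()` emits a minimal VCF 4.2 with GT calls (REF =
#' major, ALT = minor allele; missing dosage as `./.`).
#'
#' @param geno_list list with `geno` matrix and `info` data frame as
#'   returned by [read_genotypes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno_list, path) {
  info <- geno_list$info
  tab <- cbind(info[, .geno_meta_cols],
               as.data.frame(geno_list$geno, check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_genotypes_vcf <- function(geno_list, path) {
  info <- geno_list$info
  geno <- geno_list$geno
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  obs <- !is.na(geno)
  gt[obs] <- gt_code[geno[obs] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=teloscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(geno)), function(i) {
    paste(c(info$chrom[i], info$pos[i], info$id[i], info$major[i],
            info$minor[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write a methylation M-value matrix
#'
#' TSV with probes in rows and samples in columns; first column `id` holds
#' probe IDs, header row holds sample IDs, `NA` is the missing token.
#' Values are written with 12 significant digits so a write/read round
#' trip is value-preserving at that precision.
#'
#' @param path file path.
#' @return `read_methylation()` returns a numeric matrix (probes x
#'   samples) with probe-ID rownames.
#' @export
read_methylation <- function(path) {
  stopifnot(file.exists(path))
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])
    first <- scan(path, what = character(), sep = "\t", skip = bad[1] - 1,
                  nlines = 1, quiet = TRUE)[1]
    stop(sprintf("ragged methylation TSV: probe '%s' (line %d) has %d fields, expected %d",
                 first, bad[1], nf[bad[1]], nf[1]))
  }
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, colClasses = "character")
  if (names(tab)[1] != "id") stop("methylation TSV must have first column 'id'")
  if (anyDuplicated(tab$id)) {
    stop("duplicate probe ID(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                 vals[bad][1], tab$id[idx[1]], colnames(vals)[idx[2]]))
  }
  dimnames(num) <- list(tab$id, colnames(vals))
  num
}

#' @rdname read_methylation
#' @param m numeric matrix of M-values, probes in rows.
#' @export
write_methylation <- function(m, path) {
  tab <- data.frame(id = rownames(m),
                    signif(m, 12), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a single-base feature manifest (BED)
#'
#' BED is half-open and 0-based; features must span exactly one base
#' (`end == start + 1`) and are converted to 1-based positions
#' (`pos = start + 1`) on read. Parsing and serialization go through
#' rtracklayer.
#'
#' @param path BED file path.
#' @return `read_manifest()` returns a data frame `id`, `chrom`, `pos`.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "BED")
  w <- GenomicRanges::width(gr)
  if (any(w != 1)) {
    bad <- which(w != 1)
    stop("manifest feature(s) not single-base (end != start + 1): ",
         paste(gr$name[bad], collapse = ", "))
  }
  data.frame(id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr))
}

#' @rdname read_manifest
#' @param manifest data frame with columns `id`, `chrom`, `pos` (1-based).
#' @export
write_manifest <- function(manifest, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1),
    name = manifest$id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write the covariate table
#'
#' TSV with a `sample_id` column, the ten study covariates and the seven
#' `cell_*` proportion columns; categorical covariates are stored as their
#' level labels and re-read as factors with the declared level order.
#'
#' @param path file path.
#' @return `read_covariates()` returns a data frame with `sample_id`
#'   rownames.
#' @export
read_covariates <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE)
  lv <- .covariate_levels()
  for (col in names(lv)) {
    if (col %in% names(tab)) tab[[col]] <- factor(tab[[col]], levels = lv[[col]])
  }
  rownames(tab) <- tab$sample_id
  tab$sample_id <- NULL
  tab
}

#' @rdname read_covariates
#' @param covariates covariate data frame (rownames = sample IDs).
#' @export
write_covariates <- function(covariates, path) {
  tab <- cbind(sample_id = rownames(covariates), covariates)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the telomere phenotype
#'
#' TSV with columns `sample_id` and `tl` (T/S ratio).
#'
#' @param path file path.
#' @return `read_phenotype()` returns a named numeric vector.
#' @export
read_phenotype <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "")
  setNames(as.numeric(tab$tl), tab$sample_id)
}

#' @rdname read_phenotype
#' @param tl named numeric vector of T/S ratios.
#' @export
write_phenotype <- function(tl, path) {
  write.table(data.frame(sample_id = names(tl), tl = signif(tl, 12)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulated study bundle back from disk
#'
#' Reassembles a [study_dataset()] from the files written by
#' [simulate_study()].
#'
#' @param dir directory containing the bundle.
#' @return A `study_dataset`.
#' @export
read_study <- function(dir) {
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"))
  snp_man <- read_manifest(file.path(dir, "snp_manifest.bed"))
  meth <- read_methylation(file.path(dir, "methylation.tsv"))
  cpg_man <- read_manifest(file.path(dir, "cpg_manifest.bed"))
  covs <- read_covariates(file.path(dir, "covariates.tsv"))
  tl <- read_phenotype(file.path(dir, "phenotype.tsv"))
  samples <- names(tl)
  info <- merge(geno$info[, c("id", "major", "minor", "maf")],
                snp_man, by = "id", sort = FALSE)
  info <- info[match(rownames(geno$geno), info$id),
               c("id", "chrom", "pos", "major", "minor", "maf")]
  cpg_info <- cpg_man[match(rownames(meth), cpg_man$id), ]
  study_dataset(
    geno = geno$geno[, samples, drop = FALSE], snp_info = info,
    meth = meth[, samples, drop = FALSE], cpg_info = cpg_info,
    covariates = covs[samples, , drop = FALSE],
    phenotype = tl, sample_ids = samples
  )
}
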