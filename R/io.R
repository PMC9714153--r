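# On-disk formats. All tables are tab-delimited UTF-8 with "NA" for
# missing. Coordinates: CpG/SNP positions are 1-based; BED files keep
# their native 0-based half-open convention and are converted exactly
# once, in read_features().

#' Construct a genotype matrix object
#'
#' @param dosages numeric matrix, samples x variants, entries in `[0, 2]`
#'   or `NA`; column names are variant ids, row names sample ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos`
#'   (1-based), `effect_allele`, `other_allele`, and optionally `imp_r2`.
#'   MAF is (re)computed from the dosages.
#' @return object of class `genotype_matrix` with elements `dosages`
#'   and `variants` (variants sorted by chromosome then position).
#' @export
genotype_matrix <- function(dosages, variants) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (ncol(dosages) != nrow(variants))
    stop("ncol(dosages) != nrow(variants)")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosage outside [0, 2]: range ", rng[1], "..", rng[2])
  if (any(variants$pos < 1)) stop("variant pos must be >= 1")
  if (any(variants$effect_allele == variants$other_allele))
    stop("effect_allele must differ from other_allele")
  colnames(dosages) <- variants$id
  ord <- order(variants$chrom, variants$pos, variants$id)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  p <- colMeans(dosages, na.rm = TRUE) / 2
  variants$maf <- pmin(p, 1 - p)
  variants$missingness <- colMeans(is.na(dosages))
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' Construct a methylation matrix object
#'
#' @param betas numeric matrix, samples x CpGs, beta values in `[0, 1]`.
#' @param cpgs data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `island_relation` (one of Island, N_Shore, S_Shore, N_Shelf,
#'   S_Shelf, OpenSea) and optionally `platform` (K450, EPIC, BOTH).
#' @return object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, cpgs) {
  if (!is.matrix(betas)) betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  req <- c("id", "chrom", "pos", "island_relation")
  miss <- setdiff(req, names(cpgs))
  if (length(miss)) stop("CpG manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (ncol(betas) != nrow(cpgs)) stop("ncol(betas) != nrow(cpgs)")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values outside [0, 1]")
  ok <- cpgs$island_relation %in% island_relation_levels()
  if (!all(ok)) stop("unknown island_relation: ",
                     paste(unique(cpgs$island_relation[!ok]), collapse = ", "))
  colnames(betas) <- cpgs$id
  rownames(cpgs) <- NULL
  structure(list(betas = betas, cpgs = cpgs), class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d samples x %d CpGs\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Island-relation categories
#' @return character vector of the six annotation categories.
#' @export
island_relation_levels <- function() {
  c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
}

#' Validate a sample covariate table
#'
#' Checks the columns the EWAS designs require: `sample_id`, `sex`
#' (F/M), `batch`, `case_status` (0/1), `gestational_age` (weeks, > 0),
#' `birthweight` (grams, > 0), `ancestry_group` (NLW/LAT), `pc1`..`pc10`
#' and the six cell fractions `cell_CD8T`, `cell_CD4T`, `cell_NK`,
#' `cell_Bcell`, `cell_Mono`, `cell_nRBC` (each in `[0, 1]`, summing to
#' at most 1; granulocytes are the omitted remainder).
#' `maternal_weight_gain` (kg) is optional.
#'
#' @param samples data.frame.
#' @return the validated data.frame, invisibly classed `sample_table`.
#' @export
validate_sample_table <- function(samples) {
  req <- c("sample_id", "sex", "batch", "case_status", "gestational_age",
           "birthweight", "ancestry_group", paste0("pc", 1:10),
           cell_covariate_names())
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(samples$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!all(samples$case_status %in% c(0, 1)))
    stop("case_status must be 0/1")
  if (any(samples$gestational_age <= 0)) stop("gestational_age must be > 0")
  if (any(samples$birthweight <= 0)) stop("birthweight must be > 0")
  cells <- as.matrix(samples[cell_covariate_names()])
  if (any(cells < 0 | cells > 1)) stop("cell fractions must lie in [0, 1]")
  if (any(rowSums(cells) > 1 + 1e-8))
    stop("cell fractions must sum to <= 1 (granulocytes are the remainder)")
  class(samples) <- unique(c("sample_table", class(samples)))
  invisible(samples)
}

#' @keywords internal
cell_covariate_names <- function() {
  paste0("cell_", c("CD8T", "CD4T", "NK", "Bcell", "Mono", "nRBC"))
}

# ---------------------------------------------------------------------
# readers / writers

#' Read a genotype matrix from VCF or a dosage TSV
#'
#' For VCF input the `DS` FORMAT field is used when present, otherwise
#' dosages are counted from `GT` (number of ALT alleles). Multiallelic
#' records are skipped with a warning giving the count. For dosage-TSV
#' input (first column `sample_id`, remaining columns one per variant)
#' a variant manifest is required to supply positions and alleles.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_tsv"` (`"auto"` guesses from the
#'   extension).
#' @param variant_manifest for dosage TSVs: a data.frame or path to a
#'   TSV with columns `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele` (and optionally `imp_r2`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           variant_manifest = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path, variant_manifest)
}

#' @keywords internal
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("%d multiallelic record(s) skipped", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    d <- apply(gt, c(1, 2), cnt)
  } else {
    stop("VCF has neither GT nor DS FORMAT fields: ", path)
  }
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad)) stop(sprintf("dosage outside [0,2] at record %s sample %s",
                              rownames(d)[bad[1, 1]], colnames(d)[bad[1, 2]]))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         effect_allele = fix$ALT, other_allele = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(d), variants)
}

#' @keywords internal
read_genotypes_tsv <- function(path, variant_manifest) {
  if (is.null(variant_manifest))
    stop("dosage TSV input needs a variant_manifest")
  if (is.character(variant_manifest))
    variant_manifest <- read_tsv_checked(variant_manifest,
                                         c("id", "chrom", "pos",
                                           "effect_allele", "other_allele"))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("dosage TSV must have 'sample_id' as its first column: ", path)
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$sample_id
  idx <- match(colnames(d), variant_manifest$id)
  if (anyNA(idx)) stop("variants absent from manifest: ",
                       paste(utils::head(colnames(d)[is.na(idx)], 5),
                             collapse = ", "))
  genotype_matrix(d, variant_manifest[idx, , drop = FALSE])
}

#' Write a genotype matrix as dosage TSV + variant manifest
#'
#' @param g a [genotype_matrix()].
#' @param dosage_path,manifest_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(g, dosage_path, manifest_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(sample_id = rownames(g$dosages),
                    g$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, dosage_path)
  write_tsv(g$variants, manifest_path)
  invisible(c(dosage_path, manifest_path))
}

#' Read a methylation matrix (beta TSV + CpG manifest)
#'
#' @param beta_path TSV with first column `sample_id`, one column per CpG.
#' @param manifest CpG manifest data.frame or TSV path with columns
#'   `id`, `chrom`, `pos`, `island_relation` (optionally `platform`).
#' @return a [methylation_matrix()].
#' @export
read_methylation <- function(beta_path, manifest) {
  if (is.character(manifest))
    manifest <- read_tsv_checked(manifest,
                                 c("id", "chrom", "pos", "island_relation"))
  tab <- utils::read.delim(beta_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("beta TSV must have 'sample_id' as its first column: ", beta_path)
  b <- as.matrix(tab[, -1, drop = FALSE])
  rownames(b) <- tab$sample_id
  idx <- match(colnames(b), manifest$id)
  if (anyNA(idx)) stop("CpGs absent from manifest: ",
                       paste(utils::head(colnames(b)[is.na(idx)], 5),
                             collapse = ", "))
  methylation_matrix(b, manifest[idx, , drop = FALSE])
}

#' Write a methylation matrix as beta TSV + CpG manifest
#' @param m a [methylation_matrix()].
#' @param beta_path,manifest_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_methylation <- function(m, beta_path, manifest_path) {
  stopifnot(inherits(m, "methylation_matrix"))
  tab <- data.frame(sample_id = rownames(m$betas), m$betas,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, beta_path)
  write_tsv(m$cpgs, manifest_path)
  invisible(c(beta_path, manifest_path))
}

#' Read and validate a sample covariate table
#' @param path TSV path.
#' @return validated `sample_table` data.frame.
#' @export
read_samples <- function(path) {
  validate_sample_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @keywords internal
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop(path, " missing columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' Write a tab-delimited table ("NA" for missing, full precision)
#' @param tab data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(tab, path) {
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.17g", x))
  })
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------
# genotype QC

#' Variant-level genotype quality control
#'
#' Filters variants in the order missingness, Hardy-Weinberg
#' equilibrium, minor allele frequency, imputation quality. HWE uses
#' the exact test on rounded hard calls; samples whose dosage at a site
#' has fractional part above 0.1 are excluded from that site's HWE
#' counts. The imputation filter applies only when the variant table
#' carries an `imp_r2` column.
#'
#' @param g a [genotype_matrix()].
#' @param hwe_p_min exclude variants with exact HWE P below this
#'   (default `1e-4`).
#' @param maf_min exclude variants with MAF below this (default 0.01).
#' @param miss_max exclude variants with missingness above this
#'   (default 0.05).
#' @param imp_r2_min exclude imputed variants with R-squared at or below
#'   this (default 0.6).
#' @return the filtered `genotype_matrix`, with a `qc_report` attribute
#'   listing the number removed by each filter.
#' @export
apply_genotype_qc <- function(g, hwe_p_min = 1e-4, maf_min = 0.01,
                              miss_max = 0.05, imp_r2_min = 0.6) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  keep <- rep(TRUE, ncol(d))
  report <- c(missingness = 0L, hwe = 0L, maf = 0L, imputation_r2 = 0L)

  miss <- colMeans(is.na(d))
  drop <- keep & miss > miss_max
  report["missingness"] <- sum(drop)
  keep <- keep & !drop

  hwe_p <- vapply(which(keep), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    hard <- x[abs(x - round(x)) <= 0.1]
    gt <- round(hard)
    hwe_exact_p(sum(gt == 1), sum(gt == 0), sum(gt == 2))
  }, numeric(1))
  drop_idx <- which(keep)[!is.na(hwe_p) & hwe_p < hwe_p_min]
  report["hwe"] <- length(drop_idx)
  keep[drop_idx] <- FALSE

  drop <- keep & g$variants$maf < maf_min
  report["maf"] <- sum(drop)
  keep <- keep & !drop

  if ("imp_r2" %in% names(g$variants)) {
    r2 <- g$variants$imp_r2
    drop <- keep & !is.na(r2) & r2 <= imp_r2_min
    report["imputation_r2"] <- sum(drop)
    keep <- keep & !drop
  }

  if (!any(keep)) stop("genotype QC removed every variant")
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         g$variants[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

# ---------------------------------------------------------------------
# genomic feature sets (BED)

#' Read a BED3+ feature file
#'
#' BED intervals are 0-based half-open; they are converted here, and
#' only here, to 1-based closed `GRanges` so that a CpG at 1-based
#' position p overlaps `[start0, end0)` iff `start0 <= p - 1 < end0`.
#'
#' @param path BED file path.
#' @param name feature-set label (defaults to the file name).
#' @return a `feature_set`: a `GRanges` with a `name` attribute.
#' @export
read_features <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("not a BED3+ file: ", path)
  tab <- tab[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  if (any(tab$end <= tab$start))
    stop("BED interval with end <= start in ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end))
  attr(gr, "name") <- name %||% basename(path)
  gr
}

#' Point-overlap of CpG positions with a feature set
#'
#' @param features a `GRanges` from [read_features()].
#' @param chrom character vector of chromosomes.
#' @param pos integer vector of 1-based positions.
#' @return logical vector: does each position fall in any interval?
#' @export
overlaps_features <- function(features, chrom, pos) {
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(start = pos,
                                                        width = 1L))
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(features))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(features) <- lv
  GenomicRanges::countOverlaps(q, features) > 0
}
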