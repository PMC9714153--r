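# Inverse-variance fixed-effects meta-analysis of per-dataset mQTL
# scans, construction of the per-platform CpG-SNP database, and
# LD-based cross-dataset concordance of assigned mQTLs.

#' Inverse-variance fixed-effects pooling
#'
#' Weights `w_i = 1 / se_i^2`; `pooled_beta = sum(w b) / sum(w)`,
#' `pooled_se = sum(w)^(-1/2)`, `z = pooled_beta / pooled_se`,
#' `p = 2 Phi(-|z|)` (computed on the log scale so P values below the
#' double-precision underflow limit keep a usable `log10_p`).
#'
#' @param beta vector of per-dataset effect estimates.
#' @param se vector of per-dataset standard errors (all > 0).
#' @return list with `beta`, `se`, `z`, `p`, `log10_p`, `n_datasets`.
#' @export
inverse_variance_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  pb <- sum(w * beta) / sum(w)
  ps <- 1 / sqrt(sum(w))
  z <- pb / ps
  logp <- stats::pnorm(-abs(z), log.p = TRUE) + log(2)
  list(beta = pb, se = ps, z = z,
       p = exp(logp), log10_p = logp / log(10),
       n_datasets = length(beta))
}

#' Align effect alleles across datasets for each CpG-SNP pair
#'
#' Within each `(cpg_id, snp_id)` group the first record's effect
#' allele is the reference orientation: records reporting the swapped
#' allele pair have their effect sign flipped; records whose alleles
#' neither match nor flip are dropped. Strand-ambiguous variants
#' (A/T or C/G) with MAF in `[0.4, 0.5]` are dropped entirely, since
#' their orientation cannot be resolved from allele frequency.
#'
#' @param records data.frame with columns `cpg_id`, `snp_id`, `beta`,
#'   `effect_allele`, `other_allele`, `snp_maf` (plus anything else,
#'   carried through).
#' @return the aligned records; attribute `dropped` gives counts
#'   `ambiguous` and `irreconcilable`.
#' @export
harmonize_alleles <- function(records) {
  ambiguous_pair <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  amb <- ambiguous_pair(records$effect_allele, records$other_allele) &
    records$snp_maf >= 0.4 & records$snp_maf <= 0.5
  n_amb <- sum(amb)
  records <- records[!amb, , drop = FALSE]

  irreconcilable <- rep(FALSE, nrow(records))
  key <- paste(records$cpg_id, records$snp_id)
  for (grp in split(seq_len(nrow(records)), key)) {
    ea <- records$effect_allele[grp[1]]
    oa <- records$other_allele[grp[1]]
    for (i in grp[-1]) {
      if (records$effect_allele[i] == ea && records$other_allele[i] == oa) {
        next
      } else if (records$effect_allele[i] == oa &&
                 records$other_allele[i] == ea) {
        records$beta[i] <- -records$beta[i]
        records$effect_allele[i] <- ea
        records$other_allele[i] <- oa
      } else {
        irreconcilable[i] <- TRUE
      }
    }
  }
  out <- records[!irreconcilable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(ambiguous = n_amb,
                            irreconcilable = sum(irreconcilable))
  out
}

#' Build a per-platform CpG-mQTL database from per-dataset scans
#'
#' Takes the union of significant (adjusted P < `adj_p_max`) CpG-SNP
#' pairs across the per-dataset scan tables; pairs observed in two or
#' more datasets are pooled by [inverse_variance_meta()] after allele
#' harmonization, pairs observed once carry their single dataset's
#' statistics. Within each CpG, records are ranked by `(p, |distance
#' to CpG|, snp_id)`; the rank-1 SNP is the CpG's assigned mQTL.
#'
#' @param scan_tables list of `mqtl_scan` data.frames (one per
#'   dataset); list names label the datasets in the direction string.
#' @param platform platform tag (e.g. `"K450"`, `"EPIC"`).
#' @param adj_p_max inclusion threshold on the per-dataset adjusted P
#'   (default 0.05).
#' @return data.frame of class `mqtl_db`: `cpg_id`, `snp_id`,
#'   `cpg_chrom`, `cpg_pos`, `snp_pos`, `pooled_beta`, `pooled_se`,
#'   `z`, `p`, `log10_p`, `direction`, `n_datasets`, `rank`,
#'   `assigned` (rank == 1).
#' @export
build_database <- function(scan_tables, platform = "K450",
                           adj_p_max = 0.05) {
  if (is.null(names(scan_tables)))
    names(scan_tables) <- paste0("dataset", seq_along(scan_tables))
  labs <- names(scan_tables)
  sig <- lapply(labs, function(l) {
    t <- scan_tables[[l]]
    t <- t[t$adjusted_p < adj_p_max, , drop = FALSE]
    if (nrow(t)) t$dataset <- l
    t
  })
  all <- do.call(rbind, lapply(sig, function(t) as.data.frame(t)))
  if (is.null(all) || !nrow(all)) {
    out <- data.frame(cpg_id = character(0), snp_id = character(0),
                      pooled_beta = numeric(0), pooled_se = numeric(0),
                      z = numeric(0), p = numeric(0),
                      log10_p = numeric(0), direction = character(0),
                      n_datasets = integer(0), rank = integer(0),
                      assigned = logical(0), stringsAsFactors = FALSE)
    attr(out, "platform") <- platform
    class(out) <- c("mqtl_db", "data.frame")
    return(out)
  }
  all <- harmonize_alleles(all)
  dropped <- attr(all, "dropped")

  key <- paste(all$cpg_id, all$snp_id)
  rows <- lapply(split(seq_len(nrow(all)), key), function(grp) {
    g <- all[grp, , drop = FALSE]
    if (nrow(g) >= 2) {
      mm <- inverse_variance_meta(g$beta, g$se)
    } else {
      z <- g$beta / g$se
      logp <- stats::pnorm(-abs(z), log.p = TRUE) + log(2)
      mm <- list(beta = g$beta, se = g$se, z = z, p = exp(logp),
                 log10_p = logp / log(10), n_datasets = 1L)
    }
    dir <- rep("?", length(labs))
    dir[match(g$dataset, labs)] <- ifelse(g$beta >= 0, "+", "-")
    data.frame(cpg_id = g$cpg_id[1], snp_id = g$snp_id[1],
               cpg_chrom = g$cpg_chrom[1], cpg_pos = g$cpg_pos[1],
               snp_pos = g$snp_pos[1],
               pooled_beta = mm$beta, pooled_se = mm$se, z = mm$z,
               p = mm$p, log10_p = mm$log10_p,
               direction = paste(dir, collapse = ""),
               n_datasets = mm$n_datasets, stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  ord <- order(db$cpg_id, db$p, abs(db$snp_pos - db$cpg_pos), db$snp_id)
  db <- db[ord, , drop = FALSE]
  db$rank <- stats::ave(seq_len(nrow(db)), db$cpg_id,
                        FUN = seq_along)
  db$assigned <- db$rank == 1L
  rownames(db) <- NULL
  attr(db, "platform") <- platform
  attr(db, "datasets") <- labs
  attr(db, "dropped") <- dropped
  class(db) <- c("mqtl_db", "data.frame")
  db
}

#' @export
print.mqtl_db <- function(x, ...) {
  cat(sprintf(
    "mqtl_db (%s): %d CpG-SNP pairs covering %d CpGs (%d datasets)\n",
    attr(x, "platform") %||% "?", nrow(x), length(unique(x$cpg_id)),
    length(attr(x, "datasets") %||% character(0))))
  invisible(x)
}

#' Assigned (top-ranked) mQTL per CpG
#' @param db an `mqtl_db`.
#' @return data.frame with one row per CpG (rank-1 records).
#' @export
assigned_mqtls <- function(db) {
  db[db$assigned, , drop = FALSE]
}

#' LD between two variants as squared dosage correlation
#'
#' @param dosage_a,dosage_b dosage vectors over the same samples.
#' @return squared Pearson correlation in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD undefined for a constant dosage vector")
  stats::cor(a, b)^2
}

#' Cross-dataset concordance of assigned mQTLs
#'
#' Over CpGs present in both databases, counts how many have the
#' identical assigned SNP (`same_snp`), a different SNP in LD
#' (`in_ld`, dosage r-squared > `r2_min` in the supplied genotypes),
#' and either. CpGs whose SNPs are missing from the genotype matrix
#' are counted `untestable` and excluded from the denominators.
#'
#' @param db_a,db_b `mqtl_db` objects.
#' @param geno a [genotype_matrix()] covering the assigned SNPs.
#' @param r2_min LD threshold (default 0.5).
#' @return object of class `mqtl_concordance`: list with `counts`
#'   (`shared`, `same_snp`, `in_ld`, `either`, `untestable`) and a
#'   per-CpG `detail` data.frame.
#' @export
concordance <- function(db_a, db_b, geno, r2_min = 0.5) {
  a <- assigned_mqtls(db_a)
  b <- assigned_mqtls(db_b)
  shared <- intersect(a$cpg_id, b$cpg_id)
  if (!length(shared)) stop("no CpGs shared between the two databases")
  sa <- a$snp_id[match(shared, a$cpg_id)]
  sb <- b$snp_id[match(shared, b$cpg_id)]
  same <- sa == sb
  r2 <- rep(NA_real_, length(shared))
  untestable <- rep(FALSE, length(shared))
  for (i in which(!same)) {
    if (!(sa[i] %in% colnames(geno$dosages)) ||
        !(sb[i] %in% colnames(geno$dosages))) {
      untestable[i] <- TRUE
      next
    }
    r2[i] <- tryCatch(ld_r2(geno$dosages[, sa[i]], geno$dosages[, sb[i]]),
                      error = function(e) NA_real_)
    if (is.na(r2[i])) untestable[i] <- TRUE
  }
  in_ld <- !same & !untestable & !is.na(r2) & r2 > r2_min
  detail <- data.frame(cpg_id = shared, snp_a = sa, snp_b = sb,
                       same_snp = same, r2 = r2, in_ld = in_ld,
                       untestable = untestable, stringsAsFactors = FALSE)
  testable <- !untestable
  counts <- c(shared = length(shared),
              testable = sum(testable),
              same_snp = sum(same[testable]),
              in_ld = sum(in_ld),
              either = sum((same | in_ld)[testable]),
              untestable = sum(untestable))
  structure(list(counts = counts, detail = detail, r2_min = r2_min),
            class = "mqtl_concordance")
}

#' @export
print.mqtl_concordance <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(paste0("mQTL concordance over %d shared CpGs ",
                     "(%d testable): same SNP %d, in LD (r2 > %.2g) %d, ",
                     "either %d, untestable %d\n"),
              ct["shared"], ct["testable"], ct["same_snp"], x$r2_min,
              ct["in_ld"], ct["either"], ct["untestable"]))
  invisible(x)
}

#' Write an mQTL database as TSV
#' @param db an `mqtl_db`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_database <- function(db, path) {
  write_tsv(as.data.frame(db), path)
}
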