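# Paired birthweight EWAS. For each CpG two nested linear models are
# fitted on the beta values: the plain model
#   beta ~ birthweight + sex + gestational age + batch + case status +
#          CD8T + CD4T + NK + Bcell + Mono + nRBC + PC1..PC10
# and the mQTL model, which adds the CpG's assigned mQTL dosage. The
# sensitivity model further adds maternal weight gain. Granulocytes are
# never entered (the six fractions already span the composition up to
# the granulocyte remainder; adding the seventh is collinear).

#' Exclude preterm samples ahead of the EWAS
#'
#' Samples with gestational age below `min_weeks` (default 30) are
#' removed; the number removed is recorded in attribute `n_excluded`.
#'
#' @param samples a validated sample table.
#' @param min_weeks gestational-age floor in weeks.
#' @return filtered sample table with attribute `n_excluded`.
#' @export
exclude_preterm <- function(samples, min_weeks = 30) {
  keep <- samples$gestational_age >= min_weeks
  out <- samples[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' EWAS design matrix
#'
#' @param samples a validated sample table.
#' @param mqtl_dosage optional mQTL dosage vector (adds one column).
#' @param maternal_weight_gain add the maternal-weight-gain column
#'   (sensitivity model)?
#' @return numeric design matrix including the intercept; the
#'   birthweight column is named `birthweight`.
#' @export
ewas_design <- function(samples, mqtl_dosage = NULL,
                        maternal_weight_gain = FALSE) {
  if ("cell_Gran" %in% names(samples))
    stop(paste("granulocyte fraction must not enter the design",
               "(collinear with the remaining cell fractions)"))
  f <- ~ birthweight + sex + gestational_age + batch + case_status +
    cell_CD8T + cell_CD4T + cell_NK + cell_Bcell + cell_Mono + cell_nRBC +
    pc1 + pc2 + pc3 + pc4 + pc5 + pc6 + pc7 + pc8 + pc9 + pc10
  X <- stats::model.matrix(f, data = samples)
  if (maternal_weight_gain) {
    mwg <- samples$maternal_weight_gain
    if (stats::var(mwg) == 0) {
      warning("maternal_weight_gain is constant; column dropped")
    } else {
      X <- cbind(X, maternal_weight_gain = mwg)
    }
  }
  if (!is.null(mqtl_dosage)) {
    stopifnot(length(mqtl_dosage) == nrow(X))
    X <- cbind(X, mqtl = mqtl_dosage)
  }
  X
}

#' @keywords internal
ewas_record <- function(cpg_id, model, fit, mqtl_snp_id = NA_character_) {
  i <- match("birthweight", names(fit$coef))
  data.frame(cpg_id = cpg_id, model = model,
             beta_bw = unname(fit$coef[i]), se = unname(fit$se[i]),
             t = unname(fit$t[i]), p = unname(fit$p[i]),
             n = fit$n, mqtl_snp_id = mqtl_snp_id,
             rss = fit$rss, df_resid = fit$df,
             stringsAsFactors = FALSE)
}

#' Fit the paired EWAS models (with and without the mQTL covariate)
#'
#' @param y methylation beta vector (preterm samples already excluded).
#' @param samples matching sample table.
#' @param mqtl_dosage assigned-mQTL dosage vector, or `NULL` when the
#'   CpG has no matched mQTL (the two records are then identical up to
#'   the model tag).
#' @param cpg_id CpG identifier for the output records.
#' @param mqtl_snp_id identifier of the mQTL SNP (for the record).
#' @return data.frame with two `ewas_record` rows, models `"mqtl"` and
#'   `"plain"`.
#' @export
fit_pair <- function(y, samples, mqtl_dosage = NULL, cpg_id = "cpg",
                     mqtl_snp_id = NA_character_) {
  Xp <- ewas_design(samples)
  fit_plain <- ols_fit(Xp, y)
  if (is.null(mqtl_dosage)) {
    full <- ewas_record(cpg_id, "mqtl", fit_plain)
  } else {
    Xm <- cbind(Xp, mqtl = mqtl_dosage)
    full <- ewas_record(cpg_id, "mqtl", ols_fit(Xm, y), mqtl_snp_id)
  }
  rbind(full, ewas_record(cpg_id, "plain", fit_plain))
}

#' Partial F-test of nested EWAS models
#'
#' `F = ((rss_reduced - rss_full) / q) / (rss_full / df_full)` with
#' `q = df_reduced - df_full`; P from the `F(q, df_full)` distribution.
#' With `q = 1` the statistic equals the squared t of the added
#' coefficient.
#'
#' @param full,reduced one-row `ewas_record` data.frames (same CpG and
#'   samples; `reduced$rss >= full$rss` up to rounding).
#' @return list with `F`, `p`, `q`, `df_full`.
#' @export
partial_f <- function(full, reduced) {
  if (full$df_resid <= 0) stop("no residual degrees of freedom")
  q <- reduced$df_resid - full$df_resid
  if (q < 1) {
    if (isTRUE(all.equal(reduced$rss, full$rss))) {
      return(list(F = 0, p = 1, q = 0L, df_full = full$df_resid))
    }
    stop("models are not nested (df difference < 1)")
  }
  num <- max(reduced$rss - full$rss, 0)
  Fstat <- (num / q) / (full$rss / full$df_resid)
  list(F = Fstat, p = stats::pf(Fstat, q, full$df_resid, lower.tail = FALSE),
       q = q, df_full = full$df_resid)
}

#' Dataset-wide paired EWAS
#'
#' Applies the preterm exclusion, fetches each CpG's assigned mQTL
#' dosage from the database (when present among the genotypes), and
#' fits the paired models CpG by CpG. Partial F-tests of the mQTL term
#' are computed for CpGs with an mQTL covariate.
#'
#' @param meth a [methylation_matrix()].
#' @param samples a validated sample table.
#' @param db an `mqtl_db` from [build_database()], or `NULL` to fit
#'   plain models only.
#' @param geno a [genotype_matrix()] supplying mQTL dosages.
#' @param cpg_ids CpGs to fit (default: all columns of `meth`).
#' @return list of class `ewas_fit` with elements `mqtl` and `plain`
#'   (stacked `ewas_record` data.frames), `partial_f` (per-CpG F and
#'   P for CpGs with an mQTL), and `n_excluded` (preterm samples
#'   removed).
#' @export
ewas_dataset <- function(meth, samples, db = NULL, geno = NULL,
                         cpg_ids = NULL) {
  stopifnot(inherits(meth, "methylation_matrix"))
  samples <- exclude_preterm(samples)
  n_excl <- attr(samples, "n_excluded")
  ids <- samples$sample_id
  B <- meth$betas[ids, , drop = FALSE]
  if (is.null(cpg_ids)) cpg_ids <- colnames(B)

  assign_map <- NULL
  if (!is.null(db)) {
    top <- assigned_mqtls(db)
    assign_map <- top$snp_id[match(cpg_ids, top$cpg_id)]
  }
  G <- if (!is.null(geno)) geno$dosages[ids, , drop = FALSE]

  Xp <- ewas_design(samples)
  qp <- qr(Xp)
  mq_rows <- vector("list", length(cpg_ids))
  pl_rows <- vector("list", length(cpg_ids))
  pf_rows <- vector("list", length(cpg_ids))
  for (k in seq_along(cpg_ids)) {
    cg <- cpg_ids[k]
    y <- B[, cg]
    fit_plain <- ols_fit(Xp, y)
    pl_rows[[k]] <- ewas_record(cg, "plain", fit_plain)
    snp <- if (!is.null(assign_map)) assign_map[k] else NA_character_
    if (!is.na(snp) && !is.null(G) && snp %in% colnames(G)) {
      g <- G[, snp]
      if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
      fit_full <- ols_fit(cbind(Xp, mqtl = g), y)
      mq_rows[[k]] <- ewas_record(cg, "mqtl", fit_full, snp)
      pf <- partial_f(mq_rows[[k]], pl_rows[[k]])
      pf_rows[[k]] <- data.frame(cpg_id = cg, partial_F = pf$F,
                                 partial_F_p = pf$p,
                                 stringsAsFactors = FALSE)
    } else {
      mq_rows[[k]] <- ewas_record(cg, "mqtl", fit_plain)
    }
  }
  structure(list(mqtl = do.call(rbind, mq_rows),
                 plain = do.call(rbind, pl_rows),
                 partial_f = do.call(rbind,
                                     pf_rows[!vapply(pf_rows, is.null,
                                                     logical(1))]),
                 n_excluded = n_excl),
            class = "ewas_fit")
}

#' @export
print.ewas_fit <- function(x, ...) {
  cat(sprintf("ewas_fit: %d CpGs, %d with an mQTL covariate, %d preterm sample(s) excluded\n",
              nrow(x$plain), sum(!is.na(x$mqtl$mqtl_snp_id)),
              x$n_excluded))
  invisible(x)
}

#' Meta-analyze per-dataset EWAS tables on one platform
#'
#' Per-CpG inverse-variance pooling of the birthweight coefficient
#' across datasets, Bonferroni threshold `alpha / m` where `m` is the
#' number of CpGs pooled on the platform.
#'
#' @param tables list of stacked `ewas_record` data.frames (one per
#'   dataset, same model).
#' @param platform platform tag.
#' @param alpha family-wise error rate for Bonferroni (default 0.05).
#' @return data.frame of class `ewas_meta`: per CpG `beta_bw`, `se`,
#'   `z`, `p`, `log10_p`, `direction`, `n_datasets`, `significant`;
#'   attributes `bonferroni` (threshold) and `platform`.
#' @export
meta_ewas <- function(tables, platform = "K450", alpha = 0.05) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- paste0("dataset", seq_along(tables))
  labs <- names(tables)
  all <- do.call(rbind, lapply(labs, function(l) {
    t <- tables[[l]]
    data.frame(cpg_id = t$cpg_id, beta = t$beta_bw, se = t$se,
               dataset = l, stringsAsFactors = FALSE)
  }))
  rows <- lapply(split(seq_len(nrow(all)), all$cpg_id), function(grp) {
    g <- all[grp, , drop = FALSE]
    mm <- inverse_variance_meta(g$beta, g$se)
    dir <- rep("?", length(labs))
    dir[match(g$dataset, labs)] <- ifelse(g$beta >= 0, "+", "-")
    data.frame(cpg_id = g$cpg_id[1], beta_bw = mm$beta, se = mm$se,
               z = mm$z, p = mm$p, log10_p = mm$log10_p,
               direction = paste(dir, collapse = ""),
               n_datasets = mm$n_datasets, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  thr <- alpha / nrow(out)
  out$significant <- out$p < thr
  attr(out, "bonferroni") <- thr
  attr(out, "platform") <- platform
  class(out) <- c("ewas_meta", "data.frame")
  out
}

#' @export
print.ewas_meta <- function(x, ...) {
  cat(sprintf(
    "ewas_meta (%s): %d CpGs, %d significant at Bonferroni P < %.3g\n",
    attr(x, "platform") %||% "?", nrow(x), sum(x$significant),
    attr(x, "bonferroni")))
  invisible(x)
}

#' Compare mQTL-model and plain-model EWAS results per CpG
#'
#' For every CpG present in both tables, computes the relative change
#' of the birthweight coefficient
#' `(beta_mqtl - beta_plain) / |beta_plain|`, flags changes above
#' `change_min` in either direction, and flags CpGs whose P value is
#' strictly smaller in the mQTL model. When both tables are meta-level
#' (carry a `significant` flag) the gain/loss of Bonferroni
#' significance is counted. Optionally appends Benjamini-Hochberg FDR
#' values for both models.
#'
#' @param mqtl_table,plain_table data.frames with `cpg_id`, a
#'   birthweight coefficient column (`beta_bw`) and `p`.
#' @param change_min relative-change threshold (default 0.20).
#' @param fdr append BH-adjusted P columns?
#' @return data.frame of class `ewas_comparison` with a `summary`
#'   attribute (`fraction_more_significant`, `fraction_changed`,
#'   `n_gained`, `n_lost`).
#' @export
compare_models <- function(mqtl_table, plain_table, change_min = 0.20,
                           fdr = FALSE) {
  shared <- intersect(mqtl_table$cpg_id, plain_table$cpg_id)
  im <- match(shared, mqtl_table$cpg_id)
  ip <- match(shared, plain_table$cpg_id)
  bm <- mqtl_table$beta_bw[im]; bp <- plain_table$beta_bw[ip]
  pm <- mqtl_table$p[im]; pp <- plain_table$p[ip]
  rel <- ifelse(bp != 0, (bm - bp) / abs(bp), NA_real_)
  out <- data.frame(cpg_id = shared,
                    beta_mqtl = bm, beta_plain = bp,
                    p_mqtl = pm, p_plain = pp,
                    rel_change = rel,
                    changed_gt_20pct = !is.na(rel) & abs(rel) > change_min,
                    more_significant_with_mqtl = pm < pp,
                    stringsAsFactors = FALSE)
  if ("partial_F" %in% names(mqtl_table)) {
    out$partial_F <- mqtl_table$partial_F[im]
    out$partial_F_p <- mqtl_table$partial_F_p[im]
  }
  if (fdr) {
    out$fdr_mqtl <- stats::p.adjust(pm, "BH")
    out$fdr_plain <- stats::p.adjust(pp, "BH")
  }
  n_gained <- n_lost <- NA_integer_
  if ("significant" %in% names(mqtl_table) &&
      "significant" %in% names(plain_table)) {
    sm <- mqtl_table$significant[im]; sp <- plain_table$significant[ip]
    n_gained <- sum(sm & !sp)
    n_lost <- sum(!sm & sp)
  }
  attr(out, "summary") <- list(
    fraction_more_significant = mean(out$more_significant_with_mqtl),
    fraction_changed = mean(out$changed_gt_20pct[!is.na(rel)]),
    n_gained = n_gained, n_lost = n_lost)
  class(out) <- c("ewas_comparison", "data.frame")
  out
}

#' @export
print.ewas_comparison <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("ewas_comparison: %d CpGs; %.1f%% more significant ",
                     "with the mQTL covariate; %.1f%% changed effect size ",
                     "by > 20%%\n"),
              nrow(x), 100 * s$fraction_more_significant,
              100 * s$fraction_changed))
  if (!is.na(s$n_gained))
    cat(sprintf("  gained Bonferroni significance: %d; lost: %d\n",
                s$n_gained, s$n_lost))
  invisible(x)
}

#' @export
summary.ewas_comparison <- function(object, ...) {
  attr(object, "summary")
}

#' Sensitivity EWAS model with maternal weight gain
#'
#' The mQTL-model design plus maternal weight gain. Rows with missing
#' maternal weight gain are dropped (their count is attached); the
#' column must be observed for at least `min_present` of the samples.
#'
#' @param y methylation beta vector.
#' @param samples matching sample table (preterm already excluded).
#' @param mqtl_dosage assigned-mQTL dosage or `NULL`.
#' @param cpg_id,mqtl_snp_id identifiers for the record.
#' @param min_present minimum fraction of non-missing maternal weight
#'   gain (default 0.95).
#' @return one-row `ewas_record` (model `"sensitivity"`) with
#'   attribute `n_dropped`.
#' @export
sensitivity_fit <- function(y, samples, mqtl_dosage = NULL,
                            cpg_id = "cpg", mqtl_snp_id = NA_character_,
                            min_present = 0.95) {
  if (!"maternal_weight_gain" %in% names(samples))
    stop("maternal_weight_gain column is missing")
  mwg <- samples$maternal_weight_gain
  if (all(is.na(mwg))) stop("maternal_weight_gain is entirely missing")
  present <- mean(!is.na(mwg))
  if (present < min_present)
    stop(sprintf("maternal_weight_gain observed for only %.1f%% of samples",
                 100 * present))
  keep <- !is.na(mwg)
  samples <- samples[keep, , drop = FALSE]
  y <- y[keep]
  if (!is.null(mqtl_dosage)) mqtl_dosage <- mqtl_dosage[keep]
  X <- ewas_design(samples, mqtl_dosage, maternal_weight_gain = TRUE)
  rec <- ewas_record(cpg_id, "sensitivity", ols_fit(X, y), mqtl_snp_id)
  attr(rec, "n_dropped") <- sum(!keep)
  rec
}
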