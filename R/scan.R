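# Per-CpG cis-mQTL discovery. The scan residualizes methylation and
# dosages on the covariates once (Frisch-Waugh), screens every variant
# in the cis window, and calibrates the top association by permuting
# the residualized phenotype: the minimum nominal P across the window
# is recomputed for each permutation and a Beta(a, b) distribution is
# fitted to the permutation minima by maximum likelihood; the adjusted
# P value is the fitted-beta CDF at the observed top nominal P.

#' Variants in the cis window of a CpG
#'
#' The window is a total span (default 2 Mb flanking the CpG, i.e.
#' +/- 1 Mb): a variant is cis iff it is on the CpG's chromosome and
#' `|pos_snp - pos_cpg| <= window_bp / 2`. Implemented by binary search
#' over the position-sorted variant table.
#'
#' @param cpg one-row data.frame (or list) with `chrom` and `pos`.
#' @param variants variant data.frame sorted by `(chrom, pos)`.
#' @param window_bp total window span in bp (default 2e6).
#' @return integer indices into `variants` (possibly empty).
#' @export
cis_window <- function(cpg, variants, window_bp = 2e6) {
  half <- window_bp / 2
  on_chr <- which(variants$chrom == cpg$chrom)
  if (!length(on_chr)) return(integer(0))
  pos <- variants$pos[on_chr]
  lo <- findInterval(cpg$pos - half, pos, left.open = TRUE) + 1L
  hi <- findInterval(cpg$pos + half, pos)
  if (lo > hi) return(integer(0))
  on_chr[lo:hi]
}

#' Covariate-adjusted marginal association of methylation with dosage
#'
#' OLS of `y` on `[1, dosage, covariates]`; returns the dosage
#' coefficient with its standard error and two-sided t-test P value.
#'
#' @param y methylation vector.
#' @param dosage genotype dosage vector (non-constant).
#' @param covariates optional covariate matrix (no intercept column).
#' @return list with `beta`, `se`, `t`, `p`, `df`, `n`.
#' @export
marginal_fit <- function(y, dosage, covariates = NULL) {
  if (stats::var(dosage) == 0) stop("degenerate predictor: constant dosage")
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- ols_fit(X, y)
  list(beta = unname(fit$coef[2]), se = unname(fit$se[2]),
       t = unname(fit$t[2]), p = unname(fit$p[2]),
       df = fit$df, n = fit$n)
}

#' Fit a beta distribution to permutation P values by maximum likelihood
#'
#' Method-of-moments start, Newton iterations on the score equations
#' (tolerance 1e-8, at most `max_iter` iterations); on non-convergence
#' the method-of-moments estimate is returned with `converged = FALSE`.
#' Values are clamped to `[1e-12, 1 - 1e-12]`; exact zeros or ones
#' (degenerate perfect fits) are excluded beforehand by the caller.
#'
#' @param p vector of P values in (0, 1).
#' @param max_iter Newton iteration cap (default 100).
#' @param tol convergence tolerance on the parameter step (default 1e-8).
#' @return list with `shape1`, `shape2`, `converged`, `n_iter`.
#' @export
fit_beta_perm <- function(p, max_iter = 100L, tol = 1e-8) {
  p <- p[is.finite(p)]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  n <- length(p)
  if (n < 10) stop("need at least 10 permutation P values")
  m <- mean(p); v <- stats::var(p)
  v <- max(v, 1e-12)
  common <- m * (1 - m) / v - 1
  a <- max(m * common, 1e-3)
  b <- max((1 - m) * common, 1e-3)
  mom <- c(a, b)
  s1 <- mean(log(p)); s2 <- mean(log1p(-p))
  th <- mom
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    dg <- digamma(sum(th))
    grad <- c(dg - digamma(th[1]) + s1,
              dg - digamma(th[2]) + s2)
    tg <- trigamma(sum(th))
    H <- matrix(c(tg - trigamma(th[1]), tg,
                  tg, tg - trigamma(th[2])), 2, 2)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    new <- th - step
    halvings <- 0L
    while (any(new <= 0) && halvings < 30L) {
      step <- step / 2
      new <- th - step
      halvings <- halvings + 1L
    }
    if (any(new <= 0)) break
    if (max(abs(new - th)) < tol) {
      th <- new
      converged <- TRUE
      break
    }
    th <- new
  }
  if (!converged) th <- mom
  list(shape1 = th[1], shape2 = th[2], converged = converged, n_iter = it)
}

# Workhorse on residualized data. yr: residualized methylation; Gr:
# residualized dosage matrix restricted to the cis window; df: residual
# df of the full design (n - rank(covariates) - 1).
#' @keywords internal
scan_cpg_core <- function(yr, Gr, df, n_perm, seed, snp_pos, snp_id,
                          cpg_pos) {
  n <- length(yr)
  xnorm <- sqrt(colSums(Gr^2))
  ok <- xnorm > 1e-10
  if (!any(ok)) return(NULL)
  Gr <- Gr[, ok, drop = FALSE]
  xnorm <- xnorm[ok]
  snp_pos <- snp_pos[ok]; snp_id <- snp_id[ok]
  ynorm <- sqrt(sum(yr^2))
  if (ynorm <= 1e-12) return(NULL)
  Xu <- sweep(Gr, 2, xnorm, "/")
  r <- as.vector(crossprod(Xu, yr)) / ynorm
  r <- pmin(pmax(r, -1), 1)
  r2c <- pmax(1 - r^2, 0)
  tval <- ifelse(r2c > 0, r * sqrt(df) / sqrt(r2c),
                 sign(r) * Inf)
  pnom <- ifelse(is.finite(tval), 2 * stats::pt(-abs(tval), df),
                 0)
  ord <- order(pnom, abs(snp_pos - cpg_pos), snp_id)
  top <- ord[1]
  beta <- as.vector(crossprod(Gr[, top], yr)) / xnorm[top]^2
  rss <- sum(yr^2) * r2c[top]
  se <- if (rss > 0) sqrt(rss / df) / xnorm[top] else 0

  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  Yp <- matrix(yr[perm_idx], n, n_perm)
  Rp <- crossprod(Xu, Yp) / ynorm # K x n_perm
  rmax <- apply(abs(Rp), 2, max)
  rmax <- pmin(rmax, 1)
  t_perm <- ifelse(rmax < 1, rmax * sqrt(df) / sqrt(1 - rmax^2), Inf)
  p_min <- ifelse(is.finite(t_perm), 2 * stats::pt(-t_perm, df), 0)

  emp_p <- (1 + sum(p_min <= pnom[top])) / (n_perm + 1)
  usable <- p_min > 0 & p_min < 1
  bf <- fit_beta_perm(p_min[usable])
  adj_p <- stats::pbeta(pnom[top], bf$shape1, bf$shape2)

  list(snp_id = snp_id[top], beta = beta, se = se,
       nominal_p = pnom[top], adjusted_p = adj_p, empirical_p = emp_p,
       beta_shape1 = bf$shape1, beta_shape2 = bf$shape2,
       converged = bf$converged, n_cis = ncol(Gr), n = n,
       perm_minima = p_min)
}

#' Permutation-calibrated cis-mQTL scan for one CpG
#'
#' Residualizes methylation and each cis dosage on the covariates
#' (numerically equivalent to [marginal_fit()] on the full design),
#' selects the variant with the smallest nominal P (ties broken by
#' distance to the CpG, then variant id), permutes the residualized
#' methylation `n_perm` times to obtain the null distribution of the
#' window minimum P, fits `Beta(a, b)` to the minima and reports
#' `adjusted_p = pbeta(nominal_p_top, a, b)` together with the
#' empirical permutation P `(1 + #{minima <= top}) / (n_perm + 1)`.
#'
#' @param y methylation vector.
#' @param cis_dosages dosage matrix for the cis variants (columns named
#'   by variant id), missing values mean-imputed beforehand.
#' @param cis_variants data.frame with `id` and `pos` for the columns
#'   of `cis_dosages`.
#' @param cpg one-row data.frame/list with `id` and `pos`.
#' @param covariates covariate matrix (no intercept), or `NULL`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return one-row data.frame (`mqtl_record`): `cpg_id`, `snp_id`,
#'   `beta`, `se`, `nominal_p`, `adjusted_p`, `empirical_p`,
#'   `beta_shape1`, `beta_shape2`, `converged`, `n_cis`, `n`; the
#'   permutation minima are attached as attribute `perm_minima`.
#' @export
scan_cpg <- function(y, cis_dosages, cis_variants, cpg, covariates = NULL,
                     n_perm = 1000L, seed = 1L) {
  cis_dosages <- as.matrix(cis_dosages)
  n <- length(y)
  Z <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qz <- qr(Z)
  yr <- qr.resid(qz, y)
  Gr <- qr.resid(qz, cis_dosages)
  df <- n - qz$rank - 1L
  if (df <= 0) stop("not enough samples for the covariate design")
  core <- scan_cpg_core(yr, Gr, df, n_perm, seed,
                        snp_pos = cis_variants$pos,
                        snp_id = cis_variants$id, cpg_pos = cpg$pos)
  if (is.null(core)) stop("no usable (non-constant) cis variants")
  rec <- data.frame(cpg_id = cpg$id, snp_id = core$snp_id,
                    beta = core$beta, se = core$se,
                    nominal_p = core$nominal_p,
                    adjusted_p = core$adjusted_p,
                    empirical_p = core$empirical_p,
                    beta_shape1 = core$beta_shape1,
                    beta_shape2 = core$beta_shape2,
                    converged = core$converged,
                    n_cis = core$n_cis, n = core$n,
                    stringsAsFactors = FALSE)
  attr(rec, "perm_minima") <- core$perm_minima
  rec
}

#' Scan covariates used for mQTL discovery
#'
#' Sex, methylation batch and the first five genetic principal
#' components (the EWAS stage uses a different, richer covariate set).
#'
#' @param samples a validated sample table.
#' @return numeric covariate matrix without intercept.
#' @export
scan_covariates <- function(samples) {
  mm <- stats::model.matrix(~ sex + batch + pc1 + pc2 + pc3 + pc4 + pc5,
                            data = samples)
  mm[, -1, drop = FALSE]
}

#' Dataset-wide cis-mQTL scan
#'
#' Applies the CpG pre-filters (sex-chromosome CpGs; CpGs overlapping a
#' variant with MAF > 0.05 at the CpG position or position + 1),
#' mean-imputes missing dosages, residualizes methylation and dosages
#' on the scan covariates once, and runs [scan_cpg()] per CpG. Each
#' CpG's permutation stream is seeded by a stable hash of
#' `(seed, cpg_id)`, so results do not depend on scan order.
#'
#' @param meth a [methylation_matrix()].
#' @param geno a [genotype_matrix()] (QC'd).
#' @param samples a validated sample table; sample ids must match the
#'   row names of the methylation and genotype matrices.
#' @param window_bp total cis window span (default 2e6).
#' @param n_perm permutations per CpG (default 1000).
#' @param seed global integer seed.
#' @param snp_overlap_maf MAF threshold for the CpG-overlaps-SNP filter
#'   (default 0.05).
#' @param verbose log progress every 1000 CpGs.
#' @return data.frame of class `mqtl_scan`, one row per scanned CpG,
#'   with a `significant` flag (`adjusted_p < 0.05`), allele and
#'   position columns for downstream meta-analysis, and an attribute
#'   `skipped` (data.frame of CpG id + reason).
#' @export
scan_dataset <- function(meth, geno, samples, window_bp = 2e6,
                         n_perm = 1000L, seed = 1L,
                         snp_overlap_maf = 0.05, verbose = FALSE) {
  stopifnot(inherits(meth, "methylation_matrix"),
            inherits(geno, "genotype_matrix"))
  ids <- samples$sample_id
  bad <- setdiff(ids, intersect(rownames(meth$betas), rownames(geno$dosages)))
  if (length(bad))
    stop("samples absent from methylation or genotype data: ",
         paste(utils::head(bad, 5), collapse = ", "))
  B <- meth$betas[ids, , drop = FALSE]
  G <- geno$dosages[ids, , drop = FALSE]
  # mean-impute residual missing dosages per variant
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }

  cpgs <- meth$cpgs
  skip <- character(0); skip_why <- character(0)
  sexchr <- cpgs$chrom %in% c("chrX", "chrY", "X", "Y")
  overl <- overlaps_common_snp(cpgs, geno$variants, snp_overlap_maf)
  drop <- sexchr | overl
  if (any(drop)) {
    skip <- cpgs$id[drop]
    skip_why <- ifelse(sexchr[drop], "sex chromosome", "overlaps common SNP")
  }
  keep_idx <- which(!drop)

  Z <- scan_covariates(samples)
  qz <- qr(cbind(1, Z))
  df <- length(ids) - qz$rank - 1L
  if (df <= 0) stop("not enough samples for the scan covariates")
  Br <- qr.resid(qz, B[, keep_idx, drop = FALSE])
  Gr <- qr.resid(qz, G)

  rows <- vector("list", length(keep_idx))
  for (k in seq_along(keep_idx)) {
    j <- keep_idx[k]
    win <- cis_window(cpgs[j, ], geno$variants, window_bp)
    if (!length(win)) {
      skip <- c(skip, cpgs$id[j]); skip_why <- c(skip_why, "no cis variants")
      next
    }
    core <- scan_cpg_core(Br[, k], Gr[, win, drop = FALSE], df, n_perm,
                          seed = hash_seed(seed, cpgs$id[j]),
                          snp_pos = geno$variants$pos[win],
                          snp_id = geno$variants$id[win],
                          cpg_pos = cpgs$pos[j])
    if (is.null(core)) {
      skip <- c(skip, cpgs$id[j])
      skip_why <- c(skip_why, "no usable cis variants")
      next
    }
    core$perm_minima <- NULL
    rows[[k]] <- data.frame(cpg_id = cpgs$id[j], core,
                            stringsAsFactors = FALSE)
    if (verbose && k %% 1000 == 0)
      msg("scanned %d / %d CpGs", k, length(keep_idx))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cpg_id = character(0), snp_id = character(0),
                      beta = numeric(0), se = numeric(0),
                      nominal_p = numeric(0), adjusted_p = numeric(0),
                      empirical_p = numeric(0), beta_shape1 = numeric(0),
                      beta_shape2 = numeric(0), converged = logical(0),
                      n_cis = integer(0), n = integer(0),
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$adjusted_p < 0.05
  vi <- match(out$snp_id, geno$variants$id)
  out$snp_chrom <- geno$variants$chrom[vi]
  out$snp_pos <- geno$variants$pos[vi]
  out$effect_allele <- geno$variants$effect_allele[vi]
  out$other_allele <- geno$variants$other_allele[vi]
  out$snp_maf <- geno$variants$maf[vi]
  ci <- match(out$cpg_id, cpgs$id)
  out$cpg_chrom <- cpgs$chrom[ci]
  out$cpg_pos <- cpgs$pos[ci]
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(cpg_id = skip, reason = skip_why,
                                     stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("mqtl_scan", "data.frame")
  out
}

#' @keywords internal
overlaps_common_snp <- function(cpgs, variants, maf_min = 0.05) {
  common <- variants[variants$maf > maf_min, , drop = FALSE]
  if (!nrow(common)) return(rep(FALSE, nrow(cpgs)))
  key <- paste(common$chrom, common$pos)
  paste(cpgs$chrom, cpgs$pos) %in% key |
    paste(cpgs$chrom, cpgs$pos + 1L) %in% key
}

#' @export
print.mqtl_scan <- function(x, ...) {
  cat(sprintf("mqtl_scan: %d CpGs scanned, %d significant (adjusted P < 0.05)\n",
              nrow(x), sum(x$significant)))
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk)) cat(sprintf("  %d CpGs skipped\n", nrow(sk)))
  invisible(x)
}

#' @export
summary.mqtl_scan <- function(object, ...) {
  structure(list(n_cpgs = nrow(object),
                 n_significant = sum(object$significant),
                 median_n_cis = stats::median(object$n_cis),
                 n_skipped = nrow(attr(object, "skipped") %||%
                                    data.frame())),
            class = "summary.mqtl_scan")
}

#' @export
print.summary.mqtl_scan <- function(x, ...) {
  cat(sprintf(paste0("cis-mQTL scan: %d CpGs (%d skipped), ",
                     "%d with adjusted P < 0.05; median cis window size %s\n"),
              x$n_cpgs, x$n_skipped, x$n_significant, x$median_n_cis))
  invisible(x)
}
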