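test_that("inverse-variance pooling matches the printed examples", {
  m <- inverse_variance_meta(c(2, 4), c(1, 1))
  expect_equal(m$beta, 3)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-12)
  # single study passes through unchanged
  one <- inverse_variance_meta(0.37, 0.21)
  expect_equal(one$beta, 0.37)
  expect_equal(one$se, 0.21)
  # k identical studies: pooled se = s / sqrt(k)
  k <- 7
  mk <- inverse_variance_meta(rep(0.5, k), rep(0.3, k))
  expect_equal(mk$beta, 0.5, tolerance = 1e-12)
  expect_equal(mk$se, 0.3 / sqrt(k), tolerance = 1e-12)
  expect_error(inverse_variance_meta(c(1, 2), c(1, 0)), "> 0")
})

test_that("pooling matches an independent fixed-effects fitter", {
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    beta <- rnorm(k)
    se <- runif(k, 0.05, 0.5)
    got <- inverse_variance_meta(beta, se)
    ref <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(got$beta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(got$se, as.numeric(ref$se), tolerance = 1e-10)
    expect_equal(got$p, as.numeric(ref$pval), tolerance = 1e-10)
  }
})

test_that("pooling is invariant to input order and |z| is consistent", {
  set.seed(3)
  beta <- rnorm(5); se <- runif(5, 0.1, 1)
  a <- inverse_variance_meta(beta, se)
  o <- sample(5)
  b <- inverse_variance_meta(beta[o], se[o])
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_equal(abs(a$z), abs(a$beta) / a$se, tolerance = 1e-12)
})

test_that("extreme z keeps a finite log10 P", {
  m <- inverse_variance_meta(5, 1e-12)
  expect_equal(m$p, 0) # below double underflow
  expect_true(is.finite(m$log10_p) && m$log10_p < -1e10 * 0)
  expect_lt(m$log10_p, -300)
})

test_that("allele harmonization flips, keeps and drops correctly", {
  rec <- data.frame(
    cpg_id = "cg1", snp_id = "s1",
    beta = c(0.1, -0.1, 0.1),
    effect_allele = c("G", "C", "G"), other_allele = c("C", "G", "C"),
    snp_maf = 0.2, dataset = c("d1", "d2", "d3"),
    stringsAsFactors = FALSE)
  out <- harmonize_alleles(rec)
  expect_equal(out$beta, c(0.1, 0.1, 0.1))
  expect_true(all(out$effect_allele == "G"))

  # ambiguous A/T at MAF 0.45 dropped
  amb <- data.frame(cpg_id = "cg1", snp_id = "s2", beta = 0.2,
                    effect_allele = "A", other_allele = "T",
                    snp_maf = 0.45, dataset = "d1",
                    stringsAsFactors = FALSE)
  out2 <- harmonize_alleles(rbind(rec, amb))
  expect_false("s2" %in% out2$snp_id)
  expect_equal(unname(attr(out2, "dropped")["ambiguous"]), 1L)

  # irreconcilable alleles dropped
  bad <- rec
  bad$effect_allele[2] <- "T"; bad$other_allele[2] <- "A"
  bad$snp_maf <- 0.2
  out3 <- harmonize_alleles(bad)
  expect_equal(nrow(out3), 2L)
  expect_equal(unname(attr(out3, "dropped")["irreconcilable"]), 1L)
})

test_that("the database ranks pairs by meta P within CpG and assigns the top SNP", {
  mk <- function(cpg, snp, beta, se, adj, pos_snp) {
    data.frame(cpg_id = cpg, snp_id = snp, beta = beta, se = se,
               nominal_p = 1e-6, adjusted_p = adj, empirical_p = adj,
               beta_shape1 = 1, beta_shape2 = 10, converged = TRUE,
               n_cis = 10L, n = 100L, significant = adj < 0.05,
               snp_chrom = "chr1", snp_pos = pos_snp,
               effect_allele = "G", other_allele = "A", snp_maf = 0.3,
               cpg_chrom = "chr1", cpg_pos = 5000L,
               stringsAsFactors = FALSE)
  }
  # snpX seen in both datasets (meta P stronger), snpY in one only
  d1 <- rbind(mk("cg1", "snpX", 0.10, 0.02, 0.01, 4000L),
              mk("cg1", "snpY", 0.08, 0.03, 0.02, 6000L))
  d2 <- mk("cg1", "snpX", 0.11, 0.02, 0.015, 4000L)
  db <- build_database(list(A = d1, B = d2), platform = "K450")
  expect_s3_class(db, "mqtl_db")
  expect_equal(nrow(db), 2L) # distinct pairs
  top <- assigned_mqtls(db)
  expect_equal(top$snp_id, "snpX")
  expect_equal(top$n_datasets, 2L)
  expect_equal(top$direction, "++")
  ranked <- db[db$cpg_id == "cg1", ]
  expect_equal(ranked$rank, c(1L, 2L))
  expect_true(all(diff(ranked$p) >= 0))
  # snpY carries its single dataset's stats
  y <- db[db$snp_id == "snpY", ]
  expect_equal(y$pooled_beta, 0.08)
  expect_equal(y$pooled_se, 0.03)
  expect_equal(y$direction, "+?")

  # one dataset only: database = that table re-sorted
  db1 <- build_database(list(A = d1), platform = "K450")
  expect_equal(nrow(db1), 2L)
  expect_equal(db1$pooled_beta, d1$beta[order(d1$nominal_p)])

  # non-significant rows are excluded
  d3 <- mk("cg2", "snpZ", 0.2, 0.05, 0.2, 1000L)
  db2 <- build_database(list(A = rbind(d1, d3)))
  expect_false("cg2" %in% db2$cpg_id)
})

test_that("ld_r2 is the squared dosage correlation, sign-invariant", {
  set.seed(6)
  a <- rbinom(200, 2, 0.4)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  b <- rbinom(1000, 2, 0.4)
  a2 <- rbinom(1000, 2, 0.4)
  expect_lt(ld_r2(a2, b), 0.01)
  expect_error(ld_r2(a, rep(2, 200)), "constant")
})

test_that("concordance counts same-SNP, in-LD and untestable CpGs", {
  cohort <- get_small_cohort()
  scan <- scan_dataset(cohort$LAT$methylation, cohort$LAT$genotypes,
                       cohort$LAT$samples, n_perm = 100L, seed = 2L)
  db <- build_database(list(LAT = scan), platform = "SIM")
  # identical databases: everything same-SNP
  cc <- concordance(db, db, cohort$LAT$genotypes)
  expect_equal(unname(cc$counts["same_snp"]), unname(cc$counts["shared"]))
  expect_equal(unname(cc$counts["in_ld"]), 0L)

  # swap each assigned SNP for a perfect proxy (duplicated dosage column)
  g <- cohort$LAT$genotypes
  top <- assigned_mqtls(db)
  proxy_ids <- paste0(top$snp_id, "_proxy")
  d2 <- cbind(g$dosages, g$dosages[, top$snp_id, drop = FALSE])
  colnames(d2) <- c(colnames(g$dosages), proxy_ids)
  v2 <- rbind(g$variants,
              transform(g$variants[match(top$snp_id, g$variants$id), ],
                        id = proxy_ids, pos = pos + 1L))
  g2 <- genotype_matrix(d2, v2)
  db_b <- db
  db_b$snp_id <- ifelse(db_b$assigned, paste0(db_b$snp_id, "_proxy"),
                        db_b$snp_id)
  cc2 <- concordance(db, db_b, g2)
  expect_equal(unname(cc2$counts["same_snp"]), 0L)
  expect_equal(unname(cc2$counts["in_ld"]), unname(cc2$counts["shared"]))

  # SNP absent from genotypes is untestable
  db_c <- db
  db_c$snp_id[db_c$assigned][1] <- "missing_snp"
  cc3 <- concordance(db, db_c, g)
  expect_equal(unname(cc3$counts["untestable"]), 1L)
  expect_equal(unname(cc3$counts["testable"]),
               unname(cc3$counts["shared"]) - 1L)
})

test_that("meta of per-stratum fits is consistent with a pooled mega-analysis", {
  set.seed(77)
  # one homogeneous effect, two strata
  n1 <- 150; n2 <- 250
  g <- c(rbinom(n1, 2, 0.3), rbinom(n2, 2, 0.35))
  y <- 0.04 * g + rnorm(n1 + n2, 0, 0.03)
  f1 <- marginal_fit(y[1:n1], g[1:n1])
  f2 <- marginal_fit(y[(n1 + 1):(n1 + n2)], g[(n1 + 1):(n1 + n2)])
  mm <- inverse_variance_meta(c(f1$beta, f2$beta), c(f1$se, f2$se))
  pooled <- marginal_fit(y, g)
  expect_lt(abs(mm$beta - pooled$beta), 2 * pooled$se)
})
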