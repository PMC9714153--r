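test_that("cis window is the +/- 1 Mb flank with closed boundaries", {
  variants <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                         pos = c(400000L, 500000L, 2500001L),
                         stringsAsFactors = FALSE)
  cpg <- list(chrom = "chr1", pos = 1500000L)
  got <- cis_window(cpg, variants, window_bp = 2e6)
  # 500,000 is exactly 1,000,000 away (included); 400,000 and 2,500,001
  # are 1,100,000 and 1,000,001 away (excluded)
  expect_equal(variants$id[got], "b")
  # different chromosome: empty
  expect_length(cis_window(list(chrom = "chr2", pos = 1500000L), variants),
                0)
})

test_that("cis window agrees with a brute-force filter on random maps", {
  set.seed(31)
  variants <- data.frame(id = sprintf("v%05d", 1:10000),
                         chrom = sample(c("chr1", "chr2"), 10000, TRUE),
                         pos = sample.int(5e7, 10000, replace = TRUE),
                         stringsAsFactors = FALSE)
  variants <- variants[order(variants$chrom, variants$pos), ]
  for (i in 1:50) {
    cpg <- list(chrom = sample(c("chr1", "chr2"), 1),
                pos = sample.int(5e7, 1))
    got <- sort(variants$id[cis_window(cpg, variants)])
    want <- sort(variants$id[variants$chrom == cpg$chrom &
                               abs(variants$pos - cpg$pos) <= 1e6])
    expect_identical(got, want)
  }
})

test_that("marginal_fit reproduces the closed-form normal equations", {
  set.seed(7)
  for (i in 1:10) {
    n <- 200
    g <- rbinom(n, 2, 0.3)
    Z <- cbind(rnorm(n), rnorm(n))
    y <- 0.03 * g + Z %*% c(0.1, -0.2) + rnorm(n, 0, 0.05)
    fit <- marginal_fit(y, g, Z)
    X <- cbind(1, g, Z)
    bt <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% bt
    s2 <- sum(res^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(fit$beta, bt[2], tolerance = 1e-10)
    expect_equal(fit$se, se, tolerance = 1e-10)
  }
})

test_that("marginal_fit handles perfect and orthogonal fits by convention", {
  g <- c(0, 1, 2, 0, 1, 2)
  fit <- marginal_fit(0.1 * g, g)
  expect_equal(fit$beta, 0.1)
  expect_equal(fit$se, 0)
  expect_equal(fit$p, 0)

  set.seed(2)
  y0 <- rnorm(50)
  g2 <- rbinom(50, 2, 0.4)
  y_orth <- qr.resid(qr(cbind(1, g2)), y0)
  fit2 <- marginal_fit(y_orth, g2)
  expect_equal(fit2$beta, 0, tolerance = 1e-12)
  expect_equal(fit2$p, 1, tolerance = 1e-9)

  expect_error(marginal_fit(y0, rep(1, 50)), "degenerate predictor")
})

test_that("residualized fast path equals the full-design fit (Frisch-Waugh)", {
  set.seed(12)
  for (i in 1:100) {
    n <- 60
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(g) == 0) next
    Z <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    full <- marginal_fit(y, g, Z)
    rec <- scan_cpg(y, matrix(g, ncol = 1),
                    data.frame(id = "v1", pos = 1000L),
                    list(id = "cg1", pos = 1500L),
                    covariates = Z, n_perm = 20L, seed = 1L)
    expect_equal(rec$beta, full$beta, tolerance = 1e-8)
    expect_equal(rec$nominal_p, full$p, tolerance = 1e-8)
  }
})

test_that("beta-distribution MLE recovers known shapes", {
  set.seed(5)
  p <- rbeta(2000, 1.3, 40)
  fit <- fit_beta_perm(p)
  expect_true(fit$converged)
  expect_equal(fit$shape1, 1.3, tolerance = 0.15)
  expect_equal(fit$shape2, 40, tolerance = 0.15 * 40)
  # cross-check against an independent ML fitter
  ref <- fitdistrplus::fitdist(p, "beta")
  expect_equal(fit$shape1, unname(ref$estimate["shape1"]), tolerance = 1e-3)
  expect_equal(fit$shape2, unname(ref$estimate["shape2"]), tolerance = 1e-3)
})

test_that("single null cis variant gives an approximately uniform null (a = b = 1)", {
  set.seed(41)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  rec <- scan_cpg(y, matrix(g, ncol = 1),
                  data.frame(id = "v1", pos = 1000L),
                  list(id = "cg1", pos = 2000L), n_perm = 1000L, seed = 3L)
  expect_equal(rec$beta_shape1, 1, tolerance = 0.25)
  expect_equal(rec$beta_shape2, 1, tolerance = 0.25)
  expect_equal(rec$adjusted_p, rec$nominal_p, tolerance = 0.05)
})

test_that("K independent null cis variants give shape2 near K", {
  set.seed(42)
  n <- 300; K <- 50
  b2 <- replicate(8, {
    G <- matrix(rbinom(n * K, 2, 0.3), n, K)
    y <- rnorm(n)
    rec <- scan_cpg(y, G, data.frame(id = sprintf("v%02d", 1:K),
                                     pos = 1000L * (1:K)),
                    list(id = "cg1", pos = 25000L),
                    n_perm = 1000L, seed = sample.int(1e6, 1))
    rec$beta_shape2
  })
  expect_equal(median(b2), K, tolerance = 0.3 * K)
})

test_that("a planted cis effect is detected at adjusted P < 0.05", {
  set.seed(17)
  n <- 300
  K <- 30
  G <- matrix(rbinom(n * K, 2, 0.3), n, K)
  y <- 0.5 + 0.06 * G[, 7] + rnorm(n, 0, 0.02)
  rec <- scan_cpg(y, G, data.frame(id = sprintf("v%02d", 1:K),
                                   pos = 1000L * (1:K)),
                  list(id = "cg1", pos = 7100L), n_perm = 1000L, seed = 2L)
  expect_lt(rec$adjusted_p, 0.05)
  expect_equal(rec$snp_id, "v07")
  expect_lt(abs(rec$beta - 0.06), 0.01)
})

test_that("empirical and beta-approximated adjusted P agree in rank", {
  cohort <- get_small_cohort()
  scan <- scan_dataset(cohort$LAT$methylation, cohort$LAT$genotypes,
                       cohort$LAT$samples, n_perm = 300L, seed = 5L)
  expect_gt(cor(scan$adjusted_p, scan$empirical_p, method = "spearman"),
            0.95)
})

test_that("scan results are independent of CpG order (per-CpG seeding)", {
  cohort <- get_small_cohort()
  m <- cohort$NLW$methylation
  scan1 <- scan_dataset(m, cohort$NLW$genotypes, cohort$NLW$samples,
                        n_perm = 100L, seed = 9L)
  perm <- rev(seq_len(ncol(m$betas)))
  m2 <- methylation_matrix(m$betas[, perm], m$cpgs[perm, ])
  scan2 <- scan_dataset(m2, cohort$NLW$genotypes, cohort$NLW$samples,
                        n_perm = 100L, seed = 9L)
  i <- match(scan1$cpg_id, scan2$cpg_id)
  expect_identical(scan1$snp_id, scan2$snp_id[i])
  expect_equal(scan1$adjusted_p, scan2$adjusted_p[i], tolerance = 1e-12)
})

test_that("scan pre-filters drop sex-chromosome and SNP-overlapping CpGs", {
  cohort <- get_small_cohort()
  m <- cohort$NLW$methylation
  g <- cohort$NLW$genotypes
  cpgs <- m$cpgs
  cpgs$chrom[1] <- "chrX"
  # place CpG 2 exactly on a common variant
  v <- which(g$variants$maf > 0.05)[1]
  cpgs$pos[2] <- g$variants$pos[v]
  cpgs$chrom[2] <- g$variants$chrom[v]
  m2 <- methylation_matrix(m$betas, cpgs)
  scan <- scan_dataset(m2, g, cohort$NLW$samples, n_perm = 50L, seed = 1L)
  sk <- attr(scan, "skipped")
  expect_true(cpgs$id[1] %in% sk$cpg_id)
  expect_true(cpgs$id[2] %in% sk$cpg_id)
  expect_equal(sk$reason[match(cpgs$id[1], sk$cpg_id)], "sex chromosome")
  expect_equal(sk$reason[match(cpgs$id[2], sk$cpg_id)],
               "overlaps common SNP")
})

test_that("sample mismatch raises an alignment error naming offenders", {
  cohort <- get_small_cohort()
  s <- cohort$NLW$samples
  s$sample_id[1] <- "GHOST001"
  expect_error(scan_dataset(cohort$NLW$methylation, cohort$NLW$genotypes,
                            s, n_perm = 10L),
               "GHOST001")
})
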