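test_that("fit_pair without an mQTL returns identical records up to the tag", {
  set.seed(1)
  s <- make_samples(120)
  y <- runif(120, 0.3, 0.7)
  pair <- fit_pair(y, s, mqtl_dosage = NULL, cpg_id = "cg1")
  expect_equal(pair$model, c("mqtl", "plain"))
  for (col in c("beta_bw", "se", "t", "p", "rss", "df_resid", "n")) {
    expect_identical(pair[[col]][1], pair[[col]][2])
  }
})

test_that("a planted birthweight effect is recovered by both models", {
  set.seed(22)
  n <- 600
  s <- make_samples(n, seed = 4)
  b_true <- 2e-5 # beta-units per gram
  y <- 0.5 + b_true * (s$birthweight - 3400) + rnorm(n, 0, 0.02)
  y <- pmin(pmax(y, 0), 1)
  pair <- fit_pair(y, s, cpg_id = "cg1")
  for (i in 1:2) {
    expect_lt(abs(pair$beta_bw[i] - b_true), 2 * pair$se[i])
  }
})

test_that("adjusting for a strong mQTL shrinks the birthweight SE", {
  set.seed(33)
  n <- 400
  s <- make_samples(n, seed = 9)
  wins <- 0
  for (i in 1:40) {
    g <- rbinom(n, 2, 0.3)
    # SNP explains ~40% of methylation variance
    y <- 0.4 + 0.08 * g + 1.5e-5 * (s$birthweight - 3400) + rnorm(n, 0, 0.04)
    pair <- fit_pair(y, s, mqtl_dosage = g, cpg_id = "cg", mqtl_snp_id = "v")
    if (pair$se[pair$model == "mqtl"] < pair$se[pair$model == "plain"])
      wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})

test_that("the granulocyte collinearity guard trips", {
  s <- make_samples(50)
  s$cell_Gran <- pmax(0, 1 - rowSums(s[, cell_covariate_names()]))
  expect_error(ewas_design(s), "collinear")
})

test_that("partial F equals squared t for one added coefficient", {
  set.seed(8)
  for (i in 1:100) {
    n <- 80
    s <- make_samples(n, seed = i)
    g <- rbinom(n, 2, runif(1, 0.15, 0.5))
    if (var(g) == 0) next
    y <- runif(n)
    pair <- fit_pair(y, s, mqtl_dosage = g, cpg_id = "cg", mqtl_snp_id = "v")
    full <- pair[pair$model == "mqtl", ]
    red <- pair[pair$model == "plain", ]
    pf <- partial_f(full, red)
    # recompute t of the mqtl coefficient from the full design
    X <- cbind(ewas_design(s), mqtl = g)
    fit <- mqtlewas:::ols_fit(X, y)
    t_mqtl <- fit$t[length(fit$t)]
    expect_equal(pf$F, t_mqtl^2, tolerance = 1e-8)
    expect_equal(pf$q, 1L)
  }
})

test_that("identical nested models give F = 0, p = 1", {
  s <- make_samples(60)
  y <- runif(60)
  pair <- fit_pair(y, s, cpg_id = "cg")
  pf <- partial_f(pair[1, ], pair[2, ])
  expect_equal(pf$F, 0)
  expect_equal(pf$p, 1)
})

test_that("partial-F P is uniform when the added covariate is null", {
  set.seed(55)
  n <- 100
  s <- make_samples(n, seed = 13)
  X <- ewas_design(s)
  ps <- replicate(500, {
    y <- runif(n)
    g <- rbinom(n, 2, 0.3)
    full <- mqtlewas:::ols_fit(cbind(X, mqtl = g), y)
    red <- mqtlewas:::ols_fit(X, y)
    f <- ((red$rss - full$rss) / 1) / (full$rss / full$df)
    pf(f, 1, full$df, lower.tail = FALSE)
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("beta_bw is invariant to covariate column order", {
  set.seed(10)
  n <- 150
  s <- make_samples(n, seed = 20)
  g <- rbinom(n, 2, 0.3)
  y <- runif(n)
  X <- cbind(ewas_design(s), mqtl = g)
  f1 <- mqtlewas:::ols_fit(X, y)
  perm <- c(1, sample(2:ncol(X)))
  f2 <- mqtlewas:::ols_fit(X[, perm], y)
  expect_equal(unname(f1$coef["birthweight"]),
               unname(f2$coef["birthweight"]), tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
})

test_that("preterm samples are excluded with a logged count", {
  cohort <- get_small_cohort()
  s <- cohort$NLW$samples
  planted <- sum(s$gestational_age < 30)
  expect_gt(planted, 0)
  fit <- ewas_dataset(cohort$NLW$methylation, s,
                      cpg_ids = colnames(cohort$NLW$methylation$betas)[1:3])
  expect_equal(fit$n_excluded, planted)
  expect_true(all(fit$plain$n == nrow(s) - planted))
})

test_that("ewas_dataset wires assigned mQTL dosages and partial F-tests", {
  cohort <- get_small_cohort()
  scan <- scan_dataset(cohort$LAT$methylation, cohort$LAT$genotypes,
                       cohort$LAT$samples, n_perm = 100L, seed = 4L)
  db <- build_database(list(LAT = scan), platform = "SIM")
  fit <- ewas_dataset(cohort$LAT$methylation, cohort$LAT$samples,
                      db = db, geno = cohort$LAT$genotypes)
  with_q <- !is.na(fit$mqtl$mqtl_snp_id)
  expect_equal(sum(with_q), length(unique(db$cpg_id)))
  expect_equal(nrow(fit$partial_f), sum(with_q))
  expect_true(all(fit$partial_f$partial_F >= 0))
  # mqtl model has one fewer residual df where the covariate entered
  expect_true(all(fit$mqtl$df_resid[with_q] ==
                    fit$plain$df_resid[with_q] - 1L))
})

test_that("meta_ewas applies the per-platform Bonferroni threshold", {
  cohort <- get_small_cohort()
  fits <- lapply(cohort, function(x)
    ewas_dataset(x$methylation, x$samples))
  mt <- meta_ewas(lapply(fits, `[[`, "plain"), platform = "SIM")
  expect_equal(attr(mt, "bonferroni"), 0.05 / nrow(mt))
  expect_identical(mt$significant, mt$p < 0.05 / nrow(mt))
  expect_true(all(nchar(mt$direction) == 2L))
  # single dataset: meta equals input with Bonferroni applied
  m1 <- meta_ewas(list(A = fits[[1]]$plain))
  i <- match(fits[[1]]$plain$cpg_id, m1$cpg_id)
  expect_equal(m1$beta_bw[i], fits[[1]]$plain$beta_bw, tolerance = 1e-12)
  expect_equal(m1$se[i], fits[[1]]$plain$se, tolerance = 1e-12)
})

test_that("opposite planted signs cancel in the meta-analysis", {
  t1 <- data.frame(cpg_id = "cg1", beta_bw = 0.3, se = 0.1, p = 0.0027,
                   stringsAsFactors = FALSE)
  t2 <- t1; t2$beta_bw <- -0.3
  mm <- meta_ewas(list(A = t1, B = t2))
  expect_lt(abs(mm$z), abs(0.3 / 0.1))
  expect_equal(mm$beta_bw, 0)
  expect_equal(mm$direction, "+-")
})

test_that("compare_models computes relative changes and significance shifts", {
  mq <- data.frame(cpg_id = c("cg1", "cg2"), beta_bw = c(0.13, 0.10),
                   p = c(0.001, 0.5), significant = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  pl <- data.frame(cpg_id = c("cg1", "cg2"), beta_bw = c(0.10, 0.10),
                   p = c(0.01, 0.5), significant = c(FALSE, FALSE),
                   stringsAsFactors = FALSE)
  cmp <- compare_models(mq, pl)
  expect_equal(cmp$rel_change, c(0.3, 0))
  expect_identical(cmp$changed_gt_20pct, c(TRUE, FALSE))
  expect_identical(cmp$more_significant_with_mqtl, c(TRUE, FALSE))
  s <- summary(cmp)
  expect_equal(s$fraction_more_significant, 0.5)
  expect_equal(s$n_gained, 1L)
  expect_equal(s$n_lost, 0L)

  # identical tables: no changes, ties are not "more significant"
  cmp0 <- compare_models(pl, pl)
  expect_true(all(cmp0$rel_change == 0))
  expect_false(any(cmp0$more_significant_with_mqtl))

  # zero plain beta: flags undefined and excluded from the fraction
  pl0 <- pl; pl0$beta_bw[2] <- 0
  cmp1 <- compare_models(mq, pl0)
  expect_true(is.na(cmp1$rel_change[2]))
})

test_that("sensitivity model drops missing weight gain and degrades gracefully", {
  set.seed(3)
  n <- 200
  s <- make_samples(n, seed = 30)
  y <- runif(n)
  s2 <- s
  s2$maternal_weight_gain[1:5] <- NA
  rec <- sensitivity_fit(y, s2, cpg_id = "cg")
  expect_equal(attr(rec, "n_dropped"), 5L)
  expect_equal(rec$n, n - 5L)

  # constant weight gain: column dropped with a warning, fit equals mqtl model
  s3 <- s
  s3$maternal_weight_gain <- 0
  g <- rbinom(n, 2, 0.3)
  expect_warning(rec3 <- sensitivity_fit(y, s3, mqtl_dosage = g,
                                         cpg_id = "cg"),
                 "constant")
  ref <- fit_pair(y, s3, mqtl_dosage = g, cpg_id = "cg")
  expect_equal(rec3$beta_bw, ref$beta_bw[ref$model == "mqtl"],
               tolerance = 1e-12)

  s4 <- s
  s4$maternal_weight_gain <- NULL
  expect_error(sensitivity_fit(y, s4), "missing")
  s5 <- s
  s5$maternal_weight_gain[1:50] <- NA
  expect_error(sensitivity_fit(y, s5), "only")
})

test_that("independent maternal weight gain barely moves the estimate", {
  set.seed(44)
  n <- 300
  s <- make_samples(n, seed = 50)
  ok <- 0
  for (i in 1:40) {
    y <- 0.5 + 2e-5 * (s$birthweight - 3400) + rnorm(n, 0, 0.02)
    pair <- fit_pair(y, s, cpg_id = "cg")
    rec <- sensitivity_fit(y, s, cpg_id = "cg")
    mq <- pair[pair$model == "mqtl", ]
    if (abs(rec$beta_bw - mq$beta_bw) < 0.5 * mq$se) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.95)
})
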