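# Synthetic multi-stratum cohort generator. Plants known cis-mQTL,
# birthweight and nuisance (batch / sex / cell-composition) effects so
# every downstream stage can be validated against a truth table.

#' Simulation configuration
#'
#' Defaults describe a two-stratum newborn cohort on one synthetic
#' chromosome: a smaller NLW stratum and a larger LAT stratum (the LAT
#' group is larger, as in admixed-population birth cohorts), biallelic
#' variants in LD blocks, and beta-value methylation with planted
#' additive cis effects.
#'
#' @param n_samples named integer vector, samples per stratum.
#' @param n_variants number of variants on the simulated chromosome.
#' @param n_cpgs number of CpGs.
#' @param chrom_length chromosome length in bp.
#' @param maf_range named list of `[low, high]` allele-frequency ranges
#'   per stratum (the strata differ in allele frequency draws).
#' @param ld_block_size variants per LD block.
#' @param ld_rho within-block adjacent-haplotype correlation in `[0, 1)`.
#' @param frac_cpgs_with_mqtl fraction of CpGs given a causal cis-SNP.
#' @param mqtl_effect_sd SD of planted mQTL effects (beta-units per
#'   effect allele); effects are drawn `N(0, mqtl_effect_sd)`.
#' @param mqtl_effect_fixed optional fixed magnitude for planted mQTL
#'   effects (random sign); overrides the normal draw when non-`NULL`.
#' @param frac_cpgs_bw_assoc fraction of CpGs given a birthweight effect.
#' @param bw_effect_sd SD of planted birthweight effects, in beta-units
#'   per 1000 g.
#' @param noise_sd residual SD of beta values.
#' @param frac_preterm fraction of samples with gestational age below 30
#'   weeks (so the preterm exclusion rule is exercised).
#' @param seed integer seed; all draws are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = c(NLW = 200L, LAT = 300L),
                       n_variants = 2000L,
                       n_cpgs = 500L,
                       chrom_length = 1e8,
                       maf_range = list(NLW = c(0.05, 0.50),
                                        LAT = c(0.10, 0.50)),
                       ld_block_size = 10L,
                       ld_rho = 0.8,
                       frac_cpgs_with_mqtl = 0.2,
                       mqtl_effect_sd = 0.05,
                       mqtl_effect_fixed = NULL,
                       frac_cpgs_bw_assoc = 0.05,
                       bw_effect_sd = 0.02,
                       noise_sd = 0.02,
                       frac_preterm = 0.02,
                       seed = 1L) {
  n_samples <- unlist(n_samples) # allow YAML-style named lists
  storage.mode(n_samples) <- "integer"
  if (is.list(maf_range)) maf_range <- lapply(maf_range, unlist)
  cfg <- list(n_samples = n_samples, n_variants = as.integer(n_variants),
              n_cpgs = as.integer(n_cpgs),
              chrom_length = as.numeric(chrom_length),
              maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
              ld_rho = ld_rho, frac_cpgs_with_mqtl = frac_cpgs_with_mqtl,
              mqtl_effect_sd = mqtl_effect_sd,
              mqtl_effect_fixed = mqtl_effect_fixed,
              frac_cpgs_bw_assoc = frac_cpgs_bw_assoc,
              bw_effect_sd = bw_effect_sd, noise_sd = noise_sd,
              frac_preterm = frac_preterm, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(all(cfg$n_samples >= 30),
            cfg$n_variants >= 2, cfg$n_cpgs >= 1,
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$frac_cpgs_with_mqtl >= 0, cfg$frac_cpgs_with_mqtl <= 1,
            cfg$frac_cpgs_bw_assoc >= 0, cfg$frac_cpgs_bw_assoc <= 1,
            cfg$noise_sd > 0, cfg$frac_preterm >= 0, cfg$frac_preterm < 1)
  for (s in names(cfg$n_samples)) {
    r <- cfg$maf_range[[s]]
    if (is.null(r) || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
      stop("maf_range for stratum ", s, " must be within (0, 0.5]")
  }
  invisible(cfg)
}

# Variant and CpG positions are shared across strata so that scans can
# be meta-analyzed; they are drawn from the config seed alone.
#' @keywords internal
simulate_map <- function(cfg) {
  set.seed(hash_seed(cfg$seed, "map"))
  vpos <- sort(sample.int(cfg$chrom_length, cfg$n_variants))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(
    id = sprintf("snp%05d", seq_len(cfg$n_variants)),
    chrom = "chr1", pos = vpos,
    effect_allele = unname(alt), other_allele = unname(ref),
    stringsAsFactors = FALSE)
  cpos <- sort(sample.int(cfg$chrom_length, cfg$n_cpgs))
  cpgs <- data.frame(
    id = sprintf("cg%05d", seq_len(cfg$n_cpgs)),
    chrom = "chr1", pos = cpos,
    island_relation = sample(island_relation_levels(), cfg$n_cpgs,
                             replace = TRUE,
                             prob = c(0.31, 0.13, 0.10, 0.05, 0.04, 0.37)),
    platform = "BOTH", stringsAsFactors = FALSE)
  list(variants = variants, cpgs = cpgs)
}

#' Simulate genotype dosages for one stratum
#'
#' Dosages are sums of two haplotypes. Haplotypes are drawn by
#' thresholding a Gaussian AR(1) process within each LD block
#' (Gaussian-copula LD): adjacent variants in a block have latent
#' correlation `ld_rho`, blocks are independent. Per-variant allele
#' frequencies are uniform on the stratum's `maf_range`.
#'
#' @param cfg a [sim_config()].
#' @param stratum stratum name (`"NLW"` or `"LAT"`).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg, stratum = names(cfg$n_samples)[1]) {
  validate_sim_config(cfg)
  stopifnot(stratum %in% names(cfg$n_samples))
  map <- simulate_map(cfg)
  n <- cfg$n_samples[[stratum]]
  m <- cfg$n_variants
  set.seed(hash_seed(cfg$seed, paste0("geno:", stratum)))
  r <- cfg$maf_range[[stratum]]
  block <- (seq_len(m) - 1L) %/% cfg$ld_block_size
  # variants in strong LD necessarily have similar allele frequencies,
  # so frequencies are drawn per block with small per-variant jitter
  f_block <- stats::runif(max(block) + 1L, r[1], r[2])
  freq <- pmin(pmax(f_block[block + 1L] + stats::rnorm(m, 0, 0.02),
                    r[1]), r[2])
  thr <- stats::qnorm(freq) # latent z below threshold => effect allele
  # latent AR(1) correlations calibrated so that the *allele* (binary)
  # correlation of each within-block adjacent pair is ld_rho
  rho_lat <- numeric(m)
  if (cfg$ld_rho > 0 && m >= 2) {
    for (j in 2:m) {
      if (block[j] == block[j - 1L]) {
        rho_lat[j] <- latent_rho(freq[j - 1L], freq[j], cfg$ld_rho)
      }
    }
  }
  haplo <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (cfg$ld_rho > 0) {
      for (j in 2:m) {
        if (rho_lat[j] > 0) {
          z[, j] <- rho_lat[j] * z[, j - 1L] +
            sqrt(1 - rho_lat[j]^2) * z[, j]
        }
      }
    }
    z
  }
  d <- (haplo() < rep(thr, each = n)) + (haplo() < rep(thr, each = n))
  storage.mode(d) <- "double"
  rownames(d) <- sprintf("%s%04d", stratum, seq_len(n))
  genotype_matrix(d, map$variants)
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho
#' @keywords internal
bvn_orthant <- function(rho, t1, t2) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) stats::pnorm((t2 - rho * z) / s) *
                     stats::dnorm(z),
                   -Inf, t1, rel.tol = 1e-9)$value
}

# Latent Gaussian correlation that yields binary (allele) correlation
# r_target after thresholding at frequencies f1, f2.
#' @keywords internal
latent_rho <- function(f1, f2, r_target) {
  if (r_target <= 0) return(0)
  t1 <- stats::qnorm(f1); t2 <- stats::qnorm(f2)
  target_p11 <- f1 * f2 + r_target * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  hi <- 0.9999
  if (bvn_orthant(hi, t1, t2) <= target_p11) return(hi)
  stats::uniroot(function(rho) bvn_orthant(rho, t1, t2) - target_p11,
                 c(0, hi), tol = 1e-8)$root
}

#' @keywords internal
rdirichlet1 <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Simulate phenotypes, covariates and methylation for one stratum
#'
#' Birthweight follows
#' `3400 + 150 (GA - 39) + 120 I(male) + N(0, 400)` grams with
#' gestational age `N(39, 1.5)` weeks (a `frac_preterm` fraction is
#' drawn preterm, below 30 weeks). Cell proportions over 7 classes are
#' Dirichlet with a granulocyte-dominated mean, as in neonatal blood.
#' Methylation is additive on the beta scale:
#' `beta_ij = clip(mu_j + b_mqtl,j g_ij + b_bw,j (BW_i - 3400) + batch +
#' sex + cell effects + N(0, noise_sd), 0, 1)` with baseline `mu_j`
#' drawn from a trimodal mixture near 0.1 / 0.5 / 0.9. Which CpGs carry
#' mQTL or birthweight effects is decided once from the config seed, so
#' all strata share the same truth.
#'
#' @param cfg a [sim_config()].
#' @param genotypes the stratum's [genotype_matrix()] from
#'   [simulate_genotypes()].
#' @param stratum stratum name.
#' @return list with `samples` (a `sample_table`), `methylation`
#'   (a [methylation_matrix()]) and `truth` (per-CpG causal SNP and
#'   effect sizes; per-sample true 7-class cell proportions as an
#'   attribute).
#' @export
simulate_phenotypes <- function(cfg, genotypes,
                                stratum = names(cfg$n_samples)[1]) {
  validate_sim_config(cfg)
  map <- simulate_map(cfg)
  truth <- simulate_truth(cfg, map)
  n <- nrow(genotypes$dosages)
  set.seed(hash_seed(cfg$seed, paste0("pheno:", stratum)))

  sex <- sample(c("F", "M"), n, replace = TRUE)
  ga <- stats::rnorm(n, 39, 1.5)
  ga <- pmax(ga, 30.01)
  n_pre <- round(cfg$frac_preterm * n)
  if (n_pre > 0) {
    pre <- sample.int(n, n_pre)
    ga[pre] <- stats::runif(n_pre, 26, 29.9)
  }
  bw <- 3400 + 150 * (ga - 39) + 120 * (sex == "M") + stats::rnorm(n, 0, 400)
  bw <- pmax(bw, 500)
  batch <- sample(paste0("B", 1:2), n, replace = TRUE)
  case <- stats::rbinom(n, 1, 0.5)
  mwg <- stats::rnorm(n, 14, 5) # maternal weight gain, kg
  pcs <- matrix(stats::rnorm(n * 10, 0, 1), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  # neonatal whole blood: granulocytes dominate
  alpha <- c(CD8T = 2, CD4T = 4, NK = 1, Bcell = 2, Mono = 2,
             Gran = 14, nRBC = 2)
  cells7 <- rdirichlet1(n, alpha)
  colnames(cells7) <- names(alpha)

  mu <- truth$mu
  ncp <- cfg$n_cpgs
  batch_eff <- truth$batch_eff
  sex_eff <- truth$sex_eff
  cell_load <- truth$cell_load # n_cpgs x 7

  g <- genotypes$dosages
  B <- matrix(rep(mu, each = n), n, ncp)
  has_q <- !is.na(truth$table$causal_snp_id)
  if (any(has_q)) {
    gi <- g[, truth$table$causal_snp_id[has_q], drop = FALSE]
    B[, has_q] <- B[, has_q] +
      gi * rep(truth$table$mqtl_beta[has_q], each = n)
  }
  B <- B + outer(bw - 3400, truth$table$bw_beta)
  B <- B + outer(batch == "B2", batch_eff)
  B <- B + outer(sex == "M", sex_eff)
  cc <- sweep(cells7, 2, colMeans(cells7))
  B <- B + cc %*% t(cell_load)
  B <- B + matrix(stats::rnorm(n * ncp, 0, cfg$noise_sd), n, ncp)
  B <- pmin(pmax(B, 0), 1)
  rownames(B) <- rownames(g)

  samples <- data.frame(
    sample_id = rownames(g), sex = sex, batch = batch, case_status = case,
    gestational_age = ga, birthweight = bw, maternal_weight_gain = mwg,
    ancestry_group = stratum, pcs,
    cell_CD8T = cells7[, "CD8T"], cell_CD4T = cells7[, "CD4T"],
    cell_NK = cells7[, "NK"], cell_Bcell = cells7[, "Bcell"],
    cell_Mono = cells7[, "Mono"], cell_nRBC = cells7[, "nRBC"],
    stringsAsFactors = FALSE)
  samples <- validate_sample_table(samples)

  truth_tab <- truth$table
  attr(truth_tab, "cell_proportions") <- cells7
  list(samples = samples,
       methylation = methylation_matrix(B, map$cpgs),
       truth = truth_tab)
}

# Truth (which CpGs carry which effects) is shared across strata: drawn
# once from the config seed.
#' @keywords internal
simulate_truth <- function(cfg, map) {
  set.seed(hash_seed(cfg$seed, "truth"))
  ncp <- cfg$n_cpgs
  modes <- sample(c(0.1, 0.5, 0.9), ncp, replace = TRUE,
                  prob = c(0.35, 0.3, 0.35))
  mu <- pmin(pmax(modes + stats::rnorm(ncp, 0, 0.04), 0.03), 0.97)

  causal <- rep(NA_character_, ncp)
  mqtl_beta <- numeric(ncp)
  n_q <- round(cfg$frac_cpgs_with_mqtl * ncp)
  pick_q <- sample.int(ncp, n_q)
  half <- 1e6
  for (j in pick_q) {
    cis <- which(map$variants$chrom == map$cpgs$chrom[j] &
                   abs(map$variants$pos - map$cpgs$pos[j]) <= half)
    if (!length(cis)) next
    causal[j] <- map$variants$id[sample(cis, 1)]
    mqtl_beta[j] <- if (!is.null(cfg$mqtl_effect_fixed)) {
      sample(c(-1, 1), 1) * cfg$mqtl_effect_fixed
    } else {
      stats::rnorm(1, 0, cfg$mqtl_effect_sd)
    }
  }

  bw_beta <- numeric(ncp)
  n_bw <- round(cfg$frac_cpgs_bw_assoc * ncp)
  if (n_bw > 0) {
    pick_bw <- sample.int(ncp, n_bw)
    bw_beta[pick_bw] <- stats::rnorm(n_bw, 0, cfg$bw_effect_sd / 1000)
    zero <- pick_bw[bw_beta[pick_bw] == 0]
    bw_beta[zero] <- cfg$bw_effect_sd / 1000 # degenerate draw guard
  }

  batch_eff <- stats::rnorm(ncp, 0, 0.01)
  sex_eff <- stats::rnorm(ncp, 0, 0.005)
  cell_load <- matrix(stats::rnorm(ncp * 7, 0, 0.02), ncp, 7)

  list(mu = mu, batch_eff = batch_eff, sex_eff = sex_eff,
       cell_load = cell_load,
       table = data.frame(cpg_id = map$cpgs$id, causal_snp_id = causal,
                          mqtl_beta = mqtl_beta, bw_beta = bw_beta,
                          stringsAsFactors = FALSE))
}

#' Simulate a full multi-stratum cohort
#'
#' @param cfg a [sim_config()].
#' @return named list (one element per stratum) of lists with
#'   `genotypes`, `samples`, `methylation`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  out <- lapply(names(cfg$n_samples), function(s) {
    g <- simulate_genotypes(cfg, s)
    ph <- simulate_phenotypes(cfg, g, s)
    c(list(genotypes = g), ph)
  })
  names(out) <- names(cfg$n_samples)
  out
}

#' Write a simulated cohort to a fixture directory
#'
#' Emits, per stratum: dosage TSV + variant manifest, beta TSV + CpG
#' manifest, sample TSV; plus a shared truth TSV. Files round-trip
#' losslessly through the package readers.
#'
#' @param dir output directory.
#' @param cohort result of [simulate_cohort()].
#' @param force overwrite a non-empty directory.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(dir, cohort, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("directory ", dir, " is not empty (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort)) {
    x <- cohort[[s]]
    write_genotypes(x$genotypes,
                    file.path(dir, paste0(s, "_dosages.tsv")),
                    file.path(dir, paste0(s, "_variants.tsv")))
    write_methylation(x$methylation,
                      file.path(dir, paste0(s, "_betas.tsv")),
                      file.path(dir, paste0(s, "_cpgs.tsv")))
    write_tsv(x$samples, file.path(dir, paste0(s, "_samples.tsv")))
  }
  write_tsv(cohort[[1]]$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort fixture directory written by [write_cohort()]
#' @param dir directory path.
#' @param strata stratum names to read (default: inferred from files).
#' @return list as from [simulate_cohort()] (truth attached per stratum).
#' @export
read_cohort <- function(dir, strata = NULL) {
  if (is.null(strata)) {
    strata <- sub("_dosages\\.tsv$", "",
                  basename(Sys.glob(file.path(dir, "*_dosages.tsv"))))
  }
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  out <- lapply(strata, function(s) {
    list(genotypes = read_genotypes(file.path(dir, paste0(s, "_dosages.tsv")),
                                    "dosage_tsv",
                                    file.path(dir, paste0(s, "_variants.tsv"))),
         samples = read_samples(file.path(dir, paste0(s, "_samples.tsv"))),
         methylation = read_methylation(
           file.path(dir, paste0(s, "_betas.tsv")),
           file.path(dir, paste0(s, "_cpgs.tsv"))),
         truth = truth)
  })
  names(out) <- strata
  out
}

#' Simulate a cell-type methylation reference
#'
#' Builds a reference matrix over marker CpGs for the seven
#' umbilical-blood cell classes (CD8T, CD4T, NK, Bcell, Mono, Gran,
#' nRBC): each class gets a set of hypermethylated marker CpGs
#' (beta about 0.85 in-class, about 0.15 elsewhere).
#'
#' @param n_cpgs number of reference CpGs (default 200).
#' @param seed integer seed.
#' @return matrix `n_cpgs x 7` with CpG row names and class column
#'   names, entries in `[0, 1]`.
#' @export
simulate_reference <- function(n_cpgs = 200L, seed = 1L) {
  classes <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran", "nRBC")
  set.seed(hash_seed(seed, "reference"))
  R <- matrix(0.15 + stats::rnorm(n_cpgs * 7, 0, 0.03), n_cpgs, 7,
              dimnames = list(sprintf("ref%04d", seq_len(n_cpgs)), classes))
  owner <- rep(seq_len(7), length.out = n_cpgs)
  R[cbind(seq_len(n_cpgs), owner)] <-
    0.85 + stats::rnorm(n_cpgs, 0, 0.03)
  pmin(pmax(R, 0), 1)
}
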