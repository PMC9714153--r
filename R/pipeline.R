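# End-to-end orchestration: simulate -> genotype QC -> per-stratum
# cis-mQTL scan -> meta-analysis / database -> cross-stratum
# concordance -> paired EWAS -> model comparison -> enrichment ->
# report. Driven by a config list (or YAML file) with one global seed;
# re-running with the same config reproduces every numeric output.

#' Default pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param sim named list of overrides for [sim_config()].
#' @param scan list with `window_bp`, `n_perm`.
#' @param thresholds list with `adjusted_p`, `r2`, `change`,
#'   `bonferroni_alpha`.
#' @param platform platform tag for the simulated array.
#' @param seed global integer seed (overrides the one in `sim`).
#' @param deconvolve run the deconvolution demonstration stage?
#' @return config list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("mqtlewas_run_"),
                       sim = list(),
                       scan = list(window_bp = 2e6, n_perm = 200L),
                       thresholds = list(adjusted_p = 0.05, r2 = 0.5,
                                         change = 0.20,
                                         bonferroni_alpha = 0.05),
                       platform = "SIM450",
                       seed = 1L,
                       deconvolve = TRUE) {
  cfg <- list(out_dir = out_dir, sim = sim, scan = scan,
              thresholds = thresholds, platform = platform,
              seed = as.integer(seed), deconvolve = isTRUE(deconvolve))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @keywords internal
validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  for (k in c("adjusted_p", "r2", "change", "bonferroni_alpha")) {
    v <- th[[k]]
    if (is.null(v) || v <= 0 || v >= 1)
      stop("threshold ", k, " must lie in (0, 1)")
  }
  if (is.null(cfg$scan$window_bp) ||
      !is.numeric(cfg$scan$window_bp) || cfg$scan$window_bp <= 0)
    stop("scan window_bp must be a number > 0")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML maps 1:1 onto [run_config()] (top-level keys `out_dir`,
#' `sim`, `scan`, `thresholds`, `platform`, `seed`, `deconvolve`).
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  names(formals(run_config)))])
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes every stage and writes TSV artifacts plus a plain-text
#' report into `config$out_dir`. Every output is stamped (in
#' `run_info.tsv`) with the seed and a hash of the configuration.
#' Re-running with the same config reproduces all numeric outputs.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @param verbose log stage progress.
#' @return invisibly, a list with the in-memory stage results:
#'   `cohort`, `scans`, `db`, `concordance`, `ewas`, `meta_mqtl`,
#'   `meta_plain`, `comparison`, `island`, `deconvolution`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  strata <- names(cfg$n_samples)

  msg("[simulate] %s", paste(strata, collapse = ", "), verbose = verbose)
  cohort <- simulate_cohort(cfg)
  write_cohort(file.path(out, "cohort"), cohort, force = TRUE)

  msg("[qc]", verbose = verbose)
  for (s in strata) {
    cohort[[s]]$genotypes <- apply_genotype_qc(cohort[[s]]$genotypes)
  }

  msg("[scan]", verbose = verbose)
  scans <- lapply(strata, function(s) {
    scan_dataset(cohort[[s]]$methylation, cohort[[s]]$genotypes,
                 cohort[[s]]$samples,
                 window_bp = config$scan$window_bp,
                 n_perm = config$scan$n_perm,
                 seed = hash_seed(config$seed, paste0("scan:", s)),
                 verbose = verbose)
  })
  names(scans) <- strata
  for (s in strata) {
    write_tsv(as.data.frame(scans[[s]]),
              file.path(out, paste0("scan_", s, ".tsv")))
  }

  msg("[build-db]", verbose = verbose)
  db <- build_database(scans, platform = config$platform,
                       adj_p_max = config$thresholds$adjusted_p)
  write_database(db, file.path(out, "mqtl_db.tsv"))

  conc <- NULL
  per_stratum_dbs <- lapply(strata, function(s) {
    build_database(scans[s], platform = config$platform,
                   adj_p_max = config$thresholds$adjusted_p)
  })
  names(per_stratum_dbs) <- strata
  if (length(strata) >= 2) {
    shared <- intersect(assigned_mqtls(per_stratum_dbs[[1]])$cpg_id,
                        assigned_mqtls(per_stratum_dbs[[2]])$cpg_id)
    if (length(shared)) {
      conc <- concordance(per_stratum_dbs[[1]], per_stratum_dbs[[2]],
                          cohort[[strata[2]]]$genotypes,
                          r2_min = config$thresholds$r2)
      write_tsv(conc$detail, file.path(out, "concordance.tsv"))
    }
  }

  msg("[ewas]", verbose = verbose)
  ewas_fits <- lapply(strata, function(s) {
    ewas_dataset(cohort[[s]]$methylation, cohort[[s]]$samples,
                 db = db, geno = cohort[[s]]$genotypes)
  })
  names(ewas_fits) <- strata

  meta_mqtl <- meta_ewas(lapply(ewas_fits, `[[`, "mqtl"),
                         platform = config$platform,
                         alpha = config$thresholds$bonferroni_alpha)
  meta_plain <- meta_ewas(lapply(ewas_fits, `[[`, "plain"),
                          platform = config$platform,
                          alpha = config$thresholds$bonferroni_alpha)
  write_tsv(as.data.frame(meta_mqtl), file.path(out, "ewas_meta_mqtl.tsv"))
  write_tsv(as.data.frame(meta_plain), file.path(out, "ewas_meta_plain.tsv"))

  msg("[compare]", verbose = verbose)
  comparison <- compare_models(meta_mqtl, meta_plain,
                               change_min = config$thresholds$change)
  write_tsv(as.data.frame(comparison), file.path(out, "comparison.tsv"))

  msg("[enrich]", verbose = verbose)
  cpgs <- cohort[[1]]$methylation$cpgs
  flags <- cpgs$id %in% assigned_mqtls(db)$cpg_id
  island <- island_relation_test(cpgs, flags)
  write_tsv(as.data.frame(island), file.path(out, "island_enrichment.tsv"))

  deconv <- NULL
  if (config$deconvolve) {
    msg("[deconvolve]", verbose = verbose)
    ref <- simulate_reference(seed = config$seed)
    truth_p <- attr(cohort[[1]]$truth, "cell_proportions")
    set.seed(hash_seed(config$seed, "deconv"))
    n_demo <- min(20L, nrow(cohort[[1]]$samples))
    mix <- truth_p[seq_len(n_demo), cell_classes(), drop = FALSE]
    profiles <- mix %*% t(ref) +
      matrix(stats::rnorm(n_demo * nrow(ref), 0, 0.02), n_demo)
    colnames(profiles) <- rownames(ref)
    est <- estimate_proportions_all(pmin(pmax(profiles, 0), 1), ref)
    deconv <- list(truth = mix, estimate = est,
                   mae = colMeans(abs(est - mix)))
    write_tsv(data.frame(class = names(deconv$mae), mae = deconv$mae),
              file.path(out, "deconvolution_mae.tsv"))
  }

  info <- data.frame(
    key = c("seed", "config_hash", "package_version"),
    value = c(config$seed,
              stable_hash(utils::capture.output(utils::str(config))),
              as.character(utils::packageVersion("mqtlewas"))),
    stringsAsFactors = FALSE)
  write_tsv(info, file.path(out, "run_info.tsv"))

  report <- c(
    sprintf("cohort: %s", paste(sprintf("%s n=%d", strata,
                                        cfg$n_samples), collapse = ", ")),
    sprintf("scan: %s",
            paste(sprintf("%s %d/%d CpGs significant", strata,
                          vapply(scans, function(x) sum(x$significant),
                                 integer(1)),
                          vapply(scans, nrow, integer(1))),
                  collapse = "; ")),
    sprintf("database: %d pairs, %d CpGs", nrow(db),
            length(unique(db$cpg_id))),
    sprintf("ewas: %d / %d CpGs Bonferroni-significant (mqtl / plain: %d / %d)",
            sum(meta_mqtl$significant), nrow(meta_mqtl),
            sum(meta_mqtl$significant), sum(meta_plain$significant)),
    sprintf("comparison: %.1f%% more significant with mQTL; %.1f%% changed > 20%%",
            100 * attr(comparison, "summary")$fraction_more_significant,
            100 * attr(comparison, "summary")$fraction_changed))
  writeLines(report, file.path(out, "report.txt"))

  invisible(list(cohort = cohort, scans = scans, db = db,
                 concordance = conc, ewas = ewas_fits,
                 meta_mqtl = meta_mqtl, meta_plain = meta_plain,
                 comparison = comparison, island = island,
                 deconvolution = deconv, config = config))
}
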