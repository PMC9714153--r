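# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  sim_config(n_samples = c(NLW = 60L, LAT = 80L), n_variants = 400L,
             n_cpgs = 60L, chrom_length = 2e7, seed = 11L, ...)
}

# one shared two-stratum cohort with planted effects
get_small_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- simulate_cohort(small_cfg())
  }
  .fixture_cache$cohort
}

# minimal VCF text, 3 samples, GT field
write_fixture_vcf <- function(path, extra_lines = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    extra_lines)
  writeLines(lines, path)
  path
}

# genotype matrix with prescribed dosage columns
make_geno <- function(dosages, pos = NULL, chrom = "chr1") {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  genotype_matrix(dosages, data.frame(
    id = sprintf("v%03d", seq_len(m)), chrom = chrom, pos = pos,
    effect_allele = "G", other_allele = "A", stringsAsFactors = FALSE))
}

# minimal valid sample table with n samples
make_samples <- function(n, seed = 1) {
  set.seed(seed)
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("pc", 1:10)))
  cells <- matrix(runif(n * 6, 0.01, 0.12), n, 6,
                  dimnames = list(NULL, cell_covariate_names()))
  validate_sample_table(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, TRUE),
    batch = sample(c("B1", "B2"), n, TRUE),
    case_status = rbinom(n, 1, 0.5),
    gestational_age = rnorm(n, 39, 1.5),
    birthweight = rnorm(n, 3400, 450),
    maternal_weight_gain = rnorm(n, 14, 5),
    ancestry_group = "NLW", pcs, cells,
    stringsAsFactors = FALSE))
}
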