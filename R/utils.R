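#' @keywords internal
"_PACKAGE"

# Shared numerical helpers. All regression in the package funnels through
# ols_fit() so that every stage (mQTL scan, EWAS, partial F) uses one QR path.

#' Ordinary least squares via QR
#'
#' Fits `y ~ X` (X must already contain an intercept column if one is
#' wanted) and returns coefficients, standard errors, t statistics,
#' two-sided P values, the residual sum of squares and residual degrees
#' of freedom. A perfect fit (residual sum of squares numerically zero)
#' reports `se = 0` and `p = 0` for nonzero coefficients by convention.
#'
#' @param X numeric design matrix, one row per sample.
#' @param y numeric response vector.
#' @return list with `coef`, `se`, `t`, `p`, `rss`, `df`, `n`, `rank`.
#' @keywords internal
ols_fit <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  qrx <- qr(X)
  r <- qrx$rank
  if (r < ncol(X)) {
    piv <- qrx$pivot
    aliased <- colnames(X)[piv[(r + 1L):ncol(X)]]
    if (is.null(aliased)) aliased <- paste0("column ", piv[(r + 1L):ncol(X)])
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  rss <- sum(res^2)
  df <- n - r
  if (df <= 0) stop("no residual degrees of freedom (n <= rank)")
  # (X'X)^{-1} diagonal from the R factor, honouring the pivot
  Rmat <- qr.R(qrx)[seq_len(r), seq_len(r), drop = FALSE]
  xtx_inv <- chol2inv(Rmat)
  d <- numeric(ncol(X))
  d[qrx$pivot[seq_len(r)]] <- diag(xtx_inv)
  tss_scale <- max(1, sum(y^2))
  perfect <- rss <= 1e-24 * tss_scale
  sigma2 <- if (perfect) 0 else rss / df
  se <- sqrt(sigma2 * d)
  tval <- ifelse(se > 0, beta / se, ifelse(abs(beta) > 0, Inf, 0))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(beta / se), df),
              ifelse(abs(beta) > 0, 0, 1))
  list(coef = beta, se = se, t = tval, p = p,
       rss = rss, df = df, n = n, rank = r)
}

#' Residualize columns on a covariate design
#'
#' Projects each column of `M` onto the orthogonal complement of the
#' column space of `Z` (which should include an intercept).
#'
#' @param M numeric matrix (or vector) to residualize.
#' @param Z covariate design matrix.
#' @return matrix of residuals, same shape as `M`.
#' @keywords internal
residualize <- function(M, Z) {
  M <- as.matrix(M)
  qr.resid(qr(Z), M)
}

#' Stable per-identifier random seed
#'
#' Derives a deterministic 31-bit seed from a global seed and a string
#' identifier, so per-CpG permutation streams do not depend on scan
#' order or parallel scheduling. Pure integer arithmetic on doubles
#' (exact below 2^53), hence platform independent.
#'
#' @param seed integer global seed.
#' @param id character identifier.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
hash_seed <- function(seed, id) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (k in utf8ToInt(as.character(id))) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h + 1)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on hard-call genotype counts: the P value is the
#' sum of probabilities of all heterozygote counts (given the allele
#' counts) whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param n_het observed heterozygote count.
#' @param n_hom1 observed count of one homozygote class.
#' @param n_hom2 observed count of the other homozygote class.
#' @return exact two-sided P value.
#' @export
#' @examples
#' hwe_exact_p(n_het = 0, n_hom1 = 50, n_hom2 = 50) # extreme departure
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(NA_real_)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0) return(1)
  # support: het counts with the parity of n_rare, 0..n_rare (and <= alleles)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log conditional probability of each het count given allele margins
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple FNV-1a style hash of a character vector, for config stamping.
#' @keywords internal
stable_hash <- function(x) {
  m <- 2^31 - 1
  h <- 2166136261 %% m
  for (k in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- ((h + k) * 16777619) %% m
  }
  sprintf("%08x", as.integer(h))
}

#' @keywords internal
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
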