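# Reference-based deconvolution of cell-type proportions from a
# methylation profile: constrained projection of the sample's beta
# values over marker CpGs onto the reference profiles of the seven
# umbilical-blood cell classes, solved by active-set nonnegative least
# squares with renormalization onto the unit simplex.

#' Cell classes used throughout the package
#' @return character vector of the seven class names.
#' @export
cell_classes <- function() {
  c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran", "nRBC")
}

#' Estimate cell-type proportions for one sample
#'
#' Solves `min ||y - R p||^2` subject to `p >= 0`, then renormalizes
#' onto the simplex `sum(p) = 1`. Deterministic: the Lawson-Hanson
#' active-set algorithm has no random component.
#'
#' @param sample_betas named beta vector over (a superset of) the
#'   reference CpGs; at least `min_overlap` of the reference CpGs must
#'   be present.
#' @param ref reference matrix (CpGs x 7 classes) as from
#'   [simulate_reference()], entries in `[0, 1]`.
#' @param min_overlap minimum fraction of reference CpGs required
#'   (default 0.9).
#' @return named numeric vector of 7 proportions (`>= 0`, summing to 1).
#' @export
estimate_proportions <- function(sample_betas, ref, min_overlap = 0.9) {
  stopifnot(is.matrix(ref), ncol(ref) == 7)
  shared <- intersect(rownames(ref), names(sample_betas))
  frac <- length(shared) / nrow(ref)
  if (frac < min_overlap)
    stop(sprintf("only %.1f%% of reference CpGs present in the sample (need %.0f%%)",
                 100 * frac, 100 * min_overlap))
  R <- ref[shared, , drop = FALSE]
  y <- sample_betas[shared]
  p <- pracma::lsqnonneg(R, y)$x
  s <- sum(p)
  if (s <= 0) stop("degenerate profile: all proportions estimated zero")
  p <- p / s
  names(p) <- colnames(ref)
  p
}

#' Estimate proportions for every sample of a methylation matrix
#'
#' @param meth a [methylation_matrix()] whose columns include the
#'   reference CpGs, or a plain samples-x-CpGs matrix.
#' @param ref reference matrix (CpGs x 7 classes).
#' @param min_overlap see [estimate_proportions()].
#' @return samples x 7 matrix of proportions.
#' @export
estimate_proportions_all <- function(meth, ref, min_overlap = 0.9) {
  B <- if (inherits(meth, "methylation_matrix")) meth$betas else meth
  t(apply(B, 1, estimate_proportions, ref = ref,
          min_overlap = min_overlap))
}

#' Cell covariate block for the EWAS design
#'
#' Drops the granulocyte column (the dominant class; keeping all seven
#' would be collinear with the intercept) and fixes the column order
#' CD8T, CD4T, NK, Bcell, Mono, nRBC.
#'
#' @param props proportion matrix (samples x 7) or vector of length 7.
#' @return matrix with the six covariate columns, named
#'   `cell_CD8T` .. `cell_nRBC`.
#' @export
make_covariates <- function(props) {
  if (is.null(dim(props))) props <- matrix(props, 1,
                                           dimnames = list(NULL,
                                                           names(props)))
  keep <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "nRBC")
  miss <- setdiff(keep, colnames(props))
  if (length(miss)) stop("missing cell classes: ",
                         paste(miss, collapse = ", "))
  out <- props[, keep, drop = FALSE]
  colnames(out) <- paste0("cell_", keep)
  out
}
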