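# Enrichment of mQTL-matched CpGs in genomic feature sets (two-sided
# Fisher exact test on the 2x2 table) and in CpG-island-relation
# categories (two-sample proportion chi-squared tests against the
# array-wide distribution).

#' Two-sided Fisher exact test P value for a 2x2 table
#'
#' Exact hypergeometric enumeration: conditioning on the margins, the
#' P value sums the probabilities of all tables whose conditional
#' probability does not exceed that of the observed table. When the
#' smallest margin exceeds `exact_max` the chi-squared approximation
#' (without continuity correction) is used instead.
#'
#' @param a,b,c,d cell counts: rows split the classification of
#'   interest (e.g. mQTL-matched vs not), columns the feature overlap.
#' @param exact_max largest minimum-margin size for which the exact
#'   enumeration is used (default `1e4`).
#' @return two-sided P value.
#' @export
fisher_p <- function(a, b, c, d, exact_max = 1e4) {
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (min(margins) > exact_max) {
    e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
    x2 <- sum((c(a, b, c, d) - as.vector(t(e)))^2 / as.vector(t(e)))
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  k <- a + b          # draws (row 1 total)
  x <- seq(max(0, k - (b + d)), min(k, a + c))
  pr <- stats::dhyper(x, a + c, b + d, k)
  obs <- stats::dhyper(a, a + c, b + d, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Feature enrichment of mQTL-matched CpGs
#'
#' Builds the 2x2 table (mQTL-matched vs not, in-feature vs not),
#' computes fold enrichment
#' `(a / (a + b)) / ((a + c) / (a + b + c + d))`, the sample odds
#' ratio `ad / bc`, and the two-sided Fisher exact P value.
#'
#' @param membership_mqtl logical vector: CpG has an assigned mQTL.
#' @param membership_feature logical vector (same length): CpG falls
#'   in the feature.
#' @param feature_name label for the output.
#' @return one-row data.frame of class `enrichment`: `feature_name`,
#'   `a`, `b`, `c`, `d`, `fold_enrichment`, `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(membership_mqtl, membership_feature,
                              feature_name = "feature") {
  stopifnot(length(membership_mqtl) == length(membership_feature))
  m <- as.logical(membership_mqtl); f <- as.logical(membership_feature)
  if (!any(m) || !any(f) || all(m) || all(f))
    stop("a margin of the 2x2 table is empty")
  a <- sum(m & f); b <- sum(m & !f); c <- sum(!m & f); d <- sum(!m & !f)
  n <- a + b + c + d
  fold <- (a / (a + b)) / ((a + c) / n)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else Inf
  out <- data.frame(feature_name = feature_name, a = a, b = b, c = c,
                    d = d, fold_enrichment = fold, odds_ratio = or,
                    p = fisher_p(a, b, c, d), stringsAsFactors = FALSE)
  class(out) <- c("enrichment", "data.frame")
  out
}

#' Enrichment of mQTL-matched CpGs across several BED feature sets
#'
#' @param cpgs CpG manifest data.frame (`id`, `chrom`, `pos`).
#' @param mqtl_flags logical vector aligned with `cpgs`.
#' @param feature_paths character vector of BED file paths (names used
#'   as feature labels).
#' @return stacked `enrichment` data.frame, one row per feature set.
#' @export
enrich_features <- function(cpgs, mqtl_flags, feature_paths) {
  if (is.null(names(feature_paths)))
    names(feature_paths) <- basename(feature_paths)
  rows <- lapply(names(feature_paths), function(nm) {
    fs <- read_features(feature_paths[[nm]], nm)
    inside <- overlaps_features(fs, cpgs$chrom, cpgs$pos)
    fisher_enrichment(mqtl_flags, inside, nm)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment", "data.frame")
  out
}

#' @export
print.enrichment <- function(x, ...) {
  cat("feature enrichment of mQTL-matched CpGs:\n")
  df <- as.data.frame(x)
  df$fold_enrichment <- sprintf("%.3f", df$fold_enrichment)
  df$p <- format(df$p, digits = 3)
  print(df[, c("feature_name", "a", "b", "c", "d",
               "fold_enrichment", "p")], row.names = FALSE)
  invisible(x)
}

#' Island-relation distribution of mQTL-matched CpGs
#'
#' For each island-relation category, compares the proportion among
#' mQTL-matched CpGs with the proportion among all CpGs (the array-wide
#' superset) by a two-sample proportion chi-squared test without
#' continuity correction, with star coding (* < 0.05, ** < 0.01,
#' *** < 0.001). A combined shore-vs-rest (N_Shore or S_Shore) test is
#' attached as attribute `shore_test`. The disjoint mQTL vs non-mQTL
#' Fisher test per category is also reported (`fisher_p` column).
#'
#' @param cpgs CpG manifest data.frame with `island_relation`.
#' @param mqtl_flags logical vector aligned with `cpgs`.
#' @return data.frame of class `island_enrichment`: per category the
#'   two proportions, chi-squared P, stars, and disjoint Fisher P.
#' @export
island_relation_test <- function(cpgs, mqtl_flags) {
  stopifnot(nrow(cpgs) == length(mqtl_flags))
  rel <- cpgs$island_relation
  n1 <- sum(mqtl_flags); n2 <- length(mqtl_flags)
  if (n1 == 0) stop("no mQTL-matched CpGs")
  rows <- lapply(island_relation_levels(), function(cat) {
    x1 <- sum(mqtl_flags & rel == cat)
    x2 <- sum(rel == cat)
    if (x2 == 0) {
      return(data.frame(category = cat, prop_mqtl = NA_real_,
                        prop_all = 0, p = NA_real_, stars = "",
                        fisher_p = NA_real_, stringsAsFactors = FALSE))
    }
    p <- tryCatch(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value,
      warning = function(w) suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value))
    fp <- tryCatch(
      fisher_p(x1, n1 - x1, x2 - x1, (n2 - n1) - (x2 - x1)),
      error = function(e) NA_real_)
    data.frame(category = cat, prop_mqtl = x1 / n1, prop_all = x2 / n2,
               p = p, stars = star_code(p), fisher_p = fp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  shore <- rel %in% c("N_Shore", "S_Shore")
  x1 <- sum(mqtl_flags & shore); x2 <- sum(shore)
  shore_test <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  attr(out, "shore_test") <- list(prop_mqtl = x1 / n1, prop_all = x2 / n2,
                                  p = shore_test$p.value)
  class(out) <- c("island_enrichment", "data.frame")
  out
}

#' @keywords internal
star_code <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.island_enrichment <- function(x, ...) {
  cat("island-relation distribution, mQTL-matched vs all CpGs:\n")
  df <- as.data.frame(x)
  df$prop_mqtl <- sprintf("%.3f", df$prop_mqtl)
  df$prop_all <- sprintf("%.3f", df$prop_all)
  df$p <- format(df$p, digits = 3)
  print(df[, c("category", "prop_mqtl", "prop_all", "p", "stars")],
        row.names = FALSE)
  st <- attr(x, "shore_test")
  cat(sprintf("shore (N_Shore/S_Shore) vs rest: %.3f vs %.3f, chi-squared P = %s\n",
              st$prop_mqtl, st$prop_all, format(st$p, digits = 3)))
  invisible(x)
}
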