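#' Two-sided or one-sided Fisher's exact test on a 2x2 table
#'
#' Thin, validated wrapper around [stats::fisher.test()] used by every
#' contingency-table comparison in the pipeline (frame divisibility, peptide
#' hit-rate enrichment, Ribo-seq enrichment, per-replicate editing tests).
#' Two-sided p-values follow the point-probability rule: the sum of
#' probabilities of all tables (at fixed margins) no more likely than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = groups,
#'   columns = success/failure. Alternatively supply `a,b,c,d`.
#' @param a,b,c,d scalar counts (row-major) used when `table` is missing.
#' @param alternative "two_sided", "greater" or "less" (for the odds ratio
#'   of group 1 relative to group 2).
#' @return list with `odds_ratio` (conditional MLE) and `p`.
#' @examples
#' fisher_exact_2x2(a = 182, b = 80, c = 159, d = 490)$p  # ~2e-36
#' @export
fisher_exact_2x2 <- function(table = NULL, a = NULL, b = NULL, c = NULL,
                             d = NULL,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(table)) {
    table <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  }
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) {
    stop("fisher_exact_2x2 requires a 2x2 table")
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater",
                less = "less")
  ft <- stats::fisher.test(table, alternative = alt)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Combine independent p-values with Fisher's method
#'
#' chi-squared statistic `-2 * sum(log(p))` on `2k` degrees of freedom; used
#' to combine per-replicate differential-editing tests.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return list with `chi2`, `df`, and the combined `p`.
#' @export
fisher_method_combine <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) stop("no p-values to combine")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]; handle underflow before combining")
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input; empty in, empty out.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped. The exact null distribution is used for
#' n <= 25 untied differences; otherwise the normal approximation with
#' continuity correction.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param two_tailed logical; one-sided alternative is "greater" (x > y).
#' @return list with `p`, `n` (non-zero pairs) and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, two_tailed = TRUE) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(p = 1, n = 0L, all_zero = TRUE))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  alt <- if (two_tailed) "two.sided" else "greater"
  wt <- suppressWarnings(
    stats::wilcox.test(nz, alternative = alt, mu = 0,
                       exact = exact, correct = TRUE)
  )
  list(p = wt$p.value, n = length(nz), all_zero = FALSE)
}

#' Fold change implied by a difference of log2-odds splice-site scores
#'
#' Splice-site strength models (e.g. maximum-entropy 5' splice-site scores)
#' report log2 odds of matching the consensus model; the likelihood fold
#' change between two variants is `2^(after - before)`.
#'
#' @param score_before,score_after log2-odds scores.
#' @return the fold change (numeric).
#' @examples
#' log2_odds_fold_change(5.29, 9.46)  # ~18, an over 16-fold increase
#' @export
log2_odds_fold_change <- function(score_before, score_after) {
  2^(score_after - score_before)
}
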