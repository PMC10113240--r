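#' Two-sided rank-sum (Mann-Whitney / Wilcoxon) test
#'
#' Thin wrapper around [stats::wilcox.test()] fixing the conventions used
#' throughout the package: two-sided, exact when both groups have at most
#' 10 untied observations (e.g. the minimal 4-vs-4 fully separated
#' configuration gives p = 2/70 = 0.0286), normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param paired Paired signed-rank test instead of the two-sample test.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y, paired = FALSE) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  if (paired && all(x == y)) return(1)  # all zero differences: no evidence
  small <- length(x) <= 10 && length(y) <= 10
  ties <- anyDuplicated(c(x, y)) > 0
  res <- suppressWarnings(stats::wilcox.test(
    x, y, paired = paired, exact = small && !ties, correct = TRUE,
    alternative = "two.sided"))
  unname(res$p.value)
}
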