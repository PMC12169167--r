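#' Simple two-sample and correlation tests
#'
#' Thin, contract-checked wrappers around the base distributional tests
#' used for baseline group comparisons (Student's t), the non-normal
#' hormone variables (Mann-Whitney U between groups, Wilcoxon
#' signed-rank within group) and bivariate relationships (Pearson r).
#'
#' @name simple_tests
NULL

#' @rdname simple_tests
#' @param group_a,group_b numeric vectors (independent samples).
#' @return `student_t_independent()`: list with `t`, `df`, `p`,
#'   `mean_diff` (pooled-variance, two-sided).
#' @export
student_t_independent <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stopf("need at least 2 observations per group")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    stopf("zero pooled variance; t undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(group_a) - mean(group_b))
}

#' @rdname simple_tests
#' @param exact_max largest per-group n for which the exact U
#'   distribution is used (default 12); larger samples, or ties, use the
#'   normal approximation with tie correction.
#' @return `mann_whitney_u()`: list with `U`, `p`, `exact`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 12L) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stopf("need at least 2 observations per group")
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- !has_ties && length(group_a) <= exact_max &&
    length(group_b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = !use_exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' @rdname simple_tests
#' @param paired_a,paired_b numeric vectors of paired observations.
#' @return `wilcoxon_signed_rank()`: list with `W`, `p`, `exact`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_max = 12L) {
  if (length(paired_a) != length(paired_b)) stopf("pairs must have equal length")
  d <- paired_a - paired_b
  d_nz <- d[d != 0]
  if (length(d_nz) < 2L) {
    stopf("fewer than 2 nonzero paired differences; test undefined")
  }
  has_ties <- anyDuplicated(abs(d_nz)) > 0L
  use_exact <- !has_ties && length(d_nz) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(paired_a, paired_b, paired = TRUE,
                       exact = use_exact, correct = !use_exact))
  list(W = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' @rdname simple_tests
#' @param x,y numeric vectors, `n >= 3`, finite variance.
#' @return `pearson_r()`: list with `r`, `p` (two-sided via the t
#'   transform), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stopf("zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
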