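#' Contingency-table test for a score class vs metastasis cross-tabulation
#'
#' For 2x2 tables the default is the chi-square test with Yates continuity
#' correction (clamped at zero); r x c tables use the uncorrected Pearson
#' chi-square. `method = "auto"` switches a 2x2 table to Fisher's exact test
#' whenever any expected cell count falls below 5, the usual small-sample
#' rule. `method = "fisher"` forces the exact test (no statistic reported).
#'
#' @param counts A non-negative integer matrix, at least 2x2, with positive
#'   row and column margins.
#' @param method `"auto"`, `"pearson"`, `"yates"`, or `"fisher"`.
#' @return A one-row tibble: `method` (the method actually used),
#'   `statistic` (`NA` for Fisher), `df`, `p_value`.
#' @export
#' @examples
#' contingency_test(matrix(c(35, 3, 22, 12), 2, byrow = TRUE), "yates")
contingency_test <- function(counts,
                             method = c("auto", "pearson", "yates",
                                        "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("table must be at least 2x2")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("degenerate table: a row or column margin is zero")
  }
  is2x2 <- nrow(counts) == 2 && ncol(counts) == 2
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (method == "auto") {
    method <- if (is2x2 && any(expected < 5)) "fisher"
              else if (is2x2) "yates" else "pearson"
  }
  if (method == "yates" && !is2x2) {
    abort("Yates correction applies only to 2x2 tables")
  }
  if (method == "fisher") {
    ft <- fisher.test(counts)
    return(tibble(method = "fisher", statistic = NA_real_, df = NA_integer_,
                  p_value = ft$p.value))
  }
  ct <- suppressWarnings(
    chisq.test(counts, correct = identical(method, "yates")))
  tibble(method = method, statistic = unname(ct$statistic),
         df = as.integer(ct$parameter), p_value = ct$p.value)
}

#' Two-group comparison of a continuous variable
#'
#' Student's t test (equal-variance, the classical form) or the
#' Mann-Whitney U test. The Mann-Whitney P is exact (no ties, both groups
#' of size <= 8) or uses the normal approximation with tie correction and no
#' continuity correction otherwise. When every value in both groups is
#' identical the comparison is vacuous: P = 1 with `degenerate = TRUE`.
#'
#' @param values_a,values_b Numeric vectors, each non-empty (t test needs
#'   >= 2 per group).
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @return A one-row tibble: `method`, `statistic` (U or t), `p_value`,
#'   `degenerate`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
compare_groups <- function(values_a, values_b,
                           method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  if (!length(values_a) || !length(values_b)) {
    abort("both groups must be non-empty")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    warn("all values identical across both groups; P = 1 by convention")
    stat <- if (method == "mann_whitney") {
      length(values_a) * length(values_b) / 2
    } else 0
    return(tibble(method = method, statistic = stat, p_value = 1,
                  degenerate = TRUE))
  }
  if (method == "t_test") {
    if (length(values_a) < 2 || length(values_b) < 2) {
      abort("t test needs at least 2 values per group")
    }
    tt <- t.test(values_a, values_b, var.equal = TRUE)
    return(tibble(method = method, statistic = unname(tt$statistic),
                  p_value = tt$p.value, degenerate = FALSE))
  }
  ties <- any(duplicated(pooled))
  use_exact <- !ties && length(values_a) <= 8 && length(values_b) <= 8
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = use_exact,
                correct = FALSE))
  tibble(method = method, statistic = unname(wt$statistic),
         p_value = min(wt$p.value, 1), degenerate = FALSE)
}

#' Pearson correlation of a grading score with time to metastasis
#'
#' Applied to the metastatic subjects: a negative r means higher scores go
#' with earlier metastasis. Uses the t-distributed test with n - 2 degrees
#' of freedom.
#'
#' @param scores,times Numeric vectors of equal length >= 3, each with
#'   nonzero variance.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_mfs_corr <- function(scores, times) {
  if (length(scores) != length(times)) abort("length mismatch")
  if (length(scores) < 3) abort("need at least 3 pairs")
  if (var(scores) == 0 || var(times) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- cor.test(scores, times, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(scores))
}
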