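# ROC analysis for grading scores. Direction is fixed throughout: a higher
# score predicts metastasis, and an operating point calls "score >= cutoff"
# positive.

check_binary_labels <- function(labels) {
  labels <- as.numeric(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
    abort("labels must be binary 0/1")
  }
  if (length(unique(labels)) < 2) {
    abort("both classes must be present in labels")
  }
  labels
}

# Midrank placement values: for each case, the fraction of the other class
# it beats (ties count one half). AUC is the mean placement of the positives.
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v_pos <- vapply(pos, function(x) {
    mean((x > neg) + 0.5 * (x == neg))
  }, numeric(1))
  v_neg <- vapply(neg, function(y) {
    mean((pos > y) + 0.5 * (pos == y))
  }, numeric(1))
  list(v_pos = v_pos, v_neg = v_neg, auc = mean(v_pos))
}

#' ROC curve and AUC for a grading score
#'
#' The AUC is the Mann-Whitney probability that a random metastatic subject
#' scores above a random non-metastatic one, ties counting one half.
#' Operating points are computed at every distinct observed score.
#' The AUC standard error is DeLong's placement-value estimate.
#'
#' @param scores Numeric score vector (higher = more metastatic potential).
#' @param labels Binary outcome (1/TRUE = metastatic); both classes
#'   required.
#' @return A list of class `ppgl_roc`: `auc`, `auc_se`, `n_positive`,
#'   `n_negative`, and `points`, a tibble of (`cutoff`, `sensitivity`,
#'   `specificity`) sorted by increasing cutoff.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) abort("length mismatch")
  if (any(is.na(scores))) abort("missing scores")
  pl <- placement_values(scores, labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  auc_var <- var(pl$v_pos) / m + var(pl$v_neg) / n
  cutoffs <- sort(unique(scores))
  points <- tibble(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c) {
      mean(scores[labels == 1] >= c)
    }, numeric(1)),
    specificity = vapply(cutoffs, function(c) {
      mean(scores[labels == 0] < c)
    }, numeric(1)))
  structure(
    list(auc = pl$auc, auc_se = sqrt(auc_var),
         n_positive = m, n_negative = n, points = points),
    class = "ppgl_roc")
}

#' @export
print.ppgl_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (SE %.3f), %d positive / %d negative\n",
              x$auc, x$auc_se, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
tidy.ppgl_roc <- function(x, ...) x$points

#' @export
glance.ppgl_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' DeLong comparison of two correlated AUCs
#'
#' Both scores are measured on the same subjects, so their AUCs are
#' correlated; DeLong's method estimates the covariance of the paired AUCs
#' from per-subject placement values and tests the difference with a normal
#' statistic. The test is symmetric in argument order (same P, negated
#' difference). Identical score vectors give a zero difference with zero
#' variance, reported as P = 1.
#'
#' @param scores_1,scores_2 Two score vectors on the same subjects.
#' @param labels Shared binary outcome.
#' @return A one-row tibble: `auc_1`, `auc_2`, `difference` (auc_1 -
#'   auc_2), `se_difference`, `z`, `p_value`.
#' @export
#' @examples
#' delong_compare(c(1, 2, 3, 4), c(4, 3, 2, 1), c(0, 0, 1, 1))
delong_compare <- function(scores_1, scores_2, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_1) != length(labels) ||
      length(scores_2) != length(labels)) {
    abort("length mismatch")
  }
  p1 <- placement_values(scores_1, labels)
  p2 <- placement_values(scores_2, labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  s10 <- stats::cov(cbind(p1$v_pos, p2$v_pos))
  s01 <- stats::cov(cbind(p1$v_neg, p2$v_neg))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- p1$auc - p2$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_1 = p1$auc, auc_2 = p2$auc, difference = diff,
         se_difference = sqrt(max(var_diff, 0)), z = z, p_value = p)
}

#' Youden-index cutoff for a grading score
#'
#' Scans every distinct observed score as a candidate cutoff (rule: score >=
#' cutoff is called positive) and returns the one maximizing J =
#' sensitivity + specificity - 1. Ties are broken toward the smallest
#' cutoff, which maximizes sensitivity at equal J.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))  # cutoff 3, J = 1
youden_cutoff <- function(scores, labels) {
  roc <- roc_auc(scores, labels)
  pts <- roc$points %>%
    mutate(j = .data$sensitivity + .data$specificity - 1) %>%
    arrange(desc(.data$j), .data$cutoff)
  best <- pts[1, ]
  tibble(cutoff = best$cutoff, j = best$j,
         sensitivity = best$sensitivity, specificity = best$specificity)
}
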