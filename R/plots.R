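# ggplot2 figures for the result objects. Curve data stay exportable as
# plain tables; these helpers only draw them.

#' Plot a Kaplan-Meier metastasis-free survival curve
#'
#' @param object A `ppgl_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppgl_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since surgery",
                  y = "Metastasis-free survival") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `ppgl_roc` object from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppgl_roc <- function(object, ...) {
  pts <- object$points %>%
    arrange(desc(.data$cutoff))
  df <- tibble(fpr = c(0, 1 - pts$specificity, 1),
               tpr = c(0, pts$sensitivity, 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' ROC curves of the three scoring systems from a validation report
#'
#' @param report A `ppgl_validation` object.
#' @return A ggplot overlaying the GAPP, PASS and M-GAPP ROC curves.
#' @export
plot_roc_comparison <- function(report) {
  if (is.null(report$roc)) abort("report has no ROC stage")
  df <- purrr::imap(report$roc$rocs, function(r, nm) {
    pts <- arrange(r$points, desc(.data$cutoff))
    tibble(system = toupper(nm),
           fpr = c(0, 1 - pts$specificity, 1),
           tpr = c(0, pts$sensitivity, 1))
  }) %>% bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$system)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Score") +
    ggplot2::theme_minimal()
}

#' Metastasis-free survival curves by score class from a validation report
#'
#' @param report A `ppgl_validation` object.
#' @param system `"gapp"`, `"pass"` or `"mgapp"`.
#' @return A ggplot of the grouped Kaplan-Meier curves with the log-rank P.
#' @export
plot_mfs <- function(report, system = c("gapp", "pass", "mgapp")) {
  system <- match.arg(system)
  if (is.null(report$mfs)) abort("report has no MFS stage")
  m <- report$mfs[[system]]
  ggplot2::ggplot(m$curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since surgery",
                  y = "Metastasis-free survival",
                  colour = NULL,
                  title = sprintf("Log-rank P = %.3g", m$log_rank$p_value)) +
    ggplot2::theme_minimal()
}
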