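#' Cox proportional-hazards association of score parameters with metastasis
#'
#' Fits a Cox model to right-censored time-to-metastasis data by partial
#' likelihood (Newton-Raphson, via the survival machinery). Univariate use
#' passes one covariate; multivariate use passes several, fitted jointly.
#' Ties are handled by the Breslow method by default (the convention of the
#' classical clinical-statistics packages), with Efron available. Wald 95%
#' confidence intervals are exp(coef +/- 1.96 SE).
#'
#' Monotone partial likelihoods (complete separation, e.g. every event in
#' one category of a binary covariate) are refused with a diagnostic rather
#' than returned as a huge finite hazard ratio; zero-variance covariates are
#' likewise errors.
#'
#' @param data A data frame holding the time, event, and covariate columns.
#' @param time,event Column names (strings) of the follow-up time and the
#'   0/1 or logical event indicator.
#' @param covariates Character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A tibble with one row per covariate: `term`, `estimate` (log
#'   hazard ratio), `std_error`, `hr`, `conf_low`, `conf_high`, `p_value`,
#'   plus attributes `ties`, `iterations`, `converged`, `n`, `n_events`.
#' @export
#' @examples
#' d <- data.frame(t = c(1, 2, 3), e = c(1, 1, 0), x = c(1, 0, 1))
#' fit_cox(d, "t", "e", "x")  # hr = 1/sqrt(2)
fit_cox <- function(data, time, event, covariates,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(time, event, covariates), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  ev <- as.numeric(data[[event]])
  if (sum(ev) < 1) abort("need at least one event")
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.logical(v)) v <- as.numeric(v)
    if (is.numeric(v) && var(v) == 0) {
      abort(paste0("zero-variance covariate: ", cv))
    }
  }
  fml <- reformulate(covariates,
                     response = paste0("Surv(", time, ", ", event, ")"))
  warned <- character()
  fit <- withCallingHandlers(
    coxph(fml, data = data, ties = ties),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  coefs <- sm$coefficients
  se <- coefs[, "se(coef)"]
  beta <- coefs[, "coef"]
  infinite_like <- any(grepl("infinite", warned)) ||
    any(!is.finite(beta)) || any(abs(beta) > 15) || any(se > 1e3)
  if (infinite_like) {
    abort(paste0(
      "monotone partial likelihood (complete separation): coefficient for ",
      paste(rownames(coefs)[abs(beta) > 15 | se > 1e3 | !is.finite(beta)],
            collapse = ", "),
      " diverges; the hazard ratio is not estimable"))
  }
  out <- tibble(
    term = rownames(coefs),
    estimate = unname(beta),
    std_error = unname(se),
    hr = exp(unname(beta)),
    conf_low = exp(unname(beta) - 1.96 * unname(se)),
    conf_high = exp(unname(beta) + 1.96 * unname(se)),
    p_value = unname(coefs[, "Pr(>|z|)"]))
  attr(out, "ties") <- ties
  attr(out, "iterations") <- fit$iter
  attr(out, "converged") <- TRUE
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  out
}

#' Kaplan-Meier metastasis-free survival curve
#'
#' Product-limit estimator of the metastasis-free survival function. At tied
#' times events are processed before censorings (the standard convention).
#' The curve starts at S(0) = 1 and is non-increasing and piecewise constant
#' between event times.
#'
#' @param times Non-negative follow-up / event times (months).
#' @param events Logical or 0/1 event indicators.
#' @return A tibble of class `ppgl_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, starting with the `time = 0` row.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
km_estimate <- function(times, events) {
  if (!length(times)) abort("empty input")
  if (length(times) != length(events)) abort("length mismatch")
  if (any(is.na(times)) || any(is.na(events))) abort("missing values")
  if (any(times < 0)) abort("times must be non-negative")
  events <- as.numeric(events)
  sf <- survfit(Surv(times, events) ~ 1)
  out <- tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                n_censor = sf$n.censor, survival = sf$surv)
  out <- bind_rows(
    tibble(time = 0, n_risk = length(times), n_event = 0, n_censor = 0,
           survival = 1),
    filter(out, .data$time > 0))
  class(out) <- c("ppgl_km", class(out))
  out
}

#' Log-rank comparison of metastasis-free survival between groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, chi-square with (groups - 1) degrees of freedom.
#'
#' @param times,events As for [km_estimate()].
#' @param group A grouping vector (>= 2 non-empty groups).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
log_rank <- function(times, events, group) {
  if (length(times) != length(events) || length(times) != length(group)) {
    abort("length mismatch")
  }
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) abort("need at least 2 non-empty groups")
  events <- as.numeric(events)
  if (sum(events) < 1) abort("need at least one event")
  sd <- survdiff(Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  tibble(statistic = unname(sd$chisq), df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}
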