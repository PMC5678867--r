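# End-to-end validation pipeline: score the cohort, then reproduce the full
# table set of a grading-score validation study — baseline comparison, Cox
# association per parameter, score distribution and classification
# contingencies, ROC comparison, metastasis-free survival, and score/MFS
# correlations. Stages that need both outcome classes degrade gracefully:
# the stage is skipped with a logged reason instead of failing the run.

cox_time_event <- function(scored) {
  scored %>%
    mutate(.time = ifelse(.data$metastasis,
                          .data$time_to_metastasis_months,
                          .data$followup_months),
           .event = as.numeric(.data$metastasis))
}

baseline_continuous <- function(scored, var, method) {
  a <- scored[[var]][scored$metastasis]
  b <- scored[[var]][!scored$metastasis]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  res <- tryCatch(suppressWarnings(compare_groups(a, b, method)),
                  error = function(e) {
                    tibble(method = NA_character_, p_value = NA_real_)
                  })
  tibble(variable = var, kind = "continuous", method = res$method,
         metastatic = mean(a), non_metastatic = mean(b),
         p_value = res$p_value)
}

baseline_binary <- function(scored, var) {
  tab <- table(factor(scored[[var]], levels = c(FALSE, TRUE)),
               factor(scored$metastasis, levels = c(FALSE, TRUE)))
  res <- tryCatch(contingency_test(unclass(tab), "auto"),
                  error = function(e) {
                    tibble(method = NA_character_, p_value = NA_real_)
                  })
  tibble(variable = var, kind = "binary", method = res$method,
         metastatic = mean(scored[[var]][scored$metastasis]),
         non_metastatic = mean(scored[[var]][!scored$metastasis]),
         p_value = res$p_value)
}

baseline_table <- function(scored) {
  cont <- c(age_years = "t_test", height_cm = "t_test",
            weight_kg = "t_test", bmi = "t_test",
            tumor_size_cm = "t_test",
            umn_ug_day = "mann_whitney", unm_ug_day = "mann_whitney",
            followup_months = "t_test")
  cont <- cont[names(cont) %in% names(scored)]
  rows <- purrr::imap(cont, function(m, v) baseline_continuous(scored, v, m))
  scored2 <- scored %>%
    mutate(female = .data$sex == "female",
           pgl = .data$tumor_site == "PGL",
           functioning = .data$umn_elevated | .data$unm_elevated,
           noradrenergic = .data$catecholamine_type == "noradrenergic",
           sdhb_loss = !.data$sdhb_ihc_positive)
  bin <- c("female", "pgl", "familial", "functioning", "noradrenergic",
           "sdhb_loss")
  rows2 <- purrr::map(bin, function(v) baseline_binary(scored2, v))
  bind_rows(c(unname(rows), rows2))
}

gapp_cox_covariates <- function(scored) {
  scored %>%
    mutate(gapp_pattern = .data$large_irregular_nest | .data$pseudorosette,
           cellularity_moderate = .data$cellularity_class == "moderate",
           cellularity_high = .data$cellularity_class == "high",
           ki67_1_3 = .data$ki67_percent >= 1 & .data$ki67_percent <= 3,
           ki67_gt3 = .data$ki67_percent > 3,
           invasion = .data$vascular_invasion | .data$capsular_invasion,
           noradrenergic = .data$catecholamine_type == "noradrenergic")
}

mgapp_cox_covariates <- function(scored) {
  scored %>%
    mutate(mgapp_pattern = .data$large_irregular_nest | .data$pseudorosette,
           ki67_ge1 = .data$ki67_percent >= 1,
           noradrenergic = .data$catecholamine_type == "noradrenergic",
           sdhb_loss = !.data$sdhb_ihc_positive)
}

cox_stage <- function(scored, covariates, ties, log_skip) {
  dat <- cox_time_event(scored)
  uni <- purrr::map(covariates, function(cv) {
    tryCatch(
      fit_cox(dat, ".time", ".event", cv, ties = ties) %>%
        mutate(mode = "univariate"),
      error = function(e) {
        log_skip(paste0("univariate Cox for '", cv, "': ",
                        conditionMessage(e)))
        NULL
      })
  })
  multi <- tryCatch(
    fit_cox(dat, ".time", ".event", covariates, ties = ties) %>%
      mutate(mode = "multivariate"),
    error = function(e) {
      log_skip(paste0("multivariate Cox: ", conditionMessage(e)))
      NULL
    })
  bind_rows(bind_rows(uni), multi)
}

score_comparison_table <- function(scored) {
  scored <- scored %>%
    mutate(pass_band = ifelse(.data$pass_high, "PASS >=4", "PASS <4"),
           mgapp_band = ifelse(.data$mgapp_high, "M-GAPP >=3", "M-GAPP <3"))
  med_iqr <- function(x) {
    sprintf("%.1f [%.1f, %.1f]", median(x), quantile(x, 0.25),
            quantile(x, 0.75))
  }
  one_system <- function(score_col, class_col) {
    s_met <- scored[[score_col]][scored$metastasis]
    s_non <- scored[[score_col]][!scored$metastasis]
    mw <- suppressWarnings(compare_groups(s_met, s_non, "mann_whitney"))
    tab <- table(scored[[class_col]], factor(scored$metastasis,
                                             levels = c(FALSE, TRUE)))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    ct <- if (nrow(tab) >= 2) contingency_test(unclass(tab), "auto") else {
      tibble(p_value = NA_real_)
    }
    classes <- rownames(tab)
    bind_rows(
      tibble(system = score_col, row = "score",
             non_metastatic = med_iqr(s_non), metastatic = med_iqr(s_met),
             n = nrow(scored), metastatic_fraction = NA_real_,
             p_value = mw$p_value),
      tibble(system = score_col, row = classes,
             non_metastatic = sprintf("%d (%.1f%%)", tab[, 1],
                                      100 * tab[, 1] / rowSums(tab)),
             metastatic = sprintf("%d (%.1f%%)", tab[, 2],
                                  100 * tab[, 2] / rowSums(tab)),
             n = as.integer(rowSums(tab)),
             metastatic_fraction = tab[, 2] / rowSums(tab),
             p_value = c(ct$p_value, rep(NA_real_, length(classes) - 1))))
  }
  bind_rows(one_system("gapp_score", "gapp_class"),
            one_system("pass_score", "pass_band"),
            one_system("mgapp_score", "mgapp_band"))
}

roc_stage <- function(scored) {
  labels <- as.numeric(scored$metastasis)
  systems <- c(gapp = "gapp_score", pass = "pass_score",
               mgapp = "mgapp_score")
  rocs <- purrr::map(systems, function(col) roc_auc(scored[[col]], labels))
  auc_tab <- purrr::imap(rocs, function(r, nm) {
    ci <- r$auc + c(-1.96, 1.96) * r$auc_se
    tibble(system = nm, auc = r$auc, auc_se = r$auc_se,
           conf_low = max(0, ci[1]), conf_high = min(1, ci[2]))
  }) %>% bind_rows()
  pairs <- list(c("mgapp", "gapp"), c("mgapp", "pass"), c("pass", "gapp"))
  cmp <- purrr::map(pairs, function(pr) {
    d <- delong_compare(scored[[systems[pr[1]]]], scored[[systems[pr[2]]]],
                        labels)
    tibble(system_1 = pr[1], system_2 = pr[2],
           auc_1 = d$auc_1, auc_2 = d$auc_2,
           difference = d$difference, p_value = d$p_value)
  }) %>% bind_rows()
  youden <- purrr::imap(systems, function(col, nm) {
    yc <- youden_cutoff(scored[[col]], labels)
    mutate(yc, system = nm, .before = 1)
  }) %>% bind_rows()
  list(rocs = rocs, auc = auc_tab, delong = cmp, youden = youden)
}

mfs_stage <- function(scored) {
  dat <- cox_time_event(scored)
  groupings <- list(gapp = dat$gapp_class,
                    pass = factor(ifelse(dat$pass_high, "PASS >=4",
                                         "PASS <4")),
                    mgapp = factor(ifelse(dat$mgapp_high, "M-GAPP >=3",
                                          "M-GAPP <3")))
  purrr::imap(groupings, function(g, nm) {
    g <- droplevels(g)
    curves <- purrr::map(levels(g), function(lv) {
      sel <- g == lv
      km_estimate(dat$.time[sel], dat$.event[sel]) %>%
        mutate(group = lv, .before = 1)
    }) %>% bind_rows()
    lr <- if (nlevels(g) >= 2 && sum(dat$.event) >= 1) {
      log_rank(dat$.time, dat$.event, g)
    } else {
      tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
    }
    list(curves = curves, log_rank = lr)
  })
}

correlation_stage <- function(scored, log_skip) {
  met <- filter(scored, .data$metastasis)
  purrr::map(c(gapp = "gapp_score", pass = "pass_score",
               mgapp = "mgapp_score"),
             function(col) {
               tryCatch(
                 pearson_mfs_corr(met[[col]],
                                  met$time_to_metastasis_months) %>%
                   mutate(system = col, .before = 1),
                 error = function(e) {
                   log_skip(paste0("correlation for ", col, ": ",
                                   conditionMessage(e)))
                   NULL
                 })
             }) %>% bind_rows()
}

#' Run the full score-validation pipeline on a cohort
#'
#' Computes the score panel for every subject, then the complete set of
#' validation outputs: baseline group comparison (overall and split by
#' tumor site), univariate and multivariate Cox association of each GAPP /
#' PASS / M-GAPP parameter with metastasis, score distributions and
#' classification contingency tables, the three ROC curves with pairwise
#' DeLong comparisons and Youden cutoffs, Kaplan-Meier metastasis-free
#' survival with log-rank tests, and the score/time-to-metastasis Pearson
#' correlations among metastatic subjects. Deterministic given the cohort
#' and configuration. Stages whose preconditions fail (e.g. a single-class
#' cohort) are skipped with the reason recorded in `$skip_log`.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param config A [score_config()].
#' @param ties Tie handling for the Cox stages: `"breslow"` or `"efron"`.
#' @return An object of class `ppgl_validation`.
#' @export
#' @examples
#' report <- generate_cohort(default_cohort_config(seed = 3)) |>
#'   run_validation()
#' report$roc$auc
run_validation <- function(cohort, config = score_config(),
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cohort <- as_tibble(cohort)
  if (!nrow(cohort)) abort("empty cohort")
  scored <- score_cohort(cohort, config)
  skip_log <- character()
  log_skip <- function(msg) skip_log <<- c(skip_log, msg)

  both_classes <- length(unique(scored$metastasis)) == 2 &&
    sum(scored$metastasis) >= 2 && sum(!scored$metastasis) >= 2

  baseline <- if (both_classes) baseline_table(scored) else {
    log_skip("baseline comparison: need both outcome classes")
    NULL
  }
  baseline_by_site <- if (both_classes) {
    purrr::map(split(scored, scored$tumor_site), function(sub) {
      if (length(unique(sub$metastasis)) == 2) baseline_table(sub) else NULL
    })
  } else NULL

  cox <- if (both_classes) {
    list(
      gapp = cox_stage(gapp_cox_covariates(scored),
                       c("gapp_pattern", "comedo_necrosis",
                         "cellularity_moderate", "cellularity_high",
                         "ki67_1_3", "ki67_gt3", "invasion",
                         "noradrenergic"),
                       ties, log_skip),
      pass = cox_stage(scored, pass_items()$item, ties, log_skip),
      mgapp = cox_stage(mgapp_cox_covariates(scored),
                        c("mgapp_pattern", "comedo_necrosis",
                          "vascular_invasion", "ki67_ge1", "noradrenergic",
                          "sdhb_loss"),
                        ties, log_skip))
  } else {
    log_skip("Cox stage: need >= 2 subjects per outcome class")
    NULL
  }

  scores_tab <- if (both_classes) score_comparison_table(scored) else {
    log_skip("score comparison: need both outcome classes")
    NULL
  }
  roc <- if (both_classes) roc_stage(scored) else {
    log_skip("ROC stage: need >= 2 subjects per outcome class")
    NULL
  }
  mfs <- if (sum(scored$metastasis) >= 1) mfs_stage(scored) else {
    log_skip("MFS stage: no events")
    NULL
  }
  correlations <- correlation_stage(scored, log_skip)

  structure(
    list(scored = scored,
         baseline = baseline,
         baseline_by_site = baseline_by_site,
         cox = cox,
         scores = scores_tab,
         roc = roc,
         mfs = mfs,
         correlations = correlations,
         skip_log = skip_log,
         metadata = list(
           n = nrow(scored),
           n_metastatic = sum(scored$metastasis),
           config = config,
           ties = ties,
           package_version = as.character(packageVersion("ppglscore")))),
    class = "ppgl_validation")
}

#' @export
print.ppgl_validation <- function(x, ...) {
  cat(sprintf("PPGL score validation: %d subjects, %d metastatic (%.1f%%)\n",
              x$metadata$n, x$metadata$n_metastatic,
              100 * x$metadata$n_metastatic / x$metadata$n))
  if (!is.null(x$roc)) {
    for (i in seq_len(nrow(x$roc$auc))) {
      cat(sprintf("  %-6s AUC %.3f (%.3f-%.3f)\n", x$roc$auc$system[i],
                  x$roc$auc$auc[i], x$roc$auc$conf_low[i],
                  x$roc$auc$conf_high[i]))
    }
  }
  if (length(x$skip_log)) {
    cat("skipped stages:\n")
    for (s in x$skip_log) cat("  -", s, "\n")
  }
  invisible(x)
}

#' @export
tidy.ppgl_validation <- function(x, ...) {
  parts <- list()
  if (!is.null(x$baseline)) {
    parts$baseline <- x$baseline %>%
      mutate(stage = "baseline", term = .data$variable) %>%
      select("stage", "term", "p_value")
  }
  if (!is.null(x$cox)) {
    parts$cox <- purrr::imap(x$cox, function(tab, nm) {
      if (is.null(tab) || !nrow(tab)) return(NULL)
      tab %>%
        mutate(stage = paste0("cox_", nm, "_", .data$mode)) %>%
        select("stage", "term", "p_value")
    }) %>% bind_rows()
  }
  if (!is.null(x$roc)) {
    parts$delong <- x$roc$delong %>%
      mutate(stage = "delong",
             term = paste(.data$system_1, "vs", .data$system_2)) %>%
      select("stage", "term", "p_value")
  }
  if (!is.null(x$mfs)) {
    parts$mfs <- purrr::imap(x$mfs, function(m, nm) {
      mutate(m$log_rank, stage = "log_rank", term = nm) %>%
        select("stage", "term", "p_value")
    }) %>% bind_rows()
  }
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    parts$corr <- x$correlations %>%
      mutate(stage = "mfs_correlation", term = .data$system) %>%
      select("stage", "term", "p_value")
  }
  bind_rows(parts)
}

#' @export
glance.ppgl_validation <- function(x, ...) {
  out <- tibble(n = x$metadata$n, n_metastatic = x$metadata$n_metastatic,
                prevalence = x$metadata$n_metastatic / x$metadata$n)
  if (!is.null(x$roc)) {
    aucs <- setNames(x$roc$auc$auc, paste0("auc_", x$roc$auc$system))
    out <- bind_cols(out, as_tibble(as.list(aucs)))
  }
  out
}

#' Write every table of a validation report as delimited text
#'
#' One CSV per report table (baseline, Cox per system, score comparison,
#' ROC/AUC, DeLong, Youden, log-rank, correlations) plus the MFS curve data
#' as (group, time, survival, at-risk) rows per system, under `dir`.
#'
#' @param report A `ppgl_validation` object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      readr::write_csv(x, file.path(dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }
  wr(report$baseline, "baseline")
  if (!is.null(report$cox)) {
    purrr::iwalk(report$cox, function(tab, nm) wr(tab, paste0("cox_", nm)))
  }
  wr(report$scores, "score_comparison")
  if (!is.null(report$roc)) {
    wr(report$roc$auc, "roc_auc")
    wr(report$roc$delong, "roc_delong")
    wr(report$roc$youden, "roc_youden")
  }
  if (!is.null(report$mfs)) {
    purrr::iwalk(report$mfs, function(m, nm) {
      wr(m$curves, paste0("mfs_curves_", nm))
      wr(m$log_rank, paste0("mfs_logrank_", nm))
    })
  }
  wr(report$correlations, "mfs_correlations")
  invisible(dir)
}
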