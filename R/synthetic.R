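# Synthetic PPGL cohort generator. The defaults are calibrated to the
# published cohort summaries (n = 72, 20.8% metastatic, SDHB-loss rates
# 33.3% vs 10.5%, noradrenergic 53.8% vs 29.8% of functioning tumors, mean
# follow-up 43.5 months); features are drawn conditionally independent given
# metastasis status because no joint structure is published.

#' Generative configuration for a synthetic PPGL cohort
#'
#' Every probability is a conditional prevalence pair `c(metastatic,
#' non_metastatic)`. Two event-time mechanisms are available:
#'
#' * `event_model = "status_first"` (default): metastasis status is drawn
#'   first (Bernoulli at `metastasis_prevalence`) and features are drawn
#'   conditional on it; metastatic subjects get a Weibull time to
#'   metastasis with the configured synchronous fraction mapped to times
#'   below 6 months by quantile mapping.
#' * `event_model = "proportional_hazards"`: a single binary covariate
#'   (`ph_covariate`, prevalence `ph_covariate_prevalence`) scales a Weibull
#'   baseline hazard by `exp(ph_log_hr)`; metastasis status emerges from the
#'   race between the event time and an exponential censoring time. This
#'   mode exists so that the Cox stage can be checked against a known truth.
#'
#' @param n_patients Cohort size.
#' @param metastasis_prevalence P(metastatic).
#' @param feature_prevalence Named list of `c(p_met, p_nonmet)` pairs for
#'   every binary feature column.
#' @param cellularity_probs List of two length-3 simplex vectors
#'   (low/moderate/high), `met` and `nonmet`.
#' @param ki67_meanlog,ki67_sdlog Log-normal Ki-67 (%) parameters, each a
#'   `c(met, nonmet)` pair.
#' @param pgl_fraction P(extra-adrenal site), shared across status.
#' @param weibull_shape,weibull_scale Time-to-metastasis Weibull (months).
#' @param synchronous_fraction Fraction of metastatic subjects whose event
#'   time is mapped below 6 months.
#' @param followup_mean_months Mean of the exponential follow-up/censoring
#'   time.
#' @param event_model `"status_first"` or `"proportional_hazards"`.
#' @param ph_covariate,ph_log_hr,ph_covariate_prevalence Proportional-
#'   hazards mode: covariate column name, its log hazard ratio, and its
#'   prevalence.
#' @param seed Integer seed; identical seed and config give a byte-identical
#'   cohort.
#' @return A list of class `cohort_config`.
#' @export
default_cohort_config <- function(n_patients = 72,
                                  metastasis_prevalence = 0.208,
                                  feature_prevalence = default_feature_prevalence(),
                                  cellularity_probs = list(
                                    met = c(0.3, 0.5, 0.2),
                                    nonmet = c(0.5, 0.4, 0.1)),
                                  ki67_meanlog = c(log(2), log(0.5)),
                                  ki67_sdlog = c(1.0, 0.9),
                                  pgl_fraction = 0.125,
                                  weibull_shape = 1.2,
                                  weibull_scale = 24,
                                  synchronous_fraction = 1 / 3,
                                  followup_mean_months = 43.5,
                                  event_model = c("status_first",
                                                  "proportional_hazards"),
                                  ph_covariate = "comedo_necrosis",
                                  ph_log_hr = 0,
                                  ph_covariate_prevalence = 0.5,
                                  seed = 20871L) {
  event_model <- match.arg(event_model)
  cfg <- structure(
    list(n_patients = n_patients,
         metastasis_prevalence = metastasis_prevalence,
         feature_prevalence = feature_prevalence,
         cellularity_probs = cellularity_probs,
         ki67_meanlog = ki67_meanlog,
         ki67_sdlog = ki67_sdlog,
         pgl_fraction = pgl_fraction,
         weibull_shape = weibull_shape,
         weibull_scale = weibull_scale,
         synchronous_fraction = synchronous_fraction,
         followup_mean_months = followup_mean_months,
         event_model = event_model,
         ph_covariate = ph_covariate,
         ph_log_hr = ph_log_hr,
         ph_covariate_prevalence = ph_covariate_prevalence,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname default_cohort_config
#' @export
default_feature_prevalence <- function() {
  list(
    # (metastatic, non-metastatic)
    female             = c(0.667, 0.825),
    familial           = c(0.133, 0.070),
    functioning        = c(0.867, 0.825),
    noradrenergic_if_functioning = c(0.538, 0.298),
    large_irregular_nest = c(0.50, 0.30),
    pseudorosette        = c(0.25, 0.10),
    comedo_necrosis      = c(0.30, 0.02),
    vascular_invasion    = c(0.60, 0.30),
    capsular_invasion    = c(0.40, 0.30),
    sdhb_loss            = c(0.333, 0.105),
    pass_large_nests_diffuse_growth = c(0.50, 0.35),
    pass_central_necrosis           = c(0.30, 0.05),
    pass_high_cellularity           = c(0.25, 0.15),
    pass_cellular_monotony          = c(0.30, 0.25),
    pass_spindling                  = c(0.25, 0.15),
    pass_mitoses_gt3_per_10hpf      = c(0.20, 0.05),
    pass_atypical_mitoses           = c(0.15, 0.05),
    pass_fat_invasion               = c(0.25, 0.10),
    pass_profound_pleomorphism      = c(0.40, 0.30),
    pass_hyperchromasia             = c(0.45, 0.35))
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$metastasis_prevalence, cfg$pgl_fraction,
             cfg$synchronous_fraction, cfg$ph_covariate_prevalence,
             unlist(cfg$feature_prevalence),
             unlist(cfg$cellularity_probs))
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all configured probabilities must lie in [0, 1]")
  }
  for (nm in c("met", "nonmet")) {
    p <- cfg$cellularity_probs[[nm]]
    if (length(p) != 3 || abs(sum(p) - 1) > 1e-8) {
      abort("cellularity_probs must be two length-3 probability vectors")
    }
  }
  bad_pair <- vapply(cfg$feature_prevalence, function(p) length(p) != 2,
                     logical(1))
  if (any(bad_pair)) {
    abort("every feature_prevalence entry must be a (met, nonmet) pair")
  }
  if (cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients)) {
    abort("n_patients must be a non-negative integer")
  }
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0 ||
      cfg$followup_mean_months <= 0) {
    abort("shape, scale and follow-up mean must be positive")
  }
  invisible(cfg)
}

draw_feature <- function(cfg, name, met) {
  p <- cfg$feature_prevalence[[name]]
  runif(length(met)) < ifelse(met, p[1], p[2])
}

#' Generate a synthetic PPGL cohort
#'
#' Draws one subject per row with the statistical structure described in
#' [default_cohort_config()]. All output satisfies the cohort schema of
#' [read_cohort()]: `time_to_metastasis_months` is present exactly for
#' metastatic subjects, follow-up is non-negative, raw urinary metanephrine
#' levels are consistent with their elevation flags.
#'
#' @param config A [default_cohort_config()] list.
#' @return A cohort tibble with `n_patients` rows.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(seed = 7))
#' mean(cohort$metastasis)
generate_cohort <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  if (n == 0) return(empty_cohort())
  if (cfg$event_model == "proportional_hazards") {
    return(generate_cohort_ph(cfg))
  }
  met <- runif(n) < cfg$metastasis_prevalence
  cohort <- build_subjects(cfg, met)

  # Event times: Weibull with the synchronous fraction enforced by quantile
  # mapping — synchronous subjects draw from the conditional distribution
  # below 6 months, metachronous from the one above.
  f6 <- stats::pweibull(6, cfg$weibull_shape, cfg$weibull_scale)
  sync <- runif(n) < cfg$synchronous_fraction
  u <- runif(n)
  q <- ifelse(sync, u * f6, f6 + u * (1 - f6))
  t_event <- stats::qweibull(q, cfg$weibull_shape, cfg$weibull_scale)
  followup <- rexp(n, rate = 1 / cfg$followup_mean_months)
  cohort$metastasis <- met
  cohort$time_to_metastasis_months <- ifelse(met, round(t_event, 1), NA_real_)
  cohort$followup_months <- round(followup, 1)
  cohort
}

generate_cohort_ph <- function(cfg) {
  n <- cfg$n_patients
  x <- runif(n) < cfg$ph_covariate_prevalence
  e <- rexp(n)
  t_event <- cfg$weibull_scale *
    (e / exp(cfg$ph_log_hr * x))^(1 / cfg$weibull_shape)
  censor <- rexp(n, rate = 1 / cfg$followup_mean_months)
  met <- t_event <= censor
  cohort <- build_subjects(cfg, met)
  cohort[[cfg$ph_covariate]] <- x
  cohort$metastasis <- met
  cohort$time_to_metastasis_months <- ifelse(met, t_event, NA_real_)
  cohort$followup_months <- censor
  cohort
}

build_subjects <- function(cfg, met) {
  n <- length(met)
  female <- draw_feature(cfg, "female", met)
  height <- round(rnorm(n, ifelse(female, 157, 170), 6), 1)
  weight <- round(rnorm(n, ifelse(female, 57, 68), 8), 1)
  functioning <- draw_feature(cfg, "functioning", met)
  norad <- functioning & draw_feature(cfg, "noradrenergic_if_functioning", met)
  adren <- functioning & !norad
  # Raw 24-h urinary levels drawn consistently with the elevation flags
  # (log-normal around the published medians; non-elevated values sit low).
  umn <- round(exp(rnorm(n, ifelse(adren, log(1500), log(80)), 0.8)), 1)
  unm <- round(exp(rnorm(n, ifelse(norad, log(4000),
                                   ifelse(adren, log(2000), log(300))), 0.7)),
               1)
  unm_elev <- norad | (adren & runif(n) < 0.5)
  cell_idx <- vapply(met, function(m) {
    p <- if (m) cfg$cellularity_probs$met else cfg$cellularity_probs$nonmet
    sample.int(3, 1, prob = p)
  }, integer(1))
  ki67 <- round(exp(rnorm(n,
                          ifelse(met, cfg$ki67_meanlog[1], cfg$ki67_meanlog[2]),
                          ifelse(met, cfg$ki67_sdlog[1], cfg$ki67_sdlog[2]))),
                2)
  ki67 <- pmin(ki67, 100)
  age <- pmax(18, pmin(90, round(rnorm(n, ifelse(met, 39.5, 47.8),
                                       ifelse(met, 16.7, 14.5)))))
  size <- pmax(0.5, round(rnorm(n, ifelse(met, 8.5, 6.6),
                                ifelse(met, 4.1, 3.3)), 1))
  tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_years = age,
    sex = ifelse(female, "female", "male"),
    height_cm = height,
    weight_kg = weight,
    bmi = round(weight / (height / 100)^2, 1),
    tumor_site = ifelse(runif(n) < cfg$pgl_fraction, "PGL", "PHEO"),
    tumor_size_cm = size,
    familial = draw_feature(cfg, "familial", met),
    umn_ug_day = umn,
    unm_ug_day = unm,
    umn_elevated = adren,
    unm_elevated = unm_elev,
    large_irregular_nest = draw_feature(cfg, "large_irregular_nest", met),
    pseudorosette = draw_feature(cfg, "pseudorosette", met),
    comedo_necrosis = draw_feature(cfg, "comedo_necrosis", met),
    cellularity_class = c("low", "moderate", "high")[cell_idx],
    ki67_percent = ki67,
    vascular_invasion = draw_feature(cfg, "vascular_invasion", met),
    capsular_invasion = draw_feature(cfg, "capsular_invasion", met),
    pass_large_nests_diffuse_growth =
      draw_feature(cfg, "pass_large_nests_diffuse_growth", met),
    pass_central_necrosis = draw_feature(cfg, "pass_central_necrosis", met),
    pass_high_cellularity = draw_feature(cfg, "pass_high_cellularity", met),
    pass_cellular_monotony = draw_feature(cfg, "pass_cellular_monotony", met),
    pass_spindling = draw_feature(cfg, "pass_spindling", met),
    pass_mitoses_gt3_per_10hpf =
      draw_feature(cfg, "pass_mitoses_gt3_per_10hpf", met),
    pass_atypical_mitoses = draw_feature(cfg, "pass_atypical_mitoses", met),
    pass_fat_invasion = draw_feature(cfg, "pass_fat_invasion", met),
    pass_profound_pleomorphism =
      draw_feature(cfg, "pass_profound_pleomorphism", met),
    pass_hyperchromasia = draw_feature(cfg, "pass_hyperchromasia", met),
    sdhb_ihc_positive = !draw_feature(cfg, "sdhb_loss", met))
}

empty_cohort <- function() {
  cols <- cohort_schema()
  out <- lapply(cols$type, function(tp) {
    switch(tp, character = character(), numeric = numeric(),
           logical = logical())
  })
  names(out) <- cols$column
  as_tibble(out)
}
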