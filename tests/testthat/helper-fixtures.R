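# Fixture builders and independent oracles shared across the test files.

# One benign baseline patient row; override any field by name.
benign_patient <- function(...) {
  row <- tibble::tibble(
    patient_id = "P0001", age_years = 50, sex = "female",
    height_cm = 160, weight_kg = 60, bmi = 23.4,
    tumor_site = "PHEO", tumor_size_cm = 4.5, familial = FALSE,
    umn_ug_day = 80, unm_ug_day = 300,
    umn_elevated = FALSE, unm_elevated = FALSE,
    large_irregular_nest = FALSE, pseudorosette = FALSE,
    comedo_necrosis = FALSE, cellularity_class = "low",
    ki67_percent = 0.5, vascular_invasion = FALSE,
    capsular_invasion = FALSE,
    pass_large_nests_diffuse_growth = FALSE,
    pass_central_necrosis = FALSE, pass_high_cellularity = FALSE,
    pass_cellular_monotony = FALSE, pass_spindling = FALSE,
    pass_mitoses_gt3_per_10hpf = FALSE, pass_atypical_mitoses = FALSE,
    pass_fat_invasion = FALSE, pass_profound_pleomorphism = FALSE,
    pass_hyperchromasia = FALSE,
    sdhb_ihc_positive = TRUE, metastasis = FALSE,
    time_to_metastasis_months = NA_real_, followup_months = 36)
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

# Exhaustive GAPP input grid (one representative Ki-67 value per band).
gapp_input_grid <- function() {
  expand.grid(
    large_irregular_nest = c(FALSE, TRUE),
    pseudorosette = c(FALSE, TRUE),
    comedo_necrosis = c(FALSE, TRUE),
    cellularity_class = c("low", "moderate", "high"),
    ki67_percent = c(0.5, 2, 5),
    vascular_invasion = c(FALSE, TRUE),
    capsular_invasion = c(FALSE, TRUE),
    catecholamine_type = c("non_functioning", "adrenergic",
                           "noradrenergic"),
    stringsAsFactors = FALSE)
}

# Brute-force two-sided Mann-Whitney P by enumerating every assignment of
# the pooled values into the two groups.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(ga, gb) {
    sum(vapply(ga, function(x) sum(x > gb) + 0.5 * sum(x == gb),
               numeric(1)))
  }
  u_obs <- u_of(a, b)
  mu <- n1 * length(b) / 2
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Fisher's exact two-sided P for a 2x2 table by full enumeration of all
# tables with the observed margins, summing probabilities <= observed.
fisher_oracle_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  lp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  }
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(as, lp, numeric(1)))
  p_obs <- exp(lp(tab[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-written Breslow log partial likelihood for a single covariate.
breslow_loglik <- function(beta, time, event, x) {
  vapply(beta, function(b) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      d <- which(event == 1 & time == t)
      risk <- which(time >= t)
      ll <- ll + sum(b * x[d]) - length(d) * log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
}

# Grid-search maximizer of the Breslow partial likelihood.
cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(breslow_loglik(grid, time, event, x))]
}

# AUC by exhaustive positive-negative pair counting (ties count one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Small right-censored Cox fixtures (<= 5 subjects), all with at least one
# event in each covariate group so the likelihood is bounded.
cox_small_fixtures <- function() {
  list(
    list(time = c(1, 2, 3), event = c(1, 1, 0), x = c(1, 0, 1)),
    list(time = c(1, 1, 2, 2), event = c(1, 1, 1, 1), x = c(1, 0, 0, 1)),
    list(time = c(2, 4, 6, 8, 10), event = c(1, 1, 0, 1, 0),
         x = c(1, 0, 1, 0, 1)),
    list(time = c(1, 2, 2, 3, 5), event = c(1, 0, 1, 1, 1),
         x = c(0, 1, 1, 0, 1)),
    list(time = c(3, 3, 3, 7, 9), event = c(1, 1, 0, 1, 1),
         x = c(1, 0, 0, 1, 0)))
}

# A 72-subject cohort engineered so that each scoring system's
# classification cross-tabulation with metastasis matches the published
# marginal counts: GAPP WD 29/3, MD 28/8, PD 0/4; PASS <4 35/3, >=4 22/12;
# M-GAPP <3 48/5, >=3 9/10.
published_marginals_cohort <- function() {
  rows <- list()
  add <- function(n, ..., extra = NULL) {
    args <- c(list(...), extra)
    for (i in seq_len(n)) {
      rows[[length(rows) + 1]] <<- do.call(benign_patient, args)
    }
  }
  pass_boost <- list(pass_large_nests_diffuse_growth = TRUE,
                     pass_central_necrosis = TRUE)  # +4 PASS, nothing else

  # --- 57 non-metastatic ---
  # 29 WD, M-GAPP < 3: 13 of them PASS >= 4 via pass-only items.
  add(13, extra = pass_boost)
  add(16)
  # 9 MD with M-GAPP >= 3 (necrosis + vascular + SDHB loss -> GAPP 3,
  # M-GAPP 3, PASS 1); all 9 also PASS >= 4.
  add(9, comedo_necrosis = TRUE, vascular_invasion = TRUE,
      sdhb_ihc_positive = FALSE, extra = pass_boost)
  # 19 MD with M-GAPP < 3 (necrosis + moderate cellularity -> GAPP 3,
  # M-GAPP 1, PASS 0).
  add(19, comedo_necrosis = TRUE, cellularity_class = "moderate")
  # 22 non-met PASS >= 4 in total: 13 + 9 = 22. 35 below 4. ok.

  # --- 15 metastatic ---
  # 3 WD, PASS < 4, M-GAPP < 3.
  add(1, metastasis = TRUE, time_to_metastasis_months = 2)
  add(1, metastasis = TRUE, time_to_metastasis_months = 14)
  add(1, metastasis = TRUE, time_to_metastasis_months = 26)
  # 4 PD (necrosis + high cellularity + Ki67 > 3 + vascular -> GAPP 7,
  # M-GAPP 3), PASS >= 4 via boost.
  for (k in c(1, 4, 9, 12)) {
    add(1, metastasis = TRUE, time_to_metastasis_months = k,
        comedo_necrosis = TRUE, cellularity_class = "high",
        ki67_percent = 5, vascular_invasion = TRUE, extra = pass_boost)
  }
  # 6 MD with M-GAPP >= 3 (necrosis + vascular + SDHB loss), PASS >= 4.
  for (k in c(3, 7, 11, 18, 24, 30)) {
    add(1, metastasis = TRUE, time_to_metastasis_months = k,
        comedo_necrosis = TRUE, vascular_invasion = TRUE,
        sdhb_ihc_positive = FALSE, extra = pass_boost)
  }
  # 2 MD with M-GAPP < 3 (necrosis + moderate cellularity), PASS >= 4.
  for (k in c(8, 20)) {
    add(1, metastasis = TRUE, time_to_metastasis_months = k,
        comedo_necrosis = TRUE, cellularity_class = "moderate",
        extra = pass_boost)
  }
  cohort <- dplyr::bind_rows(rows)
  cohort$patient_id <- sprintf("P%04d", seq_len(nrow(cohort)))
  cohort
}
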