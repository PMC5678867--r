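#' Scoring thresholds and M-GAPP weights
#'
#' Bundles every tunable constant consumed by the scoring engines: the GAPP
#' differentiation bands (well differentiated 0-2, moderately 3-6, poorly
#' 7-10), the PASS high-risk cutoff (>= 4), the M-GAPP cutoff (>= 3, the
#' Youden-selected value), the synchronous/metachronous boundary (6 months),
#' and the M-GAPP point weights. M-GAPP weights default to one point per
#' parameter, giving the 0-6 range consistent with the published medians
#' (1.0 non-metastatic vs 4.0 metastatic) and the >= 3 cutoff; they are kept
#' configurable because the originating study prints no explicit point
#' scheme.
#'
#' @param gapp_wd_max Highest GAPP score still classed well differentiated.
#' @param gapp_md_max Highest GAPP score still classed moderately
#'   differentiated; scores above (up to 10) are poorly differentiated.
#' @param pass_cutoff PASS value at and above which a tumor is flagged as
#'   having increased metastatic potential.
#' @param mgapp_cutoff M-GAPP value at and above which a tumor is flagged
#'   high risk.
#' @param timing_cutoff_months Months separating synchronous (<) from
#'   metachronous (>=) metastasis.
#' @param mgapp_weights Named integer vector of non-negative weights for the
#'   six M-GAPP parameters: `pattern` (large irregular nest or
#'   pseudorosette), `comedo_necrosis`, `vascular_invasion`, `ki67`
#'   (labeling index >= 1%), `noradrenergic`, `sdhb_loss`.
#'
#' @return A list of class `score_config`.
#' @export
#' @examples
#' cfg <- score_config()
#' cfg$mgapp_weights
score_config <- function(gapp_wd_max = 2,
                         gapp_md_max = 6,
                         pass_cutoff = 4,
                         mgapp_cutoff = 3,
                         timing_cutoff_months = 6,
                         mgapp_weights = default_mgapp_weights()) {
  mgapp_weights <- unlist(mgapp_weights)
  need <- names(default_mgapp_weights())
  if (!setequal(names(mgapp_weights), need)) {
    abort(paste0("mgapp_weights must have exactly the keys: ",
                 paste(need, collapse = ", ")))
  }
  mgapp_weights <- mgapp_weights[need]
  if (any(is.na(mgapp_weights)) || any(mgapp_weights < 0) ||
      any(mgapp_weights != round(mgapp_weights))) {
    abort("mgapp_weights must be non-negative integers")
  }
  stopifnot(gapp_wd_max >= 0, gapp_md_max > gapp_wd_max, gapp_md_max <= 10,
            pass_cutoff >= 0, mgapp_cutoff >= 0, timing_cutoff_months > 0)
  structure(
    list(gapp_wd_max = gapp_wd_max,
         gapp_md_max = gapp_md_max,
         pass_cutoff = pass_cutoff,
         mgapp_cutoff = mgapp_cutoff,
         timing_cutoff_months = timing_cutoff_months,
         mgapp_weights = mgapp_weights),
    class = "score_config")
}

#' @rdname score_config
#' @export
default_mgapp_weights <- function() {
  c(pattern = 1L, comedo_necrosis = 1L, vascular_invasion = 1L,
    ki67 = 1L, noradrenergic = 1L, sdhb_loss = 1L)
}

#' Read a scoring configuration from a YAML file
#'
#' The file holds flat `key: integer` entries matching the arguments of
#' [score_config()], with M-GAPP weights under an `mgapp_weights` section.
#' Absent keys keep their defaults.
#'
#' @param path Path to a YAML config file.
#' @return A `score_config` list.
#' @export
read_score_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(score_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("unknown score config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(score_config, raw)
}

#' The twelve PASS items and their published weights
#'
#' The Pheochromocytoma of the Adrenal Scaled Score sums twelve weighted
#' histological features to a maximum of 20. Vascular and capsular invasion
#' are stored once on the cohort (shared with the GAPP invasion item); the
#' remaining ten items live in `pass_*` columns.
#'
#' @return A tibble with columns `item` (cohort column name), `label`, and
#'   `weight`.
#' @export
#' @examples
#' sum(pass_items()$weight)  # 20
pass_items <- function() {
  tibble(
    item = c("pass_large_nests_diffuse_growth", "pass_central_necrosis",
             "pass_high_cellularity", "pass_cellular_monotony",
             "pass_spindling", "pass_mitoses_gt3_per_10hpf",
             "pass_atypical_mitoses", "pass_fat_invasion",
             "vascular_invasion", "capsular_invasion",
             "pass_profound_pleomorphism", "pass_hyperchromasia"),
    label = c("Large nests or diffuse growth (>10% of tumor volume)",
              "Central or confluent tumor necrosis",
              "High cellularity",
              "Cellular monotony",
              "Tumor cell spindling (even focal)",
              "Mitotic figures >3/10 HPF",
              "Atypical mitotic figure(s)",
              "Extension into periadrenal adipose tissue",
              "Vascular invasion",
              "Capsular invasion",
              "Profound nuclear pleomorphism",
              "Nuclear hyperchromasia"),
    weight = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L))
}
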