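# Scoring engines. All low-level functions are vectorized over their
# arguments and error (never silently zero) on missing values: a silent zero
# would bias every score toward the benign end.

check_no_na <- function(x, field) {
  if (any(is.na(x))) {
    abort(paste0("missing values in required field '", field, "'"))
  }
  x
}

check_logical <- function(x, field) {
  if (!is.logical(x)) abort(paste0("field '", field, "' must be logical"))
  check_no_na(x, field)
}

#' Catecholamine secretory type from urinary metanephrine elevation flags
#'
#' Typing follows the urinary pattern: an elevated 24-h fractionated
#' metanephrine (UMN) makes the tumor adrenergic regardless of
#' normetanephrine (UNM); an elevated UNM without elevated UMN makes it
#' noradrenergic; neither elevated means non-functioning. Elevation is judged
#' upstream against symptom-dependent assay thresholds — only the flags are
#' consumed here.
#'
#' @param umn_elevated,unm_elevated Logical vectors; no missing values.
#' @return A factor with levels `non_functioning`, `adrenergic`,
#'   `noradrenergic`.
#' @export
#' @examples
#' classify_catecholamine_type(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE))
classify_catecholamine_type <- function(umn_elevated, unm_elevated) {
  check_logical(umn_elevated, "umn_elevated")
  check_logical(unm_elevated, "unm_elevated")
  out <- ifelse(umn_elevated, "adrenergic",
                ifelse(unm_elevated, "noradrenergic", "non_functioning"))
  factor(out, levels = c("non_functioning", "adrenergic", "noradrenergic"))
}

#' GAPP score (0-10)
#'
#' Sums the six GAPP items: histological pattern (large irregular cell
#' nest +1, pseudorosette even focal +1, both creditable), comedo-type
#' necrosis (+2), cellularity (moderate +1, high +2), Ki-67 labeling index
#' (1-3% +1, >3% +2), vascular or capsular invasion (+1), and catecholamine
#' type (noradrenergic +1; adrenergic and non-functioning 0). Maximum 10.
#'
#' @param large_irregular_nest,pseudorosette,comedo_necrosis Logical.
#' @param cellularity_class Character or factor: `"low"` (<150 cells/U),
#'   `"moderate"` (150-250), `"high"` (>250).
#' @param ki67_percent Numeric in \[0, 100\]: percent Ki-67-positive cells in
#'   the hottest spot, at least 1000 cells counted.
#' @param vascular_invasion,capsular_invasion Logical; a single OR'd
#'   one-point item.
#' @param catecholamine_type As returned by [classify_catecholamine_type()].
#' @return Integer vector in \[0, 10\].
#' @export
#' @examples
#' score_gapp(TRUE, TRUE, TRUE, "high", 5, TRUE, FALSE, "noradrenergic") # 10
score_gapp <- function(large_irregular_nest, pseudorosette, comedo_necrosis,
                       cellularity_class, ki67_percent,
                       vascular_invasion, capsular_invasion,
                       catecholamine_type) {
  check_logical(large_irregular_nest, "large_irregular_nest")
  check_logical(pseudorosette, "pseudorosette")
  check_logical(comedo_necrosis, "comedo_necrosis")
  check_logical(vascular_invasion, "vascular_invasion")
  check_logical(capsular_invasion, "capsular_invasion")
  cellularity_class <- as.character(cellularity_class)
  check_no_na(cellularity_class, "cellularity_class")
  if (!all(cellularity_class %in% c("low", "moderate", "high"))) {
    abort("cellularity_class must be one of 'low', 'moderate', 'high'")
  }
  check_no_na(ki67_percent, "ki67_percent")
  if (any(ki67_percent < 0 | ki67_percent > 100)) {
    abort("ki67_percent must lie in [0, 100]")
  }
  ctype <- as.character(catecholamine_type)
  check_no_na(ctype, "catecholamine_type")
  if (!all(ctype %in% c("non_functioning", "adrenergic", "noradrenergic"))) {
    abort("invalid catecholamine_type")
  }
  as.integer(
    large_irregular_nest + pseudorosette +
      2L * comedo_necrosis +
      (cellularity_class == "moderate") + 2L * (cellularity_class == "high") +
      gapp_ki67_points(ki67_percent) +
      (vascular_invasion | capsular_invasion) +
      (ctype == "noradrenergic"))
}

# Ki-67 bands: [0,1) -> 0, [1,3] -> 1, (3,100] -> 2.
gapp_ki67_points <- function(ki67_percent) {
  ifelse(ki67_percent > 3, 2L, ifelse(ki67_percent >= 1, 1L, 0L))
}

#' GAPP differentiation class
#'
#' Band mapping of the total GAPP score: well differentiated (WD) 0-2,
#' moderately differentiated (MD) 3-6, poorly differentiated (PD) 7-10.
#'
#' @param score Integer GAPP scores in \[0, 10\].
#' @param config A [score_config()] (bands overridable).
#' @return Factor with levels `WD`, `MD`, `PD`.
#' @export
classify_gapp_differentiation <- function(score, config = score_config()) {
  check_no_na(score, "gapp score")
  if (any(score < 0 | score > 10)) abort("GAPP score must lie in [0, 10]")
  cls <- ifelse(score <= config$gapp_wd_max, "WD",
                ifelse(score <= config$gapp_md_max, "MD", "PD"))
  factor(cls, levels = c("WD", "MD", "PD"))
}

#' PASS (0-20)
#'
#' Weighted sum of the twelve PASS histological items (see [pass_items()]).
#' Called with the ten `pass_*` item flags plus the shared vascular and
#' capsular invasion flags, all logical; any missing item is an error naming
#' it.
#'
#' @param ... The twelve items as named logical vectors; names must match
#'   `pass_items()$item` exactly.
#' @return Integer vector in \[0, 20\].
#' @export
#' @examples
#' args <- setNames(as.list(rep(TRUE, 12)), pass_items()$item)
#' do.call(score_pass, args)  # 20
score_pass <- function(...) {
  feats <- list(...)
  spec <- pass_items()
  missing_items <- setdiff(spec$item, names(feats))
  if (length(missing_items)) {
    abort(paste0("missing PASS item(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  extra <- setdiff(names(feats), spec$item)
  if (length(extra)) {
    abort(paste0("unknown PASS item(s): ", paste(extra, collapse = ", ")))
  }
  mat <- vapply(spec$item, function(it) {
    as.integer(check_logical(feats[[it]], it))
  }, integer(length(feats[[1]])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  as.integer(mat %*% spec$weight)
}

#' PASS high-metastatic-potential flag
#'
#' `TRUE` when the PASS meets the published high-risk rule (>= 4 by
#' default).
#'
#' @param score Integer PASS values in \[0, 20\].
#' @param config A [score_config()].
#' @return Logical vector.
#' @export
classify_pass <- function(score, config = score_config()) {
  check_no_na(score, "pass score")
  if (any(score < 0 | score > 20)) abort("PASS must lie in [0, 20]")
  score >= config$pass_cutoff
}

#' M-GAPP score
#'
#' The modified GAPP sums six parameters, each credited when present:
#' histological pattern (large irregular nest OR pseudorosette, one combined
#' item), comedo-type necrosis, vascular invasion (capsular invasion does
#' not count here), Ki-67 labeling index >= 1%, noradrenergic type, and loss
#' of SDHB immunohistochemical staining. Default weights are one point each
#' (range 0-6); weights are configurable via [score_config()].
#'
#' @inheritParams score_gapp
#' @param sdhb_ihc_positive Logical: `TRUE` = any definite granular
#'   cytoplasmic staining; `FALSE` = loss of staining, which scores.
#' @param config A [score_config()] supplying the weights.
#' @return Integer vector (0-6 under default weights).
#' @export
score_mgapp <- function(large_irregular_nest, pseudorosette, comedo_necrosis,
                        vascular_invasion, ki67_percent, catecholamine_type,
                        sdhb_ihc_positive, config = score_config()) {
  check_logical(large_irregular_nest, "large_irregular_nest")
  check_logical(pseudorosette, "pseudorosette")
  check_logical(comedo_necrosis, "comedo_necrosis")
  check_logical(vascular_invasion, "vascular_invasion")
  check_logical(sdhb_ihc_positive, "sdhb_ihc_positive")
  check_no_na(ki67_percent, "ki67_percent")
  ctype <- as.character(catecholamine_type)
  check_no_na(ctype, "catecholamine_type")
  w <- config$mgapp_weights
  as.integer(
    w[["pattern"]] * (large_irregular_nest | pseudorosette) +
      w[["comedo_necrosis"]] * comedo_necrosis +
      w[["vascular_invasion"]] * vascular_invasion +
      w[["ki67"]] * (ki67_percent >= 1) +
      w[["noradrenergic"]] * (ctype == "noradrenergic") +
      w[["sdhb_loss"]] * (!sdhb_ihc_positive))
}

#' M-GAPP high-risk flag
#'
#' `TRUE` at and above the cutoff (default 3, the value selected by Youden's
#' index in the originating analysis).
#'
#' @param score Integer M-GAPP values, >= 0.
#' @param config A [score_config()].
#' @return Logical vector.
#' @export
classify_mgapp <- function(score, config = score_config()) {
  check_no_na(score, "mgapp score")
  if (any(score < 0)) abort("M-GAPP score must be non-negative")
  score >= config$mgapp_cutoff
}

#' Synchronous vs metachronous metastasis
#'
#' Metastases detected at or within 6 months of primary diagnosis are
#' synchronous; at 6 months or later, metachronous.
#'
#' @param time_months Non-negative times to metastasis.
#' @param config A [score_config()] (boundary overridable).
#' @return Factor with levels `synchronous`, `metachronous`.
#' @export
classify_metastasis_timing <- function(time_months, config = score_config()) {
  check_no_na(time_months, "time_months")
  if (any(time_months < 0)) abort("time to metastasis must be non-negative")
  factor(ifelse(time_months < config$timing_cutoff_months,
                "synchronous", "metachronous"),
         levels = c("synchronous", "metachronous"))
}

#' Score every subject in a cohort
#'
#' The data-frame-first entry point: takes a cohort tibble (one row per
#' patient, columns as documented in [read_cohort()]), derives the
#' catecholamine type from the elevation flags, and appends the full score
#' panel: `catecholamine_type`, `gapp_score`, `gapp_class`, `pass_score`,
#' `pass_high`, `mgapp_score`, `mgapp_high`.
#'
#' @param cohort A cohort tibble.
#' @param config A [score_config()].
#' @return The cohort with the seven score-panel columns appended.
#' @export
#' @examples
#' generate_cohort(default_cohort_config(n_patients = 5, seed = 1)) |>
#'   score_cohort()
score_cohort <- function(cohort, config = score_config()) {
  cohort <- as_tibble(cohort)
  ctype <- classify_catecholamine_type(cohort$umn_elevated,
                                       cohort$unm_elevated)
  gapp <- score_gapp(cohort$large_irregular_nest, cohort$pseudorosette,
                     cohort$comedo_necrosis, cohort$cellularity_class,
                     cohort$ki67_percent, cohort$vascular_invasion,
                     cohort$capsular_invasion, ctype)
  pass_args <- lapply(setNames(pass_items()$item, pass_items()$item),
                      function(it) cohort[[it]])
  pass <- do.call(score_pass, pass_args)
  mgapp <- score_mgapp(cohort$large_irregular_nest, cohort$pseudorosette,
                       cohort$comedo_necrosis, cohort$vascular_invasion,
                       cohort$ki67_percent, ctype,
                       cohort$sdhb_ihc_positive, config)
  cohort %>%
    mutate(catecholamine_type = ctype,
           gapp_score = gapp,
           gapp_class = classify_gapp_differentiation(gapp, config),
           pass_score = pass,
           pass_high = classify_pass(pass, config),
           mgapp_score = mgapp,
           mgapp_high = classify_mgapp(mgapp, config))
}
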