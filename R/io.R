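# Cohort I/O. One flat comma-delimited file, UTF-8, header row, one row per
# patient. Booleans are written 0/1 and read case-insensitively from
# {0, 1, true, false, yes, no}. Units: cm, kg, ug/day, months.

#' The cohort file schema
#'
#' @return A tibble with columns `column`, `type` (`character`, `numeric`,
#'   `logical`), and `required`.
#' @export
cohort_schema <- function() {
  tribble_rows <- list(
    c("patient_id", "character", TRUE),
    c("age_years", "numeric", TRUE),
    c("sex", "character", TRUE),
    c("height_cm", "numeric", FALSE),
    c("weight_kg", "numeric", FALSE),
    c("bmi", "numeric", FALSE),
    c("tumor_site", "character", TRUE),
    c("tumor_size_cm", "numeric", TRUE),
    c("familial", "logical", FALSE),
    c("umn_ug_day", "numeric", FALSE),
    c("unm_ug_day", "numeric", FALSE),
    c("umn_elevated", "logical", TRUE),
    c("unm_elevated", "logical", TRUE),
    c("large_irregular_nest", "logical", TRUE),
    c("pseudorosette", "logical", TRUE),
    c("comedo_necrosis", "logical", TRUE),
    c("cellularity_class", "character", TRUE),
    c("ki67_percent", "numeric", TRUE),
    c("vascular_invasion", "logical", TRUE),
    c("capsular_invasion", "logical", TRUE),
    c("pass_large_nests_diffuse_growth", "logical", TRUE),
    c("pass_central_necrosis", "logical", TRUE),
    c("pass_high_cellularity", "logical", TRUE),
    c("pass_cellular_monotony", "logical", TRUE),
    c("pass_spindling", "logical", TRUE),
    c("pass_mitoses_gt3_per_10hpf", "logical", TRUE),
    c("pass_atypical_mitoses", "logical", TRUE),
    c("pass_fat_invasion", "logical", TRUE),
    c("pass_profound_pleomorphism", "logical", TRUE),
    c("pass_hyperchromasia", "logical", TRUE),
    c("sdhb_ihc_positive", "logical", TRUE),
    c("metastasis", "logical", TRUE),
    c("time_to_metastasis_months", "numeric", TRUE),
    c("followup_months", "numeric", TRUE))
  tibble(column = vapply(tribble_rows, `[[`, "", 1),
         type = vapply(tribble_rows, `[[`, "", 2),
         required = vapply(tribble_rows, function(r) as.logical(r[[3]]),
                           logical(1)))
}

parse_boolean <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "yes")] <- TRUE
  out[lx %in% c("0", "false", "no")] <- FALSE
  out[is.na(x) | lx == ""] <- NA
  bad <- !is.na(x) & lx != "" & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

#' Read a cohort file
#'
#' Reads the flat delimited cohort schema (see [cohort_schema()]),
#' validating column presence, cell parseability and record-level
#' invariants. Row-level problems are collected and reported together with
#' their row numbers in a single error.
#'
#' @param path Path to a CSV cohort file.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  schema <- cohort_schema()
  missing_cols <- setdiff(schema$column[schema$required], names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  errors <- character()
  out <- list()
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(raw)) {
      out[[col]] <- switch(schema$type[i], character = NA_character_,
                           numeric = NA_real_, logical = NA)
      next
    }
    x <- raw[[col]]
    if (schema$type[i] == "numeric") {
      v <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(v))
      if (length(bad)) {
        errors <- c(errors, sprintf(
          "row %d: field '%s' has unparseable value '%s'", bad, col, x[bad]))
      }
      out[[col]] <- v
    } else if (schema$type[i] == "logical") {
      v <- parse_boolean(x)
      bad <- attr(v, "bad")
      if (length(bad)) {
        errors <- c(errors, sprintf(
          "row %d: field '%s' has unparseable value '%s'", bad, col, x[bad]))
      }
      attr(v, "bad") <- NULL
      out[[col]] <- as.logical(v)
    } else {
      out[[col]] <- as.character(x)
    }
  }
  cohort <- as_tibble(out)
  if (nrow(cohort)) {
    bad_cell <- which(!is.na(cohort$cellularity_class) &
                        !cohort$cellularity_class %in%
                        c("low", "moderate", "high"))
    if (length(bad_cell)) {
      errors <- c(errors, sprintf(
        "row %d: field 'cellularity_class' has unparseable value '%s'",
        bad_cell, cohort$cellularity_class[bad_cell]))
    }
    mism <- which(!is.na(cohort$metastasis) &
                    (cohort$metastasis != !is.na(cohort$time_to_metastasis_months)))
    if (length(mism)) {
      errors <- c(errors, sprintf(
        "row %d: time_to_metastasis_months must be present exactly when metastasis is 1",
        mism))
    }
    neg <- which(!is.na(cohort$followup_months) & cohort$followup_months < 0)
    if (length(neg)) {
      errors <- c(errors, sprintf("row %d: negative followup_months", neg))
    }
  }
  if (length(errors)) {
    abort(paste0("cohort validation failed:\n  ",
                 paste(errors, collapse = "\n  ")))
  }
  cohort
}

#' Write a cohort file
#'
#' Lossless inverse of [read_cohort()]: logical columns serialize as 0/1,
#' everything else as plain text. An empty cohort yields a header-only file.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as_tibble(cohort)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Map an arbitrarily named table onto the cohort schema
#'
#' Import shim for externally exported participant-level tables whose
#' column names differ from [cohort_schema()]: the caller supplies an
#' explicit map from schema names to source names (column naming in such
#' exports is not guessable, so no automatic matching is attempted). The
#' renamed table is round-tripped through the cohort parser so every
#' schema validation applies.
#'
#' @param data A data frame already read from the external source.
#' @param column_map Named character vector: `c(schema_name = source_name)`.
#' @return A validated cohort tibble.
#' @export
convert_cohort <- function(data, column_map) {
  data <- as.data.frame(data)
  missing_src <- setdiff(unname(column_map), names(data))
  if (length(missing_src)) {
    abort(paste0("source column(s) not found: ",
                 paste(missing_src, collapse = ", ")))
  }
  renamed <- data
  for (schema_name in names(column_map)) {
    renamed[[schema_name]] <- data[[column_map[[schema_name]]]]
  }
  renamed <- renamed[, intersect(cohort_schema()$column, names(renamed)),
                     drop = FALSE]
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  readr::write_csv(as_tibble(renamed), tmp, na = "", progress = FALSE)
  read_cohort(tmp)
}
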