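# Patient-level cohort CSV reading/writing with data-dictionary
# validation. The CSV dialect is UTF-8, comma-separated, "." decimal,
# header required; a leading "# provenance: ..." comment line carries the
# cohort's provenance tag (real, synthetic or fixture).

cohort_dictionary <- function() {
  list(
    required = c("patient_id", "sex", "marital", "age", "bmi", "functional",
                 "vintage_years", "albumin_gL", "ferritin_ugL",
                 "dm", "htn", "ihd", "cvd", "epo",
                 "adm_vascular", "adm_nonvascular", "died"),
    optional = c("hemoglobin_gL", "ktv", "quarter", "center"),
    sex = c("M", "F"),
    marital = c("married", "single", "divorced_widowed"),
    functional = c("normal", "occasional_difficulty",
                   "dependent_difficulty", "bed_chair_bound"),
    flags = c("dm", "htn", "ihd", "cvd", "epo",
              "adm_vascular", "adm_nonvascular", "died")
  )
}

#' Read and validate a patient-level cohort CSV
#'
#' Reads a cohort table in the package's data dictionary (see Details),
#' validates every row against the categorical dictionaries and numeric
#' ranges, and returns the valid rows. Invalid rows are collected into a
#' rejection report (attribute `rejected`) rather than failing the whole
#' read, unless `strict = TRUE`.
#'
#' @details
#' Required columns: `patient_id`, `sex` (M/F), `marital` (married, single,
#' divorced_widowed), `age`, `bmi`, `functional` (the four capacity levels
#' or codes 0-3), `vintage_years`, `albumin_gL`, `ferritin_ugL`, the 0/1
#' flags `dm`, `htn`, `ihd`, `cvd`, `epo`, and the 0/1 outcomes
#' `adm_vascular`, `adm_nonvascular`, `died`. Optional: `hemoglobin_gL`,
#' `ktv`, `quarter`, `center`. Column order is irrelevant; unknown columns
#' are a schema error.
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, any invalid row aborts the read; otherwise
#'   invalid rows are dropped and reported.
#' @return A data frame of validated patients with attributes `provenance`
#'   (from the `# provenance:` header comment if present, else
#'   `"real"`) and `rejected` (data frame of row numbers and reasons).
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path,
                                class = "pewrisk_io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  provenance <- "real"
  if (length(first) && grepl("^#\\s*provenance:", first)) {
    provenance <- trimws(sub("^#\\s*provenance:", "", first))
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stopf("cannot parse CSV %s: %s", path,
                              conditionMessage(e), class = "pewrisk_schema_error"))
  dict <- cohort_dictionary()
  if (nrow(df) == 0 && ncol(df) == 0) {
    stopf("empty cohort file: %s", path, class = "pewrisk_schema_error")
  }
  absent <- setdiff(dict$required, names(df))
  if (length(absent)) {
    stopf("cohort CSV is missing required column(s): %s",
          paste(absent, collapse = ", "), class = "pewrisk_schema_error")
  }
  unknown <- setdiff(names(df), c(dict$required, dict$optional))
  if (length(unknown)) {
    stopf("unknown column(s) in cohort CSV: %s",
          paste(unknown, collapse = ", "), class = "pewrisk_schema_error")
  }
  validate_cohort(df, strict = strict, provenance = provenance)
}

validate_cohort <- function(df, strict = FALSE, provenance = "real") {
  dict <- cohort_dictionary()
  reasons <- character(nrow(df))
  flag_bad <- function(ok, why) {
    bad <- !ok & reasons == ""
    reasons[bad] <<- why
  }
  flag_bad(df$sex %in% dict$sex, "sex not in {M, F}")
  flag_bad(df$marital %in% dict$marital, "marital status out of dictionary")
  fc <- df$functional
  fc_ok <- if (is.numeric(fc)) fc %in% 0:3 else as.character(fc) %in% dict$functional
  flag_bad(fc_ok, "functional capacity out of dictionary")
  for (col in c("age", "bmi", "albumin_gL")) {
    flag_bad(!is.na(df[[col]]) & df[[col]] > 0,
             sprintf("%s missing or non-positive", col))
  }
  for (col in c("vintage_years", "ferritin_ugL")) {
    flag_bad(!is.na(df[[col]]) & df[[col]] >= 0,
             sprintf("%s missing or negative", col))
  }
  for (col in dict$flags) {
    flag_bad(!is.na(df[[col]]) & df[[col]] %in% c(0, 1),
             sprintf("%s must be 0 or 1", col))
  }
  rejected <- data.frame(row = which(reasons != ""),
                         patient_id = as.character(df$patient_id[reasons != ""]),
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) && strict) {
    stopf("cohort validation failed for %d row(s), first: row %d (%s)",
          nrow(rejected), rejected$row[1], rejected$reason[1],
          class = "pewrisk_validation_error")
  }
  keep <- df[reasons == "", , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(rejected)) {
    message(sprintf("read_cohort: rejected %d invalid row(s); see attr(, 'rejected')",
                    nrow(rejected)))
  }
  structure(keep, provenance = provenance, rejected = rejected)
}

#' Write a cohort to CSV
#'
#' Writes the cohort in the package's CSV dialect, with the provenance tag
#' preserved as a leading `# provenance:` comment line so that
#' `read_cohort(write_cohort(x))` round-trips field for field.
#'
#' @param cohort A cohort data frame (e.g. from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stopf("cohort must be a non-empty data frame",
          class = "pewrisk_invalid_input")
  }
  provenance <- attr(cohort, "provenance") %||% "real"
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stopf("cannot open %s for writing", path,
                                            class = "pewrisk_io_error"))
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", provenance), con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
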