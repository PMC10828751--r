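#' Component scorers for the six-variable PEW risk score
#'
#' Each scorer maps one clinical variable to an ordinal severity score in
#' 0..3 according to the banding grid in [default_bands()]. All scorers are
#' vectorised and reject missing, non-finite or out-of-range input rather
#' than imputing.
#'
#' @param bmi Body mass index in kg/m^2 (strictly positive).
#' @param cuts Ascending band cut points (length 3); defaults to the
#'   canonical grid. Lower values of BMI are more severe; a value exactly
#'   on a cut belongs to the less severe band.
#' @return Integer vector of scores in `{0, 1, 2, 3}`.
#' @seealso [score_components()] for scoring whole cohorts.
#' @export
#' @examples
#' score_bmi(c(22, 19, 15.9, 20))   # 0 1 3 0
score_bmi <- function(bmi, cuts = default_bands()$bmi$cuts) {
  check_numeric(bmi, "bmi", lower = 0, allow_lower = FALSE)
  as.integer(3L - findInterval(bmi, cuts))
}

#' @rdname score_bmi
#' @param albumin Serum albumin in g/L (strictly positive). Lower is more
#'   severe; albumin exactly on a cut (e.g. 35 g/L) takes the less severe
#'   score.
#' @export
#' @examples
#' score_albumin(c(36, 35, 30, 27.9))  # 0 0 2 3
score_albumin <- function(albumin, cuts = default_bands()$albumin$cuts) {
  check_numeric(albumin, "albumin", lower = 0, allow_lower = FALSE)
  as.integer(3L - findInterval(albumin, cuts))
}

#' @rdname score_bmi
#' @param years Hemodialysis vintage in years (non-negative). Longer is
#'   more severe; the third band is closed at its upper cut (vintage
#'   exactly 4 years scores 2, not 3).
#' @export
#' @examples
#' score_vintage(c(0.5, 2, 3, 4, 5))   # 0 1 2 2 3
score_vintage <- function(years, cuts = default_bands()$vintage$cuts) {
  check_numeric(years, "years", lower = 0)
  s <- findInterval(years, cuts)
  s[years == cuts[3]] <- 2L  # ">4 years" excludes exactly 4
  as.integer(s)
}

#' @rdname score_bmi
#' @param ferritin Serum ferritin in ug/L (non-negative). Higher is more
#'   severe; a value exactly on a cut belongs to the lower (less severe)
#'   band, so 700 scores 0 and 800 scores 1.
#' @export
#' @examples
#' score_ferritin(c(500, 700.5, 800, 1001))  # 0 1 1 3
score_ferritin <- function(ferritin, cuts = default_bands()$ferritin$cuts) {
  check_numeric(ferritin, "ferritin", lower = 0)
  as.integer(findInterval(ferritin, cuts, left.open = TRUE))
}

#' @rdname score_bmi
#' @param count Number of comorbid conditions among diabetes mellitus,
#'   hypertension, ischemic heart disease and cerebrovascular disease
#'   (non-negative integer). Zero or one condition scores 0; more than
#'   three scores 3.
#' @export
#' @examples
#' score_comorbidity(0:5)  # 0 0 1 2 3 3
score_comorbidity <- function(count, cuts = default_bands()$comorbidity$cuts) {
  check_numeric(count, "count", lower = 0)
  if (any(count != round(count))) {
    stopf("comorbidity count must be a whole number",
          class = "pewrisk_invalid_input")
  }
  as.integer(findInterval(count, cuts))
}

#' @rdname score_bmi
#' @param level Functional-capacity category: one of `"normal"`,
#'   `"occasional_difficulty"`, `"dependent_difficulty"`,
#'   `"bed_chair_bound"` (or the equivalent integer code 0-3).
#' @export
#' @examples
#' score_functional(c("normal", "bed_chair_bound"))  # 0 3
score_functional <- function(level) {
  levels <- default_bands()$functional
  if (is.numeric(level)) {
    if (anyNA(level) || any(!level %in% 0:3)) {
      stopf("numeric functional capacity must be in 0..3",
            class = "pewrisk_invalid_input")
    }
    return(as.integer(level))
  }
  idx <- match(as.character(level), levels)
  if (anyNA(idx)) {
    stopf("unknown functional capacity category '%s'",
          as.character(level)[which(is.na(idx))[1]],
          class = "pewrisk_invalid_input")
  }
  as.integer(idx - 1L)
}

#' Score a cohort with Hashmi's six-component tool
#'
#' Applies the six component scorers to every row of a patient-level
#' cohort table and returns the component scores and their total (0-18).
#' Any missing value in a scoring input is an error naming the field and
#' the affected patients: the score is a screening instrument and is never
#' silently computed on partial data.
#'
#' @param cohort A data frame with columns `bmi`, `functional`,
#'   `vintage_years`, `albumin_gL`, `ferritin_ugL` and the four comorbidity
#'   flags `dm`, `htn`, `ihd`, `cvd` (0/1). `patient_id` and `quarter` are
#'   carried through when present.
#' @param bands Banding grid, threshold and aggregation policy; see
#'   [default_bands()].
#' @return A data frame with one row per input row: `patient_id` (and
#'   `quarter` if supplied), the six `*_score` columns, and `total`.
#' @export
#' @examples
#' pt <- data.frame(bmi = 21, functional = "dependent_difficulty",
#'                  vintage_years = 5, albumin_gL = 33, ferritin_ugL = 650,
#'                  dm = 1, htn = 1, ihd = 1, cvd = 0)
#' score_components(pt)  # components 0,2,3,1,0,2 -> total 8
score_components <- function(cohort, bands = default_bands()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stopf("cohort must be a non-empty data frame",
          class = "pewrisk_invalid_input")
  }
  required <- c("bmi", "functional", "vintage_years", "albumin_gL",
                "ferritin_ugL", "dm", "htn", "ihd", "cvd")
  absent <- setdiff(required, names(cohort))
  if (length(absent)) {
    stopf("cohort is missing scoring column(s): %s",
          paste(absent, collapse = ", "), class = "pewrisk_missing_data")
  }
  ids <- if ("patient_id" %in% names(cohort)) as.character(cohort$patient_id)
         else sprintf("row%d", seq_len(nrow(cohort)))
  for (f in required) {
    miss <- is.na(cohort[[f]])
    if (any(miss)) {
      stopf("missing data in field '%s' for patient(s): %s", f,
            paste(utils::head(ids[miss], 5), collapse = ", "),
            class = "pewrisk_missing_data")
    }
  }
  n_comorb <- cohort$dm + cohort$htn + cohort$ihd + cohort$cvd
  out <- data.frame(
    patient_id        = ids,
    bmi_score         = score_bmi(cohort$bmi, bands$bmi$cuts),
    functional_score  = score_functional(cohort$functional),
    vintage_score     = score_vintage(cohort$vintage_years, bands$vintage$cuts),
    albumin_score     = score_albumin(cohort$albumin_gL, bands$albumin$cuts),
    ferritin_score    = score_ferritin(cohort$ferritin_ugL, bands$ferritin$cuts),
    comorbidity_score = score_comorbidity(n_comorb, bands$comorbidity$cuts),
    stringsAsFactors  = FALSE
  )
  out$total <- out$bmi_score + out$functional_score + out$vintage_score +
    out$albumin_score + out$ferritin_score + out$comorbidity_score
  if ("quarter" %in% names(cohort)) out$quarter <- cohort$quarter
  out
}

#' Dichotomise total scores into low/high risk
#'
#' @param total Integer total score(s) in 0..18.
#' @param threshold Total score at or above which a patient is classified
#'   high risk (default 6, the published stratification).
#' @return Character vector of `"low"` / `"high"`.
#' @export
#' @examples
#' classify_risk(c(5, 6, 13))  # "low" "high" "high"
classify_risk <- function(total, threshold = 6L) {
  check_numeric(total, "total", lower = 0)
  if (any(total > 18)) {
    stopf("total score outside 0..18 (got %g)", max(total),
          class = "pewrisk_invalid_input")
  }
  if (length(threshold) != 1 || threshold < 1 || threshold > 18) {
    stopf("threshold must be a single value in 1..18",
          class = "pewrisk_invalid_input")
  }
  ifelse(total >= threshold, "high", "low")
}

#' Collapse quarterly scores to one score per patient
#'
#' The score is recorded quarterly; outcome comparisons are per patient.
#' This collapses a long (patient x quarter) score table to one
#' representative row per patient under a named policy.
#'
#' @param scores A data frame as returned by [score_components()],
#'   optionally with `patient_id` and `quarter` columns. Rows without a
#'   `patient_id` are treated as one patient.
#' @param policy One of `"maximum"` (row with the highest total; the
#'   default, most conservative for screening), `"baseline"` (earliest
#'   quarter), `"latest"` (most recent quarter), or `"mean_rounded"`
#'   (component-wise mean rounded half-up, total re-summed so the
#'   total-equals-sum invariant holds).
#' @return A data frame with one row per patient.
#' @export
aggregate_quarters <- function(scores,
                               policy = c("maximum", "baseline", "latest",
                                          "mean_rounded")) {
  policy <- match.arg(policy)
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    stopf("scores must be a non-empty data frame",
          class = "pewrisk_invalid_input")
  }
  comp_cols <- c("bmi_score", "functional_score", "vintage_score",
                 "albumin_score", "ferritin_score", "comorbidity_score")
  ids <- if ("patient_id" %in% names(scores)) scores$patient_id
         else rep("patient", nrow(scores))
  ord <- if ("quarter" %in% names(scores)) order(ids, scores$quarter)
         else order(ids)
  scores <- scores[ord, , drop = FALSE]
  ids <- ids[ord]
  pick <- function(df) {
    switch(policy,
      baseline = df[1, , drop = FALSE],
      latest   = df[nrow(df), , drop = FALSE],
      maximum  = df[which.max(df$total), , drop = FALSE],
      mean_rounded = {
        rep_row <- df[1, , drop = FALSE]
        rep_row[comp_cols] <- lapply(df[comp_cols],
                                     function(x) as.integer(round_half_up(mean(x))))
        rep_row$total <- sum(unlist(rep_row[comp_cols]))
        rep_row
      })
  }
  out <- do.call(rbind, lapply(split(scores, factor(ids, unique(ids))), pick))
  rownames(out) <- NULL
  out
}
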