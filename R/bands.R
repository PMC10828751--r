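#' Canonical scoring bands for Hashmi's tool
#'
#' Returns the banding grid that defines the six-component hemodialysis
#' protein-energy wasting risk score, together with the default risk
#' threshold and quarterly aggregation policy. Each continuous component
#' is scored 0-3 from three ordered cut points; the side of each cut that
#' belongs to the less severe band is fixed per component (see Details)
#' and is not configurable -- only the cut positions are.
#'
#' @details
#' The printed banding grid leaves small gaps and one overlap between
#' adjacent bands; this implementation closes them with a fixed convention:
#'
#' * **BMI** (kg/m^2): `>=20 -> 0`, `[18,20) -> 1`, `[16,18) -> 2`,
#'   `<16 -> 3`. A boundary value belongs to the less severe (higher) band,
#'   so BMI exactly 20 scores 0.
#' * **Serum albumin** (g/L): `>=35 -> 0`, `[32,35) -> 1`, `[28,32) -> 2`,
#'   `<28 -> 3`. Same convention, so albumin exactly 35 scores 0.
#' * **HD vintage** (years): `[0,1) -> 0`, `[1,3) -> 1`, `[3,4] -> 2`,
#'   `>4 -> 3`. The third band is closed at 4 because the worst band is
#'   strictly "more than 4 years".
#' * **Serum ferritin** (ug/L): `<=700 -> 0`, `(700,800] -> 1`,
#'   `(800,1000] -> 2`, `>1000 -> 3`. Here a boundary belongs to the
#'   lower (less severe) band.
#' * **Functional capacity**: normal -> 0, occasional difficulty -> 1,
#'   difficulty in independent activities -> 2, bed/chair-bound -> 3.
#' * **Comorbidity count** (of diabetes mellitus, hypertension, ischemic
#'   heart disease, cerebrovascular disease): `<=1 -> 0`, `2 -> 1`,
#'   `3 -> 2`, `>=4 -> 3`. Zero comorbidities takes the least severe
#'   score.
#'
#' @return A list with components `bmi`, `albumin`, `vintage`, `ferritin`,
#'   `comorbidity` (each a list with a length-3 ascending `cuts` vector),
#'   `functional` (the four ordered level names), `threshold` (total score
#'   at or above which a patient is high risk; default 6) and
#'   `aggregation` (default quarterly aggregation policy, `"maximum"`).
#' @seealso [read_bands()] to override cut positions from a YAML file,
#'   [score_components()] for applying the grid to a cohort.
#' @export
#' @examples
#' b <- default_bands()
#' b$albumin$cuts  # 28 32 35
default_bands <- function() {
  list(
    bmi         = list(cuts = c(16, 18, 20)),
    albumin     = list(cuts = c(28, 32, 35)),
    vintage     = list(cuts = c(1, 3, 4)),
    ferritin    = list(cuts = c(700, 800, 1000)),
    comorbidity = list(cuts = c(2, 3, 4)),
    functional  = c("normal", "occasional_difficulty",
                    "dependent_difficulty", "bed_chair_bound"),
    threshold   = 6L,
    aggregation = "maximum"
  )
}

#' Read a scoring-band configuration from YAML
#'
#' Reads a YAML file containing any subset of the fields returned by
#' [default_bands()] and merges it over the defaults. Cut vectors must be
#' length-3, strictly increasing and positive; the threshold must lie in
#' 1..18.
#'
#' @param path Path to a YAML file, e.g. with content
#'   `albumin: {cuts: [30, 33, 36]}` or `threshold: 7`.
#' @return A bands list as from [default_bands()].
#' @export
read_bands <- function(path) {
  if (!file.exists(path)) stopf("bands config not found: %s", path,
                                class = "pewrisk_io_error")
  user <- yaml::read_yaml(path)
  bands <- utils::modifyList(default_bands(), user)
  validate_bands(bands)
}

validate_bands <- function(bands) {
  for (comp in c("bmi", "albumin", "vintage", "ferritin", "comorbidity")) {
    cuts <- bands[[comp]]$cuts
    if (!is.numeric(cuts) || length(cuts) != 3 || any(diff(cuts) <= 0) ||
        any(cuts < 0)) {
      stopf("band cuts for '%s' must be 3 non-negative strictly increasing values",
            comp, class = "pewrisk_config_error")
    }
  }
  thr <- bands$threshold
  if (!is.numeric(thr) || length(thr) != 1 || thr < 1 || thr > 18) {
    stopf("threshold must be a single value in 1..18",
          class = "pewrisk_config_error")
  }
  if (!bands$aggregation %in% c("maximum", "baseline", "latest", "mean_rounded")) {
    stopf("unknown aggregation policy '%s'", bands$aggregation,
          class = "pewrisk_config_error")
  }
  bands
}
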