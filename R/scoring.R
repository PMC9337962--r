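#' Names of the scored fitness indicators
#'
#' The seven scored items of the college physical-fitness battery: body mass
#' index, vital capacity, sitting forward flexion, standing long jump, the
#' 50 m sprint, the endurance run (1000 m men / 800 m women) and the strength
#' count (pull-ups men / one-minute sit-ups women).  Vision is examined but
#' not scored and is not modelled.
#'
#' @return Character vector of indicator column names.
#' @export
indicator_names <- function() {
  c("bmi", "vital_capacity", "sit_and_reach", "long_jump",
    "sprint_50m", "endurance_run", "strength_count")
}

#' Default indicator scoring tables
#'
#' Sex-specific piecewise-linear tables mapping each raw measurement to a
#' score in `[0, 100]`.  Each table lists ascending raw breakpoints and the
#' scores attained there; between breakpoints the score is linearly
#' interpolated, and beyond either end it is clamped to the end score, so the
#' full plausible raw range is covered with no gaps.  National student
#' fitness-test standards are the model for the *shape* of these tables, but
#' the breakpoint values shipped here are illustrative defaults, editable via
#' the JSON configuration ([write_config()]).
#'
#' @return Named list: indicator -> list with `unit`, `direction`
#'   (`"higher"` or `"lower"` = which raw direction is better) and per-sex
#'   `breaks`/`scores` vectors.
#' @export
default_scoring_tables <- function() {
  list(
    bmi = list(
      unit = "kg/m2", direction = "lower",
      male   = list(breaks = c(23.9, 25.5, 27.9, 30, 35),
                    scores = c(100, 80, 60, 40, 0)),
      female = list(breaks = c(23.9, 25.5, 27.9, 30, 35),
                    scores = c(100, 80, 60, 40, 0))),
    vital_capacity = list(
      unit = "mL", direction = "higher",
      male   = list(breaks = c(2000, 2600, 3100, 4300, 5040),
                    scores = c(0, 40, 60, 80, 100)),
      female = list(breaks = c(1200, 1600, 2000, 3000, 3400),
                    scores = c(0, 40, 60, 80, 100))),
    sit_and_reach = list(
      unit = "cm", direction = "higher",
      male   = list(breaks = c(-10, -2, 4, 11.5, 25),
                    scores = c(0, 40, 60, 80, 100)),
      female = list(breaks = c(-5, 2, 6, 14, 25.8),
                    scores = c(0, 40, 60, 80, 100))),
    long_jump = list(
      unit = "cm", direction = "higher",
      male   = list(breaks = c(160, 185, 208, 240, 273),
                    scores = c(0, 40, 60, 80, 100)),
      female = list(breaks = c(110, 130, 151, 181, 207),
                    scores = c(0, 40, 60, 80, 100))),
    sprint_50m = list(
      unit = "s", direction = "lower",
      male   = list(breaks = c(6.7, 7.1, 8.4, 9.8, 11.0),
                    scores = c(100, 80, 60, 40, 0)),
      female = list(breaks = c(7.5, 8.3, 10.0, 11.2, 12.5),
                    scores = c(100, 80, 60, 40, 0))),
    endurance_run = list(
      unit = "s", direction = "lower",
      male   = list(breaks = c(197, 222, 272, 305, 360),
                    scores = c(100, 80, 60, 40, 0)),
      female = list(breaks = c(198, 222, 274, 300, 340),
                    scores = c(100, 80, 60, 40, 0))),
    strength_count = list(
      unit = "repetitions", direction = "higher",
      male   = list(breaks = c(0, 5, 10, 15, 19),
                    scores = c(0, 40, 60, 80, 100)),
      female = list(breaks = c(10, 18, 26, 46, 56),
                    scores = c(0, 40, 60, 80, 100)))
  )
}

#' Score one indicator measurement
#'
#' Piecewise-linear lookup of a raw measurement in the sex-specific scoring
#' table: linear interpolation between breakpoints, clamped to the end scores
#' outside the table, hence monotone in the indicator's better direction and
#' always in `[0, 100]`.
#'
#' @param value Numeric raw measurement(s); must not be missing (impute
#'   first, see [impute_missing()]).
#' @param indicator Indicator name (see [indicator_names()]).
#' @param sex `"male"` or `"female"`, recycled against `value`.
#' @param tables Scoring tables; default [default_scoring_tables()].
#' @return Numeric score(s) in `[0, 100]`.
#' @examples
#' score_indicator(4000, "vital_capacity", "male")   # 80
#' score_indicator(3600, "vital_capacity", "male")   # 70 (midpoint)
#' @export
score_indicator <- function(value, indicator, sex,
                            tables = default_scoring_tables()) {
  tab <- tables[[indicator]]
  if (is.null(tab))
    stop_fitid3(paste0("no scoring table for indicator: ", indicator),
                "fitid3_lookup_error")
  if (any(is.na(value)))
    stop_fitid3("missing measurement; impute before scoring",
                "fitid3_missing_error")
  sex <- rep_len(as.character(sex), length(value))
  if (!all(sex %in% c("male", "female")))
    stop_fitid3("sex must be 'male' or 'female'", "fitid3_domain_error")
  out <- numeric(length(value))
  for (s in unique(sex)) {
    sel <- sex == s
    st <- tab[[s]]
    out[sel] <- stats::approx(st$breaks, st$scores, xout = value[sel],
                              rule = 2, ties = "ordered")$y
  }
  out
}

#' Score a whole cohort
#'
#' Applies [score_indicator()] to every indicator column of a cohort data
#' frame (as read by [read_cohort()]).  Records must be complete; run
#' [impute_missing()] first if the cohort has missing cells.
#'
#' @param records Cohort data frame with `subject_id`, `sex` and indicator
#'   columns.
#' @param tables Scoring tables.
#' @return Data frame with `subject_id`, `sex` and one 0-100 score column per
#'   indicator.
#' @export
score_cohort <- function(records, tables = default_scoring_tables()) {
  inds <- intersect(indicator_names(), names(records))
  if (length(inds) == 0)
    stop_fitid3("no known indicator columns present", "fitid3_format_error")
  out <- records[, c("subject_id", "sex"), drop = FALSE]
  for (ind in inds)
    out[[ind]] <- score_indicator(records[[ind]], ind, records$sex, tables)
  out
}

#' Grade every score column of a scored cohort
#'
#' @param scores Data frame from [score_cohort()].
#' @param cuts Grade cut points passed to [discretize()].
#' @return Data frame with the score columns replaced by ordered grade
#'   factors.
#' @export
grade_cohort <- function(scores, cuts = c(60, 75, 85)) {
  inds <- intersect(indicator_names(), names(scores))
  out <- scores
  for (ind in inds) out[[ind]] <- discretize(scores[[ind]], cuts)
  out
}

#' Convert graded records to a labeled dataset
#'
#' Builds the tree-induction container from per-indicator grades: the grade
#' columns become categorical attributes and `label` the class.  Optionally
#' the labels are dichotomized into `positive`/`negative` (the improved
#' algorithm's native two-class form), with `positive` naming the grades on
#' the positive side.
#'
#' @param grades Data frame of ordered grade factors (id/sex columns are
#'   ignored), typically from [grade_cohort()].
#' @param label Class label vector (one per row) or name of a column of
#'   `grades`.
#' @param positive Optional character vector of grades mapped to
#'   `"positive"`; e.g. `c("excellent", "good")`.  `NULL` keeps the four
#'   grades.
#' @return A [labeled_dataset].
#' @export
to_labeled_dataset <- function(grades, label, positive = NULL) {
  grades <- as.data.frame(grades)
  if (is.character(label) && length(label) == 1L) {
    if (!label %in% names(grades))
      stop_fitid3(paste0("label column not found: ", label), "fitid3_lookup_error")
    lab <- grades[[label]]
    grades[[label]] <- NULL
  } else {
    lab <- label
  }
  grades <- grades[, setdiff(names(grades), c("subject_id", "sex")), drop = FALSE]
  if (!is.null(positive)) {
    bad <- setdiff(positive, grade_levels())
    if (length(bad) > 0)
      stop_fitid3("positive set contains unknown grades", "fitid3_domain_error")
    lab <- factor(ifelse(as.character(lab) %in% positive, "positive", "negative"),
                  levels = c("negative", "positive"))
  }
  labeled_dataset(grades, lab)
}
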