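#' Fitness grade levels
#'
#' The four-grade scale used throughout the package, from worst to best:
#' `poor < medium < good < excellent`.
#'
#' @return Character vector of the four grade names in ascending order.
#' @export
grade_levels <- function() c("poor", "medium", "good", "excellent")

#' Coerce to an ordered grade factor
#'
#' @param x Character vector (or factor) of grade names.
#' @return An ordered factor with levels `poor < medium < good < excellent`.
#' @export
as_grade <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), grade_levels())
  if (length(bad) > 0)
    stop_fitid3(paste0("unknown grade value(s): ", paste(bad, collapse = ", ")),
                "fitid3_domain_error")
  factor(x, levels = grade_levels(), ordered = TRUE)
}

#' Discretize a 0-100 score into a four-level grade
#'
#' Scores are mapped onto the standard four-grade scale with left-closed
#' intervals: \eqn{[85, 100]} is excellent, \eqn{[75, 85)} good,
#' \eqn{[60, 75)} medium and \eqn{[0, 60)} poor.  The boundary scores 85, 75
#' and 60 therefore take the better grade.
#'
#' @param score Numeric vector of scores in `[0, 100]`.
#' @param cuts Ascending cut points between poor/medium, medium/good and
#'   good/excellent.  Default `c(60, 75, 85)`.
#' @return Ordered factor of grades, same length as `score`.
#' @examples
#' discretize(c(92, 85, 75, 60, 59.9))
#' @export
discretize <- function(score, cuts = c(60, 75, 85)) {
  if (any(is.na(score)))
    stop_fitid3("missing score; impute before discretizing", "fitid3_missing_error")
  if (any(score < 0 | score > 100))
    stop_fitid3("score outside [0, 100]", "fitid3_domain_error")
  idx <- findInterval(score, cuts) + 1L
  factor(grade_levels()[idx], levels = grade_levels(), ordered = TRUE)
}

# Representative score for each grade: the midpoint of its score interval.
# Used by the planted cohort rule and the grade-level composite.
grade_points <- function(cuts = c(60, 75, 85)) {
  c(poor = cuts[1] / 2,
    medium = (cuts[1] + cuts[2]) / 2,
    good = (cuts[2] + cuts[3]) / 2,
    excellent = (cuts[3] + 100) / 2)
}
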