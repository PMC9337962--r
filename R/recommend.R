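#' Default sports-mode recommendation rules
#'
#' First-match rule table keyed on the weakest primary dimension of a
#' student's grade profile: if the lowest primary grade (ties resolved by the
#' fixed primary order of the profile) belongs to the named dimension and is
#' no better than the rule's `at_most` grade, the rule fires and its modes
#' are recommended, most relevant first.  A final default rule with no
#' condition guarantees the table is total: students with no weak dimension
#' get a maintenance programme.
#'
#' @return List of rules; each rule is a list with `name`, optional `weakest`
#'   (primary name), optional `at_most` (grade), `modes` (ordered character
#'   vector) and `rationale`.
#' @export
default_rules <- function() {
  list(
    list(name = "endurance_deficit", weakest = "cardiorespiratory",
         at_most = "medium",
         modes = c("aerobic running program", "swimming", "cycling"),
         rationale = "low cardiorespiratory grade: build aerobic base"),
    list(name = "strength_deficit", weakest = "strength", at_most = "medium",
         modes = c("resistance circuit", "bodyweight strength training"),
         rationale = "low strength grade: progressive resistance work"),
    list(name = "flexibility_deficit", weakest = "flexibility",
         at_most = "medium",
         modes = c("stretching routine", "yoga"),
         rationale = "low flexibility grade: mobility work"),
    list(name = "speed_deficit", weakest = "speed", at_most = "medium",
         modes = c("sprint intervals", "agility drills"),
         rationale = "low speed grade: anaerobic/neuromuscular training"),
    list(name = "body_composition_deficit", weakest = "body_composition",
         at_most = "medium",
         modes = c("mixed aerobic training", "dietary guidance"),
         rationale = "unfavourable body composition: volume + diet"),
    list(name = "maintenance",
         modes = c("maintenance mixed training", "recreational sports"),
         rationale = "no weak dimension: keep a balanced routine")
  )
}

rule_matches <- function(rule, profile) {
  if (is.null(rule$weakest)) return(TRUE)
  primaries <- setdiff(names(profile), "overall")
  g <- as_grade(unlist(lapply(profile[primaries], as.character)))
  weakest <- primaries[which.min(as.integer(g))]   # ties: first in fixed order
  if (weakest != rule$weakest) return(FALSE)
  min(g) <= as_grade(rule$at_most %||% "excellent")
}

#' Recommend sports modes for a grade profile
#'
#' Applies the rule table with first-match semantics and returns the winning
#' rule's ordered mode list; the result is never empty because a total rule
#' table ends in an unconditional default rule.
#'
#' @param profile Named list or one-row data frame of primary grades, plus
#'   optionally `overall`.
#' @param rules Rule table; default [default_rules()].  Validated for
#'   totality with [validate_rules()] on first use.
#' @return Character vector of sports modes, most relevant first, with the
#'   matched rule's `name` and `rationale` as attributes.
#' @examples
#' recommend(list(body_composition = "good", cardiorespiratory = "poor",
#'                flexibility = "good", speed = "good", strength = "good",
#'                overall = "medium"))
#' @export
recommend <- function(profile, rules = default_rules()) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1L)
    profile <- as.list(profile)
  }
  if (!any(vapply(rules, function(r) is.null(r$weakest), logical(1))))
    stop_fitid3("rule table is not total: no default rule",
                "fitid3_configuration_error")
  for (rule in rules) {
    if (rule_matches(rule, profile)) {
      out <- rule$modes
      attr(out, "rule") <- rule$name
      attr(out, "rationale") <- rule$rationale
      return(out)
    }
  }
  stop_fitid3("no rule matched (rule table not total)",
              "fitid3_configuration_error")
}

#' Check a rule table is total
#'
#' Exhaustively enumerates every possible grade profile over the given
#' primaries (plus overall) — `4^(p+1)` profiles — and verifies at least one
#' rule matches each.
#'
#' @param rules Rule table.
#' @param primaries Character vector of primary names; defaults to those of
#'   [default_hierarchy()].
#' @return `TRUE` invisibly; errors on a non-total table.
#' @export
validate_rules <- function(rules, primaries = names(default_hierarchy()$primaries)) {
  grid <- expand.grid(c(stats::setNames(
    rep(list(grade_levels()), length(primaries)), primaries),
    list(overall = grade_levels())),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    profile <- as.list(grid[i, ])
    ok <- any(vapply(rules, rule_matches, logical(1), profile = profile))
    if (!ok)
      stop_fitid3(paste0("rule table not total; unmatched profile: ",
                         paste(unlist(profile), collapse = "/")),
                  "fitid3_configuration_error")
  }
  invisible(TRUE)
}
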