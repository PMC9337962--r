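# JSON configuration: one document holding everything a deployment may want
# to edit — scoring tables, grade cuts, judgment matrices, recommendation
# rules and algorithm options.

#' Default pipeline configuration
#'
#' @return List with `scoring_tables`, `cuts`, `hierarchy` (primaries with
#'   children and judgment-matrix entries, plus the primary matrix), `rules`
#'   and `options` (tree method, `max_depth`, optional `positive`
#'   dichotomization set).
#' @export
default_config <- function() {
  pm <- default_primary_matrix()
  list(
    scoring_tables = default_scoring_tables(),
    cuts = c(60, 75, 85),
    hierarchy = list(
      primaries = list(
        body_composition = list(children = "bmi"),
        cardiorespiratory = list(
          children = c("vital_capacity", "endurance_run"),
          matrix = list(c(1, 0.5), c(2, 1))),
        flexibility = list(children = "sit_and_reach"),
        speed = list(children = "sprint_50m"),
        strength = list(children = c("long_jump", "strength_count"),
                        matrix = list(c(1, 1), c(1, 1)))),
      primary_matrix = lapply(seq_len(nrow(pm)), function(i) unname(pm[i, ]))),
    rules = default_rules(),
    options = list(method = "binary", max_depth = 25, positive = NULL)
  )
}

default_primary_matrix <- function() {
  rbind(c(1, 1/3, 1, 1/2, 1/2),
        c(3, 1, 3, 2, 2),
        c(1, 1/3, 1, 1/2, 1/2),
        c(2, 1/2, 2, 1, 1),
        c(2, 1/2, 2, 1, 1))
}

#' Write a configuration document
#'
#' @param config Configuration list (see [default_config()]).
#' @param path Output JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a configuration document
#'
#' Reads the JSON written by [write_config()] and rebuilds the typed pieces:
#' the hierarchy becomes a validated [fitness_hierarchy()] (every judgment
#' matrix re-passes the consistency test) and the rule table is checked for
#' totality.
#'
#' @param path Path to the JSON configuration.
#' @return List with `scoring_tables`, `cuts`, `hierarchy` (a
#'   `fitness_hierarchy`), `rules` and `options`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  as_matrix <- function(rows) do.call(rbind, lapply(rows, unlist))
  primaries <- lapply(cfg$hierarchy$primaries, function(p) {
    out <- list(children = unlist(p$children))
    if (!is.null(p$matrix)) out$matrix <- as_matrix(p$matrix)
    out
  })
  hierarchy <- fitness_hierarchy(primaries,
                                 as_matrix(cfg$hierarchy$primary_matrix))
  rules <- lapply(cfg$rules, function(r) {
    r$modes <- unlist(r$modes)
    r
  })
  validate_rules(rules, names(hierarchy$primaries))
  tables <- lapply(cfg$scoring_tables, function(tab) {
    for (s in c("male", "female")) {
      tab[[s]]$breaks <- unlist(tab[[s]]$breaks)
      tab[[s]]$scores <- unlist(tab[[s]]$scores)
    }
    tab
  })
  list(scoring_tables = tables, cuts = unlist(cfg$cuts),
       hierarchy = hierarchy, rules = rules, options = cfg$options)
}
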