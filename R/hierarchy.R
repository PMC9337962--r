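#' Two-level indicator hierarchy with AHP weights
#'
#' The evaluation system groups the seven secondary indicators under primary
#' fitness dimensions; AHP judgment matrices supply the weights among the
#' primaries and among each primary's children.  Every judgment matrix must
#' pass the consistency test (`CR < 0.1`).
#'
#' @param primaries Named list; each element is a list with `children`
#'   (character vector of secondary indicator names) and, when there is more
#'   than one child, `matrix` (a [judgment_matrix()] over the children, rows
#'   in child order).
#' @param primary_matrix A [judgment_matrix()] over the primaries, rows in
#'   list order.
#' @return A `fitness_hierarchy` object: list with `primaries` (each with
#'   `children` and `weights`), `primary_weights` and the consistency reports.
#' @export
fitness_hierarchy <- function(primaries, primary_matrix) {
  primary_matrix <- judgment_matrix(primary_matrix)
  if (nrow(primary_matrix) != length(primaries))
    stop_fitid3("primary matrix order must match number of primaries",
                "fitid3_validation_error")
  cons <- ahp_consistency(primary_matrix)
  if (!cons$pass)
    stop_fitid3(sprintf("primary judgment matrix fails consistency (CR = %.3f)",
                        cons$CR),
                "fitid3_validation_error")
  pw <- stats::setNames(ahp_weights(primary_matrix), names(primaries))
  reports <- list(primary = cons)
  out_primaries <- list()
  for (nm in names(primaries)) {
    p <- primaries[[nm]]
    k <- length(p$children)
    if (k == 1L) {
      w <- stats::setNames(1, p$children)
    } else {
      m <- judgment_matrix(p$matrix)
      if (nrow(m) != k)
        stop_fitid3(sprintf("matrix order for '%s' must match its child count", nm),
                    "fitid3_validation_error")
      rep_ <- ahp_consistency(m)
      if (!rep_$pass)
        stop_fitid3(sprintf("judgment matrix for '%s' fails consistency (CR = %.3f)",
                            nm, rep_$CR),
                    "fitid3_validation_error")
      reports[[nm]] <- rep_
      w <- stats::setNames(ahp_weights(m), p$children)
    }
    out_primaries[[nm]] <- list(children = p$children, weights = w)
  }
  covered <- unlist(lapply(out_primaries, `[[`, "children"), use.names = FALSE)
  if (!setequal(covered, unique(covered)) || length(covered) == 0)
    stop_fitid3("each secondary indicator must appear under a primary",
                "fitid3_validation_error")
  structure(list(primaries = out_primaries, primary_weights = pw,
                 consistency = reports),
            class = "fitness_hierarchy")
}

#' @export
print.fitness_hierarchy <- function(x, ...) {
  cat("Fitness evaluation hierarchy\n")
  for (nm in names(x$primaries)) {
    p <- x$primaries[[nm]]
    cat(sprintf("  %s (weight %.3f): %s\n", nm, x$primary_weights[[nm]],
                paste(sprintf("%s=%.3f", p$children, p$weights), collapse = ", ")))
  }
  cat(sprintf("  primary matrix CR = %.4f\n", x$consistency$primary$CR))
  invisible(x)
}

#' Default fitness-evaluation hierarchy
#'
#' Five primary dimensions over the seven scored indicators:
#' body composition (BMI), cardiorespiratory fitness (vital capacity and
#' endurance run), flexibility (sit-and-reach), speed (50 m sprint) and
#' strength (standing long jump and the strength count).  The shipped
#' judgment matrices are the package's documented defaults — they weight
#' cardiorespiratory fitness highest, then strength and speed — and pass the
#' consistency test; edit them via the JSON configuration to encode other
#' expert judgments.
#'
#' @return A [fitness_hierarchy()].
#' @export
default_hierarchy <- function() {
  primary_matrix <- rbind(
    c(1,   1/3, 1,   1/2, 1/2),
    c(3,   1,   3,   2,   2),
    c(1,   1/3, 1,   1/2, 1/2),
    c(2,   1/2, 2,   1,   1),
    c(2,   1/2, 2,   1,   1))
  fitness_hierarchy(
    primaries = list(
      body_composition = list(children = "bmi"),
      cardiorespiratory = list(
        children = c("vital_capacity", "endurance_run"),
        matrix = rbind(c(1, 1/2), c(2, 1))),
      flexibility = list(children = "sit_and_reach"),
      speed = list(children = "sprint_50m"),
      strength = list(
        children = c("long_jump", "strength_count"),
        matrix = rbind(c(1, 1), c(1, 1)))),
    primary_matrix = primary_matrix)
}

#' Per-primary weighted scores
#'
#' @param scores Data frame of secondary-indicator scores (one column per
#'   indicator) or a named numeric vector for a single record.
#' @param hierarchy A [fitness_hierarchy()].
#' @return Data frame (or named vector for vector input) of primary scores.
#' @export
primary_scores <- function(scores, hierarchy = default_hierarchy()) {
  single <- !is.data.frame(scores)
  if (single) scores <- as.data.frame(as.list(scores))
  out <- list()
  for (nm in names(hierarchy$primaries)) {
    p <- hierarchy$primaries[[nm]]
    missing_ <- setdiff(p$children, names(scores))
    if (length(missing_) > 0)
      stop_fitid3(paste0("missing indicator score(s): ",
                         paste(missing_, collapse = ", ")),
                  "fitid3_input_error")
    mat <- as.matrix(scores[, p$children, drop = FALSE])
    out[[nm]] <- as.numeric(mat %*% p$weights)
  }
  out <- as.data.frame(out)
  if (single) unlist(out[1, ]) else out
}

#' AHP-weighted composite score
#'
#' Weighted mean of child scores within each primary, then weighted mean of
#' primary scores: a linear, monotone combination whose weights come from
#' the AHP judgment matrices.
#'
#' @inheritParams primary_scores
#' @return Numeric composite score(s) in `[0, 100]`.
#' @examples
#' h <- default_hierarchy()
#' s <- stats::setNames(rep(70, 7), indicator_names())
#' composite_score(s, h)  # 70
#' @export
composite_score <- function(scores, hierarchy = default_hierarchy()) {
  ps <- primary_scores(scores, hierarchy)
  if (is.data.frame(ps)) {
    as.numeric(as.matrix(ps[, names(hierarchy$primary_weights)]) %*%
                 hierarchy$primary_weights)
  } else {
    sum(ps[names(hierarchy$primary_weights)] * hierarchy$primary_weights)
  }
}

#' Grade-level planted rule
#'
#' Deterministic mapping from secondary grades to primary and overall grades:
#' each grade is replaced by the midpoint score of its interval
#' (poor 30, medium 67.5, good 80, excellent 92.5), the midpoints are
#' combined with the AHP weights, and the weighted mean is re-discretized.
#' Because it is a function of the grades alone, trees trained on its output
#' can reproduce it exactly — this is the ground-truth rule planted in
#' synthetic cohorts.
#'
#' @param grades Data frame of secondary-indicator grade factors.
#' @param hierarchy A [fitness_hierarchy()].
#' @param cuts Grade cut points.
#' @return List with `primary` (data frame of per-primary grades) and
#'   `overall` (ordered grade factor).
#' @export
planted_rule <- function(grades, hierarchy = default_hierarchy(),
                         cuts = c(60, 75, 85)) {
  pts <- grade_points(cuts)
  inds <- unlist(lapply(hierarchy$primaries, `[[`, "children"), use.names = FALSE)
  num <- as.data.frame(lapply(grades[, inds, drop = FALSE],
                              function(g) pts[as.character(g)]))
  names(num) <- inds
  prim_num <- primary_scores(num, hierarchy)
  primary <- as.data.frame(lapply(prim_num, discretize, cuts = cuts))
  prim_pts <- as.data.frame(lapply(primary, function(g) pts[as.character(g)]))
  overall_num <- as.numeric(as.matrix(prim_pts[, names(hierarchy$primary_weights)]) %*%
                              hierarchy$primary_weights)
  list(primary = primary, overall = discretize(overall_num, cuts))
}

#' Train the hierarchical decision trees
#'
#' Fits one tree per primary indicator (child grades predict the primary
#' grade) and one overall tree (primary grades predict the overall grade).
#' Labels default to the planted rule, which makes the trained hierarchy
#' self-consistent; supply `labels` to train against other targets.
#'
#' @param grades Data frame of secondary-indicator grades.
#' @param hierarchy A [fitness_hierarchy()].
#' @param method Tree induction method passed to [id3()].
#' @param labels Optional list like the result of [planted_rule()].
#' @param ... Further arguments to [id3()].
#' @return List of class `hierarchy_trees`: `primary` (named list of `id3`
#'   fits) and `overall` (an `id3` fit).
#' @export
train_hierarchy_trees <- function(grades, hierarchy = default_hierarchy(),
                                  method = "binary", labels = NULL, ...) {
  if (is.null(labels)) labels <- planted_rule(grades, hierarchy)
  primary_fits <- list()
  for (nm in names(hierarchy$primaries)) {
    children <- hierarchy$primaries[[nm]]$children
    d <- grades[, children, drop = FALSE]
    d$.label <- labels$primary[[nm]]
    primary_fits[[nm]] <- id3(.label ~ ., d, method = method, ...)
  }
  d <- labels$primary
  d$.label <- labels$overall
  overall_fit <- id3(.label ~ ., d, method = method, ...)
  structure(list(primary = primary_fits, overall = overall_fit,
                 method = method),
            class = "hierarchy_trees")
}

#' Hierarchical grade decision
#'
#' Runs the two-stage decision: secondary grades feed the per-primary trees,
#' whose outputs feed the overall tree.  Deterministic — identical records
#' always produce identical grade profiles.
#'
#' @param grades Data frame of secondary-indicator grades (one or more rows).
#' @param trees A [train_hierarchy_trees()] result.
#' @return Data frame with one grade column per primary plus `overall`.
#' @export
evaluate_hierarchy <- function(grades, trees) {
  stopifnot(inherits(trees, "hierarchy_trees"))
  prim <- list()
  for (nm in names(trees$primary)) {
    fit <- trees$primary[[nm]]
    needed <- names(fit$xlevels)
    missing_ <- setdiff(needed, names(grades))
    if (length(missing_) > 0)
      stop_fitid3(paste0("tree for '", nm, "' tests absent indicator(s): ",
                         paste(missing_, collapse = ", ")),
                  "fitid3_configuration_error")
    prim[[nm]] <- predict(fit, grades)
  }
  prim <- as.data.frame(prim)
  prim$overall <- predict(trees$overall, prim)
  prim
}
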