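#' Default synthetic-cohort distribution parameters
#'
#' Sex-specific truncated-normal parameters for each raw indicator, plus the
#' loading of a shared latent fitness factor.  A subject's measurements are
#' correlated through that factor — fitter students tend to do better across
#' the whole battery — with negative loadings for time-valued indicators
#' (faster is better).  The values are the package's documented illustrative
#' defaults for a college-age cohort; they are configuration, not estimates
#' of any national survey.
#'
#' @return Nested list: sex -> indicator -> `list(mean, sd, loading, lower,
#'   upper, integer)`.
#' @export
default_indicator_params <- function() {
  male <- list(
    bmi            = list(mean = 22.5, sd = 3.0, loading = -0.3,
                          lower = 13, upper = 40),
    vital_capacity = list(mean = 3800, sd = 650, loading = 0.75,
                          lower = 500, upper = 8000),
    sit_and_reach  = list(mean = 8, sd = 6, loading = 0.6,
                          lower = -25, upper = 40),
    long_jump      = list(mean = 228, sd = 18, loading = 0.8,
                          lower = 60, upper = 350),
    sprint_50m     = list(mean = 7.9, sd = 0.6, loading = -0.8,
                          lower = 5.5, upper = 16),
    endurance_run  = list(mean = 250, sd = 25, loading = -0.8,
                          lower = 140, upper = 600),
    strength_count = list(mean = 11, sd = 5, loading = 0.7,
                          lower = 0, upper = 90, integer = TRUE))
  female <- list(
    bmi            = list(mean = 21.5, sd = 2.8, loading = -0.3,
                          lower = 13, upper = 40),
    vital_capacity = list(mean = 2700, sd = 500, loading = 0.75,
                          lower = 500, upper = 8000),
    sit_and_reach  = list(mean = 12, sd = 5.5, loading = 0.6,
                          lower = -25, upper = 40),
    long_jump      = list(mean = 168, sd = 15, loading = 0.8,
                          lower = 60, upper = 350),
    sprint_50m     = list(mean = 9.1, sd = 0.7, loading = -0.8,
                          lower = 5.5, upper = 16),
    endurance_run  = list(mean = 248, sd = 25, loading = -0.8,
                          lower = 140, upper = 600),
    strength_count = list(mean = 34, sd = 9, loading = 0.7,
                          lower = 0, upper = 90, integer = TRUE))
  list(male = male, female = female)
}

#' Specify a synthetic student cohort
#'
#' @param n Number of subjects (default 300, split 150/150 downstream).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @param sex_ratio Proportion of male subjects in `[0, 1]`.
#' @param params Distribution parameters, see [default_indicator_params()].
#' @param hierarchy [fitness_hierarchy()] driving the planted grade rule.
#' @param label_noise Probability of flipping a subject's overall grade to a
#'   different random grade.
#' @param missing_rate Probability of blanking each measurement cell.
#' @param tables Scoring tables used for the ground-truth grades.
#' @param cuts Grade cut points.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n = 300, seed = 1, sex_ratio = 0.5,
                        params = default_indicator_params(),
                        hierarchy = default_hierarchy(),
                        label_noise = 0, missing_rate = 0,
                        tables = default_scoring_tables(),
                        cuts = c(60, 75, 85)) {
  stopifnot(n >= 0, sex_ratio >= 0, sex_ratio <= 1,
            label_noise >= 0, label_noise <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (s in names(params)) for (ind in names(params[[s]]))
    if (params[[s]][[ind]]$sd <= 0)
      stop_fitid3("distribution scales must be positive", "fitid3_domain_error")
  structure(list(n = as.integer(n), seed = seed, sex_ratio = sex_ratio,
                 params = params, hierarchy = hierarchy,
                 label_noise = label_noise, missing_rate = missing_rate,
                 tables = tables, cuts = cuts),
            class = "cohort_spec")
}

#' Generate a synthetic student cohort
#'
#' Draws `n` subjects under the spec: sex by `sex_ratio`, a latent fitness
#' factor `z ~ N(0, 1)` per subject, and each raw indicator from its
#' sex-specific normal shifted along the factor loading, truncated to the
#' plausible range (counts are rounded to integers).  Ground truth is
#' computed from the clean measurements — scores, grades, and the planted
#' primary/overall grades — before `label_noise` flips overall grades and
#' `missing_rate` blanks measurement cells in the delivered records.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` object: list with `records` (cohort data
#'   frame, possibly with missing cells), `truth` (list: `scores`, `grades`,
#'   `primary`, `overall`) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  inds <- indicator_names()
  if (n == 0) {
    rec <- empty_cohort(c("subject_id", "sex", inds))
    return(structure(list(records = rec,
                          truth = list(scores = rec, grades = rec,
                                       primary = rec[0, 0],
                                       overall = as_grade(character(0))),
                          spec = spec),
                     class = "synthetic_cohort"))
  }
  with_seed(spec$seed, {
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
    z <- stats::rnorm(n)
    rec <- data.frame(subject_id = sprintf("S%05d", seq_len(n)), sex = sex,
                      stringsAsFactors = FALSE)
    for (ind in inds) {
      x <- numeric(n)
      for (s in c("male", "female")) {
        sel <- sex == s
        if (!any(sel)) next
        p <- spec$params[[s]][[ind]]
        eps <- stats::rnorm(sum(sel))
        raw <- p$mean + p$sd * (p$loading * z[sel] +
                                  sqrt(1 - p$loading^2) * eps)
        raw <- pmin(pmax(raw, p$lower), p$upper)
        if (isTRUE(p$integer)) raw <- round(raw)
        x[sel] <- raw
      }
      rec[[ind]] <- x
    }
    scores <- score_cohort(rec, spec$tables)
    grades <- grade_cohort(scores, spec$cuts)
    rule <- planted_rule(grades[, inds], spec$hierarchy, spec$cuts)
    overall <- rule$overall
    if (spec$label_noise > 0) {
      flip <- stats::runif(n) < spec$label_noise
      if (any(flip)) {
        overall <- as.character(overall)
        overall[flip] <- vapply(overall[flip], function(g)
          sample(setdiff(grade_levels(), g), 1L), character(1))
        overall <- as_grade(overall)
      }
    }
    if (spec$missing_rate > 0) {
      for (ind in inds) {
        blank <- stats::runif(n) < spec$missing_rate
        rec[[ind]][blank] <- NA_real_
      }
    }
    structure(list(records = rec,
                   truth = list(scores = scores, grades = grades,
                                primary = rule$primary, overall = overall),
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (seed %s)\n",
              nrow(x$records), format(x$spec$seed)))
  if (nrow(x$records) > 0) {
    cat("Overall grade counts:\n")
    print(table(x$truth$overall))
  }
  invisible(x)
}

#' Labeled dataset from a synthetic cohort
#'
#' Attributes are the seven secondary-indicator grades; the label is the
#' ground-truth overall grade (optionally dichotomized).
#'
#' @param cohort A [generate_cohort()] result.
#' @param positive Optional grades mapped to `"positive"`; see
#'   [to_labeled_dataset()].
#' @return A [labeled_dataset].
#' @export
cohort_to_dataset <- function(cohort, positive = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  to_labeled_dataset(cohort$truth$grades[, indicator_names(), drop = FALSE],
                     cohort$truth$overall, positive = positive)
}

#' Generate independent cohort groups
#'
#' Mirrors the grouped experimental design (default: 5 groups of 30): a
#' single cohort of `n_groups * group_size` subjects is drawn under the spec
#' and cut sequentially into groups, so subject ids are disjoint across
#' groups.
#'
#' @param n_groups Number of groups (default 5).
#' @param group_size Subjects per group (default 30, `>= 2`).
#' @param spec A [cohort_spec()]; its `n` is overridden.
#' @param positive Optional dichotomization passed to [cohort_to_dataset()].
#' @return List of `n_groups` [labeled_dataset] objects.
#' @export
generate_grouped_cohort <- function(n_groups = 5, group_size = 30,
                                    spec = cohort_spec(), positive = NULL) {
  stopifnot(n_groups >= 1, group_size >= 2)
  spec$n <- as.integer(n_groups * group_size)
  cohort <- generate_cohort(spec)
  ds <- cohort_to_dataset(cohort, positive = positive)
  lapply(seq_len(n_groups), function(g) {
    idx <- ((g - 1L) * group_size + 1L):(g * group_size)
    dataset_subset(ds, idx)
  })
}

#' Seeded train/test split
#'
#' Random partition into a training part of `ceiling(fraction * n)` rows and
#' a test part holding the rest; the parts are disjoint and exhaustive, and
#' identical seeds give identical partitions.
#'
#' @param x A [labeled_dataset] or data frame.
#' @param fraction Training fraction in `(0, 1)`; default 0.5.
#' @param seed Integer seed.
#' @return List with `train` and `test` of the same type as `x`.
#' @export
train_test_split <- function(x, fraction = 0.5, seed = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop_fitid3("fraction must be in (0, 1)", "fitid3_precondition_error")
  n <- if (inherits(x, "labeled_dataset")) x$n else nrow(x)
  if (n < 2)
    stop_fitid3("need at least 2 rows to split", "fitid3_precondition_error")
  idx <- with_seed(seed, sample(n, ceiling(fraction * n)))
  take <- function(i) {
    if (inherits(x, "labeled_dataset")) dataset_subset(x, i)
    else x[i, , drop = FALSE]
  }
  list(train = take(sort(idx)), test = take(setdiff(seq_len(n), idx)))
}
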