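test_that("cohort generation is seeded, sized and bounded", {
  expect_equal(nrow(generate_cohort(cohort_spec(n = 0))$records), 0)
  c1 <- generate_cohort(cohort_spec(n = 50, seed = 19, missing_rate = 0.1))
  c2 <- generate_cohort(cohort_spec(n = 50, seed = 19, missing_rate = 0.1))
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth$overall, c2$truth$overall)
  # truncation bounds hold for every sex and indicator
  big <- generate_cohort(cohort_spec(n = 2000, seed = 23))
  params <- default_indicator_params()
  for (s in c("male", "female")) {
    sel <- big$records$sex == s
    for (ind in indicator_names()) {
      p <- params[[s]][[ind]]
      expect_true(all(big$records[[ind]][sel] >= p$lower))
      expect_true(all(big$records[[ind]][sel] <= p$upper))
    }
  }
  expect_false(anyDuplicated(big$records$subject_id) > 0)
})

test_that("per-sex empirical means track the distribution parameters", {
  big <- generate_cohort(cohort_spec(n = 10000, seed = 29))
  params <- default_indicator_params()
  for (s in c("male", "female")) {
    sel <- big$records$sex == s
    for (ind in indicator_names()) {
      p <- params[[s]][[ind]]
      se <- p$sd / sqrt(sum(sel))
      expect_lt(abs(mean(big$records[[ind]][sel]) - p$mean), 3 * se)
    }
  }
})

test_that("noise-free labels are a function of the discretized grades", {
  cohort <- generate_cohort(cohort_spec(n = 200, seed = 31))
  key <- apply(sapply(cohort$truth$grades[, indicator_names()], as.character),
               1, paste, collapse = "|")
  split_labels <- split(as.character(cohort$truth$overall), key)
  expect_true(all(vapply(split_labels, function(x)
    length(unique(x)) == 1L, logical(1))))
  # label noise breaks determinism but only at the configured rate
  noisy <- generate_cohort(cohort_spec(n = 2000, seed = 31, label_noise = 0.2))
  clean <- generate_cohort(cohort_spec(n = 2000, seed = 31))
  flip_rate <- mean(as.character(noisy$truth$overall) !=
                      as.character(clean$truth$overall))
  expect_gt(flip_rate, 0.15)
  expect_lt(flip_rate, 0.25)
})

test_that("missingness is injected at the configured rate, records only", {
  cohort <- generate_cohort(cohort_spec(n = 2000, seed = 37,
                                        missing_rate = 0.1))
  rate <- mean(is.na(as.matrix(cohort$records[, indicator_names()])))
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
  expect_false(anyNA(cohort$truth$scores[, indicator_names()]))
})

test_that("grouped cohorts mirror the 5x30 design with disjoint subjects", {
  groups <- generate_grouped_cohort(5, 30, cohort_spec(seed = 41))
  expect_length(groups, 5)
  expect_true(all(vapply(groups, function(g) g$n, integer(1)) == 30L))
  single <- generate_grouped_cohort(1, 7, cohort_spec(seed = 41))
  expect_length(single, 1)
  expect_equal(single[[1]]$n, 7L)
})

test_that("train/test split partitions exhaustively and reproducibly", {
  cohort <- generate_cohort(cohort_spec(n = 300, seed = 43))
  ds <- cohort_to_dataset(cohort)
  p1 <- train_test_split(ds, 0.5, seed = 43)
  expect_equal(p1$train$n, 150L)
  expect_equal(p1$test$n, 150L)
  p2 <- train_test_split(ds, 0.5, seed = 43)
  expect_identical(p1$train$attributes, p2$train$attributes)
  # data-frame input: disjoint and exhaustive partition by subject id
  rec <- cohort$records
  pr <- train_test_split(rec, 0.3, seed = 7)
  expect_equal(ceiling(0.3 * nrow(rec)), nrow(pr$train))
  expect_length(intersect(pr$train$subject_id, pr$test$subject_id), 0)
  expect_setequal(c(pr$train$subject_id, pr$test$subject_id), rec$subject_id)
  expect_error(train_test_split(rec, 1.2), class = "fitid3_precondition_error")
  expect_error(train_test_split(rec[1, ], 0.5),
               class = "fitid3_precondition_error")
})
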