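write_tmp_cohort <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("reading cohorts: header-only, missing cells, malformed input", {
  hdr <- "subject_id,sex,bmi,vital_capacity"
  expect_equal(nrow(read_cohort(write_tmp_cohort(hdr))), 0)
  rec <- read_cohort(write_tmp_cohort(c(hdr,
    "S1,male,22.1,3500", "S2,female,20.3,", "S3,male,24.0,oops")))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$bmi, c(22.1, 20.3, 24.0))
  expect_true(is.na(rec$vital_capacity[2]))   # blank cell -> missing
  expect_true(is.na(rec$vital_capacity[3]))   # unparseable -> missing
  expect_error(read_cohort(write_tmp_cohort(c("subject_id,bmi", "S1,20"))),
               class = "fitid3_format_error")
  expect_error(read_cohort(write_tmp_cohort(c(hdr, "S1,male,20,3000",
                                              "S1,male,21,3100"))),
               class = "fitid3_validation_error")
  expect_error(read_cohort(write_tmp_cohort(c(hdr, "S1,male,20,-5"))),
               class = "fitid3_validation_error")
})

test_that("write/read round trip preserves values and missingness", {
  cohort <- generate_cohort(cohort_spec(n = 25, seed = 3, missing_rate = 0.15))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort$records, path)
  back <- read_cohort(path)
  expect_equal(back, cohort$records, tolerance = 1e-12)
  expect_identical(is.na(back$vital_capacity),
                   is.na(cohort$records$vital_capacity))
})

test_that("attribute-mean imputation is sex-stratified and mean-preserving", {
  rec <- data.frame(
    subject_id = paste0("S", 1:6),
    sex = c("male", "male", "male", "female", "female", "female"),
    bmi = c(10, 20, NA, 30, 40, NA),
    stringsAsFactors = FALSE)
  out <- impute_missing(rec, "attribute-mean")
  expect_equal(out$bmi[3], 15)   # male mean, not pooled mean
  expect_equal(out$bmi[6], 35)
  # observed cells untouched; observed mean unchanged within sex
  expect_equal(out$bmi[1:2], c(10, 20))
  expect_equal(mean(out$bmi[out$sex == "male"]), mean(c(10, 20, 15)))
  # no missing cells: identity
  expect_identical(impute_missing(out, "attribute-mean"), out)
  # drop-row removes incomplete records
  dropped <- impute_missing(rec, "drop-row")
  expect_identical(dropped$subject_id, c("S1", "S2", "S4", "S5"))
  # indicator entirely missing within a sex is unimputable
  rec$bmi[1:3] <- NA
  expect_error(impute_missing(rec, "attribute-mean"),
               class = "fitid3_unimputable_error")
})

test_that("attribute reduction thresholds normalized mutual information", {
  set.seed(91)
  n <- 60
  lab <- sample(c("p", "n"), n, replace = TRUE)
  ds <- labeled_dataset(
    data.frame(copy = lab,                                  # NMI = 1
               const = rep("k", n),                         # NMI = 0
               noise = sample(c("a", "b"), n, TRUE)),
    label = lab)
  expect_identical(names(reduce_attributes(ds, 0)$attributes),
                   c("copy", "const", "noise"))
  red <- reduce_attributes(ds, 0.9)
  expect_identical(names(red$attributes), "copy")
  expect_true("const" %in% attr(red, "removed"))
  # constant attribute removed for any positive threshold
  red2 <- reduce_attributes(ds, 1e-6)
  expect_false("const" %in% names(red2$attributes))
  # the best attribute is always retained
  ds_weak <- labeled_dataset(data.frame(const = rep("k", n)), lab)
  expect_equal(ncol(reduce_attributes(ds_weak, 0.99)$attributes), 1)
})
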