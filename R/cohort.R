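#' Read a student fitness cohort from delimited text
#'
#' Expects UTF-8 comma-separated text with a header row naming `subject_id`
#' (or `id`), `sex` and any subset of the known indicators
#' ([indicator_names()]).  Unparseable numeric cells become missing entries
#' (`NA`); unknown columns are kept as-is.
#'
#' @param path Path to the CSV file.
#' @return Cohort data frame: `subject_id` (character), `sex`
#'   (`"male"`/`"female"`) and numeric indicator columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_fitid3(paste0("file not found: ", path), "fitid3_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  names(df)[names(df) == "id"] <- "subject_id"
  if (!all(c("subject_id", "sex") %in% names(df)))
    stop_fitid3("cohort file must have 'subject_id' (or 'id') and 'sex' columns",
                "fitid3_format_error")
  if (nrow(df) == 0) return(empty_cohort(names(df)))
  if (anyDuplicated(df$subject_id))
    stop_fitid3("duplicate subject_id values", "fitid3_validation_error")
  sex <- tolower(trimws(df$sex))
  if (!all(sex %in% c("male", "female")))
    stop_fitid3("sex column must contain only 'male'/'female'",
                "fitid3_validation_error")
  df$sex <- sex
  for (ind in intersect(indicator_names(), names(df))) {
    x <- suppressWarnings(as.numeric(df[[ind]]))
    x[!is.finite(x)] <- NA_real_
    df[[ind]] <- x
  }
  validate_measurements(df)
  df
}

empty_cohort <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  for (ind in intersect(indicator_names(), cols)) df[[ind]] <- numeric(0)
  df
}

# Times and counts cannot be negative; sit-and-reach and BMI have their own
# plausible ranges but may legitimately be small or (sit-and-reach) negative.
validate_measurements <- function(df) {
  nonneg <- c("bmi", "vital_capacity", "long_jump", "sprint_50m",
              "endurance_run", "strength_count")
  for (ind in intersect(nonneg, names(df))) {
    bad <- which(!is.na(df[[ind]]) & df[[ind]] < 0)
    if (length(bad) > 0)
      stop_fitid3(sprintf("negative %s for subject %s", ind,
                          df$subject_id[bad[1]]),
                  "fitid3_validation_error")
  }
  invisible(df)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()]: missing measurements are written as empty
#' cells, so a read/write round trip preserves values and missingness.
#'
#' @param records Cohort data frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fill or drop missing measurements
#'
#' The preprocessing step for incomplete records: either drop every record
#' with a missing measurement (`"drop-row"`), or fill each missing cell with
#' the mean of the observed values for that indicator (`"attribute-mean"`).
#' Means are computed within sex, because every indicator in the battery is
#' sex-specific.  Observed cells are never touched.
#'
#' @param records Cohort data frame.
#' @param strategy `"attribute-mean"` (default) or `"drop-row"`.
#' @return Cohort data frame with no missing indicator cells.
#' @export
impute_missing <- function(records, strategy = c("attribute-mean", "drop-row")) {
  strategy <- match.arg(strategy)
  inds <- intersect(indicator_names(), names(records))
  if (strategy == "drop-row") {
    keep <- stats::complete.cases(records[, inds, drop = FALSE])
    return(records[keep, , drop = FALSE])
  }
  for (ind in inds) {
    for (s in unique(records$sex)) {
      sel <- records$sex == s
      x <- records[[ind]][sel]
      if (!anyNA(x)) next
      if (all(is.na(x)))
        stop_fitid3(sprintf("cannot impute '%s' for sex '%s': no observed values",
                            ind, s),
                    "fitid3_unimputable_error")
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      records[[ind]][sel] <- x
    }
  }
  records
}
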