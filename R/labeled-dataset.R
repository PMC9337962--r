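#' Labeled categorical dataset
#'
#' The training container used by both tree-induction algorithms: a
#' data frame of categorical attributes plus one class label per row, with
#' per-class counts cached.  Rows with a missing class label are dropped.
#'
#' @param attributes Data frame (or coercible) whose columns are categorical
#'   attributes.  Character columns are converted to factors; existing factor
#'   levels are kept as the attribute's value domain.
#' @param label Vector of class labels, one per row, or the name of a column
#'   of `attributes` to pull out as the label.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `attributes` (data frame of factors), `label` (factor), `n` (row count)
#'   and `class_counts` (named integer vector, one entry per observed class).
#' @examples
#' d <- labeled_dataset(
#'   data.frame(a = c("x", "x", "y"), b = c("u", "v", "u")),
#'   label = c("pos", "neg", "neg")
#' )
#' d$class_counts
#' @export
labeled_dataset <- function(attributes, label) {
  attributes <- as.data.frame(attributes)
  if (is.character(label) && length(label) == 1L && label %in% names(attributes)) {
    lab <- attributes[[label]]
    attributes[[label]] <- NULL
    label <- lab
  }
  if (nrow(attributes) == 0L)
    stop_fitid3("empty dataset", "fitid3_empty_error")
  if (length(label) != nrow(attributes))
    stop_fitid3("label length must match attribute row count", "fitid3_input_error")
  keep <- !is.na(label)
  attributes <- attributes[keep, , drop = FALSE]
  label <- label[keep]
  if (length(label) == 0L)
    stop_fitid3("empty dataset after dropping rows with missing labels",
                "fitid3_empty_error")
  for (nm in names(attributes)) {
    if (!is.factor(attributes[[nm]]))
      attributes[[nm]] <- factor(attributes[[nm]])
    if (anyNA(attributes[[nm]]))
      stop_fitid3(paste0("attribute '", nm, "' has missing values; impute first"),
                  "fitid3_missing_error")
  }
  if (!is.factor(label)) label <- factor(label)
  label <- droplevels(label)
  counts <- table(label)
  structure(
    list(attributes = attributes, label = label,
         n = nrow(attributes),
         class_counts = stats::setNames(as.integer(counts), names(counts))),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", x$n, "rows,",
      ncol(x$attributes), "attributes\n")
  cat("Attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  cat("Class counts:\n")
  print(x$class_counts)
  invisible(x)
}

# Row subset preserving factor domains and the cached counts invariant.
dataset_subset <- function(ds, idx) {
  labeled_dataset(ds$attributes[idx, , drop = FALSE], ds$label[idx])
}

#' Drop attributes weakly associated with the class label
#'
#' Attribute reduction step of cohort preprocessing: each attribute's
#' relevance is its normalized mutual information with the class label
#' (MI divided by the label entropy, both in bits), and attributes below
#' `min_relevance` are removed.  The single most relevant attribute is always
#' retained so the output is never attribute-free.
#'
#' @param dataset A [labeled_dataset].
#' @param min_relevance Relevance threshold in `[0, 1]`; default 0.01.
#' @return A [labeled_dataset] on the retained attributes, with the names of
#'   the removed ones in `attr(, "removed")`.
#' @export
reduce_attributes <- function(dataset, min_relevance = 0.01) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (min_relevance < 0 || min_relevance > 1)
    stop_fitid3("min_relevance must be in [0, 1]", "fitid3_domain_error")
  h_label <- expected_info(dataset$class_counts)
  rel <- vapply(names(dataset$attributes), function(a) {
    if (h_label == 0) return(0)
    mutual_info(table(dataset$attributes[[a]], dataset$label)) / h_label
  }, numeric(1))
  keep <- rel >= min_relevance
  if (!any(keep)) keep[which.max(rel)] <- TRUE
  out <- labeled_dataset(dataset$attributes[, keep, drop = FALSE], dataset$label)
  attr(out, "removed") <- names(rel)[!keep]
  out
}

# Mutual information (bits) of a two-way contingency table.
mutual_info <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}
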