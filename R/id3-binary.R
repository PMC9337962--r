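#' One-vs-rest binary test
#'
#' A candidate split for the improved algorithm: "does attribute `F` take
#' value `f`?"  Rows satisfying the test go to the yes-branch, all others to
#' the no-branch, so the resulting tree is strictly binary whatever the size
#' of the attribute's value domain.
#'
#' @param attribute Attribute name.
#' @param value Tested value within that attribute's domain.
#' @return A `binary_test` object.
#' @export
binary_test <- function(attribute, value) {
  structure(list(attribute = attribute, value = as.character(value)),
            class = "binary_test")
}

#' @export
print.binary_test <- function(x, ...) {
  cat(sprintf("binary test: %s == %s\n", x$attribute, x$value))
  invisible(x)
}

# All candidate one-vs-rest tests for a dataset, attribute order then value
# order, restricted to values observed in the current subset.
enumerate_binary_tests <- function(ds) {
  out <- list()
  for (a in names(ds$attributes)) {
    for (v in levels(ds$attributes[[a]])) {
      if (any(ds$attributes[[a]] == v)) out[[length(out) + 1L]] <- binary_test(a, v)
    }
  }
  out
}

#' Choose the best one-vs-rest test under the simplified criterion
#'
#' Scores every candidate test by the generalized impurity of its yes/no
#' partition (identical to the Maclaurin-simplified criterion
#' [simplified_gain()] when the label is two-class) and returns the minimizer.
#' Tests that leave one side empty are skipped; ties break by candidate
#' order.
#'
#' @param dataset A [labeled_dataset].
#' @param candidates List of [binary_test()] objects; defaults to every
#'   observed (attribute, value) pair.
#' @return The selected `binary_test`, or `NULL` if no candidate produces two
#'   non-empty branches (the no-split signal).
#' @export
select_binary_test <- function(dataset, candidates = enumerate_binary_tests(dataset)) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(candidates) == 0)
    stop_fitid3("no candidate tests", "fitid3_precondition_error")
  best <- NULL
  best_score <- Inf
  for (cand in candidates) {
    yes <- dataset$attributes[[cand$attribute]] == cand$value
    n_yes <- sum(yes)
    if (n_yes == 0L || n_yes == dataset$n) next
    score <- generalized_impurity(list(
      table(dataset$label[yes]),
      table(dataset$label[!yes])
    ))
    if (score < best_score) {
      best <- cand
      best_score <- score
    }
  }
  best
}

#' Build a strictly binary tree with the improved ID3
#'
#' Recursively applies [select_binary_test()]: every internal node tests one
#' (attribute, value) pair and has exactly a yes- and a no-child.  Recursion
#' stops when a subset is pure, when no test splits it into two non-empty
#' parts, or at `max_depth` (then a majority leaf).  A pair tested on a
#' yes-path is never retested below it, because the yes-branch is uniform on
#' that pair and uniform tests are degenerate.
#'
#' @param dataset A non-empty [labeled_dataset].
#' @param max_depth Depth cap guaranteeing termination on inconsistent data;
#'   default 25.
#' @return The root node: nested list with `kind` `"binary"` (fields
#'   `attribute`, `value`, `yes`, `no`, `majority`, `support`) or `"leaf"`.
#' @export
build_binary_tree <- function(dataset, max_depth = 25) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (dataset$n == 0)
    stop_fitid3("empty dataset at root", "fitid3_precondition_error")
  if (max_depth < 1)
    stop_fitid3("max_depth must be >= 1", "fitid3_precondition_error")
  build_binary_rec(dataset, seq_len(dataset$n), max_depth)
}

build_binary_rec <- function(ds, idx, depth_left) {
  label <- ds$label[idx]
  maj <- majority_label(label)
  counts <- table(droplevels(label))
  if (length(counts) == 1L)
    return(leaf_node(names(counts), length(idx)))
  if (depth_left <= 0L)
    return(leaf_node(maj, length(idx)))
  sub <- dataset_subset(ds, idx)
  test <- select_binary_test(sub)
  if (is.null(test))
    return(leaf_node(maj, length(idx)))
  yes <- ds$attributes[[test$attribute]][idx] == test$value
  list(kind = "binary",
       attribute = test$attribute, value = test$value,
       yes = build_binary_rec(ds, idx[yes], depth_left - 1L),
       no = build_binary_rec(ds, idx[!yes], depth_left - 1L),
       majority = maj, support = length(idx))
}
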