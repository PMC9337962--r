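# Algorithm-comparison metrics: node-entropy ratio, mutual-information loss
# rate, and the grouped two-algorithm comparison harness.

# Per-node class-count vectors obtained by routing `ds` through the tree.
# Empty branches are skipped (they receive no rows).
route_counts <- function(tree, ds) {
  out <- list()
  walk <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    out[[length(out) + 1L]] <<- table(ds$label[idx])
    if (node$kind == "leaf") return(invisible())
    if (node$kind == "split") {
      v <- ds$attributes[[node$attribute]][idx]
      for (b in names(node$children))
        walk(node$children[[b]], idx[v == b])
    } else {
      yes <- ds$attributes[[node$attribute]][idx] == node$value
      walk(node$yes, idx[yes])
      walk(node$no, idx[!yes])
    }
  }
  walk(tree, seq_len(ds$n))
  out
}

# Subset-weighted sum of node entropies over every node the data reaches.
tree_entropy_sum <- function(tree, ds) {
  counts <- route_counts(tree, ds)
  sum(vapply(counts, function(cnt) (sum(cnt) / ds$n) * expected_info(cnt),
             numeric(1)))
}

#' Information-entropy ratio of two trees
#'
#' Compares how much class disorder the two trees retain on the same data:
#' each tree's nodes are visited with the dataset routed through them, the
#' subset-weighted class entropies are summed over all nodes, and the ratio
#' of the improved tree's sum to the classic tree's sum is reported as a
#' percentage.  Under self-comparison the ratio is 100%; values below 100%
#' mean the improved tree carries less residual entropy.
#'
#' @param tree_improved,tree_classic Tree roots (or `"id3"` fits).
#' @param dataset The [labeled_dataset] both trees were trained on.
#' @return Percentage (ratio times 100).
#' @export
entropy_ratio <- function(tree_improved, tree_classic, dataset) {
  if (inherits(tree_improved, "id3")) tree_improved <- tree_improved$tree
  if (inherits(tree_classic, "id3")) tree_classic <- tree_classic$tree
  num <- tree_entropy_sum(tree_improved, dataset)
  den <- tree_entropy_sum(tree_classic, dataset)
  if (den == 0) {
    if (num == 0) return(100)
    stop_fitid3("classic-tree entropy sum is zero with nonzero numerator",
                "fitid3_undefined_ratio_error")
  }
  100 * num / den
}

#' Operation information loss rate
#'
#' The share of label information a classifier fails to transmit:
#' \deqn{100 \left(1 - \frac{I(Y; \hat Y)}{H(Y)}\right)}
#' with `Y` the true labels, `\hat Y` the tree's predictions on the dataset,
#' `I` mutual information and `H` entropy (bits).  0% for a classifier whose
#' predictions carry all label information, 100% for a constant classifier.
#'
#' @param tree Tree root or `"id3"` fit.
#' @param dataset A [labeled_dataset] with at least two classes.
#' @return Percentage in `[0, 100]`.
#' @export
information_loss_rate <- function(tree, dataset) {
  if (inherits(tree, "id3")) tree <- tree$tree
  if (length(dataset$class_counts) < 2)
    stop_fitid3("loss rate undefined on a single-class dataset (H(Y) = 0)",
                "fitid3_undefined_ratio_error")
  pred <- classify(tree, dataset$attributes)
  h <- expected_info(dataset$class_counts)
  mi <- mutual_info(table(as.character(dataset$label), pred))
  rate <- 100 * (1 - mi / h)
  min(max(rate, 0), 100)   # clip floating-point spill
}

#' Grouped comparison of classic and improved ID3
#'
#' Reproduces the experimental design of the comparison study: for each
#' group, the records are split into training and held-out halves, both
#' algorithms are trained on the training half, and four quantities are
#' reported per algorithm and group — the information-entropy ratio on the
#' training data, the information loss rate and accuracy on the held-out
#' half, and the wall-clock training time (relative to the fastest fit in
#' the report).  A final row averages the groups.  All fields except the
#' timings are deterministic given `seed`.
#'
#' @param groups List of [labeled_dataset] groups (see
#'   [generate_grouped_cohort()]).
#' @param train_fraction Fraction of each group used for training.
#' @param seed Integer seed for the train/test splits.
#' @param improved If `FALSE` the classic algorithm is compared with itself
#'   (a self-comparison control: entropy ratio 100%, equal accuracies).
#' @param classic_method `"classic"` or `"windowed"` for the baseline fits.
#' @param max_depth Depth cap for the improved trees.
#' @return An `id3_comparison` data frame: one row per group plus a `"mean"`
#'   row, columns `entropy_ratio`, `loss_classic`, `loss_improved`,
#'   `acc_classic`, `acc_improved`, `time_classic`, `time_improved`.
#' @export
compare_algorithms <- function(groups, train_fraction = 0.5, seed = 1,
                               improved = TRUE,
                               classic_method = c("classic", "windowed"),
                               max_depth = 25) {
  classic_method <- match.arg(classic_method)
  if (length(groups) < 1)
    stop_fitid3("need at least one group", "fitid3_precondition_error")
  rows <- list()
  for (g in seq_along(groups)) {
    ds <- groups[[g]]
    if (ds$n < 2)
      stop_fitid3(sprintf("group %d too small to split", g),
                  "fitid3_group_size_error")
    parts <- train_test_split(ds, fraction = train_fraction,
                              seed = seed + g - 1L)
    train <- parts$train
    test <- parts$test
    t_classic <- system.time(
      fit_classic <- if (classic_method == "classic") build_id3(train)
                     else train_windowed(train, seed = seed + g - 1L)
    )[["elapsed"]]
    t_improved <- system.time(
      fit_improved <- if (improved) build_binary_tree(train, max_depth)
                      else build_id3(train)
    )[["elapsed"]]
    acc <- function(tree) {
      100 * mean(classify(tree, test$attributes) == as.character(test$label))
    }
    loss <- function(tree) {
      if (length(test$class_counts) < 2) return(NA_real_)
      information_loss_rate(tree, test)
    }
    rows[[g]] <- data.frame(
      group = as.character(g),
      entropy_ratio = entropy_ratio(fit_improved, fit_classic, train),
      loss_classic = loss(fit_classic), loss_improved = loss(fit_improved),
      acc_classic = acc(fit_classic), acc_improved = acc(fit_improved),
      time_classic = t_classic, time_improved = t_improved)
  }
  rep_ <- do.call(rbind, rows)
  mean_row <- rep_[1, ]
  mean_row$group <- "mean"
  for (cl in names(rep_)[-1]) mean_row[[cl]] <- mean(rep_[[cl]], na.rm = TRUE)
  rep_ <- rbind(rep_, mean_row)
  # Express timings relative to the fastest observed fit (dimensionless).
  tmin <- min(c(rep_$time_classic, rep_$time_improved), na.rm = TRUE)
  if (is.finite(tmin) && tmin > 0) {
    rep_$time_classic <- rep_$time_classic / tmin
    rep_$time_improved <- rep_$time_improved / tmin
  }
  rownames(rep_) <- NULL
  class(rep_) <- c("id3_comparison", "data.frame")
  rep_
}

#' @export
print.id3_comparison <- function(x, digits = 3, ...) {
  cat("Classic vs improved ID3 comparison",
      sprintf("(%d groups + mean; timings relative, not asserted)\n",
              nrow(x) - 1L))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
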