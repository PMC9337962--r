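#' Build a classic multiway ID3 tree
#'
#' Recursive top-down induction: at each node the candidate attribute with the
#' highest information gain is chosen ([select_attribute()]) and one branch is
#' grown per value in that attribute's domain.  Recursion stops when a subset
#' is single-class (leaf of that class), when candidates are exhausted or the
#' subset is uniform on every remaining candidate (leaf of the majority
#' class), or when a branch's subset is empty (leaf of the parent's majority
#' class).  No attribute is reused along a root-to-leaf path.
#'
#' @param dataset A non-empty [labeled_dataset].
#' @param candidates Attribute names available for splitting; defaults to all.
#' @return The root node: a nested list with `kind` `"split"` (fields
#'   `attribute`, `children`, `majority`, `support`) or `"leaf"` (fields
#'   `label`, `support`).
#' @seealso [classify()], [train_windowed()], [build_binary_tree()]
#' @export
build_id3 <- function(dataset, candidates = names(dataset$attributes)) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (dataset$n == 0)
    stop_fitid3("empty dataset at root", "fitid3_precondition_error")
  build_id3_rec(dataset, seq_len(dataset$n), candidates)
}

build_id3_rec <- function(ds, idx, cands) {
  label <- ds$label[idx]
  maj <- majority_label(label)
  counts <- table(droplevels(label))
  if (length(counts) == 1L)
    return(leaf_node(names(counts), length(idx)))
  uniform <- vapply(cands, function(a)
    length(unique(ds$attributes[[a]][idx])) <= 1L, logical(1))
  cands <- cands[!uniform]
  if (length(cands) == 0L)
    return(leaf_node(maj, length(idx)))
  sub <- dataset_subset(ds, idx)
  a <- select_attribute(sub, cands)
  vals <- levels(ds$attributes[[a]])
  children <- stats::setNames(vector("list", length(vals)), vals)
  for (v in vals) {
    child_idx <- idx[ds$attributes[[a]][idx] == v]
    children[[v]] <- if (length(child_idx) == 0L) {
      leaf_node(maj, 0L)   # empty branch: parent majority
    } else {
      build_id3_rec(ds, child_idx, setdiff(cands, a))
    }
  }
  list(kind = "split", attribute = a, children = children,
       majority = maj, support = length(idx))
}

leaf_node <- function(label, support) {
  list(kind = "leaf", label = label, support = as.integer(support))
}

#' Classify rows with an induced tree
#'
#' Follows matching branches from the root to a leaf for every row.  At a
#' multiway node an attribute value with no matching branch falls through to
#' that node's training-majority class; binary nodes route on whether the
#' tested attribute equals the tested value.
#'
#' @param tree A node as returned by [build_id3()], [train_windowed()] or
#'   [build_binary_tree()].
#' @param newdata Data frame supplying every attribute the tree may test.
#' @return Character vector of predicted class labels, one per row.
#' @export
classify <- function(tree, newdata) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$attributes
  newdata <- as.data.frame(newdata)
  needed <- tree_attributes(tree)
  missing_attr <- setdiff(needed, names(newdata))
  if (length(missing_attr) > 0)
    stop_fitid3(paste0("newdata lacks attribute(s): ",
                       paste(missing_attr, collapse = ", ")),
                "fitid3_input_error")
  vapply(seq_len(nrow(newdata)), function(i)
    classify_row(tree, newdata[i, , drop = FALSE]), character(1))
}

classify_row <- function(node, row) {
  repeat {
    if (node$kind == "leaf") return(node$label)
    if (node$kind == "split") {
      v <- as.character(row[[node$attribute]])
      child <- node$children[[v]]
      if (is.null(child) || is.na(v)) return(node$majority)
      node <- child
    } else {  # binary test node
      v <- as.character(row[[node$attribute]])
      if (is.na(v)) return(node$majority)
      node <- if (v == node$value) node$yes else node$no
    }
  }
}

tree_attributes <- function(node) {
  if (node$kind == "leaf") return(character(0))
  kids <- if (node$kind == "split") node$children else list(node$yes, node$no)
  unique(c(node$attribute, unlist(lapply(kids, tree_attributes))))
}

#' Windowed ID3 training
#'
#' Quinlan-style main loop: a random window containing at least two classes
#' is drawn from the training set, a tree is built on it, the rows outside
#' the window are classified, and every misclassified row is added to the
#' window.  The loop stops when the tree classifies all remaining rows
#' correctly or after `max_rounds` rounds, and returns the final tree.
#'
#' @param dataset A [labeled_dataset] with at least two classes.
#' @param window_size Initial window size (`>= 2`); default half the rows.
#' @param max_rounds Cap on window-growing rounds; default 10.
#' @param seed Integer seed making the window draw reproducible.
#' @return The final tree, with attributes `rounds` (rounds used) and
#'   `converged` (logical: no misclassified rows remained).
#' @export
train_windowed <- function(dataset, window_size = ceiling(dataset$n / 2),
                           max_rounds = 10, seed = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset$class_counts) < 2)
    stop_fitid3("windowed training needs at least two classes",
                "fitid3_degenerate_window_error")
  window_size <- max(2L, min(as.integer(window_size), dataset$n))
  with_seed(seed, {
    # Seed the window with one row from each of two classes, then fill.
    cls <- names(dataset$class_counts)[1:2]
    anchor <- vapply(cls, function(cl)
      sample(which(dataset$label == cl), 1L), integer(1))
    rest <- setdiff(seq_len(dataset$n), anchor)
    extra <- if (window_size > 2L)
      sample(rest, window_size - 2L) else integer(0)
    window <- sort(c(anchor, extra))
    rounds <- 0L
    converged <- FALSE
    repeat {
      rounds <- rounds + 1L
      tree <- build_id3(dataset_subset(dataset, window))
      outside <- setdiff(seq_len(dataset$n), window)
      if (length(outside) == 0L) { converged <- TRUE; break }
      pred <- classify(tree, dataset$attributes[outside, , drop = FALSE])
      wrong <- outside[pred != as.character(dataset$label[outside])]
      if (length(wrong) == 0L) { converged <- TRUE; break }
      if (rounds >= max_rounds) break
      window <- sort(c(window, wrong))
    }
    attr(tree, "rounds") <- rounds
    attr(tree, "converged") <- converged
    tree
  })
}

#' Multiway attribute choice under the simplified criterion
#'
#' Alternative reading of the fast criterion in which each attribute is one
#' multiway candidate: the attribute whose value-partition minimizes the
#' generalized impurity is chosen.  The strictly binary tree of
#' [build_binary_tree()] uses one-vs-rest value tests instead; this function
#' exposes the per-attribute reading for comparison.
#'
#' @inheritParams select_attribute
#' @return The selected attribute name (ties by candidate order).
#' @export
select_attribute_simplified <- function(dataset, candidates) {
  if (length(candidates) == 0)
    stop_fitid3("no candidate attributes", "fitid3_precondition_error")
  score <- vapply(candidates, function(a) {
    tab <- table(dataset$attributes[[a]], dataset$label)
    branches <- lapply(seq_len(nrow(tab)), function(d) tab[d, ])
    branches <- branches[vapply(branches, sum, numeric(1)) > 0]
    generalized_impurity(branches)
  }, numeric(1))
  candidates[which.min(score)]
}
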