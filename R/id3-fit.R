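#' Fit an ID3 decision tree
#'
#' The package's main modelling interface, in the style of `rpart()` /
#' `tree()`: a formula plus a data frame of categorical variables.  Three
#' induction methods are available:
#' \describe{
#'   \item{`"classic"`}{multiway ID3 maximizing exact information gain
#'     ([build_id3()]);}
#'   \item{`"windowed"`}{classic ID3 trained through the window-growing main
#'     loop ([train_windowed()]);}
#'   \item{`"binary"`}{the improved algorithm: a strictly binary tree over
#'     one-vs-rest value tests, split by the Maclaurin-simplified criterion
#'     ([build_binary_tree()]).}
#' }
#'
#' @param formula Model formula, e.g. `grade ~ .`; the response is the class
#'   label, the right-hand side the candidate attributes.  All variables must
#'   be categorical.
#' @param data Data frame containing the variables.
#' @param method `"classic"`, `"windowed"` or `"binary"`.
#' @param max_depth Depth cap for `method = "binary"`.
#' @param window_size,max_rounds,seed Windowing controls for
#'   `method = "windowed"`; see [train_windowed()].
#' @return An object of class `"id3"`: list with the induction `method`, the
#'   tree root `tree`, the training `dataset`, class `levels`, attribute
#'   domains `xlevels` and the matched `call`.
#' @examples
#' d <- data.frame(
#'   wind = c("weak", "strong", "weak", "strong"),
#'   sky  = c("sun", "sun", "rain", "rain"),
#'   play = c("yes", "yes", "no", "no")
#' )
#' fit <- id3(play ~ ., d)
#' predict(fit, d)
#' @export
id3 <- function(formula, data, method = c("classic", "windowed", "binary"),
                max_depth = 25, window_size = NULL, max_rounds = 10,
                seed = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  label <- stats::model.response(mf)
  attrs <- mf[, -1, drop = FALSE]
  ds <- labeled_dataset(attrs, label)
  tree <- switch(method,
    classic  = build_id3(ds),
    windowed = train_windowed(ds,
                              window_size = window_size %||% ceiling(ds$n / 2),
                              max_rounds = max_rounds, seed = seed),
    binary   = build_binary_tree(ds, max_depth = max_depth))
  structure(
    list(method = method, tree = tree, dataset = ds,
         levels = levels(ds$label),
         xlevels = lapply(ds$attributes, levels),
         call = match.call()),
    class = "id3")
}

#' Predict classes from a fitted ID3 tree
#'
#' @param object An `"id3"` fit.
#' @param newdata Data frame with the attributes the tree tests; defaults to
#'   the training data.
#' @param ... Unused.
#' @return Factor of predicted class labels (training label levels).
#' @export
predict.id3 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$dataset$attributes
  factor(classify(object$tree, newdata), levels = object$levels,
         ordered = identical(object$levels, grade_levels()))
}

#' @export
print.id3 <- function(x, ...) {
  cat(sprintf("ID3 decision tree (%s), %d training rows\n",
              x$method, x$dataset$n))
  print_node(x$tree, indent = "")
  invisible(x)
}

print_node <- function(node, indent) {
  if (node$kind == "leaf") {
    cat(sprintf("%s=> %s (n=%d)\n", indent, node$label, node$support))
  } else if (node$kind == "split") {
    for (v in names(node$children)) {
      cat(sprintf("%s%s = %s\n", indent, node$attribute, v))
      print_node(node$children[[v]], paste0(indent, "  "))
    }
  } else {
    cat(sprintf("%s%s == %s?\n", indent, node$attribute, node$value))
    cat(sprintf("%s yes:\n", indent)); print_node(node$yes, paste0(indent, "  "))
    cat(sprintf("%s no:\n", indent));  print_node(node$no, paste0(indent, "  "))
  }
}

#' @export
summary.id3 <- function(object, ...) {
  stats_ <- tree_stats(object$tree)
  pred <- predict(object)
  acc <- mean(as.character(pred) == as.character(object$dataset$label))
  out <- list(method = object$method, n = object$dataset$n,
              nodes = stats_$nodes, leaves = stats_$leaves,
              depth = stats_$depth, training_accuracy = acc)
  class(out) <- "summary.id3"
  out
}

#' @export
print.summary.id3 <- function(x, ...) {
  cat(sprintf("ID3 (%s): %d nodes (%d leaves), depth %d\n",
              x$method, x$nodes, x$leaves, x$depth))
  cat(sprintf("Training rows: %d, training accuracy: %.1f%%\n",
              x$n, 100 * x$training_accuracy))
  invisible(x)
}

tree_stats <- function(node) {
  if (node$kind == "leaf")
    return(list(nodes = 1L, leaves = 1L, depth = 0L))
  kids <- if (node$kind == "split") node$children else list(node$yes, node$no)
  ks <- lapply(kids, tree_stats)
  list(nodes = 1L + sum(vapply(ks, `[[`, integer(1), "nodes")),
       leaves = sum(vapply(ks, `[[`, integer(1), "leaves")),
       depth = 1L + max(vapply(ks, `[[`, integer(1), "depth")))
}

#' Serialize a tree to JSON
#'
#' Writes the node structure (node kind, test attribute, branch values or
#' tested value, leaf label and support) as a JSON document that
#' [tree_from_json()] reads back.
#'
#' @param tree A tree node or an `"id3"` fit.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  if (inherits(tree, "id3")) tree <- tree$tree
  json <- jsonlite::toJSON(strip_node(tree), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

strip_node <- function(node) {
  if (node$kind == "leaf")
    return(list(kind = "leaf", label = node$label, support = node$support))
  if (node$kind == "split")
    return(list(kind = "split", attribute = node$attribute,
                majority = node$majority, support = node$support,
                children = lapply(node$children, strip_node)))
  list(kind = "binary-test", attribute = node$attribute, value = node$value,
       majority = node$majority, support = node$support,
       yes = strip_node(node$yes), no = strip_node(node$no))
}

#' Read a serialized tree back from JSON
#'
#' @param x JSON string or path to a JSON file written by [tree_to_json()].
#' @return A tree node usable with [classify()].
#' @export
tree_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  rebuild_node(obj)
}

rebuild_node <- function(obj) {
  if (obj$kind == "leaf")
    return(leaf_node(obj$label, obj$support))
  if (obj$kind == "split")
    return(list(kind = "split", attribute = obj$attribute,
                children = lapply(obj$children, rebuild_node),
                majority = obj$majority, support = as.integer(obj$support)))
  list(kind = "binary", attribute = obj$attribute, value = obj$value,
       yes = rebuild_node(obj$yes), no = rebuild_node(obj$no),
       majority = obj$majority, support = as.integer(obj$support))
}

#' Export a tree as a Graphviz DOT document
#'
#' @param tree A tree node or `"id3"` fit.
#' @param path Optional file path for the DOT text.
#' @return The DOT source as a character scalar.
#' @export
tree_to_dot <- function(tree, path = NULL) {
  if (inherits(tree, "id3")) tree <- tree$tree
  counter <- new.env()
  counter$i <- 0L
  lines <- c("digraph id3 {", "  node [shape=box];",
             dot_node(tree, counter)$lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(dot, path)
  invisible(dot)
}

dot_node <- function(node, counter) {
  counter$i <- counter$i + 1L
  id <- sprintf("n%d", counter$i)
  esc <- function(s) gsub('"', '\\\\"', s)
  if (node$kind == "leaf") {
    lab <- sprintf('%s [label="%s\\nn=%d", style=filled, fillcolor=lightgrey];',
                   id, esc(node$label), node$support)
    return(list(id = id, lines = paste0("  ", lab)))
  }
  if (node$kind == "split") {
    lines <- sprintf('  %s [label="%s"];', id, esc(node$attribute))
    for (v in names(node$children)) {
      child <- dot_node(node$children[[v]], counter)
      lines <- c(lines, child$lines,
                 sprintf('  %s -> %s [label="%s"];', id, child$id, esc(v)))
    }
    return(list(id = id, lines = lines))
  }
  lines <- sprintf('  %s [label="%s == %s?"];', id, esc(node$attribute),
                   esc(node$value))
  yes <- dot_node(node$yes, counter)
  no <- dot_node(node$no, counter)
  lines <- c(lines, yes$lines, no$lines,
             sprintf('  %s -> %s [label="yes"];', id, yes$id),
             sprintf('  %s -> %s [label="no"];', id, no$id))
  list(id = id, lines = lines)
}
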