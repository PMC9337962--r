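test_that("stopping rules produce the expected degenerate trees", {
  # all rows same class: single leaf
  ds <- labeled_dataset(data.frame(a = c("x", "y", "x")), rep("p", 3))
  tr <- build_id3(ds)
  expect_identical(tr$kind, "leaf")
  expect_identical(tr$label, "p")
  expect_identical(tr$support, 3L)
  # label equals an attribute: depth-1 tree, pure leaves
  ds2 <- labeled_dataset(
    data.frame(sep = c("a", "a", "b", "b"), junk = c("1", "2", "1", "2")),
    label = c("p", "p", "n", "n"))
  tr2 <- build_id3(ds2)
  expect_identical(tr2$kind, "split")
  expect_identical(tr2$attribute, "sep")
  expect_true(all(vapply(tr2$children, function(ch) ch$kind == "leaf",
                         logical(1))))
})

test_that("trees classify all training rows on consistent data", {
  set.seed(41)
  for (i in 1:20) {
    ds <- planted_dataset(30)
    tr <- build_id3(ds)
    expect_identical(classify(tr, ds$attributes), as.character(ds$label))
  }
})

test_that("no attribute repeats on a path and depth is bounded", {
  set.seed(43)
  for (i in 1:30) {
    ds <- random_dataset(max_rows = 40, max_attrs = 4, classes = c("p", "n", "m"))
    tr <- build_id3(ds)
    for (path in tree_paths(tr)) {
      expect_false(anyDuplicated(path) > 0)
      expect_lte(length(path), ncol(ds$attributes))
    }
  }
})

test_that("classify falls through to the node majority on unseen values", {
  ds <- labeled_dataset(
    data.frame(a = factor(c("x", "x", "y"), levels = c("x", "y", "z"))),
    label = c("p", "p", "n"))
  tr <- build_id3(ds)
  # value z never observed: empty branch carries the parent majority "p"
  expect_identical(classify(tr, data.frame(a = "z")), "p")
  expect_error(classify(tr, data.frame(b = "x")), class = "fitid3_input_error")
})

test_that("single-leaf tree labels any row; empty dataset is rejected", {
  ds <- labeled_dataset(data.frame(a = "x"), "p")
  tr <- build_id3(ds)
  expect_identical(classify(tr, data.frame(a = c("q", "r"))), c("p", "p"))
  expect_error(labeled_dataset(data.frame(a = character(0)), character(0)),
               class = "fitid3_empty_error")
})

test_that("windowed training reduces to build_id3 when the window is everything", {
  set.seed(47)
  ds <- planted_dataset(25)
  tw <- train_windowed(ds, window_size = ds$n, max_rounds = 5, seed = 1)
  tb <- build_id3(ds)
  attr(tw, "rounds") <- NULL
  attr(tw, "converged") <- NULL
  expect_identical(tw, tb)
})

test_that("windowed training converges on separable data with a small window", {
  set.seed(53)
  for (i in 1:5) {
    ds <- planted_dataset(40)
    tr <- train_windowed(ds, window_size = 8, max_rounds = 10, seed = i)
    expect_true(attr(tr, "converged"))
    expect_identical(classify(tr, ds$attributes), as.character(ds$label))
  }
})

test_that("windowed training respects max_rounds and seeds deterministically", {
  set.seed(59)
  ds <- planted_dataset(40)
  t1 <- train_windowed(ds, window_size = 6, max_rounds = 1, seed = 9)
  expect_lte(attr(t1, "rounds"), 1L)
  t2 <- train_windowed(ds, window_size = 6, max_rounds = 10, seed = 9)
  t3 <- train_windowed(ds, window_size = 6, max_rounds = 10, seed = 9)
  expect_identical(t2, t3)
  # single-class dataset cannot seed a two-class window
  ds1 <- labeled_dataset(data.frame(a = c("x", "y")), c("p", "p"))
  expect_error(train_windowed(ds1, 2),
               class = "fitid3_degenerate_window_error")
})

test_that("the id3() formula interface round-trips through predict and JSON", {
  d <- data.frame(
    wind = c("weak", "strong", "weak", "strong"),
    sky = c("sun", "sun", "rain", "rain"),
    play = c("yes", "yes", "no", "no"))
  fit <- id3(play ~ ., d)
  expect_s3_class(fit, "id3")
  expect_identical(as.character(predict(fit, d)), d$play)
  s <- summary(fit)
  expect_equal(s$training_accuracy, 1)
  # JSON round trip preserves classification behaviour
  tr2 <- tree_from_json(tree_to_json(fit))
  expect_identical(classify(tr2, d), d$play)
  # DOT export is well-formed
  dot <- tree_to_dot(fit)
  expect_match(dot, "^digraph")
  expect_match(dot, "sky", fixed = TRUE)
})
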