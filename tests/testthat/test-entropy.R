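test_that("expected_info matches hand-derived and oracle values", {
  expect_equal(expected_info(c(8, 8)), 1.0)
  expect_equal(expected_info(c(5, 0)), 0.0)
  expect_equal(expected_info(c(9, 5)), 0.9403, tolerance = 1e-4)
  expect_equal(expected_info(c(9, 5)), oracle_entropy(c(9, 5)))
  # zero-count classes contribute nothing
  expect_equal(expected_info(c(3, 0, 7)), expected_info(c(3, 7)))
  expect_error(expected_info(c(0, 0)), class = "fitid3_domain_error")
  expect_error(expected_info(c(-1, 2)), class = "fitid3_domain_error")
})

test_that("expected_info is bounded by log2(k) with equality at uniformity", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    cnt <- sample(1:20, k, replace = TRUE)
    h <- expected_info(cnt)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
  for (k in 2:6) expect_equal(expected_info(rep(7, k)), log2(k))
})

test_that("split_info and info_gain agree with brute-force evaluation", {
  # worked two-subset example: (2,2) and (1,3) over 8 rows
  ds <- labeled_dataset(
    data.frame(a = rep(c("l", "r"), each = 4),
               b = rep("k", 8)),
    label = c("p", "p", "n", "n", "p", "n", "n", "n"))
  expect_equal(split_info(ds, "a"), 0.5 * 1.0 + 0.5 * oracle_entropy(c(1, 3)))
  expect_equal(split_info(ds, "a"), 0.9057, tolerance = 1e-4)
  expect_equal(info_gain(ds, "a"), 0.0488, tolerance = 1e-3)
  # single-valued attribute: no partition, zero gain
  expect_equal(split_info(ds, "b"), expected_info(ds$class_counts))
  expect_equal(info_gain(ds, "b"), 0)
  expect_error(split_info(ds, "nope"), class = "fitid3_lookup_error")
})

test_that("info_gain is non-negative on random datasets", {
  set.seed(21)
  for (i in 1:200) {
    ds <- random_dataset(max_rows = 30, classes = c("p", "n", "m"))
    for (a in names(ds$attributes))
      expect_gte(info_gain(ds, a), -1e-12)
  }
})

test_that("select_attribute picks the exhaustive argmax, ties by order", {
  # perfect separator vs constant attribute
  ds <- labeled_dataset(
    data.frame(sep = c("a", "a", "b", "b"), cst = rep("k", 4)),
    label = c("p", "p", "n", "n"))
  expect_identical(select_attribute(ds, c("cst", "sep")), "sep")
  expect_identical(select_attribute(ds, "cst"), "cst")
  expect_error(select_attribute(ds, character(0)),
               class = "fitid3_precondition_error")
  # duplicated attribute: first candidate wins the tie
  ds2 <- labeled_dataset(
    data.frame(x = c("a", "b", "a", "b"), y = c("a", "b", "a", "b")),
    label = c("p", "n", "p", "n"))
  expect_identical(select_attribute(ds2, c("y", "x")), "y")
})

test_that("binary_node_info equals the two-class expected information", {
  expect_equal(binary_node_info(4, 4), 1.0)
  expect_equal(binary_node_info(7, 0), 0.0)
  expect_equal(binary_node_info(9, 5), expected_info(c(9, 5)))
  expect_error(binary_node_info(0, 0), class = "fitid3_domain_error")
})

test_that("simplified criterion: worked values and purity law", {
  expect_equal(simplified_gain(rbind(c(1, 1))), 0.5)
  expect_equal(simplified_gain(rbind(c(2, 2), c(1, 3))), 1.75)
  expect_equal(simplified_gain(list(c(5, 0), c(0, 3))), 0)
  expect_error(simplified_gain(matrix(numeric(0), ncol = 2)),
               class = "fitid3_precondition_error")
  # zero iff every branch pure
  set.seed(31)
  for (i in 1:100) {
    p <- sample(0:10, 3, replace = TRUE)
    n <- sample(0:10, 3, replace = TRUE)
    keep <- p + n >= 1
    if (!any(keep)) next
    g <- simplified_gain(cbind(p[keep], n[keep]))
    if (all(p[keep] == 0 | n[keep] == 0)) expect_equal(g, 0)
    else expect_gt(g, 0)
  }
})

test_that("generalized impurity reduces exactly to the two-class criterion", {
  expect_equal(generalized_impurity(list(c(2, 2), c(1, 3))),
               simplified_gain(rbind(c(2, 2), c(1, 3))))
  expect_equal(generalized_impurity(list(c(1, 1, 1, 1))), 1.5)
  expect_equal(generalized_impurity(list(c(0, 4, 0))), 0)
})

test_that("approximation error: balanced-point value and decay to purity", {
  expect_equal(approximation_error(4, 4), abs(1 - (2 / log(2)) / 4))
  expect_equal(approximation_error(4, 4), 0.2787, tolerance = 1e-3)
  expect_equal(approximation_error(7, 0), 0)
  # shrinks as the minority share goes to zero along a scanned grid
  errs <- sapply(1:19, function(p) approximation_error(p, 20 - p))
  half <- errs[1:10]            # minority share rising to 1/2
  expect_true(all(diff(half) > 0))
  expect_equal(errs, rev(errs)) # symmetric in p <-> n
})
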