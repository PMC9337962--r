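#' Expected information (entropy) of a class distribution
#'
#' The expected number of bits needed to identify the class of a sample drawn
#' from a node with the given per-class counts:
#' \deqn{I(s_1,\dots,s_n) = -\sum_i p_i \log_2 p_i, \quad p_i = s_i / s.}
#' Zero-count classes contribute nothing.
#'
#' @param class_counts Non-negative integer vector of per-class sample counts;
#'   at least one must be positive.
#' @return Entropy in bits, in `[0, log2(k)]` for `k` observed classes.
#' @examples
#' expected_info(c(9, 5))   # 0.9403
#' expected_info(c(8, 8))   # 1
#' @export
expected_info <- function(class_counts) {
  class_counts <- as.numeric(class_counts)
  if (any(is.na(class_counts)) || any(class_counts < 0))
    stop_fitid3("class counts must be non-negative", "fitid3_domain_error")
  s <- sum(class_counts)
  if (s == 0)
    stop_fitid3("all class counts are zero", "fitid3_domain_error")
  p <- class_counts[class_counts > 0] / s
  -sum(p * log2(p))
}

#' Conditional entropy of the class given an attribute split
#'
#' The information still required after partitioning the dataset on
#' `attribute`: the subset-size-weighted sum of subset entropies,
#' \deqn{E(A) = \sum_d \frac{|S_d|}{s} I(s_{1d},\dots,s_{md}).}
#'
#' @param dataset A [labeled_dataset].
#' @param attribute Name of one of the dataset's attributes.
#' @return Conditional entropy in bits.
#' @export
split_info <- function(dataset, attribute) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!attribute %in% names(dataset$attributes))
    stop_fitid3(paste0("unknown attribute: ", attribute), "fitid3_lookup_error")
  tab <- table(dataset$attributes[[attribute]], dataset$label)
  sizes <- rowSums(tab)
  keep <- sizes > 0
  sum(vapply(which(keep), function(d) {
    (sizes[d] / dataset$n) * expected_info(tab[d, ])
  }, numeric(1)))
}

#' Information gain of an attribute
#'
#' Reduction in class entropy achieved by splitting on `attribute`:
#' `G(A) = I - E(A)`.  Non-negative up to floating-point rounding.
#'
#' @inheritParams split_info
#' @return Gain in bits.
#' @export
info_gain <- function(dataset, attribute) {
  expected_info(dataset$class_counts) - split_info(dataset, attribute)
}

#' Choose the attribute with maximal information gain
#'
#' Ties are broken by candidate-list order (the first maximal candidate wins),
#' which keeps tree induction reproducible.
#'
#' @param dataset A [labeled_dataset].
#' @param candidates Non-empty character vector of attribute names.
#' @return The selected attribute name.
#' @export
select_attribute <- function(dataset, candidates) {
  if (length(candidates) == 0)
    stop_fitid3("no candidate attributes", "fitid3_precondition_error")
  gains <- vapply(candidates, function(a) info_gain(dataset, a), numeric(1))
  candidates[which.max(gains)]
}

#' Node information for a two-class (positive/negative) node
#'
#' Binary-class special case of [expected_info()]:
#' \deqn{-\frac{p}{p+n}\log_2\frac{p}{p+n} - \frac{n}{p+n}\log_2\frac{n}{p+n}.}
#' Pure nodes (`p = 0` or `n = 0`) carry zero information.
#'
#' @param p,n Non-negative positive- and negative-class counts, `p + n >= 1`.
#' @return Bits in `[0, 1]`.
#' @export
binary_node_info <- function(p, n) {
  if (p < 0 || n < 0 || p + n < 1)
    stop_fitid3("need p, n >= 0 with p + n >= 1", "fitid3_domain_error")
  expected_info(c(p, n))
}

#' Maclaurin-simplified split criterion
#'
#' The fast split score of the improved binary ID3.  Expanding the node
#' entropy with \eqn{\ln(1+x) \approx x - x^2/2} as the minority proportion
#' goes to zero reduces the weighted post-split entropy (up to the constant
#' factor \eqn{2/\ln 2}) to
#' \deqn{G'(F) = \sum_j \frac{p_j\, n_j}{p_j + n_j},}
#' which costs no logarithms.  It approximates the *remaining* impurity after
#' the split, so the best split **minimizes** it.
#'
#' @param splits Branch counts: either a two-column matrix (columns `p`, `n`,
#'   one row per branch) or a list of `c(p, n)` pairs.  Every branch must hold
#'   at least one sample.
#' @return The simplified score, `>= 0`, zero iff every branch is pure.
#' @examples
#' simplified_gain(rbind(c(2, 2), c(1, 3)))  # 1.75
#' @export
simplified_gain <- function(splits) {
  if (is.list(splits)) splits <- do.call(rbind, splits)
  splits <- matrix(as.numeric(splits), ncol = 2)
  if (nrow(splits) == 0)
    stop_fitid3("empty split list", "fitid3_precondition_error")
  tot <- rowSums(splits)
  if (any(splits < 0) || any(tot < 1))
    stop_fitid3("each branch needs p, n >= 0 with p + n >= 1", "fitid3_domain_error")
  sum(splits[, 1] * splits[, 2] / tot)
}

#' Multiclass generalization of the simplified criterion
#'
#' For class proportions \eqn{q_{ij}} in branch `j` of size \eqn{|S_j|},
#' returns \eqn{\sum_j |S_j| (1 - \sum_i q_{ij}^2)/2} — a Gini-style impurity
#' that reduces *exactly* to [simplified_gain()] when there are two classes,
#' via the identity \eqn{pn/(p+n) = |S|(1 - q_+^2 - q_-^2)/2}.
#'
#' @param branch_counts List of per-class count vectors, one per branch; each
#'   branch total must be at least 1.
#' @return Non-negative impurity, zero iff every branch is pure.
#' @export
generalized_impurity <- function(branch_counts) {
  if (!is.list(branch_counts)) branch_counts <- list(branch_counts)
  if (length(branch_counts) == 0)
    stop_fitid3("empty branch list", "fitid3_precondition_error")
  sum(vapply(branch_counts, function(cnt) {
    cnt <- as.numeric(cnt)
    s <- sum(cnt)
    if (any(cnt < 0) || s < 1)
      stop_fitid3("each branch needs non-negative counts with total >= 1",
                  "fitid3_domain_error")
    q <- cnt / s
    s * (1 - sum(q^2)) / 2
  }, numeric(1)))
}

#' Gap between exact node information and its Maclaurin surrogate
#'
#' Diagnostic for the simplified criterion: the absolute difference between
#' [binary_node_info()] and its second-order Maclaurin approximation
#' \eqn{(2/\ln 2)\, pn/(p+n)^2}.  The gap vanishes as the node becomes pure
#' and is largest (about 0.279 bits) at the balanced point `p = n`.
#'
#' @inheritParams binary_node_info
#' @return Absolute approximation error in bits.
#' @export
approximation_error <- function(p, n) {
  exact <- binary_node_info(p, n)
  approx_ <- (2 / log(2)) * p * n / (p + n)^2
  abs(exact - approx_)
}
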