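#' Validate a pairwise-comparison judgment matrix
#'
#' A judgment matrix records the relative importance of `n` indicators on
#' Saaty's scale: `m[i, j] > 0`, unit diagonal, and reciprocity
#' `m[i, j] * m[j, i] = 1` (enter off-diagonal pairs as `x` and `1/x`).
#'
#' @param entries Square numeric matrix of order at least 2.
#' @param tol Tolerance for the diagonal and reciprocity checks.
#' @return The matrix with class `judgment_matrix`.
#' @examples
#' judgment_matrix(rbind(c(1, 3), c(1/3, 1)))
#' @export
judgment_matrix <- function(entries, tol = 1e-9) {
  m <- as.matrix(entries)
  if (nrow(m) != ncol(m) || nrow(m) < 2)
    stop_fitid3("judgment matrix must be square with order >= 2",
                "fitid3_validation_error")
  if (any(!is.finite(m)) || any(m <= 0))
    stop_fitid3("judgment matrix entries must be positive and finite",
                "fitid3_validation_error")
  if (any(abs(diag(m) - 1) > tol))
    stop_fitid3("judgment matrix diagonal must be 1", "fitid3_validation_error")
  prod_ <- m * t(m)
  bad <- which(abs(prod_ - 1) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_fitid3(sprintf("reciprocity violated at (%d, %d): m_ij * m_ji != 1",
                        bad[1, 1], bad[1, 2]),
                "fitid3_validation_error")
  structure(m, class = c("judgment_matrix", "matrix"))
}

#' Indicator weights from a judgment matrix
#'
#' Row-sum (arithmetic-mean) approximation to the principal eigenvector:
#' each column is normalized to sum to 1, the rows of the normalized matrix
#' are summed, and the row sums are normalized to a weight vector.
#' Exact for perfectly consistent matrices.
#'
#' @param matrix A [judgment_matrix()] (or a matrix that validates as one).
#' @return Named numeric weight vector summing to 1, all entries positive.
#' @examples
#' ahp_weights(judgment_matrix(rbind(c(1, 3), c(1/3, 1))))  # 0.75 0.25
#' @export
ahp_weights <- function(matrix) {
  if (!inherits(matrix, "judgment_matrix")) matrix <- judgment_matrix(matrix)
  t_ <- sweep(matrix, 2, colSums(matrix), "/")
  v <- rowSums(t_)
  w <- v / sum(v)
  stats::setNames(as.numeric(w), rownames(matrix))
}

#' Maximum-eigenvalue approximation for a weighted judgment matrix
#'
#' \eqn{\lambda_{max} = \frac{1}{n} \sum_i (AW)_i / w_i} where `AW` is the
#' product of the judgment matrix and the weight vector.  Equals `n` exactly
#' when the matrix is consistent; Saaty's bound gives `lambda_max >= n` for
#' every valid reciprocal matrix.
#'
#' @param matrix A [judgment_matrix()].
#' @param weights Weight vector; defaults to [ahp_weights()].
#' @return The estimated dominant eigenvalue.
#' @export
ahp_lambda_max <- function(matrix, weights = ahp_weights(matrix)) {
  if (!inherits(matrix, "judgment_matrix")) matrix <- judgment_matrix(matrix)
  if (length(weights) != nrow(matrix))
    stop_fitid3("weight length must match matrix order", "fitid3_input_error")
  if (any(weights <= 0))
    stop_fitid3("weights must be positive", "fitid3_domain_error")
  aw <- as.numeric(matrix %*% weights)
  mean(aw / weights)
}

#' Saaty's random consistency index
#'
#' @param n Matrix order, 1 to 9.
#' @return The RI value for that order.
#' @export
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)
  if (n < 1 || n > length(ri))
    stop_fitid3("RI table covers orders 1-9 only", "fitid3_unsupported_order_error")
  ri[n]
}

#' Consistency test of a judgment matrix
#'
#' Computes `CI = (lambda_max - n)/(n - 1)` and `CR = CI/RI`; the matrix
#' passes when `CR < 0.1`.  Orders 1 and 2 are always consistent (`CR = 0`).
#'
#' @param matrix A [judgment_matrix()].
#' @return An `ahp_consistency` object: list with `n`, `lambda_max`, `CI`,
#'   `RI`, `CR` and logical `pass`.
#' @export
ahp_consistency <- function(matrix) {
  if (!inherits(matrix, "judgment_matrix")) matrix <- judgment_matrix(matrix)
  n <- nrow(matrix)
  lambda <- ahp_lambda_max(matrix)
  if (n <= 2) {
    ci <- 0; ri <- saaty_ri(n); cr <- 0
  } else {
    ci <- (lambda - n) / (n - 1)
    ri <- saaty_ri(n)
    cr <- ci / ri
  }
  structure(list(n = n, lambda_max = lambda, CI = ci, RI = ri, CR = cr,
                 pass = cr < 0.1),
            class = "ahp_consistency")
}

#' @export
print.ahp_consistency <- function(x, ...) {
  cat(sprintf("AHP consistency (order %d): lambda_max = %.4f, CI = %.4f, RI = %.2f\n",
              x$n, x$lambda_max, x$CI, x$RI))
  cat(sprintf("CR = %.4f -> %s\n", x$CR,
              if (x$pass) "pass (CR < 0.1)" else "FAIL (CR >= 0.1)"))
  invisible(x)
}

#' Build a perfectly consistent judgment matrix from weights
#'
#' Returns the matrix `m[i, j] = w[i]/w[j]`, which [ahp_weights()] inverts
#' exactly.  Mainly useful for constructing reference matrices.
#'
#' @param weights Positive weight vector.
#' @return A [judgment_matrix()].
#' @export
consistent_matrix <- function(weights) {
  if (any(weights <= 0))
    stop_fitid3("weights must be positive", "fitid3_domain_error")
  m <- outer(weights, weights, "/")
  rownames(m) <- colnames(m) <- names(weights)
  judgment_matrix(m)
}
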