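# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be coercible to an integer")
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Majority label of a factor/character vector.  Ties prefer the better grade
# when the labels are an ordered factor (higher level wins); otherwise the
# lexicographically first label.
majority_label <- function(label) {
  counts <- table(label)
  counts <- counts[counts > 0]
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  if (is.ordered(label)) {
    lv <- levels(label)
    top <- top[order(match(top, lv), decreasing = TRUE)]
  } else {
    top <- sort(top)
  }
  top[1L]
}

stop_fitid3 <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fitid3_error")))
}
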