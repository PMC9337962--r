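# Independent brute-force oracles, deliberately written with plain loops and
# no calls into the package's entropy code path.

oracle_entropy <- function(counts) {
  s <- sum(counts)
  h <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / s
      h <- h - p * log(p, base = 2)
    }
  }
  h
}

# Conditional entropy of the label after partitioning rows by attribute value.
oracle_split_info <- function(attr_values, labels) {
  n <- length(labels)
  e <- 0
  for (v in unique(attr_values)) {
    sub <- labels[attr_values == v]
    cnt <- sapply(unique(sub), function(cl) sum(sub == cl))
    e <- e + (length(sub) / n) * oracle_entropy(cnt)
  }
  e
}

oracle_gain <- function(attr_values, labels) {
  cnt <- sapply(unique(labels), function(cl) sum(labels == cl))
  oracle_entropy(cnt) - oracle_split_info(attr_values, labels)
}

# Dominant eigenvalue by power iteration (AHP lambda_max oracle).
oracle_lambda_max <- function(m, iters = 500) {
  v <- rep(1, nrow(m))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(m %*% v)
    v <- v2 / sqrt(sum(v2^2))
  }
  as.numeric(t(v) %*% m %*% v) / sum(v^2)
}

# Mutual information (bits) of two discrete vectors, by explicit cell loops.
oracle_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      pa <- sum(x == a) / n
      pb <- sum(y == b) / n
      mi <- mi + pab * log(pab / (pa * pb), base = 2)
    }
  }
  mi
}

# Random categorical dataset; relies on the caller's RNG state.
random_dataset <- function(max_rows = 50, max_attrs = 4, max_values = 4,
                           classes = c("pos", "neg"), min_rows = 5) {
  nr <- sample(min_rows:max_rows, 1)
  na_ <- sample(2:max_attrs, 1)
  attrs <- as.data.frame(lapply(seq_len(na_), function(j)
    sample(letters[seq_len(sample(2:max_values, 1))], nr, replace = TRUE)))
  names(attrs) <- paste0("A", seq_len(na_))
  lab <- sample(classes, nr, replace = TRUE)
  if (length(unique(lab)) < 2) lab[1:2] <- classes[1:2]
  labeled_dataset(attrs, lab)
}

# Small planted-rule dataset: the label is a deterministic function of the
# attributes, so a consistent learner must reach 100% training accuracy.
planted_dataset <- function(nr = 30) {
  a <- sample(c("lo", "hi"), nr, replace = TRUE)
  b <- sample(c("x", "y", "z"), nr, replace = TRUE)
  c_ <- sample(c("u", "v"), nr, replace = TRUE)
  lab <- ifelse(a == "hi" & b != "z", "pos", ifelse(c_ == "u", "neg", "pos"))
  labeled_dataset(data.frame(a = a, b = b, c = c_), lab)
}

# Walk a tree collecting (node, path) facts used by structural invariants.
tree_paths <- function(node, path = character(0)) {
  if (node$kind == "leaf") return(list(path))
  if (node$kind == "split") {
    out <- list()
    for (v in names(node$children))
      out <- c(out, tree_paths(node$children[[v]], c(path, node$attribute)))
    return(out)
  }
  c(tree_paths(node$yes, c(path, paste0(node$attribute, "=", node$value))),
    tree_paths(node$no, c(path, paste0("!", node$attribute, "=", node$value))))
}

count_children <- function(node) {
  if (node$kind == "leaf") return(integer(0))
  if (node$kind == "split") {
    kids <- node$children
  } else {
    kids <- list(node$yes, node$no)
  }
  c(length(kids), unlist(lapply(kids, count_children)))
}
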