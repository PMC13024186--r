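# Independent brute-force oracles and small fixture builders shared by the
# test files.  The oracle implementations deliberately use naive O(n^2)
# loops and direct formulas, sharing no code with the package internals.

oracle_dominates <- function(a, b) all(a >= b) && any(a > b)

# Naive SPEA2 strength / raw fitness / density / fitness over an
# objective matrix (rows = individuals, all objectives maximised).
oracle_spea2 <- function(obj, k) {
  n <- nrow(obj)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && oracle_dominates(obj[i, ], obj[j, ])) dom[i, j] <- TRUE
  S <- rowSums(dom)
  R <- vapply(seq_len(n), function(i) sum(S[dom[, i]]), numeric(1))
  D <- vapply(seq_len(n), function(i) {
    dd <- sqrt(colSums((t(obj) - obj[i, ])^2))[-i]
    1 / (sort(dd)[k] + 2)
  }, numeric(1))
  list(S = S, R = R, D = D, F = R + D)
}

oracle_metrics <- function(tp, tn, fp, fn) {
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

# Two-feature toy schema on [0, 10] x [0, 10].
toy_schema <- function()
  feature_schema(c("A", "B"), c(0, 0), c(10, 10))

random_genome <- function(nf)
  rule_genome(runif(nf), runif(nf), runif(nf))

random_rule <- function(schema, target = "L") {
  nf <- nrow(schema)
  n_cond <- sample.int(nf, 1L)
  idx <- sort(sample.int(nf, n_cond))
  lo <- runif(n_cond, schema$min[idx], schema$max[idx])
  hi <- runif(n_cond, lo, schema$max[idx])
  interval_rule(schema$name[idx], lo, hi, target)
}

# Small labelled dataset with uniform features.
random_labelled_data <- function(n, schema = toy_schema()) {
  x <- vapply(seq_len(nrow(schema)),
              function(j) runif(n, schema$min[j], schema$max[j]),
              numeric(n))
  out <- as.data.frame(matrix(x, nrow = n,
                              dimnames = list(NULL, schema$name)))
  out$class <- sample(c("L", "M", "H"), n, replace = TRUE)
  out
}
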