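#' Rule genome: three unit-interval vectors
#'
#' An individual of the evolutionary search is encoded as three parallel
#' real vectors in \[0, 1\], one entry per schema feature: `incl` scores
#' (a feature enters the rule when its score exceeds the inclusion
#' threshold \eqn{\lambda}), and `lo` / `hi` scores holding the lower and
#' upper interval bounds as fractions of the feature's schema range.
#'
#' @param incl,lo,hi numeric vectors of equal length with entries in
#'   \[0, 1\].
#' @return An object of class `rule_genome`.
#' @export
rule_genome <- function(incl, lo, hi) {
  if (length(incl) != length(lo) || length(lo) != length(hi))
    stop("incl, lo and hi must have equal length")
  v <- c(incl, lo, hi)
  if (any(v < 0) || any(v > 1) || any(!is.finite(v)))
    stop("genome entries must lie in [0, 1]")
  structure(list(incl = as.numeric(incl), lo = as.numeric(lo),
                 hi = as.numeric(hi)),
            class = "rule_genome")
}

# genome <-> flat gene vector, order c(incl, lo, hi)
genome_to_vector <- function(g) c(g$incl, g$lo, g$hi)

vector_to_genome <- function(v) {
  nf <- length(v) %/% 3L
  rule_genome(v[seq_len(nf)], v[nf + seq_len(nf)], v[2L * nf + seq_len(nf)])
}

#' Construct an interval rule
#'
#' A rule is a conjunction of closed numeric intervals over a subset of
#' the schema features, together with a target class: "IF every active
#' feature lies in its interval THEN the sample belongs to the target
#' class".
#'
#' @param features character vector of feature names (at least one).
#' @param lower,upper numeric bounds per condition, `lower <= upper`.
#' @param target_class one of `"L"`, `"M"`, `"H"`.
#' @return An object of class `interval_rule`.
#' @examples
#' interval_rule("Weight", 3.614, 5.390, "L")
#' @export
interval_rule <- function(features, lower, upper, target_class) {
  if (length(features) < 1L) stop("a rule needs at least one condition")
  if (length(lower) != length(features) || length(upper) != length(features))
    stop("bounds must align with features")
  if (any(lower > upper)) stop("lower bounds must not exceed upper bounds")
  if (!target_class %in% class_labels())
    stop("target_class must be one of L, M, H")
  structure(list(features = as.character(features),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 target_class = target_class),
            class = "interval_rule")
}

#' Decode a genome into an interval rule
#'
#' Feature `i` is active iff `incl[i] > lambda_threshold`.  For an active
#' feature the raw bounds are `min_i + lo[i] * (max_i - min_i)` and
#' `min_i + hi[i] * (max_i - min_i)`; when the decoded lower bound exceeds
#' the upper bound the two are swapped, so the genome-to-rule map is
#' total.  A genome activating no feature is repaired by activating the
#' single feature with the maximal inclusion score (first such index on
#' ties).
#'
#' @param g a [rule_genome()].
#' @param schema a [feature_schema].
#' @param target_class target class label of the decoded rule.
#' @param lambda_threshold inclusion threshold \eqn{\lambda \in (0, 1)}
#'   (default 0.5).
#' @return An [interval_rule()] whose bounds lie inside the schema ranges.
#' @examples
#' sch <- feature_schema(c("A", "B"), c(0, 0), c(10, 10))
#' g <- rule_genome(c(0.7, 0.3), c(0.8, 0.1), c(0.2, 0.9))
#' decode_genome(g, sch, "H")  # A active, bounds swapped to [2, 8]
#' @export
decode_genome <- function(g, schema, target_class, lambda_threshold = 0.5) {
  stopifnot_schema(schema)
  if (length(g$incl) != nrow(schema))
    stop("genome length does not match schema")
  active <- which(g$incl > lambda_threshold)
  if (length(active) == 0L) active <- which.max(g$incl)  # repair
  rng <- schema$max - schema$min
  lo <- schema$min[active] + g$lo[active] * rng[active]
  hi <- schema$min[active] + g$hi[active] * rng[active]
  swap <- lo > hi
  if (any(swap)) {
    tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
  }
  interval_rule(schema$name[active], lo, hi, target_class)
}

#' Match a rule against samples
#'
#' A sample satisfies a rule when its value lies inside the closed
#' interval of every condition (inclusive bounds).
#'
#' @param rule an [interval_rule()].
#' @param data data frame (or numeric matrix) holding at least the rule's
#'   feature columns.
#' @return Logical vector, one entry per row of `data`.
#' @examples
#' r <- interval_rule(c("Weight", "Acidity"), c(3.614, 1.059),
#'                    c(5.390, 1.067), "L")
#' rule_matches(r, data.frame(Weight = c(4, 6), Acidity = c(1.06, 1.06)))
#' @export
rule_matches <- function(rule, data) {
  x <- as.matrix(data[, rule$features, drop = FALSE])
  ok <- x >= rep(rule$lower, each = nrow(x)) &
        x <= rep(rule$upper, each = nrow(x))
  rowSums(ok) == length(rule$features)
}

#' Confusion counts of a rule on a labelled dataset
#'
#' One-vs-rest semantics: per sample, antecedent true and label equal to
#' the rule's target class counts TP; antecedent false and label different
#' counts TN; antecedent true with a different label counts FP; antecedent
#' false with the target label counts FN.
#'
#' @param rule an [interval_rule()].
#' @param data non-empty labelled data frame (feature columns + `class`).
#' @return Named integer vector `c(TP, TN, FP, FN)` summing to `nrow(data)`.
#' @export
evaluate_rule <- function(rule, data) {
  if (nrow(data) == 0L) stop("evaluation error: empty dataset")
  if (!"class" %in% names(data)) stop("'data' must have a class column")
  m <- rule_matches(rule, data)
  pos <- data$class == rule$target_class
  c(TP = sum(m & pos), TN = sum(!m & !pos),
    FP = sum(m & !pos), FN = sum(!m & pos))
}

#' Accuracy, precision and recall from confusion counts
#'
#' Accuracy is (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP) and recall
#' TP/(TP+FN).  The degenerate cases are defined as 0: a rule that never
#' fires (TP+FP = 0) has precision 0, and a rule for an absent class
#' (TP+FN = 0) has recall 0 — the value that correctly penalises such
#' rules when the three metrics are maximised.
#'
#' @param counts named numeric vector with elements `TP`, `TN`, `FP`,
#'   `FN`, at least one positive.
#' @return Named numeric vector `c(accuracy, precision, recall)`, each in
#'   \[0, 1\].
#' @examples
#' objectives(c(TP = 2, TN = 3, FP = 3, FN = 2))
#' @export
objectives <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total < 1) stop("domain error: all confusion counts are zero")
  c(accuracy = (tp + tn) / total,
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Render a rule as if-then text
#'
#' Deterministic plain-text rendering with bounds at three decimals and
#' conditions in schema (construction) order, e.g.
#' `"IF (3.614 < Weight < 5.390) and (1.059 < Acidity < 1.067) THEN L"`.
#' The `<` separators are display convention only; matching is inclusive.
#'
#' @param rule an [interval_rule()].
#' @return A single character string.
#' @seealso [parse_rule_text()] for the inverse.
#' @export
rule_to_text <- function(rule) {
  conds <- sprintf("(%.3f < %s < %.3f)", rule$lower, rule$features,
                   rule$upper)
  paste0("IF ", paste(conds, collapse = " and "), " THEN ",
         rule$target_class)
}

#' Parse if-then rule text
#'
#' Inverse of [rule_to_text()]: recovers the feature names, interval
#' bounds (to the rendered three decimals) and target class.
#'
#' @param text a string produced by [rule_to_text()].
#' @return An [interval_rule()].
#' @export
parse_rule_text <- function(text) {
  m <- regmatches(text, regexec("^IF (.*) THEN ([LMH])$", text))[[1]]
  if (length(m) != 3L) stop("unparseable rule text: ", text)
  conds <- strsplit(m[2], " and ", fixed = TRUE)[[1]]
  parts <- regmatches(conds,
    regexec("^\\(([-0-9.eE+]+) < ([^ ]+) < ([-0-9.eE+]+)\\)$", conds))
  if (any(lengths(parts) != 4L)) stop("unparseable condition in: ", text)
  interval_rule(features = vapply(parts, `[[`, "", 3L),
                lower = as.numeric(vapply(parts, `[[`, "", 2L)),
                upper = as.numeric(vapply(parts, `[[`, "", 4L)),
                target_class = m[3])
}

#' @export
print.interval_rule <- function(x, ...) {
  cat(rule_to_text(x), "\n")
  invisible(x)
}

#' @export
format.interval_rule <- function(x, ...) rule_to_text(x)
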