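#' Structural interpretability metrics of a Pareto rule set
#'
#' `average_rule_length` is the mean number of antecedent conditions per
#' rule, `max_rule_length` the largest condition count, `rule_coverage`
#' the fraction of samples matched by the antecedent of at least one rule
#' in the set, and `feature_frequency` the per-feature count of rules
#' using that feature, ranked descending (ties alphabetical).  Rule sets
#' whose rules stay short and cover most of the data are the ones a field
#' expert can actually audit.
#'
#' @param rules a `pareto_rule_set` (from [evolve()] / [spea2_rules()])
#'   or a plain list of [interval_rule()]s; must be non-empty.
#' @return `average_rule_length`: a real; `max_rule_length`: an integer.
#' @examples
#' rs <- list(interval_rule(c("Weight", "Acidity"), c(3, 0.6),
#'                          c(5, 1.0), "L"),
#'            interval_rule("Width", 15, 20, "L"))
#' average_rule_length(rs)
#' feature_frequency(rs)
#' @export
average_rule_length <- function(rules) {
  rules <- as_rule_list(rules)
  mean(vapply(rules, function(r) length(r$features), integer(1)))
}

#' @rdname average_rule_length
#' @export
max_rule_length <- function(rules) {
  rules <- as_rule_list(rules)
  max(vapply(rules, function(r) length(r$features), integer(1)))
}

#' @rdname average_rule_length
#' @param data labelled data frame the coverage is measured on.
#' @param target_only logical; restrict coverage to samples of the rules'
#'   target class (default `FALSE`: all samples count, matching the
#'   "fraction of the test data covered" reading).
#' @export
rule_coverage <- function(rules, data, target_only = FALSE) {
  rl <- as_rule_list(rules)
  if (nrow(data) == 0L) stop("metric error: empty data")
  if (target_only) {
    tc <- rl[[1L]]$target_class
    data <- data[data$class == tc, , drop = FALSE]
    if (nrow(data) == 0L) stop("metric error: no samples of target class")
  }
  covered <- rep(FALSE, nrow(data))
  for (r in rl) covered <- covered | rule_matches(r, data)
  mean(covered)
}

#' @rdname average_rule_length
#' @export
feature_frequency <- function(rules) {
  rl <- as_rule_list(rules)
  feats <- unlist(lapply(rl, function(r) unique(r$features)))
  counts <- table(feats)
  out <- data.frame(feature = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_rule_list <- function(rules) {
  if (inherits(rules, "pareto_rule_set")) rules <- rules$rules
  if (inherits(rules, "spea2_rules")) rules <- rules$rules
  if (inherits(rules, "interval_rule")) rules <- list(rules)
  if (length(rules) == 0L) stop("metric error: empty rule set")
  rules
}

#' Interpretability summary table
#'
#' One row per supplied rule set: average and maximum rule length, rule
#' coverage on `data`, and the two most frequent features.
#'
#' @param rule_sets named list of `pareto_rule_set`s (names = classes).
#' @param data labelled data frame coverage is computed on (typically the
#'   test split).
#' @param target_only passed to [rule_coverage()].
#' @return Data frame with columns `class`, `arl`, `max_len`, `coverage`,
#'   `dominant_features`.
#' @export
interpretability_table <- function(rule_sets, data, target_only = FALSE) {
  rows <- lapply(names(rule_sets), function(cl) {
    rs <- rule_sets[[cl]]
    ff <- feature_frequency(rs)
    data.frame(class = cl,
               arl = average_rule_length(rs),
               max_len = max_rule_length(rs),
               coverage = rule_coverage(rs, data, target_only),
               dominant_features = paste(utils::head(ff$feature, 2L),
                                         collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
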