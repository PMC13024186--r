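#' Repeated one-vs-rest rule-mining experiment
#'
#' Reproduces the survey protocol: for each class in `classes` and each
#' of `n_runs` independent runs, draw a fresh stratified train/test
#' split, evolve a Pareto rule set on the training part, and evaluate
#' every returned rule on both splits.  Run `r` uses integer seed
#' `base_seed + r` for the split and the PRNG and a tent seed derived
#' from the same integer, so the whole report is deterministic given
#' `base_seed`.
#'
#' @param data labelled data frame (schema features + `class`).
#' @param control a [spea2_control()]; its seeds are re-derived per run.
#' @param n_runs independent repetitions per class (default 10).
#' @param train_fraction training fraction of the stratified split
#'   (default 0.7).
#' @param classes class labels to mine (default all three).
#' @param schema a [feature_schema]; default [cherry_schema()].
#' @param base_seed integer base seed.
#' @return An object of class `spea2_experiment`: list with `per_rule`
#'   (data frame: class, run, rule, split, accuracy, precision, recall),
#'   `per_run_best` (per run and split, the best value of each metric
#'   over the run's rules) and `summary` (min/max/mean/median/sd of the
#'   per-run best values, per class, metric and split).
#' @examples
#' \donttest{
#' d <- generate_dataset(generator_config(seed = 3))
#' rep3 <- run_experiment(d, spea2_control(generations = 10),
#'                        n_runs = 2, base_seed = 1)
#' rep3$summary
#' }
#' @export
run_experiment <- function(data, control = spea2_control(), n_runs = 10L,
                           train_fraction = 0.7,
                           classes = class_labels(),
                           schema = cherry_schema(), base_seed = 1L) {
  per_rule <- list()
  rule_sets <- list()
  for (cl in classes) {
    for (r in seq_len(n_runs)) {
      seed_r <- as.integer(base_seed) + r
      sp <- stratified_split(data, train_fraction, seed = seed_r)
      ctl <- control
      ctl$prng_seed <- seed_r
      ctl$chaos_seed <- chaos_seed_from_int(seed_r)
      rs <- evolve(sp$train, cl, schema = schema, control = ctl)
      rule_sets[[paste(cl, r, sep = "_")]] <- rs
      for (i in seq_along(rs$rules)) {
        for (split in c("train", "test")) {
          obj <- objectives(evaluate_rule(rs$rules[[i]], sp[[split]]))
          per_rule[[length(per_rule) + 1L]] <- data.frame(
            class = cl, run = r, rule = i, split = split,
            text = rule_to_text(rs$rules[[i]]),
            accuracy = obj[["accuracy"]],
            precision = obj[["precision"]],
            recall = obj[["recall"]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  per_rule <- do.call(rbind, per_rule)

  agg <- stats::aggregate(per_rule[, c("accuracy", "precision", "recall")],
                          by = per_rule[, c("class", "run", "split")],
                          FUN = max)
  summary_rows <- list()
  for (cl in unique(agg$class)) for (split in c("train", "test")) {
    sub <- agg[agg$class == cl & agg$split == split, , drop = FALSE]
    for (metric in c("accuracy", "precision", "recall")) {
      v <- sub[[metric]]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        class = cl, split = split, metric = metric,
        min = min(v), max = max(v), mean = mean(v),
        median = stats::median(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(per_rule = per_rule, per_run_best = agg,
                 summary = do.call(rbind, summary_rows),
                 rule_sets = rule_sets,
                 n_runs = n_runs, base_seed = base_seed),
            class = "spea2_experiment")
}

#' @export
print.spea2_experiment <- function(x, ...) {
  cat("Rule-mining experiment:", x$n_runs, "run(s) per class\n\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export a Pareto front to CSV
#'
#' Writes one row per rule with its training accuracy, precision, recall
#' and if-then text, at full double precision so that re-importing the
#' file reproduces the objective vectors to at least 12 significant
#' digits.
#'
#' @param rule_set a `pareto_rule_set` from [evolve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_pareto_front <- function(rule_set, path) {
  if (length(rule_set$rules) == 0L) stop("empty rule set")
  df <- data.frame(accuracy = rule_set$objectives[, "accuracy"],
                   precision = rule_set$objectives[, "precision"],
                   recall = rule_set$objectives[, "recall"],
                   rule = vapply(rule_set$rules, rule_to_text, ""),
                   stringsAsFactors = FALSE)
  df$accuracy <- format(df$accuracy, digits = 15, trim = TRUE)
  df$precision <- format(df$precision, digits = 15, trim = TRUE)
  df$recall <- format(df$recall, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
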