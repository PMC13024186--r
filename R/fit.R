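#' Fit a chaos-embedded SPEA2 interval-rule classifier
#'
#' The main modelling interface.  Given a labelled table of numeric
#' measurements, evolves — one-vs-rest, per target class — a Pareto set
#' of interpretable if-then interval rules that jointly trade off
#' accuracy, precision and recall on the training data.  This is the
#' formula front end to [evolve()]; see that function for the engine and
#' [spea2_control()] for the tunable parameters.
#'
#' The feature schema (per-feature decoding ranges) is taken from
#' `schema` if supplied, otherwise it is inferred from the observed
#' min/max of each feature column in `data`.
#'
#' @param formula model formula of the form `class ~ .` or
#'   `class ~ Weight + Acidity + ...`; the response must be a character
#'   or factor column with levels among `"L"`, `"M"`, `"H"`.
#' @param data data frame holding the response and feature columns.
#' @param target class label(s) to mine rules for; default all classes
#'   present in the response.
#' @param schema optional [feature_schema]; inferred from `data` when
#'   `NULL`.
#' @param control a [spea2_control()] with the evolutionary settings.
#' @param trace logical; keep per-generation diagnostics.
#' @return An object of class `spea2_rules`: list with one
#'   `pareto_rule_set` per target class (element `rule_sets`), the
#'   `schema`, `control`, response `levels` and the matched `call`.
#' @examples
#' \donttest{
#' d <- generate_dataset(generator_config(seed = 2))
#' fit <- spea2_rules(class ~ ., d[, c(cherry_schema()$name, "class")],
#'                    target = "H",
#'                    control = spea2_control(generations = 20))
#' print(fit)
#' table(predict(fit, d, target = "H"), d$class == "H")
#' }
#' @export
spea2_rules <- function(formula, data, target = NULL, schema = NULL,
                        control = spea2_control(), trace = FALSE) {
  mf <- stats::model.frame(formula, data)
  response <- as.character(mf[[1L]])
  feats <- mf[, -1L, drop = FALSE]
  if (!all(vapply(feats, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  if (!all(response %in% class_labels()))
    stop("response labels must be among L, M, H")
  if (is.null(schema))
    schema <- feature_schema(names(feats),
                             vapply(feats, min, numeric(1)),
                             vapply(feats, max, numeric(1)))
  train <- cbind(feats, class = response, stringsAsFactors = FALSE)
  if (is.null(target)) target <- intersect(class_labels(), unique(response))
  rule_sets <- list()
  for (cl in target)
    rule_sets[[cl]] <- evolve(train, cl, schema = schema,
                              control = control, trace = trace)
  structure(list(rule_sets = rule_sets, schema = schema,
                 control = control, levels = unique(response),
                 call = match.call()),
            class = "spea2_rules")
}

#' @export
print.spea2_rules <- function(x, ...) {
  cat("Chaos-embedded SPEA2 interval-rule classifier\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  for (rs in x$rule_sets) print(rs)
  invisible(x)
}

#' Summarise a fitted rule classifier
#'
#' Reports, per target class, the size of the Pareto set, the best value
#' reached in each objective, and the structural interpretability
#' metrics (average/maximum rule length; rule coverage on `data` when
#' supplied).
#'
#' @param object a fitted [spea2_rules()] model.
#' @param data optional labelled data frame for coverage (e.g. a test
#'   split).
#' @param ... unused.
#' @return A data frame, one row per target class, invisibly printed.
#' @export
summary.spea2_rules <- function(object, data = NULL, ...) {
  rows <- lapply(names(object$rule_sets), function(cl) {
    rs <- object$rule_sets[[cl]]
    ff <- feature_frequency(rs)
    data.frame(class = cl, n_rules = length(rs$rules),
               best_accuracy = max(rs$objectives[, "accuracy"]),
               best_precision = max(rs$objectives[, "precision"]),
               best_recall = max(rs$objectives[, "recall"]),
               arl = average_rule_length(rs),
               max_len = max_rule_length(rs),
               coverage = if (is.null(data)) NA_real_
                          else rule_coverage(rs, data),
               dominant_features = paste(utils::head(ff$feature, 2L),
                                         collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.spea2_rules", "data.frame")
  out
}

#' @export
print.summary.spea2_rules <- function(x, ...) {
  cat("Pareto rule sets:\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict class membership with a fitted rule set
#'
#' One-vs-rest prediction: a sample is predicted to belong to `target`
#' when at least one rule of that class's Pareto set matches it
#' (`type = "any"`), or when the single selected rule matches
#' (`type = "rule"`, with `rule` the index of e.g. the best-accuracy
#' rule).
#'
#' @param object a fitted [spea2_rules()] model.
#' @param newdata data frame with the schema's feature columns.
#' @param target class whose rule set is applied; defaults to the first
#'   fitted class.
#' @param type `"any"` (default) or `"rule"`.
#' @param rule rule index used when `type = "rule"`; default the rule
#'   with the highest training accuracy.
#' @param ... unused.
#' @return Logical vector: does the model assert membership of `target`?
#' @export
predict.spea2_rules <- function(object, newdata,
                                target = names(object$rule_sets)[1L],
                                type = c("any", "rule"), rule = NULL,
                                ...) {
  type <- match.arg(type)
  rs <- object$rule_sets[[target]]
  if (is.null(rs)) stop("no rule set fitted for class ", target)
  if (type == "any") {
    out <- rep(FALSE, nrow(newdata))
    for (r in rs$rules) out <- out | rule_matches(r, newdata)
    out
  } else {
    if (is.null(rule)) rule <- which.max(rs$objectives[, "accuracy"])
    rule_matches(rs$rules[[rule]], newdata)
  }
}

#' Plot the Pareto front of a fitted rule classifier
#'
#' Pairwise scatter plots of the archived rules' training objectives
#' (accuracy vs precision, accuracy vs recall, precision vs recall), one
#' panel row per target class.
#'
#' @param x a fitted [spea2_rules()] model.
#' @param ... forwarded to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spea2_rules <- function(x, ...) {
  sets <- x$rule_sets
  pairs <- list(c("accuracy", "precision"), c("accuracy", "recall"),
                c("precision", "recall"))
  old <- graphics::par(mfrow = c(length(sets), 3L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cl in names(sets)) {
    obj <- sets[[cl]]$objectives
    for (p in pairs) {
      graphics::plot(obj[, p[1L]], obj[, p[2L]], xlim = c(0, 1),
                     ylim = c(0, 1), xlab = p[1L], ylab = p[2L],
                     main = paste("class", cl), pch = 19, ...)
    }
  }
  invisible(x)
}
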