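#' Configuration of the survey-emulating data generator
#'
#' Defaults reproduce the composition of the infestation survey: 381
#' samples split 204/101/76 over the Low/Medium/High classes, ten numeric
#' fruit traits with the observed ranges of [cherry_schema()], and
#' per-class trap-count ranges 0-5 / 6-10 / 11-30 consistent with
#' [label_from_trap_count()].
#'
#' `class_shift` controls how strongly the per-class feature
#' distributions are displaced along each feature's range: 0 makes the
#' classes statistically identical (a negative control for any
#' classifier), 1 pushes the class centres to the opposite ends of every
#' range.
#'
#' @param schema a [feature_schema] (default [cherry_schema()]).
#' @param class_counts named integer vector of per-class sample counts.
#' @param trap_ranges named list of `c(min, max)` integer trap-count
#'   ranges per class.
#' @param class_shift real in \[0, 1\]; default 0.25.
#' @param seed integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(schema = cherry_schema(),
                             class_counts = c(L = 204L, M = 101L, H = 76L),
                             trap_ranges = list(L = c(0L, 5L),
                                                M = c(6L, 10L),
                                                H = c(11L, 30L)),
                             class_shift = 0.25, seed = 1L) {
  stopifnot_schema(schema)
  if (!all(class_labels() %in% names(class_counts)))
    stop("class_counts must name L, M and H")
  if (any(class_counts < 1L)) stop("class counts must be >= 1")
  if (class_shift < 0 || class_shift > 1)
    stop("class_shift must lie in [0, 1]")
  for (cl in class_labels()) {
    rng <- trap_ranges[[cl]]
    labs <- label_from_trap_count(seq(rng[1L], rng[2L]))
    if (!all(labs == cl))
      stop("trap range for class ", cl,
           " is inconsistent with label_from_trap_count")
  }
  structure(list(schema = schema, class_counts = class_counts,
                 trap_ranges = trap_ranges, class_shift = class_shift,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a survey-like labelled dataset
#'
#' Emits exactly the configured number of samples per class.  Each
#' feature value is drawn from a normal distribution centred, per class,
#' at `min + position * (max - min)` — where `position` is 0.5 shifted by
#' `-class_shift/2`, `0`, `+class_shift/2` for L, M, H respectively — with
#' standard deviation one sixth of the range, then clamped to
#' `[min, max]`.  Every sample also receives a trap count drawn uniformly
#' from its class's range, so the two labelling paths (assigned class vs
#' [label_from_trap_count()]) agree by construction.  Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return Labelled data frame: schema feature columns, `trap_count`,
#'   `class`; rows grouped L, M, H.
#' @examples
#' d <- generate_dataset(generator_config(seed = 7))
#' table(d$class)
#' @export
generate_dataset <- function(config = generator_config()) {
  sch <- config$schema
  rng <- sch$max - sch$min
  offsets <- c(L = -0.5, M = 0, H = 0.5) * config$class_shift
  with_seed(config$seed, {
    parts <- lapply(class_labels(), function(cl) {
      n <- config$class_counts[[cl]]
      pos <- pmin(pmax(0.5 + offsets[[cl]], 0), 1)
      centre <- sch$min + pos * rng
      vals <- vapply(seq_len(n_features(sch)), function(j) {
        pmin(pmax(stats::rnorm(n, centre[j], rng[j] / 6),
                  sch$min[j]), sch$max[j])
      }, numeric(n))
      out <- as.data.frame(matrix(vals, nrow = n,
                                  dimnames = list(NULL, sch$name)))
      tr <- config$trap_ranges[[cl]]
      out$trap_count <- sample(seq(tr[1L], tr[2L]), n, replace = TRUE)
      out$class <- cl
      out
    })
    do.call(rbind, parts)
  })
}

#' Generate a planted-rule dataset with known ground truth
#'
#' Builds a dataset whose labels are (up to label noise) exactly
#' determined by a known interval rule, so rule-recovery experiments have
#' a ground truth.  `round(n_samples * positive_fraction)` samples are
#' made to satisfy the rule (their active-feature values drawn uniformly
#' inside the rule's intervals, other features uniform over the schema
#' range) and receive the rule's target class; the rest are
#' rejection-sampled to violate the rule and receive a class drawn from
#' the remaining labels.  Each label is then flipped independently with
#' probability `noise_rate` (target to a random other class and vice
#' versa).  Rows are shuffled; deterministic given `seed`.
#'
#' @param planted an [interval_rule()] with bounds inside the schema
#'   ranges.
#' @param schema a [feature_schema]; default [cherry_schema()].
#' @param n_samples number of rows (default 500).
#' @param positive_fraction fraction of rows satisfying the rule, in
#'   (0, 1) (default 0.4).
#' @param noise_rate label-flip probability in \[0, 1) (default 0).
#' @param seed integer seed.
#' @return Labelled data frame (schema features + `class`) with attribute
#'   `"planted_match"`: the pre-noise logical match vector.
#' @examples
#' r <- planted_weight_rule()
#' d <- generate_planted_rule_dataset(r, n_samples = 100, seed = 1)
#' mean(rule_matches(r, d))
#' @export
generate_planted_rule_dataset <- function(planted,
                                          schema = cherry_schema(),
                                          n_samples = 500L,
                                          positive_fraction = 0.4,
                                          noise_rate = 0, seed = 1L) {
  stopifnot_schema(schema)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must lie in (0, 1)")
  if (noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must lie in [0, 1)")
  idx <- match(planted$features, schema$name)
  if (anyNA(idx)) stop("planted rule uses features outside the schema")
  if (any(planted$lower < schema$min[idx]) ||
      any(planted$upper > schema$max[idx]))
    stop("planted rule bounds must lie inside the schema ranges")

  nf <- n_features(schema)
  n_pos <- round(n_samples * positive_fraction)
  with_seed(seed, {
    x <- matrix(stats::runif(n_samples * nf,
                             rep(schema$min, each = n_samples),
                             rep(schema$max, each = n_samples)),
                nrow = n_samples, dimnames = list(NULL, schema$name))
    # positives: draw the rule's features inside its intervals
    for (j in seq_along(idx))
      x[seq_len(n_pos), idx[j]] <- stats::runif(n_pos, planted$lower[j],
                                                planted$upper[j])
    # negatives: rejection-sample the rule's features until no match
    neg <- setdiff(seq_len(n_samples), seq_len(n_pos))
    still <- neg[rule_matches(planted, x[neg, , drop = FALSE])]
    tries <- 0L
    while (length(still) > 0L) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("generation error: could not produce rule-violating samples",
             " (rule covers almost the whole feature space)")
      for (j in idx)
        x[still, j] <- stats::runif(length(still), schema$min[j],
                                    schema$max[j])
      still <- still[rule_matches(planted, x[still, , drop = FALSE])]
    }
    match_vec <- rule_matches(planted, x)
    others <- setdiff(class_labels(), planted$target_class)
    labels <- ifelse(match_vec, planted$target_class,
                     sample(others, n_samples, replace = TRUE))
    if (noise_rate > 0) {
      flip <- stats::runif(n_samples) < noise_rate
      labels[flip] <- ifelse(labels[flip] == planted$target_class,
                             sample(others, sum(flip), replace = TRUE),
                             planted$target_class)
    }
    ord <- sample.int(n_samples)
    out <- as.data.frame(x[ord, , drop = FALSE])
    out$class <- labels[ord]
    attr(out, "planted_match") <- match_vec[ord]
    out
  })
}

#' Default planted rule of the recovery harness
#'
#' A single-condition rule on fruit weight covering the central 40% of
#' its schema range (`Weight` in \[4.112, 5.780\] for the default
#' schema), target class `"H"`.  Used as the fixed ground truth of the
#' planted-rule recovery experiments.
#'
#' @param schema a [feature_schema]; default [cherry_schema()].
#' @param feature feature carrying the rule (default `"Weight"`).
#' @param target_class target class (default `"H"`).
#' @return An [interval_rule()].
#' @export
planted_weight_rule <- function(schema = cherry_schema(),
                                feature = "Weight", target_class = "H") {
  j <- match(feature, schema$name)
  if (is.na(j)) stop("feature not in schema: ", feature)
  lo <- schema$min[j] + 0.3 * (schema$max[j] - schema$min[j])
  hi <- schema$min[j] + 0.7 * (schema$max[j] - schema$min[j])
  interval_rule(feature, lo, hi, target_class)
}
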