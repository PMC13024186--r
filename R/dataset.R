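#' Derive infestation class labels from adult trap counts
#'
#' Maps the number of adult flies captured in a yellow sticky trap to the
#' three-level infestation class: counts of `0:low_max` are Low (`"L"`),
#' counts of `(low_max+1):mid_max` are Medium (`"M"`), and anything above
#' `mid_max` is High (`"H"`).  The defaults are the survey thresholds
#' 0-5 / 6-10 / >10; a count of exactly 10 is Medium.
#'
#' @param count integer vector of non-negative trap captures.
#' @param low_max largest count still labelled Low (default 5).
#' @param mid_max largest count still labelled Medium (default 10).
#' @return Character vector of labels in `c("L", "M", "H")`.
#' @examples
#' label_from_trap_count(c(0, 3, 5, 6, 10, 11, 40))
#' @export
label_from_trap_count <- function(count, low_max = 5L, mid_max = 10L) {
  count <- as.numeric(count)
  if (any(!is.finite(count)) || any(count < 0))
    stop("trap counts must be non-negative")
  if (low_max >= mid_max) stop("low_max must be below mid_max")
  ifelse(count <= low_max, "L", ifelse(count <= mid_max, "M", "H"))
}

#' Read a labelled sample table from CSV
#'
#' Reads a comma-separated table (dot decimal, UTF-8, header row) holding
#' one fruit sample per row.  The header must contain every feature named
#' in `schema`; a `trap_count` and/or `class` column may be present.  When
#' `class` is absent it is derived from `trap_count` via
#' [label_from_trap_count()].  Rows with missing or unparseable feature
#' values are dropped; the number of dropped rows is reported via
#' [message()] and attached as attribute `"n_rejected"`.
#'
#' @param path path to an existing CSV file.
#' @param schema a [feature_schema]; defaults to [cherry_schema()].
#' @return A data frame with the schema's feature columns (numeric), an
#'   optional integer `trap_count` column, and a character `class` column
#'   when labels are available; attribute `n_rejected` counts dropped rows.
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_samples_csv(d, f)
#' d2 <- read_samples_csv(f)
#' @export
read_samples_csv <- function(path, schema = cherry_schema()) {
  stopifnot_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty input: no sample rows in ", path)
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))

  feats <- suppressWarnings(
    vapply(schema$name, function(nm) as.numeric(raw[[nm]]), numeric(nrow(raw)))
  )
  feats <- matrix(feats, nrow = nrow(raw),
                  dimnames = list(NULL, schema$name))
  keep <- !apply(feats, 1L, anyNA)
  n_rejected <- sum(!keep)
  if (n_rejected > 0L)
    message(n_rejected, " row(s) rejected (missing or non-numeric feature values)")
  out <- as.data.frame(feats[keep, , drop = FALSE])

  if ("trap_count" %in% names(raw)) {
    tc <- suppressWarnings(as.numeric(raw$trap_count[keep]))
    out$trap_count <- as.integer(tc)
  }
  if ("class" %in% names(raw)) {
    cl <- raw$class[keep]
    bad <- !(cl %in% class_labels())
    if (any(bad)) stop("invalid class label(s): ",
                       paste(unique(cl[bad]), collapse = ", "))
    out$class <- cl
  } else if ("trap_count" %in% names(out)) {
    out$class <- label_from_trap_count(out$trap_count)
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a sample table to CSV
#'
#' Inverse of [read_samples_csv()]: feature values are written with full
#' double precision so that a write/read round trip reproduces them to at
#' least 12 significant digits.
#'
#' @param data data frame of samples (feature columns plus optional
#'   `trap_count` / `class`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(data, path) {
  utils::write.csv(format(data, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a labelled sample table into training and test parts class by
#' class.  Each class contributes `round-half-up(train_fraction * n_class)`
#' samples to the training part; no global correction is applied, so the
#' overall training fraction may differ slightly from `train_fraction`.
#' The split is deterministic given `seed`.
#'
#' @param data data frame with a character `class` column.
#' @param train_fraction fraction of each class assigned to training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed integer seed controlling the within-class shuffle.
#' @return A list with elements `train` and `test`, both data frames whose
#'   union is `data` (row order within parts follows the shuffle).
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' sp <- stratified_split(d, 0.7, seed = 42)
#' table(sp$train$class)
#' @export
stratified_split <- function(data, train_fraction = 0.7, seed) {
  if (!"class" %in% names(data)) stop("'data' must have a class column")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  counts <- table(data$class)
  if (any(counts < 2L))
    stop("split error: every class needs at least 2 samples")
  idx_train <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      rows <- which(data$class == cl)
      n_tr <- floor(train_fraction * length(rows) + 0.5)  # round half up
      rows <- sample(rows)
      idx_train <- c(idx_train, rows[seq_len(n_tr)])
    }
  })
  list(train = data[sort(idx_train), , drop = FALSE],
       test  = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE])
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Extract the numeric feature matrix of `data` in schema order.
feature_matrix <- function(data, schema) {
  stopifnot_schema(schema)
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols))
    stop("data lacks feature column(s): ",
         paste(missing_cols, collapse = ", "))
  as.matrix(data[, schema$name, drop = FALSE])
}
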