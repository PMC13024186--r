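#' Feature schema: named numeric attributes with observed ranges
#'
#' A feature schema is the coordinate frame every genome is decoded against:
#' an ordered set of numeric attributes, each with the minimum and maximum
#' value observed in the field survey.  Genome entries live in \[0, 1\] and
#' are mapped affinely onto these per-feature ranges.
#'
#' @param names character vector of unique feature identifiers.
#' @param min_value,max_value numeric vectors of per-feature range bounds,
#'   recycled to `length(names)`; `min_value < max_value` is required for
#'   every feature.
#' @return An object of class `feature_schema`: a data frame with columns
#'   `name`, `min` and `max`, one row per feature in order.
#' @seealso [cherry_schema()] for the default pomological schema.
#' @examples
#' feature_schema(c("Weight", "Acidity"), c(2.86, 0.59), c(7.03, 1.07))
#' @export
feature_schema <- function(names, min_value, max_value) {
  names <- as.character(names)
  if (length(names) < 1L) stop("schema needs at least one feature")
  if (anyDuplicated(names)) stop("feature names must be unique")
  min_value <- rep_len(as.numeric(min_value), length(names))
  max_value <- rep_len(as.numeric(max_value), length(names))
  if (any(!is.finite(min_value)) || any(!is.finite(max_value)))
    stop("schema ranges must be finite")
  if (any(min_value >= max_value))
    stop("min_value must be strictly below max_value for every feature")
  out <- data.frame(name = names, min = min_value, max = max_value,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_schema", "data.frame")
  out
}

#' Default pomological schema of the cherry infestation survey
#'
#' The ten numeric fruit traits measured per sample in the infestation
#' survey, with their observed ranges: colour score, fruit weight (g),
#' width (mm), length (mm), stem length (mm), firmness, pit (core) weight
#' (g), soluble solid content (SCKM), NaOH-based maturity index, and
#' titratable acidity.
#'
#' @return A [feature_schema] with ten rows.
#' @examples
#' cherry_schema()
#' @export
cherry_schema <- function() {
  feature_schema(
    names = c("Color", "Weight", "Width", "Length", "StemLength",
              "Hardness", "Core_weight", "SCKM", "NaOH", "Acidity"),
    min_value = c(1.00, 2.86, 14.28, 15.23, 13.01, 14.44, 0.60, 12.7, 8.83, 0.59),
    max_value = c(5.00, 7.03, 23.26, 29.89, 19.81, 61.14, 10.0, 17.0, 15.48, 1.07)
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema (", nrow(x), " numeric features)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

n_features <- function(schema) nrow(schema)

stopifnot_schema <- function(schema) {
  if (!inherits(schema, "feature_schema"))
    stop("'schema' must be a feature_schema object")
  invisible(schema)
}

#' The three infestation class labels
#'
#' Class labels are the single characters `"L"`, `"M"` and `"H"` (low,
#' medium, high adult trap-capture level).
#' @return Character vector `c("L", "M", "H")`.
#' @export
class_labels <- function() c("L", "M", "H")
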