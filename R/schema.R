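#' Declare a feature schema for a mixed-type cohort table
#'
#' A schema names every analysis feature, types it as `continuous`, `binary`
#' or `categorical`, and carries two per-feature knobs used downstream: a
#' `log_transform` flag (continuous only; applied as `log1p`) and a
#' nonnegative Gower weight. Binary features are treated as symmetric by
#' default (0--0 agreement counts as similarity like 1--1); Jaccard-style
#' asymmetric treatment is available via `binary_treatment = "asymmetric"`.
#'
#' @param features data.frame with columns `name`, `kind`, and optionally
#'   `log_transform` (logical, default FALSE) and `weight` (default 1).
#' @param id_column name of the patient-id column in table files.
#' @param binary_treatment `"symmetric"` (default) or `"asymmetric"`.
#' @param transforms_applied internal flag; TRUE once [apply_transforms()]
#'   has run on a table carrying this schema.
#' @return object of class `feature_schema`.
#' @export
#' @examples
#' feature_schema(data.frame(name = c("age", "shock"),
#'                           kind = c("continuous", "binary")))
feature_schema <- function(features, id_column = "id",
                           binary_treatment = c("symmetric", "asymmetric"),
                           transforms_applied = FALSE) {
  binary_treatment <- match.arg(binary_treatment)
  stopifnot(is.data.frame(features), nrow(features) >= 1L)
  if (!all(c("name", "kind") %in% names(features)))
    stop("schema features need at least 'name' and 'kind' columns")
  features$name <- as.character(features$name)
  features$kind <- as.character(features$kind)
  if (is.null(features$log_transform)) features$log_transform <- FALSE
  if (is.null(features$weight)) features$weight <- 1
  features$log_transform <- as.logical(features$log_transform)
  features$log_transform[is.na(features$log_transform)] <- FALSE
  features$weight <- as.numeric(features$weight)
  features <- features[, c("name", "kind", "log_transform", "weight")]

  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  bad <- setdiff(features$kind, c("continuous", "binary", "categorical"))
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  if (any(features$log_transform & features$kind != "continuous"))
    stop("log_transform is only valid for continuous features")
  if (any(!is.finite(features$weight)) || any(features$weight < 0))
    stop("feature weights must be finite and nonnegative")

  structure(list(features = features,
                 id_column = as.character(id_column),
                 binary_treatment = binary_treatment,
                 transforms_applied = isTRUE(transforms_applied)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("feature_schema:", nrow(x$features), "features (",
      sum(x$features$kind == "continuous"), "continuous,",
      sum(x$features$kind == "binary"), "binary,",
      sum(x$features$kind == "categorical"), "categorical )\n")
  cat("  id column:", x$id_column,
      "| binary treatment:", x$binary_treatment,
      "| transforms applied:", x$transforms_applied, "\n")
  invisible(x)
}

schema_kinds <- function(schema) {
  stats::setNames(schema$features$kind, schema$features$name)
}

#' Read / write a feature schema as JSON
#'
#' The on-disk form is a JSON object
#' `{id_column, binary_treatment, transforms_applied, features: [...]}` with
#' one record per feature (`name`, `kind`, `log_transform`, `weight`).
#'
#' @param path file path.
#' @return `read_schema()` returns a `feature_schema`.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$features)) stop("schema file has no 'features' entry: ", path)
  feature_schema(as.data.frame(obj$features),
                 id_column = if (is.null(obj$id_column)) "id" else obj$id_column,
                 binary_treatment = if (is.null(obj$binary_treatment))
                   "symmetric" else obj$binary_treatment,
                 transforms_applied = isTRUE(obj$transforms_applied))
}

#' @rdname read_schema
#' @param schema a `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(
    list(id_column = schema$id_column,
         binary_treatment = schema$binary_treatment,
         transforms_applied = schema$transforms_applied,
         features = schema$features),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
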