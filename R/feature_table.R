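#' Construct and validate a typed patient-by-feature table
#'
#' The central data container: patient ids, a [feature_schema()], and a
#' data.frame of values with one column per declared feature. Continuous
#' features are numeric, binary features are 0/1, categorical features are
#' character; `NA` encodes missingness throughout. Categorical levels are
#' recorded in discovery (first-appearance) order.
#'
#' @param data data.frame of feature values (no id column).
#' @param schema a [feature_schema()].
#' @param patient_ids character vector, one per row.
#' @return object of class `feature_table` with elements `patient_ids`,
#'   `schema`, `data` and `levels` (named list, categorical features only).
#' @export
feature_table <- function(data, schema, patient_ids = NULL) {
  stopifnot(inherits(schema, "feature_schema"), is.data.frame(data))
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(nrow(data)))
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != nrow(data))
    stop("patient_ids length does not match row count")
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  if (nrow(data) < 2L) stop("a feature table needs at least 2 patients")

  feats <- schema$features
  missing_cols <- setdiff(feats$name, names(data))
  if (length(missing_cols))
    stop("schema features absent from data: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), feats$name)
  if (length(extra))
    stop("undeclared column(s) in data: ", paste(extra, collapse = ", "),
         " -- every non-id column must be declared in the schema")
  data <- data[, feats$name, drop = FALSE]

  levels_list <- list()
  for (j in seq_len(nrow(feats))) {
    nm <- feats$name[j]
    x <- data[[nm]]
    kind <- feats$kind[j]
    if (kind == "continuous") {
      x <- suppressWarnings(as.numeric(x))
      if (any(is.infinite(x)))
        stop("non-finite value in continuous feature '", nm, "'")
      new_na <- which(is.na(x) & !is.na(data[[nm]]))
      if (length(new_na))
        stop("non-numeric value in continuous feature '", nm, "' in row(s): ",
             paste(utils::head(new_na, 10L), collapse = ", "))
      data[[nm]] <- x
    } else if (kind == "binary") {
      x <- suppressWarnings(as.numeric(as.character(x)))
      bad <- which(!is.na(data[[nm]]) & (is.na(x) | !(x %in% c(0, 1))))
      if (length(bad))
        stop("binary feature '", nm, "' has value(s) outside {0,1} in row(s): ",
             paste(utils::head(bad, 10L), collapse = ", "))
      data[[nm]] <- as.integer(x)
    } else {
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA_character_
      data[[nm]] <- x
      levels_list[[nm]] <- unique(x[!is.na(x)])
    }
  }
  rownames(data) <- NULL
  structure(list(patient_ids = patient_ids, schema = schema,
                 data = data, levels = levels_list),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", length(x$patient_ids), "patients x",
      nrow(x$schema$features), "features\n")
  print(x$schema)
  invisible(x)
}

#' Number of patients in a feature table
#' @param table a `feature_table`.
#' @export
n_patients <- function(table) length(table$patient_ids)

#' Read a feature table from CSV plus a JSON schema
#'
#' The CSV must have a header row and contain the schema's id column; every
#' other column must be declared in the schema. Empty cells (and the strings
#' in `na_strings`) become missing values.
#'
#' @param table_path CSV path.
#' @param schema_path JSON schema path (see [read_schema()]).
#' @param na_strings strings read as missing, besides the empty cell.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(table_path, schema_path,
                               na_strings = c("", "NA")) {
  schema <- read_schema(schema_path)
  raw <- utils::read.csv(table_path, check.names = FALSE,
                         colClasses = "character", na.strings = na_strings)
  if (!schema$id_column %in% names(raw))
    stop("id column '", schema$id_column, "' not found in ", table_path)
  ids <- raw[[schema$id_column]]
  raw[[schema$id_column]] <- NULL
  undeclared <- setdiff(names(raw), schema$features$name)
  if (length(undeclared))
    stop("column(s) not declared in schema: ",
         paste(undeclared, collapse = ", "))
  feature_table(raw, schema, patient_ids = ids)
}

#' Write a feature table to CSV (companion schema via [write_schema()])
#' @param table a `feature_table`.
#' @param table_path CSV destination.
#' @param schema_path optional JSON destination for the schema.
#' @export
write_feature_table <- function(table, table_path, schema_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  out <- cbind(stats::setNames(data.frame(table$patient_ids,
                                          stringsAsFactors = FALSE),
                               table$schema$id_column),
               table$data)
  utils::write.csv(out, table_path, row.names = FALSE, na = "")
  if (!is.null(schema_path)) write_schema(table$schema, schema_path)
  invisible(table_path)
}

#' Apply declared log transforms to continuous features
#'
#' Continuous features flagged `log_transform` in the schema are replaced by
#' `log1p(x) = ln(1 + x)`, chosen over a plain log because duration-type
#' clinical variables (e.g. days hospitalized before the index infection) are
#' legitimately zero. Other entries and the missingness pattern are
#' untouched; the returned schema is marked `transforms_applied`.
#'
#' @param table a [feature_table()].
#' @param strict if TRUE (default), applying to an already-transformed table
#'   is an error; if FALSE it is a no-op.
#' @return the transformed `feature_table`.
#' @export
apply_transforms <- function(table, strict = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (table$schema$transforms_applied) {
    if (strict) stop("transforms already applied to this table")
    return(table)
  }
  feats <- table$schema$features
  for (nm in feats$name[feats$kind == "continuous" & feats$log_transform]) {
    x <- table$data[[nm]]
    if (any(x < 0, na.rm = TRUE))
      stop("negative value in log-transform feature '", nm, "'")
    table$data[[nm]] <- log1p(x)
  }
  table$schema$transforms_applied <- TRUE
  table
}

#' Expand categorical features into dummy binary indicators
#'
#' Alternative representation for multi-level features such as admission
#' source: each level becomes a symmetric binary feature `<name>.<level>`.
#'
#' @param table a [feature_table()].
#' @return a `feature_table` with categorical features dummy-coded.
#' @export
dummy_code <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  feats <- table$schema$features
  if (!any(feats$kind == "categorical")) return(table)
  new_cols <- list(); new_rows <- list()
  for (j in seq_len(nrow(feats))) {
    nm <- feats$name[j]
    if (feats$kind[j] != "categorical") {
      new_cols[[nm]] <- table$data[[nm]]
      new_rows[[length(new_rows) + 1L]] <- feats[j, ]
      next
    }
    for (lev in table$levels[[nm]]) {
      cn <- paste(nm, lev, sep = ".")
      new_cols[[cn]] <- as.integer(table$data[[nm]] == lev)
      new_rows[[length(new_rows) + 1L]] <-
        data.frame(name = cn, kind = "binary", log_transform = FALSE,
                   weight = feats$weight[j], stringsAsFactors = FALSE)
    }
  }
  schema <- feature_schema(do.call(rbind, new_rows),
                           id_column = table$schema$id_column,
                           binary_treatment = table$schema$binary_treatment,
                           transforms_applied = table$schema$transforms_applied)
  feature_table(as.data.frame(new_cols, check.names = FALSE), schema,
                patient_ids = table$patient_ids)
}

#' Subset a feature table to a set of features
#' @param table a `feature_table`.
#' @param keep character vector of feature names to retain.
#' @export
select_features <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(keep, table$schema$features$name)
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  feats <- table$schema$features
  schema <- feature_schema(feats[match(keep, feats$name), , drop = FALSE],
                           id_column = table$schema$id_column,
                           binary_treatment = table$schema$binary_treatment,
                           transforms_applied = table$schema$transforms_applied)
  feature_table(table$data[, keep, drop = FALSE], schema, table$patient_ids)
}

#' Read / write an outcomes table (id, mortality, disposition)
#'
#' Mortality must be 0/1; disposition is categorical (e.g. home,
#' nursing_home, other). Patient ids must exactly match the companion
#' feature table when the two are used together.
#'
#' @param path CSV path with columns `id`, `mortality`, `disposition`.
#' @return data.frame of class `outcome_table`.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                        colClasses = "character")
  outcome_table(df$id, df$mortality, df$disposition)
}

#' @rdname read_outcomes
#' @param outcomes an `outcome_table`.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "outcome_table"))
  utils::write.csv(as.data.frame(unclass(outcomes),
                                 stringsAsFactors = FALSE),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_outcomes
#' @param id patient ids.
#' @param mortality 0/1 vector.
#' @param disposition categorical vector.
#' @export
outcome_table <- function(id, mortality, disposition) {
  id <- as.character(id)
  mortality <- suppressWarnings(as.numeric(as.character(mortality)))
  if (any(!is.na(mortality) & !(mortality %in% c(0, 1))))
    stop("mortality must be 0/1")
  structure(data.frame(id = id, mortality = as.integer(mortality),
                       disposition = as.character(disposition),
                       stringsAsFactors = FALSE),
            class = c("outcome_table", "data.frame"))
}

check_alignment <- function(table, outcomes) {
  if (!identical(table$patient_ids, outcomes$id))
    stop("outcome table patient ids do not match the feature table")
  invisible(TRUE)
}
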