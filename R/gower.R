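#' Observed ranges of continuous features
#'
#' Gower's coefficient scales continuous differences by the feature's range
#' `R_f = max - min` over observed (non-missing) values. Ranges are computed
#' once on the full cohort (after any declared transforms) and reused for
#' every subsample, so pairwise dissimilarities are subsample-invariant and
#' the full matrix can be computed once and sliced.
#'
#' @param table a [feature_table()].
#' @return named numeric vector, one entry per continuous feature; a
#'   constant feature has range 0.
#' @export
feature_ranges <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  feats <- table$schema$features
  cont <- feats$name[feats$kind == "continuous"]
  vapply(cont, function(nm) {
    x <- table$data[[nm]]
    x <- x[!is.na(x)]
    if (!length(x)) 0 else max(x) - min(x)
  }, numeric(1L))
}

#' Gower dissimilarity between two patient records
#'
#' `d = sum(w_f * delta_f * s_f) / sum(w_f * delta_f)` where `delta_f` is 1
#' iff feature `f` is observed in both records, `w_f` the schema weight, and
#' the per-feature score `s_f` is `|x_a - x_b| / R_f` for continuous
#' features (0 when `R_f = 0`) and a 0/1 mismatch indicator for binary and
#' categorical features. Binary features are symmetric by default (0--0
#' agreement scores 0, i.e. similar); under the schema's asymmetric mode a
#' 0--0 pair is excluded from the numerator and denominator instead.
#'
#' @param a,b records: named lists or single-row data.frames of feature
#'   values.
#' @param schema a [feature_schema()].
#' @param ranges named ranges from [feature_ranges()].
#' @return dissimilarity in `[0,1]`, or an error if the records share no
#'   jointly observed feature.
#' @export
gower_pair <- function(a, b, schema, ranges) {
  feats <- schema$features
  num <- 0; den <- 0
  for (j in seq_len(nrow(feats))) {
    nm <- feats$name[j]; w <- feats$weight[j]
    xa <- a[[nm]]; xb <- b[[nm]]
    if (is.null(xa) || is.null(xb) || is.na(xa) || is.na(xb)) next
    kind <- feats$kind[j]
    if (kind == "continuous") {
      r <- ranges[[nm]]
      s <- if (r > 0) abs(xa - xb) / r else 0
    } else if (kind == "binary") {
      if (schema$binary_treatment == "asymmetric" && xa == 0 && xb == 0) next
      s <- as.numeric(xa != xb)
    } else {
      s <- as.numeric(xa != xb)
    }
    num <- num + w * s
    den <- den + w
  }
  if (den == 0) stop("undefined pair: no jointly observed feature")
  num / den
}

#' Pairwise Gower dissimilarity matrix
#'
#' Computes the full symmetric n x n matrix of [gower_pair()]
#' dissimilarities, vectorized per feature. Entries lie in `[0,1]` with a
#' zero diagonal. A pair of patients with no jointly observed feature aborts
#' with a report of the offending patients.
#'
#' @param table a [feature_table()].
#' @param ranges optional precomputed [feature_ranges()]; defaults to ranges
#'   over this table.
#' @return n x n numeric matrix with patient ids as dimnames.
#' @export
gower_matrix <- function(table, ranges = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(ranges)) ranges <- feature_ranges(table)
  parts <- gower_parts(table, ranges)
  gower_from_parts(parts$num, parts$den, table$patient_ids)
}

# weighted numerator / denominator matrices of the Gower sum, per feature
# set; kept separate so feature-reduction can drop features by subtraction
gower_parts <- function(table, ranges) {
  feats <- table$schema$features
  n <- n_patients(table)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  asym <- table$schema$binary_treatment == "asymmetric"

  for (j in seq_len(nrow(feats))) {
    nm <- feats$name[j]; w <- feats$weight[j]
    if (w == 0) next
    kind <- feats$kind[j]
    x <- table$data[[nm]]
    if (kind == "categorical") x <- match(x, table$levels[[nm]])
    obs <- !is.na(x)
    x0 <- ifelse(obs, x, 0)
    o <- tcrossprod(obs * 1)          # delta_f as 0/1 matrix
    if (kind == "continuous") {
      r <- ranges[[nm]]
      s <- if (is.null(r) || is.na(r) || r <= 0) matrix(0, n, n)
           else abs(outer(x0, x0, "-")) / r
    } else {
      s <- 1 - outer(x0, x0, "==")
      if (kind == "binary" && asym) {
        both_zero <- tcrossprod((obs & x0 == 0) * 1)
        o <- o * (1 - both_zero)
      }
    }
    num <- num + w * s * o
    den <- den + w * o
  }
  list(num = num, den = den)
}

gower_from_parts <- function(num, den, patient_ids) {
  undef <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(undef))
    stop("undefined pair(s) with no jointly observed feature: ",
         paste(utils::head(paste(patient_ids[undef[, 1]],
                                 patient_ids[undef[, 2]], sep = "/"), 5L),
               collapse = ", "))
  D <- num / den
  diag(D) <- 0
  D <- (D + t(D)) / 2   # enforce exact symmetry against float noise
  dimnames(D) <- list(patient_ids, patient_ids)
  D
}

#' Write / read a dissimilarity matrix as TSV
#'
#' Plain tab-separated text with patient ids as the header row and first
#' column.
#'
#' @param D square numeric matrix with id dimnames.
#' @param path file path.
#' @export
write_dissimilarity <- function(D, path) {
  df <- data.frame(id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  D <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(D) <- list(ids, ids)
  D
}
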