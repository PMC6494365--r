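#' Item-level consensus of each patient with its assigned cluster
#'
#' A patient's item consensus is its mean pairwise consensus with the other
#' members of its assigned cluster (self excluded) — the proportion of
#' co-sampled runs in which it landed with its cluster mates. Members of a
#' singleton cluster get value 1 by convention.
#'
#' @param M consensus matrix (or a `consensus_run`, whose final labels are
#'   then the default `labels`).
#' @param labels integer cluster labels (NA allowed for unassigned).
#' @return object of class `item_consensus`: data.frame with columns `id`,
#'   `cluster`, `value`.
#' @export
item_consensus <- function(M, labels = NULL) {
  if (inherits(M, "consensus_run")) {
    if (is.null(labels)) labels <- M$final_labels
    M <- M$consensus
  }
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(length(labels) == n)
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  value <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(labels[i])) next
    mates <- which(labels == labels[i])
    mates <- mates[mates != i]
    value[i] <- if (length(mates)) mean(M[i, mates]) else 1
  }
  structure(data.frame(id = ids, cluster = as.integer(labels), value = value,
                       stringsAsFactors = FALSE),
            class = c("item_consensus", "data.frame"))
}

#' Flag low-consensus cluster members as outliers
#'
#' Within each cluster, a member is an outlier when its item consensus
#' falls more than 2 standard deviations (n-1 denominator) below the
#' cluster mean. Clusters with fewer than 3 members, or zero spread, yield
#' no outliers.
#'
#' @param ic an [item_consensus()] result.
#' @param n_sd number of standard deviations below the mean (default 2).
#' @return object of class `outlier_report`: `by_cluster` data.frame
#'   (cluster, n, mean, sd, median, n_outliers, fraction), logical vector
#'   `outlier`, and `purified_labels` with outliers set to NA.
#' @export
detect_outliers <- function(ic, n_sd = 2) {
  stopifnot(inherits(ic, "item_consensus"))
  clusters <- sort(unique(ic$cluster[!is.na(ic$cluster)]))
  outlier <- rep(FALSE, nrow(ic))
  rows <- lapply(clusters, function(cl) {
    member <- which(!is.na(ic$cluster) & ic$cluster == cl)
    v <- ic$value[member]
    mu <- mean(v); s <- if (length(v) >= 3L) stats::sd(v) else NA_real_
    flag <- if (!is.na(s) && s > 0) v < mu - n_sd * s else rep(FALSE, length(v))
    outlier[member[flag]] <<- TRUE
    data.frame(cluster = cl, n = length(v), mean = mu, sd = s,
               median = stats::median(v),
               n_outliers = sum(flag), fraction = mean(flag))
  })
  purified <- ic$cluster
  purified[outlier] <- NA_integer_
  structure(list(by_cluster = do.call(rbind, rows), outlier = outlier,
                 purified_labels = purified, n_sd = n_sd),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report (threshold: mean -", x$n_sd, "SD):\n")
  print(x$by_cluster, row.names = FALSE)
  invisible(x)
}

#' Remove flagged outliers from a labeling
#'
#' Outliers are marked unassigned (NA), never reassigned; every retained
#' patient keeps its original label.
#'
#' @param labels integer cluster labels.
#' @param report an [detect_outliers()] report aligned to `labels`.
#' @return labels with outliers set to NA.
#' @export
purify <- function(labels, report) {
  stopifnot(inherits(report, "outlier_report"),
            length(labels) == length(report$outlier))
  labels[report$outlier] <- NA_integer_
  labels
}

#' Per-cluster phenotype summaries (content validity)
#'
#' Binary and categorical features are summarized as within-cluster
#' proportions per level; continuous features as median + IQR and
#' mean + SD. Summaries are reported on the untransformed scale (log1p
#' transforms are inverted) so tables read clinically; missing values are
#' excluded per cell with denominators reported.
#'
#' @param table a [feature_table()].
#' @param labels cluster labels (NA = unassigned, excluded).
#' @return data.frame with columns `cluster`, `feature`, `kind`, `level`,
#'   `n` (non-missing denominator), `prop`, `mean`, `sd`, `median`, `q1`,
#'   `q3`.
#' @export
phenotype_summary <- function(table, labels) {
  stopifnot(inherits(table, "feature_table"),
            length(labels) == n_patients(table))
  feats <- table$schema$features
  clusters <- sort(unique(labels[!is.na(labels)]))
  out <- list()
  for (cl in clusters) {
    member <- which(!is.na(labels) & labels == cl)
    for (j in seq_len(nrow(feats))) {
      nm <- feats$name[j]; kind <- feats$kind[j]
      x <- table$data[[nm]][member]
      x <- x[!is.na(x)]
      if (kind == "continuous") {
        if (feats$log_transform[j] && table$schema$transforms_applied)
          x <- expm1(x)
        q <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
             else rep(NA_real_, 3L)
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, feature = nm, kind = kind, level = NA_character_,
          n = length(x), prop = NA_real_,
          mean = if (length(x)) mean(x) else NA_real_,
          sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
          median = q[2L], q1 = q[1L], q3 = q[3L])
      } else {
        levs <- if (kind == "binary") "1" else table$levels[[nm]]
        for (lev in levs) {
          p <- if (length(x)) mean(as.character(x) == lev) else NA_real_
          out[[length(out) + 1L]] <- data.frame(
            cluster = cl, feature = nm, kind = kind, level = lev,
            n = length(x), prop = p, mean = NA_real_, sd = NA_real_,
            median = NA_real_, q1 = NA_real_, q3 = NA_real_)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Distribution of a positive feature level across clusters
#'
#' Answers questions of the form "what share of all Candida infections fell
#' in each cluster": among indicator-positive patients, the proportion
#' landing in each cluster (rows sum to 1).
#'
#' @param indicator logical/0-1 vector marking positive patients.
#' @param labels cluster labels (NA excluded).
#' @return named numeric vector over clusters summing to 1, or all-NA with
#'   attribute `undefined = TRUE` when there are no positives.
#' @export
cross_cluster_distribution <- function(indicator, labels) {
  stopifnot(length(indicator) == length(labels))
  pos <- which(!is.na(indicator) & indicator == 1 & !is.na(labels))
  clusters <- sort(unique(labels[!is.na(labels)]))
  if (!length(pos)) {
    out <- stats::setNames(rep(NA_real_, length(clusters)), clusters)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  counts <- vapply(clusters, function(cl) sum(labels[pos] == cl), numeric(1L))
  stats::setNames(counts / length(pos), clusters)
}

chisq_table <- function(tab, yates = FALSE) {
  test <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(table = tab,
       statistic = unname(test$statistic),
       df = unname(test$parameter),
       p_value = unname(test$p.value),
       sparse = any(test$expected < 1))
}

#' Compare outcomes across clusters (predictive validity)
#'
#' Builds cluster x mortality and cluster x discharge-disposition
#' contingency tables and tests independence with Pearson's chi-square
#' (no continuity correction by default; Yates available for 2x2). If
#' purified labels are supplied, the comparison is repeated after outlier
#' removal. Tables with any expected cell below 1 are annotated as sparse
#' but still reported.
#'
#' @param outcomes an [outcome_table()].
#' @param labels cluster labels aligned to `outcomes` (NA excluded).
#' @param purified_labels optional purified labels for the repeat
#'   comparison.
#' @param yates apply the 2x2 continuity correction (default FALSE).
#' @return object of class `outcome_comparison`: per labeling, a list with
#'   `mortality` and `disposition` entries (contingency table, statistic,
#'   df, p_value, sparse flag).
#' @export
outcome_comparison <- function(outcomes, labels, purified_labels = NULL,
                               yates = FALSE) {
  stopifnot(inherits(outcomes, "outcome_table"),
            length(labels) == nrow(outcomes))
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("outcome comparison needs at least 2 clusters")
  one <- function(lab) {
    keep <- !is.na(lab)
    list(mortality = chisq_table(table(cluster = lab[keep],
                                       mortality = outcomes$mortality[keep]),
                                 yates),
         disposition = chisq_table(table(cluster = lab[keep],
                                         disposition = outcomes$disposition[keep]),
                                   yates))
  }
  out <- list(raw = one(labels))
  if (!is.null(purified_labels)) out$purified <- one(purified_labels)
  structure(out, class = "outcome_comparison")
}

#' @export
print.outcome_comparison <- function(x, ...) {
  for (nm in names(x)) {
    cat("[", nm, "] mortality: X2 =",
        format(x[[nm]]$mortality$statistic, digits = 5),
        ", df =", x[[nm]]$mortality$df,
        ", p =", format.pval(x[[nm]]$mortality$p_value), "\n")
    cat("[", nm, "] disposition: X2 =",
        format(x[[nm]]$disposition$statistic, digits = 5),
        ", df =", x[[nm]]$disposition$df,
        ", p =", format.pval(x[[nm]]$disposition$p_value), "\n")
  }
  invisible(x)
}

#' Full cluster-validity report
#'
#' Bundles item consensus, the outlier report, purified labels, per-cluster
#' phenotype summaries (content validity) and outcome comparisons before
#' and after purification (predictive validity).
#'
#' @param run a `consensus_run` (its consensus matrix and final labels are
#'   used).
#' @param table the [feature_table()] the run was computed from.
#' @param outcomes an [outcome_table()] aligned to `table`.
#' @param n_sd outlier threshold in SDs (default 2).
#' @return object of class `validity_report`.
#' @export
validity_report <- function(run, table, outcomes, n_sd = 2) {
  stopifnot(inherits(run, "consensus_run"))
  check_alignment(table, outcomes)
  labels <- run$final_labels
  ic <- item_consensus(run$consensus, labels)
  outliers <- detect_outliers(ic, n_sd = n_sd)
  purified <- purify(labels, outliers)
  structure(list(item_consensus = ic,
                 outliers = outliers,
                 labels = labels,
                 purified_labels = purified,
                 phenotype_summary = phenotype_summary(table, labels),
                 purified_phenotype_summary = phenotype_summary(table, purified),
                 outcomes = outcome_comparison(outcomes, labels, purified)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("validity_report:", length(x$labels), "patients,",
      length(unique(x$labels)), "clusters,",
      sum(x$outliers$outlier), "outliers removed on purification\n")
  print(x$outliers$by_cluster, row.names = FALSE)
  print(x$outcomes)
  invisible(x)
}

#' Serialize a validity report to JSON
#' @param report a [validity_report()].
#' @param path destination.
#' @export
write_validity_report <- function(report, path) {
  stopifnot(inherits(report, "validity_report"))
  ser_test <- function(t)
    list(table = as.data.frame.matrix(unclass(t$table)),
         statistic = t$statistic, df = t$df, p_value = t$p_value,
         sparse = t$sparse)
  obj <- list(
    item_consensus = as.data.frame(unclass(report$item_consensus),
                                   stringsAsFactors = FALSE),
    outliers_by_cluster = report$outliers$by_cluster,
    labels = report$labels,
    purified_labels = report$purified_labels,
    phenotype_summary = report$phenotype_summary,
    purified_phenotype_summary = report$purified_phenotype_summary,
    outcome_tests = lapply(report$outcomes, function(lv)
      list(mortality = ser_test(lv$mortality),
           disposition = ser_test(lv$disposition))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
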