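#' Association of each feature with a cluster labeling
#'
#' Operationalizes "equally distributed among the clusters" as low
#' feature-cluster association on a common `[0,1]` scale: Cramér's V
#' (`sqrt(chi2 / (n * min(r-1, c-1)))`, uncorrected chi-square) for binary
#' and categorical features, and rank-based epsilon-squared from the
#' Kruskal-Wallis statistic (`H / (n - 1)`, robust to the skewness typical
#' of clinical variables) for continuous features. Missing values are
#' excluded per feature; a constant feature scores 0 and is flagged.
#'
#' @param table a [feature_table()].
#' @param labels cluster labels (NA excluded); at least 2 clusters.
#' @return named numeric vector in `[0,1]`, one entry per feature, with
#'   attribute `constant` naming degenerate features.
#' @export
feature_cluster_association <- function(table, labels) {
  stopifnot(inherits(table, "feature_table"),
            length(labels) == n_patients(table))
  keep <- !is.na(labels)
  if (length(unique(labels[keep])) < 2L) stop("need at least 2 clusters")
  feats <- table$schema$features
  constant <- character()
  scores <- vapply(seq_len(nrow(feats)), function(j) {
    nm <- feats$name[j]
    x <- table$data[[nm]][keep]
    g <- labels[keep]
    ok <- !is.na(x)
    x <- x[ok]; g <- g[ok]
    if (length(unique(x)) < 2L || length(unique(g)) < 2L) {
      constant <<- c(constant, nm)
      return(0)
    }
    if (feats$kind[j] == "continuous") {
      H <- unname(stats::kruskal.test(x, factor(g))$statistic)
      min(max(H / (length(x) - 1), 0), 1)
    } else {
      tab <- base::table(x, g)  # `table` is shadowed by the argument
      chi2 <- unname(suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic))
      denom <- length(x) * min(nrow(tab) - 1L, ncol(tab) - 1L)
      min(sqrt(chi2 / denom), 1)
    }
  }, numeric(1L))
  names(scores) <- feats$name
  attr(scores, "constant") <- constant
  scores
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pairwise agreement: 1 for identical partitions (up to
#' label permutation), about 0 for independent random partitions. Patients
#' unassigned (NA) in either labeling are excluded pairwise.
#'
#' @param labels_a,labels_b cluster labelings of the same patients.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  n <- length(a)
  if (n < 2L) stop("fewer than 2 patients in common")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Iterative feature reduction with partition-stability checking
#'
#' Starting from a consensus clustering at a fixed k, features whose
#' cluster association falls below `assoc_threshold` are tentatively
#' dropped as a batch; the cohort is reclustered and the drop is accepted
#' only if the new final labels agree with the old ones (ARI at least
#' `ari_threshold`). On rejection the most-associated half of the drop set
#' is restored and the smaller drop retried. The loop stops when nothing
#' is droppable; at least `min_features` features are always retained.
#'
#' @param table a [feature_table()] (transforms already applied).
#' @param k number of clusters to hold fixed during reduction.
#' @param assoc_threshold association below which a feature is a drop
#'   candidate (default 0.1, a small effect by Cramér's V convention).
#' @param ari_threshold partition-agreement level required to accept a
#'   drop (default 0.9).
#' @param n_reps,fraction,seed consensus settings (see [consensus_run()]).
#' @param min_features floor on the retained feature count (default 3).
#' @param final_method passed to [consensus_run()].
#' @return object of class `reduction_trace`: `iterations` (list of
#'   records: dropped, scores, ari, accepted), `final_schema`,
#'   `final_table`, `final_labels`, `initial_labels`.
#' @export
reduce_features <- function(table, k, assoc_threshold = 0.1,
                            ari_threshold = 0.9, n_reps = 100L,
                            fraction = 0.8, seed = 1L, min_features = 3L,
                            final_method = "pam") {
  stopifnot(inherits(table, "feature_table"))
  ranges <- feature_ranges(table)  # fixed over the whole reduction
  cluster_D <- function(D, it) {
    consensus_run(D, k, n_reps = n_reps, fraction = fraction,
                  seed = substream_seed(seed, 0L, it),
                  final_method = final_method)$final_labels
  }
  current <- table
  parts <- gower_parts(current, ranges)
  labels0 <- cluster_D(gower_from_parts(parts$num, parts$den,
                                        table$patient_ids), 0L)
  initial_labels <- labels0
  iterations <- list()
  it <- 0L

  repeat {
    scores <- feature_cluster_association(current, labels0)
    candidates <- names(scores)[scores < assoc_threshold]
    n_feat <- nrow(current$schema$features)
    max_droppable <- n_feat - min_features
    if (max_droppable <= 0L || !length(candidates)) {
      if (!length(iterations))
        iterations[[1L]] <- list(dropped = character(), scores = scores,
                                 ari = 1, accepted = TRUE)
      break
    }
    if (length(candidates) > max_droppable)  # keep the most-associated
      candidates <- candidates[order(scores[candidates])][seq_len(max_droppable)]

    drop_set <- candidates
    accepted_this_round <- FALSE
    while (length(drop_set)) {
      it <- it + 1L
      keep <- setdiff(current$schema$features$name, drop_set)
      trial <- select_features(current, keep)
      dropped_parts <- gower_parts(select_features(current, drop_set), ranges)
      trial_parts <- list(num = parts$num - dropped_parts$num,
                          den = parts$den - dropped_parts$den)
      labels1 <- cluster_D(gower_from_parts(trial_parts$num, trial_parts$den,
                                            table$patient_ids), it)
      ari <- adjusted_rand_index(labels0, labels1)
      accepted <- ari >= ari_threshold
      iterations[[length(iterations) + 1L]] <-
        list(dropped = drop_set, scores = scores, ari = ari,
             accepted = accepted)
      if (accepted) {
        current <- trial
        parts <- trial_parts
        labels0 <- labels1
        accepted_this_round <- TRUE
        break
      }
      # restore the most-associated half, retry the least-associated half
      drop_set <- drop_set[order(scores[drop_set])]
      drop_set <- drop_set[seq_len(length(drop_set) %/% 2L)]
    }
    if (!accepted_this_round) break
  }

  structure(list(iterations = iterations,
                 final_schema = current$schema,
                 final_table = current,
                 final_labels = labels0,
                 initial_labels = initial_labels,
                 k = as.integer(k),
                 assoc_threshold = assoc_threshold,
                 ari_threshold = ari_threshold),
            class = "reduction_trace")
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat("reduction_trace:", length(x$iterations), "iteration(s);",
      nrow(x$final_schema$features), "features retained\n")
  for (i in seq_along(x$iterations)) {
    rec <- x$iterations[[i]]
    cat(sprintf("  [%d] drop {%s} ARI=%.3f %s\n", i,
                paste(rec$dropped, collapse = ", "), rec$ari,
                if (rec$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' Serialize a reduction trace to JSON
#' @param trace a [reduce_features()] result.
#' @param path destination.
#' @export
write_reduction_trace <- function(trace, path) {
  stopifnot(inherits(trace, "reduction_trace"))
  obj <- list(
    iterations = lapply(trace$iterations, function(rec)
      list(dropped = rec$dropped,
           scores = as.list(rec$scores),
           ari = rec$ari, accepted = rec$accepted)),
    final_features = trace$final_schema$features$name,
    k = trace$k,
    assoc_threshold = trace$assoc_threshold,
    ari_threshold = trace$ari_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
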