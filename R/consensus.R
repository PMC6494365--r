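#' Derive a reproducible substream seed for one (k, rep) unit of work
#'
#' One master seed drives the whole sweep; each (cluster count, repetition)
#' pair gets a counter-derived substream so per-k results do not depend on
#' sweep order. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param k cluster count (0 for non-sweep uses).
#' @param rep repetition counter.
#' @return integer seed.
#' @export
substream_seed <- function(seed, k, rep) {
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 69069 + as.numeric(k) * 1009 + as.numeric(rep)) %% 2147483647)
}

#' Draw a patient subsample for one consensus repetition
#'
#' Samples `floor(fraction * n)` distinct indices uniformly without
#' replacement using the current RNG state.
#'
#' @param n number of patients.
#' @param fraction subsampling fraction in (0, 1].
#' @return sorted integer vector of indices.
#' @export
subsample_indices <- function(n, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- floor(fraction * n)
  sort(sample.int(n, m, replace = FALSE))
}

#' Consensus clustering at a single cluster count
#'
#' Repeatedly subsamples the cohort, runs PAM with `k` clusters on the
#' sliced precomputed dissimilarity matrix, and accumulates, per patient
#' pair, how often the two were sampled together and how often they were
#' then clustered together. The consensus matrix is the elementwise ratio
#' (Monti-style normalization by the co-sampling count, not the total
#' repetition count), with a unit diagonal by convention. Final cluster
#' labels come from clustering `1 - M`: PAM by default, for consistency
#' with the base algorithm, or average-linkage hierarchical clustering.
#'
#' @param x a [feature_table()] (Gower matrix computed internally) or a
#'   precomputed square dissimilarity matrix.
#' @param k number of clusters, `k >= 2`.
#' @param n_reps number of subsampling repetitions (default 1000).
#' @param fraction subsampling fraction (default 0.8).
#' @param seed master seed.
#' @param final_method `"pam"` (default) or `"hclust"` (average linkage).
#' @param keep_reps if TRUE, store each repetition's subsample indices and
#'   within-subsample labels (for tracing/auditing).
#' @return object of class `consensus_run`: `k`, `consensus` (M),
#'   `cosample_counts`, `cocluster_counts`, `final_labels`, `n_reps`,
#'   `subsample_fraction`, `seed`, and optionally `reps`.
#' @export
consensus_run <- function(x, k, n_reps = 1000L, fraction = 0.8, seed = 1L,
                          final_method = c("pam", "hclust"),
                          keep_reps = FALSE) {
  final_method <- match.arg(final_method)
  D <- if (inherits(x, "feature_table")) gower_matrix(x) else as_dissim_matrix(x)
  n <- nrow(D)
  if (k < 2) stop("consensus clustering needs k >= 2")
  m <- floor(fraction * n)
  if (m < k) stop("floor(fraction * n) = ", m, " is smaller than k = ", k)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  idx_mat <- matrix(0L, nrow = n_reps, ncol = m)
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, k, r))
    idx_mat[r, ] <- subsample_indices(n, fraction)
  }
  counts <- consensus_counts_cpp(D, as.integer(k), idx_mat)
  cosample <- counts$cosample
  cocluster <- counts$cocluster
  reps <- NULL
  if (keep_reps)
    reps <- lapply(seq_len(n_reps), function(r) {
      idx <- idx_mat[r, ]
      list(indices = idx,
           labels = pam_fit(D[idx, idx, drop = FALSE], k)$labels)
    })

  off <- upper.tri(cosample)
  if (any(cosample[off] == 0))
    stop("some patient pairs were never co-sampled; increase n_reps")
  M <- cocluster / cosample
  diag(M) <- 1
  dimnames(M) <- dimnames(D)

  final_labels <- if (final_method == "pam") {
    pam_fit(1 - M, k)$labels
  } else {
    stats::cutree(stats::hclust(stats::as.dist(1 - M), method = "average"), k)
  }

  structure(list(k = as.integer(k), consensus = M,
                 cosample_counts = cosample, cocluster_counts = cocluster,
                 final_labels = as.integer(final_labels),
                 n_reps = as.integer(n_reps),
                 subsample_fraction = fraction,
                 final_method = final_method,
                 seed = as.integer(seed), reps = reps),
            class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat("consensus_run: k =", x$k, ", n =", nrow(x$consensus),
      ", reps =", x$n_reps, "(fraction", x$subsample_fraction, ")\n")
  cat("  cluster sizes:", paste(tabulate(x$final_labels, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Consensus sweep over a contiguous range of cluster counts
#'
#' Computes the Gower matrix once and runs [consensus_run()] for each
#' `k` in `k_min..k_max` (default 2..9, capped to avoid an excessive number
#' of clusters). Each (k, rep) uses an independent counter-derived substream
#' of the master seed.
#'
#' @inheritParams consensus_run
#' @param k_min,k_max inclusive cluster-count range (defaults 2 and 9).
#' @return object of class `consensus_sweep`: list `runs` (named `k2`,
#'   `k3`, ...), `k_range`, `seed` and the run settings.
#' @export
consensus_sweep <- function(x, k_min = 2L, k_max = 9L, n_reps = 1000L,
                            fraction = 0.8, seed = 1L,
                            final_method = c("pam", "hclust")) {
  final_method <- match.arg(final_method)
  stopifnot(2 <= k_min, k_min <= k_max)
  D <- if (inherits(x, "feature_table")) gower_matrix(x) else as_dissim_matrix(x)
  ks <- seq.int(k_min, k_max)
  runs <- lapply(ks, function(k)
    consensus_run(D, k, n_reps = n_reps, fraction = fraction, seed = seed,
                  final_method = final_method))
  names(runs) <- paste0("k", ks)
  structure(list(runs = runs, k_range = ks, n_reps = as.integer(n_reps),
                 subsample_fraction = fraction, seed = as.integer(seed),
                 final_method = final_method),
            class = "consensus_sweep")
}

#' @export
print.consensus_sweep <- function(x, ...) {
  cat("consensus_sweep: k in", min(x$k_range), "..", max(x$k_range),
      ", reps =", x$n_reps, ", fraction =", x$subsample_fraction, "\n")
  invisible(x)
}
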