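as_dissim_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  storage.mode(D) <- "double"
  D
}

#' PAM BUILD phase: greedy medoid initialization
#'
#' The first medoid minimizes total dissimilarity to all points; each
#' subsequent medoid maximizes the total decrease in cost. Ties are broken
#' by lowest index, so the result is deterministic given `D`.
#'
#' @param D square dissimilarity matrix.
#' @param k number of medoids, `1 <= k <= n`.
#' @return object of class `pam_result`: `medoids` (patient indices,
#'   ascending), `labels` (cluster of each point, numbered by ascending
#'   medoid index; equidistant points go to the lower-index medoid),
#'   `cost` (sum of dissimilarities to assigned medoids) and `cost_trace`.
#' @export
pam_build <- function(D, k) {
  D <- as_dissim_matrix(D)
  if (k < 1 || k > nrow(D)) stop("k must lie in 1..n")
  fit <- pam_build_cpp(D, as.integer(k))
  res <- assign_to_medoids_cpp(D, as.integer(fit$medoids))
  structure(list(medoids = as.integer(res$medoids) + 1L,
                 labels = as.integer(res$labels),
                 cost = res$cost,
                 cost_trace = res$cost),
            class = "pam_result")
}

#' PAM SWAP phase: best-improvement local search
#'
#' Repeatedly applies the medoid/non-medoid swap with the largest strict
#' cost decrease until no swap improves (a local optimum). The returned cost
#' never exceeds the starting cost and the cost trace is strictly
#' decreasing.
#'
#' @param D square dissimilarity matrix.
#' @param start a `pam_result` (or list with `medoids`) valid for `D`.
#' @return a `pam_result`; `cost_trace` holds the cost after each accepted
#'   swap, starting from the initial configuration.
#' @export
pam_swap <- function(D, start) {
  D <- as_dissim_matrix(D)
  med <- as.integer(start$medoids)
  if (any(med < 1L) || any(med > nrow(D))) stop("medoid index out of range")
  fit <- pam_swap_cpp(D, med - 1L)
  structure(list(medoids = as.integer(fit$medoids) + 1L,
                 labels = as.integer(fit$labels),
                 cost = fit$cost,
                 cost_trace = as.numeric(fit$cost_trace)),
            class = "pam_result")
}

#' Partitioning around medoids (BUILD then SWAP)
#'
#' k-medoids clustering over an arbitrary precomputed dissimilarity matrix.
#' Deterministic given `D` and `k`; no metricity of `D` is required (the
#' consensus stage clusters `1 - M`, which is not a metric).
#'
#' @inheritParams pam_build
#' @param do_swap run the SWAP refinement (default TRUE).
#' @return a `pam_result`.
#' @export
pam_fit <- function(D, k, do_swap = TRUE) {
  D <- as_dissim_matrix(D)
  build <- pam_build(D, k)
  if (!do_swap || k == nrow(D)) return(build)
  res <- pam_swap(D, build)
  res$build_cost <- build$cost
  res
}

#' @export
print.pam_result <- function(x, ...) {
  cat("pam_result: k =", length(x$medoids), ", n =", length(x$labels),
      ", cost =", format(x$cost, digits = 6), "\n")
  invisible(x)
}
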