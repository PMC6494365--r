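upper_tri_values <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 patients")
  M[upper.tri(M)]
}

#' Empirical CDF of pairwise consensus values
#'
#' Right-continuous step function over the `n(n-1)/2` off-diagonal
#' upper-triangle entries of a consensus matrix (the unit diagonal is a
#' convention, not evidence, and is excluded).
#'
#' @param M consensus matrix (or a `consensus_run`).
#' @return a [stats::ecdf()] step function with `CDF(1) = 1`.
#' @export
consensus_cdf <- function(M) {
  if (inherits(M, "consensus_run")) M <- M$consensus
  stats::ecdf(upper_tri_values(M))
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The fraction of off-diagonal consensus values falling strictly inside
#' the intermediate interval, `PAC = CDF(u2) - CDF(u1)`, i.e. values `v`
#' with `u1 < v <= u2`. Pairs with consensus near 0 (never together) or
#' near 1 (always together) are unambiguous; a small PAC indicates stable
#' clustering, and the k minimizing PAC is taken as optimal.
#'
#' @param M consensus matrix (or `consensus_run`).
#' @param lower,upper interval bounds, `0 <= lower < upper <= 1`
#'   (defaults 0.1 and 0.9 from the PAC literature).
#' @return PAC in `[0,1]`.
#' @export
pac <- function(M, lower = 0.1, upper = 0.9) {
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("need 0 <= lower < upper <= 1")
  if (inherits(M, "consensus_run")) M <- M$consensus
  v <- upper_tri_values(M)
  mean(v > lower & v <= upper)
}

cdf_area <- function(M) {
  # exact integral over [0,1] of the right-continuous step CDF
  v <- sort(upper_tri_values(M))
  n <- length(v)
  x <- c(v, 1)
  F <- c(seq_len(n) / n, 1)
  sum(diff(x) * F[-length(F)]) + 0  # area below min(v) is 0
}

#' Relative change in area under the consensus CDF across k
#'
#' `A(k)` is the exact integral of the consensus CDF; the profile reports
#' `A(k_min)` at the first k and `(A(k) - A(k-1)) / A(k-1)` thereafter —
#' the standard delta-area diagnostic accompanying consensus CDF plots.
#'
#' @param sweep a [consensus_sweep()].
#' @return data.frame with columns `k`, `area`, `delta`.
#' @export
delta_area <- function(sweep) {
  stopifnot(inherits(sweep, "consensus_sweep"))
  ks <- sweep$k_range
  A <- vapply(sweep$runs, function(r) cdf_area(r$consensus), numeric(1L))
  delta <- c(A[1L], diff(A) / A[-length(A)])
  data.frame(k = ks, area = as.numeric(A), delta = as.numeric(delta))
}

#' Select the number of clusters by minimum PAC
#'
#' Computes PAC for every k in the sweep and selects the argmin (ties go to
#' the smallest k). Two diagnostics are attached: a no-structure flag when
#' no k achieves a PAC below `no_structure_threshold` (in which case a
#' warning fires — resampling-based clustering can manufacture groups in
#' structureless data, and a uniformly ambiguous profile is the tell), and
#' a boundary flag when the minimum sits at the edge of the k range.
#'
#' @param sweep a [consensus_sweep()].
#' @param lower,upper PAC interval (see [pac()]).
#' @param no_structure_threshold PAC level below which some k must fall for
#'   the profile to count as evidence of structure (default 0.25: somewhere
#'   in the sweep, under a quarter of pairs may remain ambiguous).
#' @return object of class `pac_profile`: data.frame `profile` (k, pac),
#'   `selected_k`, `interval`, `no_structure`, `boundary`.
#' @export
select_k <- function(sweep, lower = 0.1, upper = 0.9,
                     no_structure_threshold = 0.25) {
  stopifnot(inherits(sweep, "consensus_sweep"))
  ks <- sweep$k_range
  pacs <- vapply(sweep$runs, function(r) pac(r$consensus, lower, upper),
                 numeric(1L))
  sel <- ks[which.min(pacs)]  # which.min takes the first (smallest k) on ties
  no_structure <- all(pacs >= no_structure_threshold)
  boundary <- length(ks) > 1L && (sel == min(ks) || sel == max(ks))
  if (no_structure)
    warning("no-structure: PAC >= ", no_structure_threshold,
            " at every k; the cohort shows no stable cluster structure",
            call. = FALSE)
  structure(list(profile = data.frame(k = ks, pac = as.numeric(pacs)),
                 selected_k = as.integer(sel),
                 interval = c(lower = lower, upper = upper),
                 no_structure = no_structure,
                 boundary = boundary),
            class = "pac_profile")
}

#' @export
print.pac_profile <- function(x, ...) {
  cat("pac_profile: selected k =", x$selected_k,
      if (x$no_structure) "(no-structure warning)" else "",
      if (x$boundary) "(minimum at k-range boundary)" else "", "\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}
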