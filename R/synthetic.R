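#' Specify a synthetic mixed-type cohort with planted phenotypes
#'
#' Defines K latent phenotypes by cluster-specific Bernoulli prevalences for
#' binary features, cluster-specific normal (or zero-truncated shifted
#' lognormal) parameters for continuous features, categorical features with
#' per-cluster level probabilities, plus nuisance features whose distribution
#' is identical across clusters. Outcomes are cluster-graded: mortality is
#' Bernoulli per cluster and discharge disposition categorical per cluster.
#'
#' @param n_patients number of patients to generate.
#' @param cluster_proportions length-K simplex vector.
#' @param binary_prevalence K x B matrix (columns named) of Bernoulli
#'   probabilities.
#' @param continuous_means,continuous_sds K x C matrices (columns named);
#'   sds strictly positive.
#' @param lognormal_flags length-C logical; TRUE draws
#'   `max(exp(Normal(mean, sd)) - 1, 0)` so the feature is skewed,
#'   nonnegative, with median `exp(mean) - 1`.
#' @param categorical_probs named list; each element a K x L row-stochastic
#'   matrix with column names giving the levels.
#' @param n_noise_binary,n_noise_continuous counts of nuisance features drawn
#'   from a single cluster-independent distribution.
#' @param noise_binary_p Bernoulli probabilities recycled over noise binaries.
#' @param noise_continuous_mean,noise_continuous_sd recycled over noise
#'   continuous features.
#' @param mortality_rates length-K vector in `[0,1]`.
#' @param disposition_probs K x L row-stochastic matrix, columns named with
#'   disposition levels.
#' @param log_transform_features names of continuous features to flag for
#'   log1p transformation in the schema (duration-type skewed variables).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        cluster_proportions,
                        binary_prevalence = NULL,
                        continuous_means = NULL,
                        continuous_sds = NULL,
                        lognormal_flags = NULL,
                        categorical_probs = list(),
                        n_noise_binary = 0L,
                        n_noise_continuous = 0L,
                        noise_binary_p = 0.4,
                        noise_continuous_mean = 0,
                        noise_continuous_sd = 1,
                        mortality_rates,
                        disposition_probs,
                        log_transform_features = character(),
                        seed = 1L) {
  K <- length(cluster_proportions)
  stopifnot(n_patients >= 2, K >= 1)
  if (abs(sum(cluster_proportions) - 1) > 1e-9)
    stop("cluster_proportions must sum to 1")
  if (any(cluster_proportions < 0)) stop("cluster_proportions must be nonnegative")

  if (!is.null(binary_prevalence)) {
    binary_prevalence <- as.matrix(binary_prevalence)
    if (nrow(binary_prevalence) != K)
      stop("binary_prevalence must have K = ", K, " rows")
    if (any(binary_prevalence < 0 | binary_prevalence > 1))
      stop("binary prevalences must lie in [0,1]")
    if (is.null(colnames(binary_prevalence)))
      colnames(binary_prevalence) <- paste0("bin", seq_len(ncol(binary_prevalence)))
  }
  if (!is.null(continuous_means)) {
    continuous_means <- as.matrix(continuous_means)
    continuous_sds <- as.matrix(continuous_sds)
    if (nrow(continuous_means) != K || nrow(continuous_sds) != K)
      stop("continuous parameter matrices must have K = ", K, " rows")
    if (!identical(dim(continuous_means), dim(continuous_sds)))
      stop("continuous_means and continuous_sds must have the same shape")
    if (any(continuous_sds <= 0)) stop("continuous_sds must be positive")
    if (is.null(colnames(continuous_means)))
      colnames(continuous_means) <- paste0("cont", seq_len(ncol(continuous_means)))
    colnames(continuous_sds) <- colnames(continuous_means)
    if (is.null(lognormal_flags))
      lognormal_flags <- rep(FALSE, ncol(continuous_means))
    if (length(lognormal_flags) != ncol(continuous_means))
      stop("lognormal_flags must have one entry per continuous feature")
  }
  for (nm in names(categorical_probs)) {
    p <- as.matrix(categorical_probs[[nm]])
    if (nrow(p) != K) stop("categorical_probs[['", nm, "']] must have K rows")
    if (any(abs(rowSums(p) - 1) > 1e-9))
      stop("categorical_probs[['", nm, "']] rows must sum to 1")
    if (is.null(colnames(p))) stop("categorical_probs need level names as colnames")
    categorical_probs[[nm]] <- p
  }
  if (length(mortality_rates) != K) stop("mortality_rates must have length K")
  if (any(mortality_rates < 0 | mortality_rates > 1))
    stop("mortality_rates must lie in [0,1]")
  disposition_probs <- as.matrix(disposition_probs)
  if (nrow(disposition_probs) != K) stop("disposition_probs must have K rows")
  if (any(abs(rowSums(disposition_probs) - 1) > 1e-9))
    stop("disposition_probs rows must sum to 1")
  if (is.null(colnames(disposition_probs)))
    stop("disposition_probs needs level names as colnames")

  structure(list(n_patients = as.integer(n_patients),
                 cluster_proportions = as.numeric(cluster_proportions),
                 binary_prevalence = binary_prevalence,
                 continuous_means = continuous_means,
                 continuous_sds = continuous_sds,
                 lognormal_flags = as.logical(lognormal_flags),
                 categorical_probs = categorical_probs,
                 n_noise_binary = as.integer(n_noise_binary),
                 n_noise_continuous = as.integer(n_noise_continuous),
                 noise_binary_p = noise_binary_p,
                 noise_continuous_mean = noise_continuous_mean,
                 noise_continuous_sd = noise_continuous_sd,
                 mortality_rates = as.numeric(mortality_rates),
                 disposition_probs = disposition_probs,
                 log_transform_features = log_transform_features,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec: n =", x$n_patients, ", K =", length(x$cluster_proportions),
      "\n  binary:", if (is.null(x$binary_prevalence)) 0 else ncol(x$binary_prevalence),
      "| continuous:", if (is.null(x$continuous_means)) 0 else ncol(x$continuous_means),
      "| categorical:", length(x$categorical_probs),
      "| noise:", x$n_noise_binary + x$n_noise_continuous, "\n")
  invisible(x)
}

#' Generate a synthetic cohort from a specification
#'
#' Each patient's latent cluster is drawn from `cluster_proportions`
#' (i.i.d., or exact multinomial quotas with `quota = TRUE`); features and
#' outcomes are then drawn independently given the cluster. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param quota if TRUE, cluster sizes are fixed to
#'   `round(n * proportions)` instead of sampled.
#' @return object of class `synthetic_cohort`: list with `table`
#'   (a [feature_table()]), `outcomes` (an [outcome_table()]) and
#'   `true_labels` (integer vector in 1..K).
#' @export
generate_cohort <- function(spec, quota = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  K <- length(spec$cluster_proportions)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  if (quota) {
    sizes <- floor(n * spec$cluster_proportions)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac <- n * spec$cluster_proportions - sizes
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      sizes[add] <- sizes[add] + 1L
    }
    z <- rep(seq_len(K), times = sizes)
  } else {
    z <- sample.int(K, n, replace = TRUE, prob = spec$cluster_proportions)
  }

  cols <- list()
  feats <- list()
  add_feat <- function(name, kind, log_transform = FALSE) {
    feats[[length(feats) + 1L]] <<- data.frame(
      name = name, kind = kind, log_transform = log_transform, weight = 1,
      stringsAsFactors = FALSE)
  }

  if (!is.null(spec$binary_prevalence)) {
    for (b in colnames(spec$binary_prevalence)) {
      cols[[b]] <- stats::rbinom(n, 1L, spec$binary_prevalence[z, b])
      add_feat(b, "binary")
    }
  }
  if (!is.null(spec$continuous_means)) {
    for (ci in seq_len(ncol(spec$continuous_means))) {
      nm <- colnames(spec$continuous_means)[ci]
      x <- stats::rnorm(n, spec$continuous_means[z, nm], spec$continuous_sds[z, nm])
      if (spec$lognormal_flags[ci]) x <- pmax(exp(x) - 1, 0)
      cols[[nm]] <- x
      add_feat(nm, "continuous", nm %in% spec$log_transform_features)
    }
  }
  for (nm in names(spec$categorical_probs)) {
    p <- spec$categorical_probs[[nm]]
    levs <- colnames(p)
    u <- stats::runif(n)
    cum <- t(apply(p, 1L, cumsum))
    idx <- vapply(seq_len(n), function(i) {
      which(u[i] <= cum[z[i], ] + 1e-12)[1L]
    }, integer(1L))
    cols[[nm]] <- levs[idx]
    add_feat(nm, "categorical")
  }
  if (spec$n_noise_binary > 0) {
    p <- rep_len(spec$noise_binary_p, spec$n_noise_binary)
    for (j in seq_len(spec$n_noise_binary)) {
      nm <- paste0("noise_bin_", j)
      cols[[nm]] <- stats::rbinom(n, 1L, p[j])
      add_feat(nm, "binary")
    }
  }
  if (spec$n_noise_continuous > 0) {
    mu <- rep_len(spec$noise_continuous_mean, spec$n_noise_continuous)
    sg <- rep_len(spec$noise_continuous_sd, spec$n_noise_continuous)
    for (j in seq_len(spec$n_noise_continuous)) {
      nm <- paste0("noise_cont_", j)
      cols[[nm]] <- stats::rnorm(n, mu[j], sg[j])
      add_feat(nm, "continuous")
    }
  }
  if (!length(cols)) stop("spec defines no features")

  mortality <- stats::rbinom(n, 1L, spec$mortality_rates[z])
  dl <- colnames(spec$disposition_probs)
  du <- stats::runif(n)
  dcum <- t(apply(spec$disposition_probs, 1L, cumsum))
  disposition <- dl[vapply(seq_len(n), function(i) {
    which(du[i] <= dcum[z[i], ] + 1e-12)[1L]
  }, integer(1L))]

  ids <- sprintf("P%04d", seq_len(n))
  schema <- feature_schema(do.call(rbind, feats))
  tab <- feature_table(as.data.frame(cols, check.names = FALSE), schema, ids)
  structure(list(table = tab,
                 outcomes = outcome_table(ids, mortality, disposition),
                 true_labels = as.integer(z)),
            class = "synthetic_cohort")
}

#' Reference 4-phenotype septic bloodstream-infection cohort specification
#'
#' Encodes a cohort with four phenotypes patterned on recurring clinical
#' profiles in septic bloodstream infection: (1) surgical outside-hospital
#' transfers (transfer prevalence 0.908), (2) functional immunocompromised
#' patients admitted from home (prior intravenous antibiotics 0.778; longest
#' pre-infection hospitalization, median ~7 days), (3) women with skin and
#' urinary-tract infection (female 0.646; median ~0 days hospitalized before
#' infection), and (4) acutely sick pneumonia (lung source 0.71; highest
#' acuity). Cluster mixing proportions are (0.215, 0.279, 0.287, 0.219) and
#' mortality rates (0.268, 0.192, 0.21, 0.446), so the outcome gradient runs
#' from 19.2% to 44.6%. Signature prevalences fall to fixed low backgrounds
#' (0.10--0.30) in the other clusters. Days-hospitalized-before-infection is
#' skewed lognormal and flagged for log1p transformation. Four nuisance
#' features (2 binary, 2 continuous) are included by default.
#'
#' @param n_patients cohort size (must be at least 16).
#' @param seed RNG seed.
#' @param separation in `[0,1]`: 1 keeps the full phenotype contrast; 0
#'   collapses every cluster-specific parameter to its mixture average,
#'   yielding a structureless null cohort (negative control).
#' @param n_noise_binary,n_noise_continuous nuisance feature counts.
#' @return a [cohort_spec()] with K = 4.
#' @export
bsi_phenotype_spec <- function(n_patients, seed = 1L, separation = 1,
                               n_noise_binary = 2L, n_noise_continuous = 2L) {
  stopifnot(n_patients >= 16, separation >= 0, separation <= 1)
  props <- c(0.215, 0.279, 0.287, 0.219)
  props <- props / sum(props)

  bp <- rbind( #           C1     C2     C3     C4
    transfer_outside    = c(0.908, 0.03,  0.03,  0.03),
    recent_surgery      = c(0.90,  0.05,  0.06,  0.06),
    tpn                 = c(0.60,  0.05,  0.03,  0.06),
    abdominal_source    = c(0.60,  0.05,  0.02,  0.02),
    prior_antibiotics   = c(0.12,  0.778, 0.12,  0.15),
    immunosuppression   = c(0.06,  0.94,  0.06,  0.10),
    active_cancer       = c(0.08,  0.80,  0.08,  0.12),
    unknown_source      = c(0.03,  0.65,  0.04,  0.03),
    female              = c(0.25,  0.30,  0.646, 0.25),
    urinary_source      = c(0.40,  0.04,  0.70,  0.02),
    skin_source         = c(0.03,  0.03,  0.11,  0.03),
    central_line        = c(0.85,  0.60,  0.06,  0.45),
    lung_source         = c(0.03,  0.03,  0.03,  0.71),
    septic_shock        = c(0.25,  0.10,  0.06,  0.95),
    mechanical_vent     = c(0.10,  0.06,  0.05,  0.90),
    icu_admission       = c(0.30,  0.12,  0.10,  0.95),
    copd                = c(0.10,  0.06,  0.08,  0.50),
    inappropriate_abx   = c(0.50,  0.32,  0.06,  0.18))
  bp <- t(bp)  # K x B

  cm <- rbind(
    age                  = c(61, 51, 66, 52),
    apache_ii            = c(17, 12, 11, 27),
    wbc                  = c(12, 9, 18, 13),
    days_hosp_before_bsi = log(c(2, 7, 0, 2) + 1))
  cs <- rbind(
    age                  = c(11, 11, 11, 11),
    apache_ii            = c(2.5, 2.5, 2.5, 2.5),
    wbc                  = c(3, 3, 3, 3),
    days_hosp_before_bsi = c(0.35, 0.35, 0.35, 0.35))
  cm <- t(cm); cs <- t(cs)
  lognormal <- c(FALSE, FALSE, FALSE, TRUE)

  cat_probs <- list(
    admission_source = rbind(c(0.12, 0.04, 0.84),
                             c(0.92, 0.03, 0.05),
                             c(0.48, 0.45, 0.07),
                             c(0.84, 0.08, 0.08)),
    organism = rbind(c(0.08, 0.18, 0.06, 0.45, 0.23),
                     c(0.10, 0.60, 0.10, 0.03, 0.17),
                     c(0.42, 0.38, 0.04, 0.02, 0.14),
                     c(0.30, 0.15, 0.40, 0.03, 0.12)))
  colnames(cat_probs$admission_source) <- c("home", "nursing_home", "other")
  colnames(cat_probs$organism) <-
    c("s_aureus", "enterobacteriaceae", "nonfermenter", "candida", "other")

  mort <- c(0.268, 0.192, 0.21, 0.446)
  disp <- rbind(c(0.30, 0.40, 0.30),
                c(0.54, 0.20, 0.26),
                c(0.45, 0.30, 0.25),
                c(0.25, 0.30, 0.45))
  colnames(disp) <- c("home", "nursing_home", "other")

  if (separation < 1) {
    blend <- function(m) {
      avg <- drop(props %*% m)
      (1 - separation) * matrix(avg, nrow = 4, ncol = ncol(m), byrow = TRUE,
                                dimnames = dimnames(m)) + separation * m
    }
    bp <- blend(bp); cm <- blend(cm)
    cat_probs <- lapply(cat_probs, blend)
    mort <- drop((1 - separation) * sum(props * mort) + separation * mort)
    disp <- blend(disp)
  }

  cohort_spec(n_patients = n_patients,
              cluster_proportions = props,
              binary_prevalence = bp,
              continuous_means = cm,
              continuous_sds = cs,
              lognormal_flags = lognormal,
              categorical_probs = cat_probs,
              n_noise_binary = n_noise_binary,
              n_noise_continuous = n_noise_continuous,
              noise_binary_p = c(0.35, 0.5),
              noise_continuous_mean = c(0, 10),
              noise_continuous_sd = c(1, 3),
              mortality_rates = mort,
              disposition_probs = disp,
              log_transform_features = "days_hosp_before_bsi",
              seed = seed)
}

#' Write a synthetic cohort to a directory as plain-text files
#'
#' Writes `table.csv`, `schema.json`, `outcomes.csv` and `true_labels.csv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir destination directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$table, file.path(dir, "table.csv"),
                      file.path(dir, "schema.json"))
  write_outcomes(cohort$outcomes, file.path(dir, "outcomes.csv"))
  utils::write.csv(data.frame(id = cohort$table$patient_ids,
                              true_label = cohort$true_labels),
                   file.path(dir, "true_labels.csv"), row.names = FALSE)
  invisible(dir)
}
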