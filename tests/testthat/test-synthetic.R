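test_that("generation is deterministic in the seed and seed-sensitive", {
  spec <- bsi_phenotype_spec(120, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$table$data, b$table$data)
  expect_identical(a$true_labels, b$true_labels)
  expect_identical(a$outcomes, b$outcomes)
  c <- generate_cohort(bsi_phenotype_spec(120, seed = 12))
  expect_false(identical(a$table$data, c$table$data))
})

test_that("a single-cluster spec concentrates prevalence at its parameter", {
  spec <- cohort_spec(
    n_patients = 400, cluster_proportions = 1,
    binary_prevalence = matrix(0.3, 1, 1, dimnames = list(NULL, "b")),
    mortality_rates = 0.2,
    disposition_probs = matrix(c(0.5, 0.5), 1, 2,
                               dimnames = list(NULL, c("home", "other"))),
    seed = 4)
  co <- generate_cohort(spec)
  expect_true(all(co$true_labels == 1L))
  phat <- mean(co$table$data$b)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("two-cluster prevalences recover within 3 binomial SDs", {
  spec <- cohort_spec(
    n_patients = 1000, cluster_proportions = c(0.5, 0.5),
    binary_prevalence = matrix(c(0.05, 0.95), 2, 1,
                               dimnames = list(NULL, "sig")),
    mortality_rates = c(0.1, 0.2),
    disposition_probs = matrix(c(1, 0, 0, 1), 2, 2, byrow = FALSE,
                               dimnames = list(NULL, c("home", "other"))),
    seed = 9)
  co <- generate_cohort(spec)
  for (k in 1:2) {
    nk <- sum(co$true_labels == k)
    phat <- mean(co$table$data$sig[co$true_labels == k])
    p <- c(0.05, 0.95)[k]
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nk))
  }
})

test_that("reference spec matches its declared study conditions", {
  spec <- bsi_phenotype_spec(4000, seed = 2)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(sum(spec$cluster_proportions), 1, tolerance = 1e-12)
  expect_equal(unname(spec$binary_prevalence[1, "transfer_outside"]), 0.908)
  expect_equal(unname(spec$binary_prevalence[2, "prior_antibiotics"]), 0.778)
  expect_equal(unname(spec$binary_prevalence[3, "female"]), 0.646)
  expect_equal(unname(spec$binary_prevalence[4, "lung_source"]), 0.71)
  expect_equal(spec$mortality_rates[2], 0.192)
  expect_equal(spec$mortality_rates[4], 0.446)
  expect_true(all(spec$mortality_rates >= 0.192 & spec$mortality_rates <= 0.446))
  expect_gte(spec$n_noise_binary + spec$n_noise_continuous, 4L)
  # skewed duration feature: median ~7 days in cluster 2, ~2/0 elsewhere
  expect_true(spec$lognormal_flags[4])
  expect_equal(exp(spec$continuous_means[, "days_hosp_before_bsi"]) - 1,
               c(2, 7, 0, 2), tolerance = 1e-12)

  co <- generate_cohort(spec)
  sizes <- tabulate(co$true_labels, 4L)
  props <- spec$cluster_proportions
  for (k in 1:4) {
    expect_lt(abs(sizes[k] - 4000 * props[k]),
              3 * sqrt(4000 * props[k] * (1 - props[k])))
  }
  m4 <- mean(co$outcomes$mortality[co$true_labels == 4])
  expect_lt(abs(m4 - 0.446), 3 * sqrt(0.446 * 0.554 / sizes[4]))
  med2 <- median(co$table$data$days_hosp_before_bsi[co$true_labels == 2])
  expect_gt(med2, 4)
})

test_that("quota mode fixes cluster sizes exactly", {
  co <- generate_cohort(bsi_phenotype_spec(400, seed = 5), quota = TRUE)
  expect_equal(sum(tabulate(co$true_labels, 4L)), 400L)
  expect_equal(tabulate(co$true_labels, 4L),
               c(86, 112, 115, 87))  # floor(n*p) plus largest remainders
})

test_that("inconsistent spec dimensions are rejected", {
  expect_error(cohort_spec(
    n_patients = 100, cluster_proportions = c(0.5, 0.5),
    binary_prevalence = matrix(0.5, 3, 1),
    mortality_rates = c(0.1, 0.2),
    disposition_probs = matrix(c(1, 1), 2, 1,
                               dimnames = list(NULL, "home"))),
    "K = 2")
  expect_error(cohort_spec(
    n_patients = 100, cluster_proportions = c(0.6, 0.5),
    mortality_rates = c(0.1, 0.2),
    disposition_probs = matrix(c(1, 1), 2, 1,
                               dimnames = list(NULL, "home"))),
    "sum to 1")
})

test_that("separation = 0 collapses all cluster-specific parameters", {
  null_spec <- bsi_phenotype_spec(100, seed = 1, separation = 0)
  expect_true(all(apply(null_spec$binary_prevalence, 2,
                        function(col) diff(range(col)) < 1e-12)))
  expect_true(all(apply(null_spec$continuous_means, 2,
                        function(col) diff(range(col)) < 1e-12)))
  expect_lt(diff(range(null_spec$mortality_rates)), 1e-12)
})

test_that("written cohort files read back consistently", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(bsi_phenotype_spec(60, seed = 3))
  write_cohort(co, dir)
  ft <- read_feature_table(file.path(dir, "table.csv"),
                           file.path(dir, "schema.json"))
  oc <- read_outcomes(file.path(dir, "outcomes.csv"))
  expect_identical(ft$patient_ids, co$table$patient_ids)
  expect_equal(ft$data$apache_ii, co$table$data$apache_ii, tolerance = 1e-12)
  expect_equal(oc$mortality, co$outcomes$mortality)
})
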