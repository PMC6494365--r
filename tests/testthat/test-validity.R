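block_M <- function(labels, hi = 1, lo = 0) {
  M <- outer(labels, labels, function(a, b) ifelse(a == b, hi, lo))
  diag(M) <- 1
  M
}

test_that("item consensus is the mean consensus with co-members", {
  lab <- c(1, 1, 1, 2, 2)
  M <- block_M(lab)
  ic <- item_consensus(M, lab)
  expect_true(all(ic$value == 1))

  # hand matrix: patient 1's consensus with co-members 2,3 is (0.8+0.6)/2
  M2 <- matrix(1, 5, 5)
  M2[1, 2] <- M2[2, 1] <- 0.8
  M2[1, 3] <- M2[3, 1] <- 0.6
  M2[2, 3] <- M2[3, 2] <- 0.9
  M2[4, 5] <- M2[5, 4] <- 0.4
  M2[1:3, 4:5] <- 0.1
  M2[4:5, 1:3] <- 0.1
  ic2 <- item_consensus(M2, lab)
  expect_equal(ic2$value, c((0.8 + 0.6) / 2, (0.8 + 0.9) / 2,
                            (0.6 + 0.9) / 2, 0.4, 0.4))

  # constant consensus 0.5 with all co-members
  M3 <- block_M(lab, hi = 0.5, lo = 0)
  expect_equal(item_consensus(M3, lab)$value, rep(0.5, 5))

  # singleton cluster convention and unassigned patients
  lab2 <- c(1, 1, 2, NA, 1)
  ic4 <- item_consensus(M2, lab2)
  expect_equal(ic4$value[3], 1)
  expect_true(is.na(ic4$value[4]))
})

test_that("outliers are flagged more than 2 SDs below the cluster mean", {
  ic <- structure(data.frame(id = as.character(1:20),
                             cluster = rep(1L, 20),
                             value = c(rep(0.9, 19), 0.2)),
                  class = c("item_consensus", "data.frame"))
  rep_ <- detect_outliers(ic)
  expect_equal(rep_$by_cluster$n_outliers, 1L)
  expect_true(rep_$outlier[20])
  expect_false(any(rep_$outlier[1:19]))
  # direct arithmetic: mean 0.865, sd ~0.1565 -> cutoff ~0.552
  expect_equal(rep_$by_cluster$mean, mean(ic$value))
  expect_equal(rep_$by_cluster$sd, sd(ic$value))

  # equal values: SD = 0, no outliers
  ic0 <- structure(data.frame(id = as.character(1:8), cluster = rep(1L, 8),
                              value = rep(0.7, 8)),
                   class = c("item_consensus", "data.frame"))
  expect_equal(detect_outliers(ic0)$by_cluster$n_outliers, 0L)

  # clusters smaller than 3 yield no outliers by rule
  ic2 <- structure(data.frame(id = as.character(1:2), cluster = rep(1L, 2),
                              value = c(0.9, 0.1)),
                   class = c("item_consensus", "data.frame"))
  expect_equal(detect_outliers(ic2)$by_cluster$n_outliers, 0L)
})

test_that("purification removes outliers without touching other labels", {
  ic <- structure(data.frame(id = as.character(1:21),
                             cluster = c(rep(1L, 20), 2L),
                             value = c(rep(0.9, 19), 0.2, 0.8)),
                  class = c("item_consensus", "data.frame"))
  rep_ <- detect_outliers(ic)
  lab <- ic$cluster
  pur <- purify(lab, rep_)
  expect_true(is.na(pur[20]))
  expect_identical(pur[-20], lab[-20])
  expect_equal(sum(!is.na(pur) & pur == 1), 20 - rep_$by_cluster$n_outliers[1])
  # no outliers -> unchanged
  none <- detect_outliers(structure(
    data.frame(id = as.character(1:5), cluster = rep(1L, 5),
               value = rep(0.8, 5)),
    class = c("item_consensus", "data.frame")))
  expect_identical(purify(rep(1L, 5), none), rep(1L, 5))
})

test_that("phenotype summaries count proportions and summarize continuous
           features on the untransformed scale", {
  sch <- feature_schema(data.frame(
    name = c("shock", "los", "source"),
    kind = c("binary", "continuous", "categorical"),
    log_transform = c(FALSE, TRUE, FALSE)))
  df <- data.frame(shock = c(rep(1L, 9), 0L, rep(0L, 5)),
                   los = c(rep(3, 10), rep(8, 5)),
                   source = c(rep("lung", 10), rep("urine", 5)))
  ft <- apply_transforms(feature_table(df, sch))
  lab <- c(rep(1L, 10), rep(2L, 5))
  ps <- phenotype_summary(ft, lab)
  shock1 <- ps[ps$cluster == 1 & ps$feature == "shock", ]
  expect_equal(shock1$prop, 0.9)
  los1 <- ps[ps$cluster == 1 & ps$feature == "los", ]
  expect_equal(los1$median, 3)   # back on the day scale despite log1p
  src2 <- ps[ps$cluster == 2 & ps$feature == "source", ]
  expect_equal(src2$prop[src2$level == "urine"], 1)

  # invariant to patient order
  set.seed(2)
  perm <- sample(15)
  ftp <- feature_table(df[perm, , drop = FALSE], sch)
  ftp <- apply_transforms(ftp)
  psp <- phenotype_summary(ftp, lab[perm])
  expect_equal(psp[order(psp$cluster, psp$feature, psp$level), -c(1:4)],
               ps[order(ps$cluster, ps$feature, ps$level), -c(1:4)],
               ignore_attr = TRUE)
})

test_that("cross-cluster distribution shares sum to one", {
  lab <- rep(1:4, each = 10)
  ind <- as.integer(lab == 2)
  expect_equal(unname(cross_cluster_distribution(ind, lab)), c(0, 1, 0, 0))
  ind2 <- rep(c(1, 0, 0, 0, 0), 8)  # 8 positives spread 2/2/2/2
  expect_equal(unname(cross_cluster_distribution(ind2, lab)),
               rep(0.25, 4))
  none <- cross_cluster_distribution(rep(0, 40), lab)
  expect_true(all(is.na(none)))
  expect_true(attr(none, "undefined"))
})

test_that("outcome chi-square matches hand-evaluated tables", {
  oc <- outcome_table(as.character(1:40),
                      c(rep(1, 30), rep(0, 10))[c(1:40)],
                      rep("home", 40))
  # build labels so cluster x mortality is [[30,10],[10,30]]:
  mort <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  oc <- outcome_table(as.character(1:80), mort, rep("home", 80))
  lab <- rep(1:2, each = 40)
  cmp <- outcome_comparison(oc, lab)
  expect_equal(cmp$raw$mortality$statistic, 20.0)
  expect_equal(cmp$raw$mortality$df, 1)

  # independence: table [[10,10],[10,10]] gives chi-square 0, p = 1
  mort2 <- rep(c(1, 1, 0, 0), 10)
  oc2 <- outcome_table(as.character(1:40), mort2, rep("home", 40))
  lab2 <- rep(c(1, 2, 1, 2), 10)
  cmp2 <- outcome_comparison(oc2, lab2)
  expect_equal(cmp2$raw$mortality$statistic, 0)
  expect_equal(cmp2$raw$mortality$p_value, 1)

  # Yates correction available for 2x2
  cmpy <- outcome_comparison(oc, lab, yates = TRUE)
  expect_lt(cmpy$raw$mortality$statistic, 20.0)

  # margins conserve n
  expect_equal(sum(cmp$raw$mortality$table), 80)
  expect_error(outcome_comparison(oc, rep(1L, 80)), "at least 2 clusters")
})

test_that("validity report bundles all pieces and purification repeats the
           outcome comparison", {
  co <- generate_cohort(bsi_phenotype_spec(150, seed = 6))
  tt <- apply_transforms(co$table)
  run <- consensus_run(gower_matrix(tt), 4, n_reps = 40, seed = 6)
  vr <- validity_report(run, tt, co$outcomes)
  expect_s3_class(vr, "validity_report")
  expect_true(all(vr$item_consensus$value >= 0 & vr$item_consensus$value <= 1))
  expect_equal(sum(vr$outcomes$raw$mortality$table), 150)
  kept <- !is.na(vr$purified_labels)
  expect_identical(vr$purified_labels[kept], vr$labels[kept])
  expect_equal(sum(!kept), sum(vr$outliers$outlier))
  expect_named(vr$outcomes, c("raw", "purified"))

  dir <- withr::local_tempdir()
  write_validity_report(vr, file.path(dir, "v.json"))
  obj <- jsonlite::read_json(file.path(dir, "v.json"))
  expect_named(obj$outcome_tests, c("raw", "purified"))
})
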