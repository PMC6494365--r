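test_that("continuous ranges use observed values only", {
  sch <- feature_schema(data.frame(name = c("age", "x"),
                                   kind = c("continuous", "continuous")))
  ft <- feature_table(data.frame(age = c(40, NA, 90), x = c(5, 5, 5)), sch)
  r <- feature_ranges(ft)
  expect_equal(r[["age"]], 50)
  expect_equal(r[["x"]], 0)   # constant feature degenerates to 0
})

test_that("pairwise dissimilarity matches hand-evaluated Gower", {
  sch <- feature_schema(data.frame(name = c("age", "shock"),
                                   kind = c("continuous", "binary")))
  ft <- feature_table(data.frame(age = c(40, 60), shock = c(1L, 0L)), sch)
  ranges <- feature_ranges(ft)
  a <- as.list(ft$data[1, ]); b <- as.list(ft$data[2, ])
  expect_equal(gower_pair(a, b, ft$schema, c(age = 50)), (20 / 50 + 1) / 2)
  expect_equal(gower_pair(a, a, ft$schema, c(age = 50)), 0)

  # identical and maximally different all-binary records
  schb <- feature_schema(data.frame(name = c("b1", "b2", "b3"),
                                    kind = rep("binary", 3)))
  fb <- feature_table(data.frame(b1 = c(1L, 0L), b2 = c(0L, 1L),
                                 b3 = c(1L, 0L)), schb)
  r0 <- feature_ranges(fb)
  expect_equal(gower_pair(as.list(fb$data[1, ]), as.list(fb$data[2, ]),
                          fb$schema, r0), 1)

  # symmetric binary: 0-0 agreement counts as similarity
  fs <- feature_table(data.frame(b1 = c(0L, 0L), b2 = c(1L, 0L),
                                 b3 = c(0L, 0L)), schb)
  expect_equal(gower_pair(as.list(fs$data[1, ]), as.list(fs$data[2, ]),
                          fs$schema, r0), 1 / 3)

  # no jointly observed feature is an undefined pair
  fna <- feature_table(data.frame(b1 = c(1L, NA), b2 = c(NA, 1L),
                                  b3 = c(1L, NA)), schb)
  expect_error(gower_pair(as.list(fna$data[1, ]), as.list(fna$data[2, ]),
                          fna$schema, r0), "undefined pair")
})

test_that("gower_matrix equals the scalar double-loop oracle on mixed data", {
  for (seed in 1:5) {
    ft <- random_mixed_table(40, seed = seed)
    D <- gower_matrix(ft)
    O <- gower_oracle(ft)
    expect_lt(max(abs(D - O)), 1e-12)
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(diag(D), setNames(rep(0, 40), ft$patient_ids))
    expect_identical(D, t(D))
  }
})

test_that("gower_matrix agrees with cluster::daisy on complete data", {
  skip_if_not_installed("cluster")
  ft <- random_mixed_table(30, miss = 0, seed = 7)
  D <- gower_matrix(ft)
  df <- ft$data
  for (nm in names(df))
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  binary_cols <- ft$schema$features$name[ft$schema$features$kind == "binary"]
  dz <- cluster::daisy(df, metric = "gower",
                       type = list(symm = binary_cols))
  expect_equal(as.numeric(as.dist(D)), as.numeric(dz), tolerance = 1e-10)
})

test_that("permuting patients permutes the matrix consistently", {
  ft <- random_mixed_table(25, seed = 3)
  D <- gower_matrix(ft)
  set.seed(1)
  perm <- sample(25)
  ftp <- feature_table(ft$data[perm, , drop = FALSE], ft$schema,
                       ft$patient_ids[perm])
  Dp <- gower_matrix(ftp)
  expect_equal(unname(Dp), unname(D[perm, perm]), tolerance = 1e-15)
})

test_that("an agreeing feature never increases a pair's dissimilarity", {
  for (seed in 1:10) {
    ft <- random_mixed_table(12, n_cont = 2, n_bin = 3, n_cat = 1,
                             miss = 0, seed = seed)
    D0 <- gower_matrix(ft)
    # add a binary feature on which every pair agrees
    df <- ft$data
    df$agree <- 1L
    feats <- rbind(ft$schema$features,
                   data.frame(name = "agree", kind = "binary",
                              log_transform = FALSE, weight = 1))
    D1 <- gower_matrix(feature_table(df, feature_schema(feats),
                                     ft$patient_ids))
    expect_true(all(D1 <= D0 + 1e-15))
  }
})

test_that("asymmetric binary mode drops 0-0 pairs from the average", {
  feats <- data.frame(name = c("b1", "b2"), kind = "binary")
  fa <- feature_table(data.frame(b1 = c(0L, 0L), b2 = c(1L, 0L)),
                      feature_schema(feats, binary_treatment = "asymmetric"))
  # b1 is a 0-0 pair: excluded; only b2 (mismatch) remains
  expect_equal(gower_matrix(fa)[1, 2], 1)
  fsym <- feature_table(data.frame(b1 = c(0L, 0L), b2 = c(1L, 0L)),
                        feature_schema(feats))
  expect_equal(gower_matrix(fsym)[1, 2], 0.5)
})

test_that("dissimilarity TSV export and import round-trip", {
  dir <- withr::local_tempdir()
  D <- gower_matrix(random_mixed_table(15, seed = 2))
  write_dissimilarity(D, file.path(dir, "d.tsv"))
  D2 <- read_dissimilarity(file.path(dir, "d.tsv"))
  expect_equal(D2, D, tolerance = 1e-12)
})
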