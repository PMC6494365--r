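test_that("CSV + JSON schema parse into a validated feature table", {
  dir <- withr::local_tempdir()
  writeLines(c("id,age,shock", "p1,40,1", "p2,60,0", "p3,90,1"),
             file.path(dir, "t.csv"))
  sch <- feature_schema(data.frame(name = c("age", "shock"),
                                   kind = c("continuous", "binary")))
  write_schema(sch, file.path(dir, "s.json"))

  ft <- read_feature_table(file.path(dir, "t.csv"), file.path(dir, "s.json"))
  expect_s3_class(ft, "feature_table")
  expect_length(ft$patient_ids, 3L)
  expect_equal(nrow(ft$schema$features), 2L)
  expect_equal(ft$data$age, c(40, 60, 90))

  # binary value outside {0,1} names the offending row and column
  writeLines(c("id,age,shock", "p1,40,1", "p2,60,2", "p3,90,1"),
             file.path(dir, "bad.csv"))
  expect_error(read_feature_table(file.path(dir, "bad.csv"),
                                  file.path(dir, "s.json")),
               "shock.*row.*2")

  # undeclared column is a schema error
  writeLines(c("id,age,shock,extra", "p1,40,1,x", "p2,60,0,y"),
             file.path(dir, "extra.csv"))
  expect_error(read_feature_table(file.path(dir, "extra.csv"),
                                  file.path(dir, "s.json")),
               "not declared")
})

test_that("empty cells become missing and write->read round-trips exactly", {
  dir <- withr::local_tempdir()
  writeLines(c("id,age,shock", "p1,,1", "p2,60,0", "p3,90,"),
             file.path(dir, "t.csv"))
  sch <- feature_schema(data.frame(name = c("age", "shock"),
                                   kind = c("continuous", "binary")))
  write_schema(sch, file.path(dir, "s.json"))
  ft <- read_feature_table(file.path(dir, "t.csv"), file.path(dir, "s.json"))
  expect_true(is.na(ft$data$age[1]))
  expect_true(is.na(ft$data$shock[3]))
  expect_equal(ft$data$age[2:3], c(60, 90))

  write_feature_table(ft, file.path(dir, "t2.csv"), file.path(dir, "s2.json"))
  ft2 <- read_feature_table(file.path(dir, "t2.csv"), file.path(dir, "s2.json"))
  expect_identical(ft2$data, ft$data)
  expect_identical(ft2$patient_ids, ft$patient_ids)
  expect_identical(ft2$schema$features, ft$schema$features)

  # categorical levels keep discovery order through the round trip
  tab <- demo_table()
  write_feature_table(tab, file.path(dir, "d.csv"), file.path(dir, "ds.json"))
  back <- read_feature_table(file.path(dir, "d.csv"), file.path(dir, "ds.json"))
  expect_identical(back$levels$source, c("lung", "urine"))
})

test_that("schema validation enforces its invariants", {
  expect_error(feature_schema(data.frame(name = c("a", "a"),
                                         kind = c("binary", "binary"))),
               "duplicate")
  expect_error(feature_schema(data.frame(name = "a", kind = "ordinal")),
               "unknown feature kind")
  expect_error(feature_schema(data.frame(name = "a", kind = "binary",
                                         log_transform = TRUE)),
               "only valid for continuous")
  expect_error(feature_schema(data.frame(name = "a", kind = "continuous",
                                         weight = -1)),
               "nonnegative")
})

test_that("log transform is ln(1+x), order preserving, and guarded", {
  sch <- feature_schema(data.frame(name = "los", kind = "continuous",
                                   log_transform = TRUE))
  x <- c(0, exp(1) - 1, 3.5, 12, 0.25)
  ft <- feature_table(data.frame(los = x), sch)
  tr <- apply_transforms(ft)
  expect_equal(tr$data$los[1], 0)           # ln(1+0) = 0
  expect_equal(tr$data$los[2], 1)           # ln(1+(e-1)) = 1
  expect_equal(tr$data$los, vapply(x, function(v) log(1 + v), 0))
  expect_true(all(diff(tr$data$los[order(x)]) > 0))  # monotone
  expect_true(tr$schema$transforms_applied)

  # re-application: error by default, no-op when strict = FALSE
  expect_error(apply_transforms(tr), "already applied")
  expect_identical(apply_transforms(tr, strict = FALSE)$data, tr$data)

  bad <- feature_table(data.frame(los = c(-1, 2)), sch)
  expect_error(apply_transforms(bad), "negative")

  # missingness untouched
  ft2 <- feature_table(data.frame(los = c(1, NA, 4)), sch)
  expect_equal(is.na(apply_transforms(ft2)$data$los), c(FALSE, TRUE, FALSE))
})

test_that("outcome tables validate and round-trip; misalignment is caught", {
  dir <- withr::local_tempdir()
  oc <- outcome_table(c("A", "B", "C"), c(0, 1, 0),
                      c("home", "other", "nursing_home"))
  write_outcomes(oc, file.path(dir, "o.csv"))
  oc2 <- read_outcomes(file.path(dir, "o.csv"))
  expect_equal(oc2$mortality, oc$mortality)
  expect_equal(oc2$disposition, oc$disposition)
  expect_error(outcome_table("A", 2, "home"), "0/1")
  expect_error(check_alignment <- phenoclust:::check_alignment(
    demo_table(), outcome_table(c("A", "X", "C"), c(0, 1, 0),
                                c("home", "home", "home"))),
    "do not match")
})

test_that("dummy coding expands categorical features into binaries", {
  dt <- dummy_code(demo_table())
  expect_setequal(dt$schema$features$name,
                  c("age", "shock", "source.lung", "source.urine"))
  expect_equal(dt$data$source.lung, c(1L, 0L, 1L))
  expect_true(all(dt$schema$features$kind[3:4] == "binary"))
})
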