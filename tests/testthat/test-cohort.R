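test_that("cohort construction validates schema and labels", {
  co <- tiny_cohort()
  expect_s3_class(co, "utm_cohort")
  expect_equal(cohort_metals(co), c("Cs", "Pb"))
  expect_error(
    new_cohort(tibble::tibble(participant_id = "a", group = "ASD", Cs = 1),
               metals = c("Cs", "Pb")),
    class = "uritox_schema_error")
  expect_error(
    new_cohort(tibble::tibble(participant_id = c("a", "a"),
                              group = c("ASD", "NT"), Cs = c(1, 2))),
    class = "uritox_validation_error")
  expect_error(
    new_cohort(tibble::tibble(participant_id = "a", group = "case", Cs = 1)),
    class = "uritox_validation_error")
})

test_that("CSV round trip is bit-exact and rejects bad input", {
  dat <- generate_cohort(reference_config(seed = 7))
  dir <- withr::local_tempdir()
  write_cohort_tables(dat$cohort, dat$severity, dir)
  back <- read_cohort_tables(file.path(dir, "asd_metals.csv"),
                             file.path(dir, "nt_metals.csv"),
                             file.path(dir, "severity.csv"),
                             file.path(dir, "detection_limits.csv"))
  expect_identical(panel_matrix(back$cohort), panel_matrix(dat$cohort))
  expect_identical(back$cohort$group, dat$cohort$group)
  expect_equal(tibble::as_tibble(back$severity), tibble::as_tibble(dat$severity))
  expect_equal(detection_limits(back$cohort)[cohort_metals(back$cohort)[1]],
               detection_limits(dat$cohort)[cohort_metals(dat$cohort)[1]])

  # empty file -> schema error
  empty <- file.path(dir, "empty.csv")
  writeLines("participant_id,group,Cs,Cs_censored", empty)
  expect_error(read_cohort_tables(empty, empty), class = "uritox_schema_error")

  # unparseable cell -> parse error naming row and column
  bad <- file.path(dir, "bad.csv")
  writeLines(c("participant_id,group,Cs,Cs_censored",
               "a1,ASD,oops,false"), bad)
  expect_error(read_cohort_tables(bad, bad), class = "uritox_parse_error",
               regexp = "row 1 col Cs")
})

test_that("single-participant file loads with all invariants intact", {
  dir <- withr::local_tempdir()
  asd <- file.path(dir, "a.csv"); nt <- file.path(dir, "n.csv")
  writeLines(c("participant_id,group,Cs,Cs_censored", "a1,ASD,2.5,false"), asd)
  writeLines(c("participant_id,group,Cs,Cs_censored", "n1,NT,1.5,false"), nt)
  out <- read_cohort_tables(asd, nt)
  expect_equal(nrow(out$cohort), 2)
  expect_true(all(panel_matrix(out$cohort) > 0))
})

test_that("below-detection substitution puts 2/3 LOD in censored cells only", {
  co <- tiny_cohort()
  co$Pb_censored[2] <- TRUE
  lod <- c(Cs = 0.1, Pb = 0.30)
  attr(co, "detection_limits") <- lod
  sub <- substitute_below_detection(co)
  expect_equal(sub$Pb[2], 0.20)                 # 2/3 x 0.30
  expect_equal(sub$Pb[-2], co$Pb[-2])           # untouched
  expect_equal(sub$Cs, co$Cs)
  # idempotent
  expect_identical(substitute_below_detection(sub), sub)
  # no censored cells -> unchanged
  expect_identical(substitute_below_detection(tiny_cohort()), tiny_cohort())
  # unknown LOD -> configuration error
  attr(co, "detection_limits") <- c(Cs = 0.1)
  expect_error(substitute_below_detection(co), class = "uritox_config_error")
})

test_that("metal selection subsets columns and drops antimony from the modelling panel", {
  dat <- generate_cohort(reference_config(seed = 3))
  full <- dat$cohort
  mod <- select_metals(full, utm_metals_modeling)
  expect_equal(cohort_metals(mod), setdiff(utm_metals_all, "Sb"))
  expect_equal(mod$participant_id, full$participant_id)
  expect_identical(select_metals(full, utm_metals_all), full)
  single <- select_metals(full, "Cs")
  expect_equal(cohort_metals(single), "Cs")
  expect_error(select_metals(full, "Fe"), class = "uritox_lookup_error")
})

test_that("standardization fits on fit_rows only and inverts exactly", {
  co <- tiny_cohort()
  std <- standardize_panel(co)
  z <- as.matrix(std$z[, std$metals])
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, var) - 1)), 1e-10)

  # n-1 denominator fixed by the two-point case {1, 3}: sd = sqrt(2),
  # so z = -+1/sqrt(2) (a population-sd convention would give -+1)
  two <- new_cohort(tibble::tibble(
    participant_id = c("x", "y"), group = c("ASD", "NT"),
    Cs = c(1, 3), Cs_censored = FALSE))
  expect_equal(as.matrix(standardize_panel(two)$z[, "Cs"])[, 1],
               c(-1, 1) / sqrt(2), ignore_attr = TRUE, tolerance = 1e-12)

  # rows outside fit_rows use the same affine map (no refit)
  std_fit <- standardize_panel(co, fit_rows = 1:4)
  z_all <- as.matrix(std_fit$z[, std_fit$metals])
  manual <- apply_standardization(std_fit, panel_matrix(co)[5:6, , drop = FALSE])
  expect_equal(z_all[5:6, ], manual, ignore_attr = TRUE)

  # inverse round trip
  back <- invert_standardization(std, z)
  expect_equal(back, panel_matrix(co), tolerance = 1e-12, ignore_attr = TRUE)

  # degenerate column named in the error
  cst <- new_cohort(tibble::tibble(
    participant_id = c("x", "y"), group = c("ASD", "NT"),
    Cs = c(2, 2), Cs_censored = FALSE))
  expect_error(standardize_panel(cst), class = "uritox_degenerate_error",
               regexp = "Cs")
})
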