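test_that("every table type round-trips through CSV exactly", {
  tables <- list(
    fertility_surface = tibble::tibble(
      country = c("KEN", "KEN", "NGA"), period = c(1990, 1990, 1995),
      age_group = c(20, 25, 20), education = c("primary", "primary", "none"),
      rate = c(0.2812345678901234, 1 / 3, 0.05)),
    cohort_cfr = tibble::tibble(
      country = "KEN", cohort = c(1955, 1960), education = "secondary",
      cfr = c(6.123456789012345, 5.4), status = c("observed", "completed")),
    slamys = tibble::tibble(region = "AFRICA", cohort = c(1955, 1960),
                            slamys = c(1.5, exp(1))),
    education_weights = generate_weights("KEN", c(1955, 1960),
                                         c(0.7, 0.2, 0.08, 0.02)),
    microdata = tibble::tibble(
      woman_id = 1:3, stratum_id = c("S1", "S1", "S2"),
      cluster_id = c("S1C1", "S1C2", "S2C1"),
      education = c("none", "higher", "primary"),
      stratum_mys = c(2.5, 2.5, 9.1),
      ideal_family_size = c(6, 2, 4),
      children_ever_born = c(7, NA, 3),
      age = c(44, 31, 47), urban = c(FALSE, TRUE, TRUE))
  )
  for (schema in names(tables)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_table(tables[[schema]], path, schema)
    back <- read_table(path, schema)
    canonical <- validate_table(tables[[schema]], schema)
    expect_equal(back, canonical, tolerance = 0, info = schema)
  }
})

test_that("an empty table with a correct header round-trips as empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- tibble::tibble(region = character(), cohort = numeric(),
                          slamys = numeric())
  write_table(empty, path, "slamys")
  back <- read_table(path, "slamys")
  expect_identical(nrow(back), 0L)
  expect_identical(names(back), c("region", "cohort", "slamys"))
})

test_that("schema errors name the missing or unexpected columns", {
  bad <- tibble::tibble(country = "KEN", period = 1990, age_group = 20,
                        education = "none")
  expect_error(validate_table(bad, "fertility_surface"),
               "missing: rate", class = "fertdiff_schema_error")
  bad2 <- tibble::tibble(region = "AFRICA", cohort = 1955, slamys = 2,
                         extra = 1)
  expect_error(validate_table(bad2, "slamys"), "unexpected: extra",
               class = "fertdiff_schema_error")
  expect_error(validate_table(bad2, "no_such_schema"), "unknown schema")
  expect_error(read_table("does/not/exist.csv", "slamys"),
               class = "fertdiff_io_error")
})

test_that("validation rejects every constructed invariant violation", {
  good_surface <- tibble::tibble(country = "KEN", period = 1990,
                                 age_group = 20, education = "none",
                                 rate = 0.2)
  corruptions <- list(
    list(schema = "fertility_surface", rule = "rate_range",
         tbl = dplyr::mutate(good_surface, rate = -0.1)),
    list(schema = "fertility_surface", rule = "rate_range",
         tbl = dplyr::mutate(good_surface, rate = 1.2)),
    list(schema = "fertility_surface", rule = "unique_key",
         tbl = dplyr::bind_rows(good_surface, good_surface)),
    list(schema = "fertility_surface", rule = "period_grid",
         tbl = dplyr::mutate(good_surface, period = 1992)),
    list(schema = "fertility_surface", rule = "age_group_grid",
         tbl = dplyr::mutate(good_surface, age_group = 22)),
    list(schema = "fertility_surface", rule = "education_levels",
         tbl = dplyr::mutate(good_surface, education = "tertiary")),
    list(schema = "cohort_cfr", rule = "cfr_range",
         tbl = tibble::tibble(country = "KEN", cohort = 1955,
                              education = "none", cfr = 16,
                              status = "observed")),
    list(schema = "cohort_cfr", rule = "status_levels",
         tbl = tibble::tibble(country = "KEN", cohort = 1955,
                              education = "none", cfr = 6, status = "guessed")),
    list(schema = "slamys", rule = "slamys_range",
         tbl = tibble::tibble(region = "AFRICA", cohort = 1955, slamys = -1)),
    list(schema = "education_weights", rule = "weight_sum",
         tbl = tibble::tibble(country = "KEN", cohort = 1955,
                              education = edu_levels,
                              weight = c(0.5, 0.3, 0.1, 0.2))),
    list(schema = "microdata", rule = "ideal_family_size_count",
         tbl = tibble::tibble(woman_id = 1, stratum_id = "S1",
                              cluster_id = "C1", education = "none",
                              stratum_mys = 2, ideal_family_size = 2.5,
                              children_ever_born = NA, age = 30,
                              urban = FALSE)),
    list(schema = "microdata", rule = "cluster_nesting",
         tbl = tibble::tibble(woman_id = 1:2, stratum_id = c("S1", "S2"),
                              cluster_id = "C1", education = "none",
                              stratum_mys = 2, ideal_family_size = 3,
                              children_ever_born = NA, age = 30,
                              urban = FALSE))
  )
  for (case in corruptions) {
    err <- tryCatch(validate_table(case$tbl, case$schema), error = identity)
    expect_s3_class(err, "fertdiff_validation_error")
    expect_identical(err$rule, case$rule,
                     info = paste(case$schema, case$rule))
  }
})

test_that("missing children_ever_born survives the round trip as NA, not zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  md <- generate_microdata(3, 20, seed = 11)
  write_table(md, path, "microdata")
  back <- read_table(path, "microdata")
  expect_identical(is.na(back$children_ever_born), is.na(md$children_ever_born))
  expect_true(all(back$children_ever_born[!is.na(back$children_ever_born)] >= 0))
})
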