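test_that("time-invariant rates give a zero time index and exact reconstruction", {
  r1 <- rank1_surface(kt_slope = 0)
  fit <- fit_lee_carter(r1$surface, r1$country, "none", r1$periods)
  expect_equal(unname(fit$kt), rep(0, length(r1$periods)))
  expect_equal(unname(fit$drift), 0)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)
  # zero drift: extrapolated rates equal the last fitted period's rates
  ext <- extrapolate_rates(fit, 1)
  last <- r1$surface[r1$surface$period == max(r1$periods) &
                       r1$surface$education == "none", ]
  expect_equal(sort(ext$rate), sort(last$rate), tolerance = 1e-12)
})

test_that("rank-1 log-bilinear data is recovered to 1e-8 with the usual constraints", {
  r1 <- rank1_surface()
  fit <- fit_lee_carter(r1$surface, r1$country, "primary", r1$periods)
  expect_equal(sum(fit$bx), 1, tolerance = 1e-9)
  expect_equal(sum(fit$kt), 0, tolerance = 1e-9)
  expect_equal(unname(fit$ax), r1$ax, tolerance = 1e-8)
  expect_equal(unname(fit$bx), r1$bx, tolerance = 1e-8)
  expect_equal(unname(fit$kt), r1$kt, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-8)
  # declining rates give nonpositive drift (sign convention)
  expect_lte(unname(fit$drift), 0)
})

test_that("normalisation constraints hold on noisy matrices too", {
  set.seed(31)
  r1 <- rank1_surface()
  noisy <- dplyr::mutate(r1$surface,
                         rate = rate * exp(rnorm(dplyr::n(), 0, 0.05)))
  for (e in c("none", "higher")) {
    fit <- fit_lee_carter(noisy, r1$country, e, r1$periods)
    expect_equal(sum(fit$bx), 1, tolerance = 1e-9)
    expect_equal(sum(fit$kt), 0, tolerance = 1e-9)
    expect_gt(fit$residual_sd, 0)
  }
})

test_that("linear-kt extrapolation continues the line exactly", {
  r1 <- rank1_surface()
  n_fit <- length(r1$periods) - 2L
  fit_periods <- r1$periods[seq_len(n_fit)]
  fit <- fit_lee_carter(r1$surface, r1$country, "none", fit_periods)
  slope <- r1$kt[2] - r1$kt[1]
  expect_equal(unname(fit$drift), slope, tolerance = 1e-10)
  ext <- extrapolate_rates(fit, 2)
  truth <- r1$surface[r1$surface$education == "none" &
                        r1$surface$period > max(fit_periods), ]
  joined <- dplyr::inner_join(ext, truth, by = c("age_group", "period"))
  expect_identical(nrow(joined), 12L)
  expect_lt(max(abs(joined$rate.x - joined$rate.y)), 1e-8)
  # horizon 2 advances the index by exactly 2 * drift
  one <- extrapolate_rates(fit, 1)
  implied_kt <- function(frag) {
    (log(frag$rate[frag$age_group == 15]) - fit$ax[["15"]]) / fit$bx[["15"]]
  }
  k1 <- implied_kt(one[one$period == max(fit_periods) + 5, ])
  k2 <- implied_kt(ext[ext$period == max(fit_periods) + 10, ])
  expect_equal(k2 - k1, unname(fit$drift), tolerance = 1e-8)
})

test_that("fit preconditions are enforced", {
  r1 <- rank1_surface()
  expect_error(fit_lee_carter(r1$surface, r1$country, "none",
                              r1$periods[1:2]),
               class = "fertdiff_leecarter_error")
  expect_error(fit_lee_carter(r1$surface, r1$country, "none",
                              c(r1$periods, 2030)),
               class = "fertdiff_leecarter_error")
  withzero <- dplyr::mutate(r1$surface,
                            rate = replace(rate, 1, 0))
  expect_warning(fit_lee_carter(withzero, r1$country, withzero$education[1],
                                r1$periods),
                 "flooring")
})

test_that("truncated cohorts are completed back to the untruncated CFR", {
  r1 <- rank1_surface()   # periods 1970-2025 cover cohorts 1980/1985 fully
  truth_1980 <- period_to_cohort_cfr(r1$surface, r1$country, "none", 1980)
  truth_1985 <- period_to_cohort_cfr(r1$surface, r1$country, "none", 1985)
  trunc <- r1$surface[r1$surface$period <= 2015, ]
  done <- complete_truncated_cohorts(trunc, c(1980, 1985))
  expect_true(all(done$status == "completed"))
  got <- done[done$education == "none", ]
  expect_equal(got$cfr[got$cohort == 1980], truth_1980, tolerance = 1e-6)
  expect_equal(got$cfr[got$cohort == 1985], truth_1985, tolerance = 1e-6)
})

test_that("constant-rate truncated surfaces complete to exactly 5 * 6 * rate", {
  cells <- dplyr::bind_rows(lapply(seq(1970, 2025, by = 5), function(p) {
    tibble::tibble(country = "KEN", period = p, age_group = seq(15, 40, 5),
                   education = "none", rate = 0.2)
  }))
  trunc <- cells[cells$period <= 2015, ]
  done <- complete_truncated_cohorts(trunc, c(1980, 1985))
  expect_equal(done$cfr, rep(5 * 6 * 0.2, 2), tolerance = 1e-10)
})

test_that("a surface already complete for the cohort completes as a plain sum", {
  r1 <- rank1_surface()
  done <- complete_truncated_cohorts(r1$surface, 1975)
  expect_true(all(done$status == "completed"))
  expect_equal(done$cfr[done$education == "none"],
               period_to_cohort_cfr(r1$surface, r1$country, "none", 1975),
               tolerance = 1e-12)
})

test_that("a cohort with zero observed cells cannot be completed", {
  r1 <- rank1_surface()
  trunc <- r1$surface[r1$surface$period <= 2015, ]
  expect_error(complete_truncated_cohorts(trunc, 2005),
               class = "fertdiff_leecarter_error")
})
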