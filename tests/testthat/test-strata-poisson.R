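test_that("the null model is recovered: intercept only, flat curves", {
  md <- generate_microdata(20, 1000, betas = null_betas(log(4)),
                           stratum_sd = 0, seed = 21)
  fit <- fit_ifs_model(md, "ideal_family_size", "fixed")
  expect_lt(abs(fit$beta0 - log(4)), 3 * fit$se$beta0)
  expect_lt(abs(fit$beta2), 3 * fit$se$beta2)
  for (e in edu_levels[-1]) {
    expect_lt(abs(fit$beta1[[e]]), 3 * fit$se$beta1[[e]])
    expect_lt(abs(fit$beta3[[e]]), 3 * fit$se$beta3[[e]])
  }
  grid <- seq(ceiling(fit$mys_range[1]), floor(fit$mys_range[2]), by = 2)
  curve <- predict_curves(fit, grid, "none")
  expect_equal(curve$predicted,
               rep(exp(fit$beta0), nrow(curve)) * exp(fit$beta2 * curve$mys),
               tolerance = 1e-12)
})

test_that("known generative coefficients are recovered within 3 SE", {
  betas <- recovery_betas()
  md <- generate_microdata(50, 1000, betas = betas, stratum_sd = 0.1,
                           seed = 33)
  fit <- fit_ifs_model(md, "ideal_family_size", "fixed")
  f <- flatten_fit(fit)
  truth <- flatten_betas(betas)
  expect_true(all(abs(f$est - truth) <= 3 * f$se))
  expect_true(fit$converged)
})

test_that("duplicating every row keeps estimates and shrinks GLM SEs by sqrt(2)", {
  md <- generate_microdata(10, 400, betas = recovery_betas(),
                           stratum_sd = 0.1, seed = 8)
  fit1 <- fit_ifs_model(md, "ideal_family_size", "fixed")
  md2 <- dplyr::bind_rows(md, dplyr::mutate(md, woman_id = woman_id + nrow(md)))
  fit2 <- fit_ifs_model(md2, "ideal_family_size", "fixed")
  expect_equal(fit2$beta1, fit1$beta1, tolerance = 1e-6)
  expect_equal(fit2$beta3, fit1$beta3, tolerance = 1e-6)
  expect_equal(fit2$beta0, fit1$beta0, tolerance = 1e-6)
  expect_equal(fit2$beta2, fit1$beta2, tolerance = 1e-6)
  # stage-1 likelihood doubles, so within-stratum contrast SEs halve by sqrt 2
  expect_equal(unname(fit2$se$beta1[-1] / fit1$se$beta1[-1]),
               rep(1 / sqrt(2), 3), tolerance = 1e-3)
  expect_equal(unname(fit2$se$beta3[-1] / fit1$se$beta3[-1]),
               rep(1 / sqrt(2), 3), tolerance = 1e-3)
})

test_that("children-ever-born fits restrict to women aged 40-49", {
  md <- generate_microdata(10, 500, betas = recovery_betas(),
                           stratum_sd = 0, seed = 12)
  fit <- fit_ifs_model(md, "children_ever_born", "fixed")
  expect_identical(fit$n_obs, sum(md$age >= 40 & md$age <= 49 &
                                    !is.na(md$children_ever_born)))
  expect_lt(abs(fit$beta0 - log(7)), 4 * fit$se$beta0)
})

test_that("fixed and random modes agree when the stratum variance is zero", {
  md <- generate_microdata(30, 300, betas = recovery_betas(),
                           stratum_sd = 0, seed = 15)
  ffix <- fit_ifs_model(md, "ideal_family_size", "fixed")
  fran <- fit_ifs_model(md, "ideal_family_size", "random")
  for (e in edu_levels[-1]) {
    expect_lt(abs(ffix$beta1[[e]] - fran$beta1[[e]]), 3 * ffix$se$beta1[[e]])
    expect_lt(abs(ffix$beta3[[e]] - fran$beta3[[e]]), 3 * ffix$se$beta3[[e]])
  }
  expect_lt(abs(ffix$beta2 - fran$beta2), 3 * ffix$se$beta2)
})

test_that("prediction curves are exp-affine in MYS and match hand arithmetic", {
  md <- generate_microdata(25, 400, betas = recovery_betas(),
                           stratum_sd = 0.05, seed = 19)
  fit <- fit_ifs_model(md, "ideal_family_size", "fixed")
  grid <- seq(ceiling(fit$mys_range[1]), floor(fit$mys_range[2]), by = 0.5)
  for (e in edu_levels) {
    curve <- predict_curves(fit, grid, e)
    # log prediction affine in MYS
    lp <- log(curve$predicted)
    expect_equal(diff(lp), rep(diff(lp)[1], length(lp) - 1),
                 tolerance = 1e-9)
    # negative beta2 + beta3 slopes make every curve strictly decreasing
    expect_lt(fit$beta2 + fit$beta3[[e]], 0)
    expect_true(all(diff(curve$predicted) < 0))
  }
  hand <- exp(fit$beta0 + fit$beta1[["secondary"]] +
                (fit$beta2 + fit$beta3[["secondary"]]) * 6.5)
  expect_equal(predict_curves(fit, 6.5, "secondary")$predicted, hand,
               tolerance = 1e-12)
  expect_warning(predict_curves(fit, 40, "none"), "extrapolat")
})

test_that("degenerate outcomes and designs are diagnosed", {
  md <- generate_microdata(5, 100, betas = null_betas(log(3)),
                           stratum_sd = 0, seed = 3)
  md$ideal_family_size[md$education == "higher"] <- 0
  expect_error(fit_ifs_model(md, "ideal_family_size", "fixed"),
               "separation", class = "fertdiff_model_error")
  one_stratum <- generate_microdata(2, 50, seed = 2)
  one_stratum$stratum_id <- "S0001"
  one_stratum$cluster_id <- sub("^S[0-9]+", "S0001", one_stratum$cluster_id)
  expect_error(fit_ifs_model(one_stratum, "ideal_family_size", "fixed"),
               "2 strata", class = "fertdiff_model_error")
})

test_that("the urban flag adds a coefficient without disturbing recovery", {
  betas <- recovery_betas()
  betas$beta_urban <- -0.1
  md <- generate_microdata(30, 500, betas = betas, stratum_sd = 0.05,
                           seed = 27)
  fit <- fit_ifs_model(md, "ideal_family_size", "fixed", include_urban = TRUE)
  expect_lt(abs(fit$beta_urban - (-0.1)), 3 * fit$se$beta_urban)
  f <- flatten_fit(fit)
  truth <- flatten_betas(betas)
  expect_true(all(abs(f$est - truth) <= 4 * f$se))
})
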