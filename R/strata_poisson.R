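# Strata-level Poisson models of fertility ideals and behaviour.
#
# Model: log E[count_i] = beta0 + beta1[educ_i] + beta2 * MYS_s +
#        beta3[educ_i] * MYS_s (+ beta_urban * urban_i) + U_s,
# where MYS_s is the mean years of schooling of women in stratum s and the
# reference education category is "none".
#
# mode = "fixed" absorbs U_s as per-stratum constants.  Because MYS_s is
# constant within a stratum, beta0 and beta2 are collinear with the stratum
# dummies; they are recovered by the standard two-stage route: stage 1 fits
# the Poisson GLM with stratum dummies plus the within-stratum education and
# education x MYS contrasts, stage 2 regresses the fitted stratum effects
# (which equal beta0 + beta2 * MYS_s + U_s) on MYS_s by OLS.  The stage-2
# standard errors absorb both the U_s variance and the stage-1 noise.
#
# mode = "random" treats U_s as zero-mean normal and fits the full model with
# lme4::glmer.

#' Fit the strata-level Poisson model of ideal or achieved family size
#'
#' @param data A `microdata` tibble.
#' @param outcome `"ideal_family_size"` or `"children_ever_born"`; the latter
#'   restricts to women aged 40-49 with a nonmissing count (their children
#'   ever born approximates completed cohort fertility).
#' @param mode `"fixed"` (stratum dummies; the default) or `"random"`
#'   (normal stratum effects via [lme4::glmer()]).
#' @param include_urban Add an urban/rural indicator to the linear predictor.
#' @param nagq Integration points for `mode = "random"`; 0 gives the fast
#'   penalised-likelihood approximation.
#' @return A `poisson_strata_fit` with coefficient blocks `beta0`, `beta1`
#'   (named, reference `none` fixed at 0), `beta2`, `beta3` (named, reference
#'   0), optional `beta_urban`, matching standard errors, `stratum_effects`,
#'   `n_obs`, `loglik`, `mode` and the observed MYS range.
#' @export
fit_ifs_model <- function(data,
                          outcome = c("ideal_family_size", "children_ever_born"),
                          mode = c("fixed", "random"),
                          include_urban = FALSE, nagq = 0L) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  data <- validate_table(data, "microdata")
  if (outcome == "children_ever_born") {
    data <- data[!is.na(data$children_ever_born) &
                   data$age >= 40 & data$age <= 49, ]
  }
  y <- data[[outcome]]
  if (anyNA(y)) {
    abort("outcome holds missing values after filtering",
          class = "fertdiff_model_error")
  }
  if (n_distinct(data$stratum_id) < 2L) {
    abort("need at least 2 strata", class = "fertdiff_model_error")
  }
  educ <- factor(data$education, levels = EDU_LEVELS)
  zero_cat <- tapply(y, educ, function(v) length(v) > 0 && all(v == 0))
  if (any(zero_cat, na.rm = TRUE)) {
    abort(paste0("all-zero outcome in education category '",
                 names(zero_cat)[which(zero_cat)[1]],
                 "': separation on the log scale"),
          class = "fertdiff_model_error")
  }
  single_edu <- tapply(as.character(educ), data$stratum_id, n_distinct)
  if (any(single_edu == 1L)) {
    inform(paste0(sum(single_edu == 1L), " stratum/strata hold a single ",
                  "education category and contribute nothing to the ",
                  "within-stratum contrasts"))
  }
  mys <- data$stratum_mys
  contrast_levels <- EDU_LEVELS[-1]

  if (mode == "fixed") {
    stratum <- factor(data$stratum_id)
    X_str <- stats::model.matrix(~ 0 + stratum)
    X_edu <- stats::model.matrix(~ educ)[, -1, drop = FALSE]
    X_int <- X_edu * mys
    colnames(X_edu) <- paste0("b1_", contrast_levels)
    colnames(X_int) <- paste0("b3_", contrast_levels)
    X <- cbind(X_str, X_edu, X_int)
    if (include_urban) X <- cbind(X, urban = as.numeric(data$urban))
    fit <- stats::glm.fit(X, y, family = poisson())
    cf <- coef(fit)
    if (anyNA(cf)) {
      abort(paste0("inestimable contrast(s) in fixed-effects fit: ",
                   paste(names(cf)[is.na(cf)], collapse = ", ")),
            class = "fertdiff_model_error")
    }
    # observed-information covariance: (X' W X)^-1 with W = diag(mu)
    mu <- fit$fitted.values
    se <- sqrt(diag(chol2inv(chol(crossprod(X * sqrt(mu))))))
    names(se) <- names(cf)
    loglik <- sum(stats::dpois(y, mu, log = TRUE))

    # stage 2: stratum effects alpha_s = beta0 + beta2 * MYS_s + U_s
    alpha <- cf[paste0("stratum", levels(stratum))]
    mys_s <- tapply(mys, stratum, function(v) v[1])[levels(stratum)]
    stage2 <- lm(alpha ~ mys_s)
    s2 <- summary(stage2)$coefficients
    beta0 <- unname(s2[1, 1]); se0 <- unname(s2[1, 2])
    beta2 <- unname(s2[2, 1]); se2 <- unname(s2[2, 2])
    stratum_effects <- setNames(stats::residuals(stage2), levels(stratum))

    beta1 <- c(none = 0, setNames(unname(cf[paste0("b1_", contrast_levels)]),
                                  contrast_levels))
    beta3 <- c(none = 0, setNames(unname(cf[paste0("b3_", contrast_levels)]),
                                  contrast_levels))
    se1 <- c(none = 0, setNames(unname(se[paste0("b1_", contrast_levels)]),
                                contrast_levels))
    se3 <- c(none = 0, setNames(unname(se[paste0("b3_", contrast_levels)]),
                                contrast_levels))
    res <- list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                se = list(beta0 = se0, beta1 = se1, beta2 = se2, beta3 = se3),
                stratum_effects = stratum_effects,
                n_obs = length(y), loglik = loglik,
                converged = fit$converged)
    if (include_urban) {
      res$beta_urban <- unname(cf["urban"])
      res$se$beta_urban <- unname(se["urban"])
    }
  } else {
    df <- tibble(y = y, educ = educ, mys = mys,
                 stratum = factor(data$stratum_id),
                 urban = as.numeric(data$urban))
    form <- if (include_urban) {
      y ~ educ * mys + urban + (1 | stratum)
    } else {
      y ~ educ * mys + (1 | stratum)
    }
    fit <- lme4::glmer(form, data = df, family = poisson(), nAGQ = nagq)
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    names(se) <- names(cf)
    pick <- function(v, nm) if (nm %in% names(v)) unname(v[nm]) else NA_real_
    beta1 <- c(none = 0,
               setNames(vapply(contrast_levels,
                               function(l) pick(cf, paste0("educ", l)),
                               numeric(1)), contrast_levels))
    beta3 <- c(none = 0,
               setNames(vapply(contrast_levels,
                               function(l) pick(cf, paste0("educ", l, ":mys")),
                               numeric(1)), contrast_levels))
    se1 <- c(none = 0,
             setNames(vapply(contrast_levels,
                             function(l) pick(se, paste0("educ", l)),
                             numeric(1)), contrast_levels))
    se3 <- c(none = 0,
             setNames(vapply(contrast_levels,
                             function(l) pick(se, paste0("educ", l, ":mys")),
                             numeric(1)), contrast_levels))
    ranefs <- lme4::ranef(fit)$stratum
    res <- list(beta0 = unname(cf["(Intercept)"]), beta1 = beta1,
                beta2 = unname(cf["mys"]), beta3 = beta3,
                se = list(beta0 = unname(se["(Intercept)"]), beta1 = se1,
                          beta2 = unname(se["mys"]), beta3 = se3),
                stratum_effects = setNames(ranefs[[1]], rownames(ranefs)),
                n_obs = length(y), loglik = as.numeric(logLik(fit)),
                converged = length(fit@optinfo$conv$lme4) == 0L)
    if (include_urban) {
      res$beta_urban <- pick(cf, "urban")
      res$se$beta_urban <- pick(se, "urban")
    }
  }
  res$mode <- mode
  res$outcome <- outcome
  res$mys_range <- range(mys)
  structure(res, class = "poisson_strata_fit")
}

#' @export
print.poisson_strata_fit <- function(x, ...) {
  cat("Strata-level Poisson fit (", x$mode, " effects), outcome = ",
      x$outcome, ", n = ", x$n_obs, "\n", sep = "")
  cat("  beta0 (intercept):", format(x$beta0, digits = 4),
      " beta2 (MYS slope):", format(x$beta2, digits = 4), "\n")
  cat("  beta1 contrasts:",
      paste(names(x$beta1)[-1], format(x$beta1[-1], digits = 3),
            collapse = ", "), "\n")
  cat("  beta3 interactions:",
      paste(names(x$beta3)[-1], format(x$beta3[-1], digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predicted mean counts over a grid of stratum schooling
#'
#' `exp(beta0 + beta1[educ] + beta2 * MYS + beta3[educ] * MYS)` at each grid
#' point, with the stratum effect at its reference level (0 for random
#' effects; the stage-2 conditional mean for fixed effects).  Grid values far
#' outside the observed MYS range trigger an extrapolation warning.
#'
#' @param fit A [fit_ifs_model()] result.
#' @param mys_grid Schooling values (years).
#' @param education Education category.
#' @return Tibble with columns `education`, `mys`, `predicted`.
#' @export
predict_curves <- function(fit, mys_grid, education) {
  stopifnot(inherits(fit, "poisson_strata_fit"),
            education %in% EDU_LEVELS)
  lo <- fit$mys_range[1]; hi <- fit$mys_range[2]
  pad <- 0.1 * (hi - lo)
  if (any(mys_grid < lo - pad | mys_grid > hi + pad)) {
    warn("grid extends beyond the observed MYS range: extrapolated predictions")
  }
  lp <- fit$beta0 + fit$beta1[[education]] +
    (fit$beta2 + fit$beta3[[education]]) * mys_grid
  tibble(education = education, mys = as.numeric(mys_grid),
         predicted = exp(lp))
}
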