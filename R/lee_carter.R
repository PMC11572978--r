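# Lee-Carter completion of truncated cohorts.
#
# Classic log-bilinear specification: log m(x, t) = a_x + b_x * k_t, fitted by
# the leading singular pair of the row-centred log-rate matrix with the usual
# identification (sum b_x = 1, sum k_t = 0), and k_t continued by the central
# path of a random walk with drift.  Fitting is per (country, education); the
# six reproductive age groups 15-19 ... 40-44 form the rows.

#' Fit a Lee-Carter model to an education-specific age-period rate block
#'
#' @param surface A `fertility_surface` tibble.
#' @param country,education Block selectors.
#' @param periods Fitted periods (>= 3); every (age group, period) cell must
#'   be present with a nonnegative rate.  Zero rates are floored at
#'   `zero_floor` before taking logs, with a warning.
#' @param zero_floor Floor applied to zero rates (default 1e-6).
#' @return A `lee_carter_fit` with fields `ax` (per-age log-rate baseline),
#'   `bx` (per-age sensitivity, sum 1), `kt` (per-period index, sum 0),
#'   `drift` (per-period-step change in kt) and `residual_sd`.
#' @export
fit_lee_carter <- function(surface, country, education, periods,
                           zero_floor = 1e-6) {
  periods <- sort(as.numeric(periods))
  if (length(periods) < 3L) {
    abort("Lee-Carter fit needs at least 3 periods (drift is degenerate below that)",
          class = "fertdiff_leecarter_error")
  }
  sub <- surface[surface$country == country & surface$education == education &
                   surface$period %in% periods &
                   surface$age_group %in% REPRO_AGES, ]
  grid <- tidyr::expand_grid(age_group = as.numeric(REPRO_AGES),
                             period = periods)
  full <- left_join(grid, sub, by = c("age_group", "period"))
  if (anyNA(full$rate)) {
    miss <- full[is.na(full$rate), c("age_group", "period")]
    abort(paste0("incomplete age x period block for ", country, "/", education,
                 ": missing ", nrow(miss), " cell(s), first (",
                 miss$age_group[1], ", ", miss$period[1], ")"),
          class = "fertdiff_leecarter_error")
  }
  if (any(full$rate < 0)) {
    abort("negative rates in Lee-Carter block", class = "fertdiff_leecarter_error")
  }
  if (any(full$rate == 0)) {
    warn(paste0("flooring ", sum(full$rate == 0), " zero rate(s) at ",
                format(zero_floor)))
    full$rate[full$rate == 0] <- zero_floor
  }

  M <- matrix(log(full$rate), nrow = length(REPRO_AGES), ncol = length(periods),
              byrow = TRUE,
              dimnames = list(REPRO_AGES, periods))
  ax <- rowMeans(M)
  C <- M - ax
  sv <- svd(C)
  if (sv$d[1] < 1e-12) {
    # rates constant over periods: no time signal
    bx <- rep(1 / length(REPRO_AGES), length(REPRO_AGES))
    kt <- rep(0, length(periods))
  } else {
    u <- sv$u[, 1]
    s <- sum(u)
    if (abs(s) < 1e-10) {
      abort("leading age loading sums to zero; sum-to-one normalisation undefined",
            class = "fertdiff_leecarter_error")
    }
    bx <- u / s
    kt <- sv$d[1] * sv$v[, 1] * s
  }
  fitted <- ax + outer(bx, kt)
  residual_sd <- sd(as.vector(M - fitted))
  structure(list(
    country = country, education = education,
    ages = as.numeric(REPRO_AGES), periods = periods,
    ax = setNames(ax, REPRO_AGES), bx = setNames(bx, REPRO_AGES),
    kt = setNames(kt, periods),
    drift = (kt[length(kt)] - kt[1]) / (length(kt) - 1),
    residual_sd = residual_sd
  ), class = "lee_carter_fit")
}

#' @export
print.lee_carter_fit <- function(x, ...) {
  cat("Lee-Carter fit:", x$country, "/", x$education, "\n")
  cat("  periods:", min(x$periods), "-", max(x$periods),
      " drift:", format(unname(x$drift), digits = 4),
      " residual sd:", format(x$residual_sd, digits = 4), "\n")
  invisible(x)
}

#' Extrapolate a Lee-Carter fit beyond its last fitted period
#'
#' The period index is continued along the central (deterministic) path of a
#' random walk with drift, `kt[T + h] = kt[T] + h * drift`, and rates
#' recovered as `exp(ax + bx * kt)`.
#'
#' @param fit A [fit_lee_carter()] result.
#' @param horizon Number of 5-year steps to extrapolate (>= 1).
#' @return A `fertility_surface` fragment covering the extrapolated periods.
#' @export
extrapolate_rates <- function(fit, horizon) {
  stopifnot(inherits(fit, "lee_carter_fit"), horizon >= 1)
  last_period <- max(fit$periods)
  kt_last <- unname(fit$kt[length(fit$kt)])
  out <- lapply(seq_len(horizon), function(h) {
    kt_h <- kt_last + h * unname(fit$drift)
    tibble(country = fit$country,
           period = last_period + 5 * h,
           age_group = fit$ages,
           education = fit$education,
           rate = exp(unname(fit$ax) + unname(fit$bx) * kt_h))
  })
  bind_rows(out)
}

#' Complete truncated cohorts by Lee-Carter extrapolation
#'
#' For each (country, education) block the model is fitted on all fully
#' observed periods up to `last_observed_period`, missing later periods are
#' extrapolated, and each requested cohort's diagonal is assembled from the
#' mix of observed and extrapolated cells and summed as in
#' [period_to_cohort_cfr()].  Rows are flagged `status = "completed"`.
#'
#' @param surface A `fertility_surface` tibble.
#' @param cohorts Cohorts to complete (each must have at least one observed
#'   diagonal cell; a cohort with none would be pure projection).
#' @param last_observed_period Last period treated as observed; defaults to
#'   the last period in the surface.
#' @return A `cohort_cfr` tibble with `status = "completed"`.
#' @export
complete_truncated_cohorts <- function(surface, cohorts,
                                       last_observed_period = max(surface$period)) {
  surface <- validate_table(surface, "fertility_surface")
  obs <- surface[surface$period <= last_observed_period, ]
  combos <- distinct(obs, .data$country, .data$education)
  res <- vector("list", 0L)
  for (i in seq_len(nrow(combos))) {
    ctry <- combos$country[i]
    edu <- combos$education[i]
    block <- obs[obs$country == ctry & obs$education == edu &
                   obs$age_group %in% REPRO_AGES, ]
    # periods with a full age block are usable for fitting
    per_tab <- block |>
      summarise(n_ages = n_distinct(.data$age_group), .by = "period")
    fit_periods <- sort(per_tab$period[per_tab$n_ages == length(REPRO_AGES)])
    fit <- NULL
    for (cohort in sort(as.numeric(cohorts))) {
      cells <- cohort_cells(cohort)
      have <- inner_join(cells, block, by = c("age_group", "period"))
      if (nrow(have) == 0L) {
        abort(paste0("cohort ", cohort, " has no observed cells for ", ctry,
                     "/", edu, ": completion would be pure projection"),
              class = "fertdiff_leecarter_error")
      }
      need <- anti_join(cells, have, by = c("age_group", "period"))
      if (nrow(need)) {
        if (any(need$period <= max(fit_periods))) {
          abort(paste0("cohort ", cohort, " is missing cells inside the ",
                       "observed window for ", ctry, "/", edu,
                       "; only end-truncation can be completed"),
                class = "fertdiff_leecarter_error")
        }
        if (is.null(fit)) {
          fit <- fit_lee_carter(obs, ctry, edu, fit_periods)
        }
        horizon <- (max(need$period) - max(fit_periods)) / 5
        ext <- extrapolate_rates(fit, horizon)
        filled <- inner_join(need, ext, by = c("age_group", "period"))
        mix <- bind_rows(have[, c("age_group", "period", "rate")],
                         filled[, c("age_group", "period", "rate")])
      } else {
        mix <- have[, c("age_group", "period", "rate")]
      }
      if (nrow(mix) != 6L) {
        abort(paste0("could not assemble all six diagonal cells for ", ctry,
                     "/", edu, "/cohort ", cohort),
              class = "fertdiff_leecarter_error")
      }
      res[[length(res) + 1L]] <- tibble(country = ctry, cohort = cohort,
                                        education = edu,
                                        cfr = 5 * sum(mix$rate),
                                        status = "completed")
    }
  }
  validate_table(bind_rows(res), "cohort_cfr")
}
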