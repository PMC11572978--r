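# Education-weighted aggregation and the out-of-sample validation protocol.

#' Aggregate education-specific CFRs with cohort-specific education weights
#'
#' The overall cohort fertility rate is the convex combination
#' `sum_e weight_e * cfr_e`; it always lies between the smallest and largest
#' education-specific input.
#'
#' @param cfr_rows Tibble with columns `education`, `cfr` covering all four
#'   education groups for one (country, cohort).
#' @param weights Tibble with columns `education`, `weight` (or a named
#'   numeric vector) summing to 1 within 1e-6.
#' @return Overall children per woman (scalar).
#' @export
#' @examples
#' aggregate_cfr(tibble::tibble(education = c("none", "primary", "secondary",
#'                                            "higher"), cfr = c(6, 5, 4, 3)),
#'               c(none = .25, primary = .25, secondary = .25, higher = .25))
aggregate_cfr <- function(cfr_rows, weights) {
  if (!is.numeric(weights)) {
    weights <- setNames(weights$weight, weights$education)
  }
  miss <- setdiff(EDU_LEVELS, cfr_rows$education)
  if (length(miss)) {
    abort(paste0("missing education group(s) in cfr_rows: ",
                 paste(miss, collapse = ", ")),
          class = "fertdiff_domain_error")
  }
  miss_w <- setdiff(EDU_LEVELS, names(weights))
  if (length(miss_w)) {
    abort(paste0("missing education group(s) in weights: ",
                 paste(miss_w, collapse = ", ")),
          class = "fertdiff_domain_error")
  }
  w <- weights[EDU_LEVELS]
  if (abs(sum(w) - 1) > 1e-6) {
    abort(paste0("weights sum to ", format(sum(w), digits = 10), ", not 1"),
          class = "fertdiff_domain_error")
  }
  cfr <- setNames(cfr_rows$cfr, cfr_rows$education)[EDU_LEVELS]
  sum(w * cfr)
}

#' Out-of-sample validation of the diffusion projection
#'
#' Replicates the hold-out protocol: diffusion rates are estimated from the
#' window `[first cohort, truncation_cohort]` only (the window's own endpoint
#' cohorts enter the estimator), the series is projected from the truncation
#' cohort to `horizon_cohort`, and projections are scored against the
#' held-back observed rows per education group and for the education-weighted
#' aggregate (using the observed weights of the held-out cohorts, so
#' composition-forecast error never contaminates the fertility-forecast
#' error).
#'
#' @param cfr_table `cohort_cfr` tibble covering the estimation window and
#'   the held-out cohorts for one country.
#' @param slamys `slamys` tibble for the driving region.
#' @param weights `education_weights` tibble covering the held-out cohorts.
#' @param truncation_cohort Last cohort used for estimation.
#' @param horizon_cohort Last projected cohort (> `truncation_cohort`).
#' @param country,region Passed to [estimate_all_rates()] /
#'   [project_series()]; default to the single country/region present.
#' @return A `validation_report`: `$details` per (education, cohort) with
#'   projected, observed, error and absolute percentage error; `$summary`
#'   with MAPE (percent) and RMSE per education group and for the weighted
#'   aggregate; `$rates` the estimated diffusion rates;
#'   `$truncation_cohort`.
#' @export
out_of_sample <- function(cfr_table, slamys, weights, truncation_cohort,
                          horizon_cohort, country = NULL, region = NULL) {
  if (truncation_cohort >= horizon_cohort) {
    abort("truncation_cohort must precede horizon_cohort",
          class = "fertdiff_domain_error")
  }
  if (is.null(country)) {
    ctries <- unique(cfr_table$country)
    if (length(ctries) != 1L) {
      abort("cfr_table holds several countries; pass `country`",
            class = "fertdiff_domain_error")
    }
    country <- ctries
  }
  if (is.null(region)) {
    regions <- unique(slamys$region)
    if (length(regions) != 1L) {
      abort("slamys holds several regions; pass `region`",
            class = "fertdiff_domain_error")
    }
    region <- regions
  }
  sub <- cfr_table[cfr_table$country == country, ]
  start_cohort <- min(sub$cohort)
  if (truncation_cohort - start_cohort < 5) {
    abort("estimation window must span at least 2 cohorts",
          class = "fertdiff_domain_error")
  }
  window <- sub[sub$cohort <= truncation_cohort, ]  # estimation never sees held-out rows
  rates <- estimate_all_rates(window, slamys, start_cohort = start_cohort,
                              end_cohort = truncation_cohort,
                              country = country, region = region)
  held_cohorts <- seq(truncation_cohort + 5, horizon_cohort, by = 5)
  jumpoff <- window[window$cohort == truncation_cohort, ]
  proj <- project_series(jumpoff, rates, slamys, held_cohorts, region = region)

  obs <- sub[sub$cohort %in% held_cohorts, c("cohort", "education", "cfr")]
  details <- proj |>
    select("cohort", "education", projected = "cfr") |>
    inner_join(obs |> rename(observed = "cfr"), by = c("cohort", "education")) |>
    mutate(error = .data$projected - .data$observed,
           ape = 100 * abs(.data$error) / .data$observed) |>
    arrange(.data$education, .data$cohort)

  summary_edu <- details |>
    summarise(mape = mean(.data$ape), rmse = sqrt(mean(.data$error^2)),
              .by = "education")

  agg <- bind_rows(lapply(held_cohorts, function(cc) {
    w <- weights[weights$country == country & weights$cohort == cc, ]
    if (nrow(w) < 4L) return(NULL)
    p <- aggregate_cfr(proj[proj$cohort == cc, ], w)
    o_rows <- obs[obs$cohort == cc, ]
    if (nrow(o_rows) < 4L) return(NULL)
    o <- aggregate_cfr(o_rows, w)
    tibble(cohort = cc, education = "aggregate", projected = p, observed = o,
           error = p - o, ape = 100 * abs(p - o) / o)
  }))
  if (nrow(agg)) {
    details <- bind_rows(details, agg)
    summary_edu <- bind_rows(
      summary_edu,
      agg |> summarise(mape = mean(.data$ape), rmse = sqrt(mean(.data$error^2))) |>
        mutate(education = "aggregate") |> select("education", "mape", "rmse"))
  }

  structure(list(details = details, summary = summary_edu, rates = rates,
                 truncation_cohort = truncation_cohort,
                 horizon_cohort = horizon_cohort, country = country),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Out-of-sample validation:", x$country, "| estimation through",
      x$truncation_cohort, "| projected to", x$horizon_cohort, "\n")
  cat("Estimated diffusion rates (fraction per SLAMYS year):\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  cat("Held-out error summary (MAPE in percent):\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
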