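# Diffusion-rate estimation and the multiplicative projection recurrence.
#
# The diffusion rate is the fractional change in education-specific completed
# cohort fertility per one-year change in skills-adjusted mean years of
# schooling (SLAMYS) between two reference cohorts (default 1955 and 1985).
# It is negative when fertility falls while SLAMYS rises; the projection
# recurrence CFR_e(t+5) = CFR_e(t) * (1 + rate_e * dSLAMYS) then carries
# education-specific fertility forward along a SLAMYS trajectory.

#' Endpoint diffusion-rate estimator
#'
#' `rate = (cfr_end - cfr_start) / cfr_start / (slamys_end - slamys_start)`:
#' the relative CFR change between the endpoint cohorts per SLAMYS
#' year-equivalent.  Negative when fertility declines as schooling rises.
#'
#' @param cfr_start,cfr_end Children per woman at the two reference cohorts
#'   (`cfr_start > 0`).
#' @param slamys_start,slamys_end SLAMYS at the two reference cohorts (must
#'   differ).
#' @return Fractional change in CFR per SLAMYS year (scalar).
#' @export
#' @examples
#' estimate_diffusion_rate(7, 4.9, 1, 4)  # -0.10
estimate_diffusion_rate <- function(cfr_start, cfr_end,
                                    slamys_start, slamys_end) {
  if (cfr_start <= 0) {
    abort("cfr_start must be strictly positive", class = "fertdiff_domain_error")
  }
  if (slamys_end == slamys_start) {
    abort("SLAMYS endpoints are equal: diffusion rate undefined",
          class = "fertdiff_domain_error")
  }
  (cfr_end - cfr_start) / cfr_start / (slamys_end - slamys_start)
}

#' Estimate diffusion rates for every education group
#'
#' Applies [estimate_diffusion_rate()] per education group between
#' `start_cohort` and `end_cohort`, using the SLAMYS series of `region`
#' (the Africa aggregate by default, as rates are estimated Africa-wide and
#' applied per country).
#'
#' @param cfr_table A `cohort_cfr` tibble holding both endpoint cohorts for
#'   every education group.
#' @param slamys A `slamys` tibble holding both endpoint cohorts for `region`.
#' @param start_cohort,end_cohort Reference cohorts (defaults 1955 and 1985).
#' @param country Country whose CFR series is used; defaults to the single
#'   country present in `cfr_table`.
#' @param region SLAMYS region (default `"AFRICA"`).
#' @return A `diffusion_rates` tibble with columns `education`, `rate`.
#' @export
estimate_all_rates <- function(cfr_table, slamys, start_cohort = 1955,
                               end_cohort = 1985, country = NULL,
                               region = "AFRICA") {
  if (is.null(country)) {
    ctries <- unique(cfr_table$country)
    if (length(ctries) != 1L) {
      abort("cfr_table holds several countries; pass `country`",
            class = "fertdiff_domain_error")
    }
    country <- ctries
  }
  sl <- slamys[slamys$region == region, ]
  s_start <- sl$slamys[sl$cohort == start_cohort]
  s_end <- sl$slamys[sl$cohort == end_cohort]
  if (!length(s_start) || !length(s_end)) {
    abort(paste0("SLAMYS series for region '", region, "' is missing cohort ",
                 if (!length(s_start)) start_cohort else end_cohort),
          class = "fertdiff_domain_error")
  }
  sub <- cfr_table[cfr_table$country == country, ]
  edus <- intersect(EDU_LEVELS, unique(sub$education))
  if (!length(edus)) edus <- unique(sub$education)
  rates <- vapply(edus, function(e) {
    c_start <- sub$cfr[sub$education == e & sub$cohort == start_cohort]
    c_end <- sub$cfr[sub$education == e & sub$cohort == end_cohort]
    if (!length(c_start)) {
      abort(paste0("cfr_table is missing endpoint (", e, ", ", start_cohort, ")"),
            class = "fertdiff_domain_error")
    }
    if (!length(c_end)) {
      abort(paste0("cfr_table is missing endpoint (", e, ", ", end_cohort, ")"),
            class = "fertdiff_domain_error")
    }
    estimate_diffusion_rate(c_start, c_end, s_start, s_end)
  }, numeric(1L))
  tibble(education = edus, rate = unname(rates))
}

#' One projection step of the diffusion recurrence
#'
#' `cfr * (1 + rate * delta_slamys)`, floored at 0 (with a warning) if the
#' linear step would cross zero.
#'
#' @param cfr Children per woman (>= 0).
#' @param rate Diffusion rate (fraction per SLAMYS year).
#' @param delta_slamys Change in SLAMYS over the cohort step (years).
#' @return Projected children per woman.
#' @export
project_cfr_step <- function(cfr, rate, delta_slamys) {
  stopifnot(all(cfr >= 0))
  out <- cfr * (1 + rate * delta_slamys)
  if (any(out < 0)) {
    warn("projection crossed zero; flooring CFR at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Project education-specific cohort fertility along a SLAMYS trajectory
#'
#' Iterates [project_cfr_step()] per education group from the jump-off cohort
#' through the requested cohorts.  Africa-wide rates may be combined with a
#' country-specific SLAMYS series (the method's cross-level design).
#'
#' @param jumpoff `cohort_cfr` rows at a single cohort (one row per education
#'   group), the projection jump-off.
#' @param rates A `diffusion_rates` tibble (`education`, `rate`).
#' @param slamys A `slamys` tibble covering the jump-off and every projected
#'   cohort for the target region/country.
#' @param cohorts Cohorts to project (5-year steps after the jump-off cohort);
#'   empty gives an empty table.
#' @param region SLAMYS region to use; defaults to the single region present.
#' @return A `cohort_cfr` tibble with `status = "projected"`.
#' @export
project_series <- function(jumpoff, rates, slamys, cohorts, region = NULL) {
  if (!length(cohorts)) {
    return(tibble(country = character(), cohort = numeric(),
                  education = character(), cfr = numeric(),
                  status = character()))
  }
  t0 <- unique(jumpoff$cohort)
  if (length(t0) != 1L) {
    abort("jumpoff must hold rows of a single cohort",
          class = "fertdiff_domain_error")
  }
  country <- unique(jumpoff$country)
  if (length(country) != 1L) {
    abort("jumpoff must hold rows of a single country",
          class = "fertdiff_domain_error")
  }
  if (is.null(region)) {
    regions <- unique(slamys$region)
    if (length(regions) != 1L) {
      abort("slamys holds several regions; pass `region`",
            class = "fertdiff_domain_error")
    }
    region <- regions
  }
  cohorts <- sort(as.numeric(cohorts))
  steps <- seq(t0 + 5, max(cohorts), by = 5)
  if (!all(cohorts %in% steps)) {
    abort("projected cohorts must lie on 5-year steps after the jump-off cohort",
          class = "fertdiff_domain_error")
  }
  sl <- slamys[slamys$region == region, ]
  needed <- c(t0, steps)
  miss <- setdiff(needed, sl$cohort)
  if (length(miss)) {
    abort(paste0("SLAMYS series for '", region, "' is missing cohort(s) ",
                 paste(miss, collapse = ", ")),
          class = "fertdiff_domain_error")
  }
  slv <- setNames(sl$slamys, sl$cohort)
  rate_vec <- setNames(rates$rate, rates$education)
  miss_edu <- setdiff(unique(jumpoff$education), names(rate_vec))
  if (length(miss_edu)) {
    abort(paste0("no diffusion rate for education group(s): ",
                 paste(miss_edu, collapse = ", ")),
          class = "fertdiff_domain_error")
  }

  out <- vector("list", 0L)
  for (e in unique(jumpoff$education)) {
    cfr <- jumpoff$cfr[jumpoff$education == e]
    for (tt in steps) {
      ds <- slv[[as.character(tt)]] - slv[[as.character(tt - 5)]]
      cfr <- project_cfr_step(cfr, rate_vec[[e]], ds)
      if (tt %in% cohorts) {
        out[[length(out) + 1L]] <- tibble(country = country, cohort = tt,
                                          education = e, cfr = cfr,
                                          status = "projected")
      }
    }
  }
  validate_table(bind_rows(out), "cohort_cfr")
}
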