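# Seeded generators for every pipeline input.
#
# The generators are the package's ground truth: cohort fertility is laid down
# along exact cohort diagonals by the same multiplicative recurrence the
# projection module uses, so the downstream stages can be checked against
# known generative parameters without any external data.

#' Define a synthetic fertility-surface scenario
#'
#' A scenario fixes the generative parameters of an education-age-specific
#' fertility surface: jump-off cohort fertility per education group, the age
#' schedule over the six reproductive age groups (15-19 ... 40-44), the true
#' per-step diffusion rates, the SLAMYS increments between successive 5-year
#' cohorts, and a multiplicative log-normal noise scale on rates.
#'
#' @param countries Character vector of country codes (or `"AFRICA"`).
#' @param cohorts Integer vector of 5-year birth-cohort start years.
#' @param base_cfr Named numeric, children per woman at the first cohort for
#'   each of the four education groups.
#' @param age_schedule Six nonnegative proportions over age groups 15-40,
#'   summing to 1.
#' @param true_diffusion_rates Named numeric, fractional change in CFR per
#'   SLAMYS year applied at each cohort step.
#' @param slamys_path Numeric vector of SLAMYS increments per cohort step
#'   (length `length(cohorts) - 1`).
#' @param slamys_start SLAMYS level at the first cohort, in year-equivalents.
#' @param noise_sd Standard deviation of log-normal multiplicative noise on
#'   each rate cell (0 = noise-free).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `surface_scenario` list.
#' @export
surface_scenario <- function(countries = "AFRICA",
                             cohorts = seq(1955, 1985, by = 5),
                             base_cfr = c(none = 7.2, primary = 6.8,
                                          secondary = 6.0, higher = 5.2),
                             age_schedule = c(0.10, 0.22, 0.24, 0.20, 0.15, 0.09),
                             true_diffusion_rates = c(none = -0.10,
                                                      primary = -0.10,
                                                      secondary = -0.10,
                                                      higher = -0.10),
                             slamys_path = rep(0.5, length(cohorts) - 1),
                             slamys_start = 1.5,
                             noise_sd = 0,
                             seed = 1L) {
  stopifnot(length(age_schedule) == 6L, all(age_schedule >= 0),
            length(slamys_path) == length(cohorts) - 1L,
            noise_sd >= 0, all(cohorts %% 5 == 0))
  if (abs(sum(age_schedule) - 1) > 1e-12) {
    abort("age_schedule must sum to 1 (tolerance 1e-12)",
          class = "fertdiff_scenario_error")
  }
  if (!all(EDU_LEVELS %in% names(base_cfr)) ||
      !all(EDU_LEVELS %in% names(true_diffusion_rates))) {
    abort("base_cfr and true_diffusion_rates must name all four education groups",
          class = "fertdiff_scenario_error")
  }
  if (any(base_cfr <= 0)) {
    abort("base_cfr must be strictly positive", class = "fertdiff_scenario_error")
  }
  structure(list(countries = countries, cohorts = sort(as.integer(cohorts)),
                 base_cfr = base_cfr[EDU_LEVELS],
                 age_schedule = age_schedule,
                 true_diffusion_rates = true_diffusion_rates[EDU_LEVELS],
                 slamys_path = slamys_path, slamys_start = slamys_start,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "surface_scenario")
}

#' True cohort fertility implied by a scenario
#'
#' Applies the recurrence CFR_e(t+5) = CFR_e(t) * (1 + rate_e * dSLAMYS)
#' exactly, with no noise: the generative ground truth for every country in
#' the scenario.
#'
#' @param scenario A [surface_scenario()].
#' @return A `cohort_cfr` tibble with `status = "observed"`.
#' @export
scenario_true_cfr <- function(scenario) {
  stopifnot(inherits(scenario, "surface_scenario"))
  cohorts <- scenario$cohorts
  rows <- lapply(EDU_LEVELS, function(e) {
    growth <- 1 + scenario$true_diffusion_rates[[e]] * scenario$slamys_path
    cfr <- scenario$base_cfr[[e]] * c(1, cumprod(growth))
    if (any(cfr < 0)) {
      abort(paste0("scenario recurrence drives CFR below 0 for education '",
                   e, "'"), class = "fertdiff_scenario_error")
    }
    tibble(cohort = cohorts, education = e, cfr = cfr)
  })
  tidyr::expand_grid(country = scenario$countries, bind_rows(rows)) |>
    mutate(status = "observed") |>
    select("country", "cohort", "education", "cfr", "status") |>
    arrange(.data$country, .data$cohort, .data$education)
}

#' Generate an education-age-specific fertility surface from a scenario
#'
#' Each cohort's CFR (from the scenario recurrence) is distributed over the
#' six age groups by the age schedule, divided by 5 to give annual rates, and
#' placed on the cohort diagonal (period = cohort + age-group start).
#' Optional multiplicative log-normal noise is applied cell-wise.  The result
#' is bit-reproducible given the scenario seed.
#'
#' @param scenario A [surface_scenario()].
#' @return A validated `fertility_surface` tibble.
#' @export
generate_surface <- function(scenario) {
  stopifnot(inherits(scenario, "surface_scenario"))
  truth <- scenario_true_cfr(scenario)
  cells <- truth |>
    tidyr::expand_grid(idx = seq_along(REPRO_AGES)) |>
    mutate(age_group = REPRO_AGES[.data$idx],
           period = .data$cohort + .data$age_group,
           rate = .data$cfr * scenario$age_schedule[.data$idx] / 5) |>
    select("country", "period", "age_group", "education", "rate") |>
    arrange(.data$country, .data$period, .data$age_group, .data$education)
  if (scenario$noise_sd > 0) {
    cells$rate <- with_substream(scenario$seed, "surface", {
      cells$rate * exp(rnorm(nrow(cells), 0, scenario$noise_sd))
    })
  }
  validate_table(cells, "fertility_surface")
}

#' Generate a cohort-indexed SLAMYS series by cumulative increments
#'
#' @param region Region or country code (e.g. `"AFRICA"`).
#' @param start SLAMYS level at the first cohort (year-equivalents, >= 0).
#' @param increments Numeric vector of per-cohort-step increments; the series
#'   has `length(increments) + 1` points.
#' @param cohorts Cohort start years; defaults to 5-year steps from 1955.
#' @return A validated `slamys` tibble.
#' @export
generate_slamys <- function(region, start, increments = numeric(),
                            cohorts = seq(1955, by = 5,
                                          length.out = length(increments) + 1)) {
  stopifnot(start >= 0, length(cohorts) == length(increments) + 1L)
  values <- start + cumsum(c(0, increments))
  if (any(values < 0)) {
    abort("cumulative SLAMYS falls below 0", class = "fertdiff_scenario_error")
  }
  validate_table(tibble(region = region, cohort = as.numeric(cohorts),
                        slamys = values), "slamys")
}

#' Linearly interpolated education-share trajectory
#'
#' @param from,to Numeric length-4 shares (none, primary, secondary, higher),
#'   each summing to 1.
#' @param n Number of cohorts.
#' @return An `n` x 4 matrix of shares, one row per cohort, rows summing to 1.
#' @export
interpolate_shares <- function(from, to, n) {
  stopifnot(length(from) == 4L, length(to) == 4L, n >= 1)
  w <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  out <- outer(1 - w, from) + outer(w, to)
  colnames(out) <- EDU_LEVELS
  out
}

#' Generate cohort-specific education composition weights
#'
#' @param country Country code.
#' @param cohorts Cohort start years.
#' @param shares Either a length-4 vector of shares applied to every cohort,
#'   or a `length(cohorts)` x 4 matrix with one row per cohort.  Rows must sum
#'   to 1.
#' @return A validated `education_weights` tibble.
#' @export
generate_weights <- function(country, cohorts, shares) {
  if (is.null(dim(shares))) {
    shares <- matrix(shares, nrow = length(cohorts), ncol = 4L, byrow = TRUE)
  }
  stopifnot(nrow(shares) == length(cohorts), ncol(shares) == 4L)
  if (any(abs(rowSums(shares) - 1) > 1e-9) || any(shares < 0)) {
    abort("education shares must be nonnegative and sum to 1 per cohort",
          class = "fertdiff_scenario_error")
  }
  colnames(shares) <- EDU_LEVELS
  tbl <- tidyr::expand_grid(cohort = as.numeric(cohorts),
                            education = EDU_LEVELS) |>
    mutate(country = country,
           weight = as.numeric(t(shares))) |>
    select("country", "cohort", "education", "weight")
  validate_table(tbl, "education_weights")
}

#' Default education mixer: attainment probabilities given stratum schooling
#'
#' A softmax over the four attainment categories whose utilities rise with
#' stratum mean years of schooling for the higher categories, so better
#' educated strata hold more secondary/higher educated women.
#'
#' @param mys Stratum mean years of schooling.
#' @return A length-4 probability vector (none, primary, secondary, higher).
#' @export
default_education_mixer <- function(mys) {
  u <- c(none = 2.0, primary = 1.2, secondary = 0.2, higher = -1.5) +
    c(0, 0.15, 0.30, 0.45) * mys
  p <- exp(u - max(u))
  p / sum(p)
}

#' Generate DHS-like survey microdata from a strata-level Poisson model
#'
#' Stratum mean years of schooling is drawn uniformly on `mys_range`; each
#' woman's attainment is drawn from `education_mixer(MYS)`; her ideal family
#' size is Poisson with log-mean `beta0 + beta1[educ] + beta2 * MYS +
#' beta3[educ] * MYS + beta_urban * urban + U_s`, where the stratum effect
#' `U_s` is zero-mean normal with standard deviation `stratum_sd`.  Children
#' ever born is drawn from the same linear predictor for women aged 40-49 and
#' left missing for younger women.
#'
#' @param n_strata Number of strata (>= 2).
#' @param women_per_stratum Women sampled per stratum (>= 1).
#' @param betas List with elements `beta0` (scalar), `beta1` and `beta3`
#'   (named length-4 vectors with `none = 0`), `beta2` (scalar) and optional
#'   `beta_urban` (scalar, default 0).
#' @param mys_range Length-2 interval for stratum mean years of schooling.
#' @param education_mixer Function of stratum MYS returning 4 probabilities.
#' @param stratum_sd Standard deviation of the normal stratum effect U_s.
#' @param clusters_per_stratum Clusters nested in each stratum.
#' @param seed Integer seed.
#' @return A validated `microdata` tibble.
#' @export
generate_microdata <- function(n_strata, women_per_stratum,
                               betas = list(beta0 = log(7),
                                            beta1 = c(none = 0, primary = -0.09,
                                                      secondary = -0.18,
                                                      higher = -0.35),
                                            beta2 = -0.044,
                                            beta3 = c(none = 0, primary = -0.005,
                                                      secondary = -0.010,
                                                      higher = -0.015)),
                               mys_range = c(0, 12),
                               education_mixer = default_education_mixer,
                               stratum_sd = 0.1,
                               clusters_per_stratum = 5L,
                               seed = 1L) {
  stopifnot(n_strata >= 2L, women_per_stratum >= 1L)
  beta_urban <- betas$beta_urban %||% 0
  b1 <- betas$beta1[EDU_LEVELS]
  b3 <- betas$beta3[EDU_LEVELS]
  stopifnot(!anyNA(b1), !anyNA(b3), b1[["none"]] == 0, b3[["none"]] == 0)

  with_substream(seed, "microdata", {
    mys_s <- runif(n_strata, mys_range[1], mys_range[2])
    u_s <- if (stratum_sd > 0) rnorm(n_strata, 0, stratum_sd) else rep(0, n_strata)

    probs <- vapply(mys_s, education_mixer, numeric(4L))
    if (any(rowSums(probs) == 0)) {
      warn("education_mixer assigns zero probability to a category in every stratum")
    }

    n <- n_strata * women_per_stratum
    stratum_idx <- rep(seq_len(n_strata), each = women_per_stratum)
    educ <- unlist(lapply(seq_len(n_strata), function(s) {
      sample(EDU_LEVELS, women_per_stratum, replace = TRUE, prob = probs[, s])
    }), use.names = FALSE)
    age <- sample(15:49, n, replace = TRUE)
    urban <- runif(n) < 0.4
    lp <- betas$beta0 + b1[educ] + betas$beta2 * mys_s[stratum_idx] +
      b3[educ] * mys_s[stratum_idx] + beta_urban * urban + u_s[stratum_idx]
    ifs <- rpois(n, exp(lp))
    ceb <- ifelse(age >= 40, rpois(n, exp(lp)), NA_real_)

    cluster_idx <- sample.int(clusters_per_stratum, n, replace = TRUE)
    tbl <- tibble(
      woman_id = seq_len(n),
      stratum_id = sprintf("S%04d", stratum_idx),
      cluster_id = sprintf("S%04dC%02d", stratum_idx, cluster_idx),
      education = unname(educ),
      stratum_mys = mys_s[stratum_idx],
      ideal_family_size = as.numeric(ifs),
      children_ever_born = ceb,
      age = as.numeric(age),
      urban = urban
    )
    validate_table(tbl, "microdata")
  })
}

#' Africa-wide demonstration scenario
#'
#' Emulates the published Africa-aggregate conditions: seven 5-year cohorts
#' 1955-1985 (preceded by earlier cohorts so the 1970-2015 period window holds
#' complete age blocks), jump-off cohort fertility near seven children per
#' woman for uneducated women, SLAMYS rising 0.5 year-equivalents per cohort
#' step, and per-step recurrence rates chosen so the 1955-to-1985 endpoint
#' diffusion-rate estimates equal the reported Africa-wide values (-10.2%,
#' -11.09%, -11.57%, -11.64% for none/primary/secondary/higher).
#'
#' @param noise_sd Multiplicative log-normal noise scale on rates.
#' @param seed Integer seed.
#' @param cohorts Cohort window (start years).
#' @return A [surface_scenario()].
#' @export
demo_scenario <- function(noise_sd = 0, seed = 1L,
                          cohorts = seq(1930, 1985, by = 5)) {
  endpoint_rates <- c(none = -0.102, primary = -0.1109,
                      secondary = -0.1157, higher = -0.1164)
  # invert the 6-step compounding so endpoint estimates match: with constant
  # per-step dS = 0.5 over 1955..1985, (1 + r*dS)^6 = 1 + R * (6*dS)
  ds <- 0.5
  per_step <- ((1 + endpoint_rates * 6 * ds)^(1 / 6) - 1) / ds
  # the recurrence starts at the first generated cohort; rescale the base so
  # the stated jump-off levels hold at cohort 1955
  cfr_1955 <- c(none = 7.2, primary = 6.8, secondary = 6.0, higher = 5.2)
  n_pre <- sum(cohorts < 1955)
  surface_scenario(
    countries = "AFRICA",
    cohorts = cohorts,
    base_cfr = cfr_1955 / (1 + per_step * ds)^n_pre,
    age_schedule = c(0.10, 0.22, 0.24, 0.20, 0.15, 0.09),
    true_diffusion_rates = per_step,
    slamys_path = rep(ds, length(cohorts) - 1),
    slamys_start = max(0, 1.5 - ds * n_pre),
    noise_sd = noise_sd,
    seed = seed
  )
}
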