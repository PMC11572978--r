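# Fixtures built in code: generative scenarios and a rank-1 log-bilinear
# surface with linear time index, for which the Lee-Carter fit is exact.

edu_levels <- c("none", "primary", "secondary", "higher")

# A scenario whose SLAMYS path is single-step-consistent over the 1955-1965
# estimation window (no SLAMYS change in the first step), so the endpoint
# diffusion-rate estimator recovers the per-step recurrence rate exactly.
closed_loop_scenario <- function(noise_sd = 0, seed = 1,
                                 countries = "AFRICA",
                                 rates = c(none = -0.10, primary = -0.11,
                                           secondary = -0.115, higher = -0.116)) {
  surface_scenario(
    countries = countries,
    cohorts = seq(1955, 1985, by = 5),
    base_cfr = c(none = 7.2, primary = 6.8, secondary = 6.0, higher = 5.2),
    true_diffusion_rates = rates,
    slamys_path = c(0, 1, 1, 1, 1, 1),
    slamys_start = 1.5,
    noise_sd = noise_sd,
    seed = seed
  )
}

scenario_slamys <- function(sc) {
  generate_slamys(sc$countries[1], sc$slamys_start, sc$slamys_path,
                  cohorts = sc$cohorts)
}

uniform_weights <- function(country, cohorts) {
  generate_weights(country, cohorts, rep(0.25, 4))
}

# Rank-1 log-bilinear rates: log m(x, t) = ax + bx * kt with sum(bx) = 1 and
# linear, sum-zero kt.  Returns the surface plus the generative components.
rank1_surface <- function(periods = seq(1970, 2025, by = 5),
                          country = "KEN", educations = edu_levels,
                          kt_slope = -0.15) {
  ax <- log(c(0.06, 0.30, 0.30, 0.18, 0.10, 0.024))
  bx <- c(0.10, 0.25, 0.25, 0.20, 0.12, 0.08)  # sums to 1
  idx <- seq_along(periods)
  kt <- kt_slope * (idx - mean(idx))            # linear, sums to 0
  cells <- expand.grid(age_i = 1:6, t_i = idx)
  rows <- do.call(rbind, lapply(educations, function(e) {
    data.frame(country = country,
               period = periods[cells$t_i],
               age_group = seq(15, 40, by = 5)[cells$age_i],
               education = e,
               rate = exp(ax[cells$age_i] + bx[cells$age_i] * kt[cells$t_i]))
  }))
  list(surface = validate_table(rows, "fertility_surface"),
       ax = ax, bx = bx, kt = kt, periods = periods, country = country)
}

null_betas <- function(beta0 = log(4)) {
  list(beta0 = beta0,
       beta1 = c(none = 0, primary = 0, secondary = 0, higher = 0),
       beta2 = 0,
       beta3 = c(none = 0, primary = 0, secondary = 0, higher = 0))
}

recovery_betas <- function() {
  list(beta0 = log(7),
       beta1 = c(none = 0, primary = -0.09, secondary = -0.18, higher = -0.35),
       beta2 = -0.044,
       beta3 = c(none = 0, primary = -0.005, secondary = -0.010,
                 higher = -0.015))
}

flatten_betas <- function(b) {
  c(beta0 = b$beta0, b1 = unname(b$beta1[-1]), beta2 = b$beta2,
    b3 = unname(b$beta3[-1]))
}

flatten_fit <- function(fit) {
  list(est = c(fit$beta0, unname(fit$beta1[-1]), fit$beta2,
               unname(fit$beta3[-1])),
       se = c(fit$se$beta0, unname(fit$se$beta1[-1]), fit$se$beta2,
              unname(fit$se$beta3[-1])))
}
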