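# Pipeline entry point: one function dispatching the CSV-to-CSV subcommands,
# driven by a YAML (or list) configuration.  All randomness flows from the
# single config seed; identical config + seed gives byte-identical outputs.

default_config <- function() {
  list(
    paths = list(
      surface = "fertility_surface.csv",
      cohort_cfr = "cohort_cfr.csv",
      slamys = "slamys.csv",
      weights = "education_weights.csv",
      microdata = "microdata.csv",
      rates = "diffusion_rates.csv",
      projected = "projected_cfr.csv",
      validation = "validation_report.csv",
      coefficients = "coefficients.csv",
      curves = "curves.csv"
    ),
    cohorts = list(start = 1955, end = 1985, step = 5),
    estimation = list(start = 1955, end = 1985),
    rates_region = "AFRICA",
    truncation = 1965,
    horizon = 1985,
    projection_horizon = 2000,
    scenario = list(noise_sd = 0.02),
    microdata = list(n_strata = 50, women_per_stratum = 200),
    strata_fit = list(outcome = "ideal_family_size", mode = "fixed",
                      urban = FALSE, grid = list(from = 0, to = 12, by = 0.5)),
    seed = 1,
    log_level = "info"
  )
}

#' Load and validate a pipeline run configuration
#'
#' @param config A YAML file path or a nested list; missing entries fall back
#'   to package defaults.
#' @return The merged, validated config list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "fertdiff_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_rec(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge_rec(default_config(), config)
  if (cfg$cohorts$step != 5) {
    abort("config field cohorts$step must be 5", class = "fertdiff_config_error")
  }
  if (cfg$cohorts$start > cfg$cohorts$end) {
    abort("config field cohorts$start must be <= cohorts$end",
          class = "fertdiff_config_error")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0 ||
      cfg$seed != round(cfg$seed)) {
    abort("config field seed must be a nonnegative integer",
          class = "fertdiff_config_error")
  }
  cfg
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message("[fertdiff] ", ...)
}

#' Run one pipeline subcommand
#'
#' Subcommands: `simulate` (write all synthetic inputs), `convert` (surface to
#' cohort CFR), `complete` (Lee-Carter completion of truncated cohorts),
#' `estimate` (diffusion rates), `project` (forward projection), `validate`
#' (out-of-sample protocol), `strata-fit` (Poisson model and prediction
#' curves).  Each subcommand reads only its declared inputs and writes its
#' declared outputs, logging the config hash, seed and row counts.
#'
#' @param config A YAML path or config list (see [load_config()]).
#' @param command Subcommand name.
#' @return Invisibly, the main artifact the subcommand wrote.
#' @export
run_pipeline <- function(config, command) {
  cfg <- load_config(config)
  commands <- c("simulate", "convert", "complete", "estimate", "project",
                "validate", "strata-fit")
  if (!command %in% commands) {
    abort(paste0("unknown subcommand '", command, "'; expected one of: ",
                 paste(commands, collapse = ", ")),
          class = "fertdiff_config_error")
  }
  pipeline_log(cfg, "command=", command, " seed=", cfg$seed,
               " config_hash=", rlang::hash(cfg))
  p <- cfg$paths
  cohorts <- seq(cfg$cohorts$start, cfg$cohorts$end, by = cfg$cohorts$step)

  out <- switch(command,
    simulate = {
      sc_over <- cfg$scenario
      sc <- demo_scenario(noise_sd = sc_over$noise_sd %||% 0.02,
                          seed = cfg$seed)
      surface <- generate_surface(sc)
      write_table(surface, p$surface, "fertility_surface")
      # extend the SLAMYS series to the projection horizon at the scenario's
      # per-step increment (projections are driven by projected SLAMYS)
      n_extra <- max(0, (cfg$projection_horizon - max(sc$cohorts)) / 5)
      incr <- c(sc$slamys_path,
                rep(sc$slamys_path[length(sc$slamys_path)], n_extra))
      slamys <- generate_slamys(sc$countries[1], sc$slamys_start, incr,
                                cohorts = seq(min(sc$cohorts), by = 5,
                                              length.out = length(incr) + 1))
      write_table(slamys, p$slamys, "slamys")
      shares <- interpolate_shares(c(0.7, 0.2, 0.08, 0.02),
                                   c(0.25, 0.3, 0.3, 0.15), length(cohorts))
      weights <- generate_weights(sc$countries[1], cohorts, shares)
      write_table(weights, p$weights, "education_weights")
      md <- generate_microdata(cfg$microdata$n_strata,
                               cfg$microdata$women_per_stratum,
                               seed = cfg$seed)
      write_table(md, p$microdata, "microdata")
      pipeline_log(cfg, "simulate: surface=", nrow(surface), " rows, slamys=",
                   nrow(slamys), ", weights=", nrow(weights), ", microdata=",
                   nrow(md))
      surface
    },
    convert = {
      surface <- read_table(p$surface, "fertility_surface")
      tbl <- convert_all(surface, cohorts)
      write_table(tbl, p$cohort_cfr, "cohort_cfr")
      pipeline_log(cfg, "convert: ", nrow(tbl), " cohort rows, ",
                   nrow(attr(tbl, "incomplete")), " incomplete")
      tbl
    },
    complete = {
      surface <- read_table(p$surface, "fertility_surface")
      obs <- convert_all(surface, cohorts)
      inc <- attr(obs, "incomplete")
      done <- if (nrow(inc)) {
        complete_truncated_cohorts(surface, unique(inc$cohort))
      } else {
        obs[0, ]
      }
      tbl <- bind_rows(obs, anti_join(done, obs,
                                      by = c("country", "cohort", "education")))
      write_table(tbl, p$cohort_cfr, "cohort_cfr")
      pipeline_log(cfg, "complete: ", nrow(done), " completed rows, ",
                   nrow(tbl), " total")
      tbl
    },
    estimate = {
      cfr <- read_table(p$cohort_cfr, "cohort_cfr")
      slamys <- read_table(p$slamys, "slamys")
      rates <- estimate_all_rates(cfr, slamys,
                                  start_cohort = cfg$estimation$start,
                                  end_cohort = cfg$estimation$end,
                                  region = cfg$rates_region)
      readr::write_csv(rates, p$rates, progress = FALSE)
      pipeline_log(cfg, "estimate: ",
                   paste(rates$education, format(rates$rate, digits = 4),
                         sep = "=", collapse = ", "))
      rates
    },
    project = {
      cfr <- read_table(p$cohort_cfr, "cohort_cfr")
      slamys <- read_table(p$slamys, "slamys")
      rates <- readr::read_csv(p$rates, show_col_types = FALSE,
                               progress = FALSE)
      t0 <- max(cfr$cohort)
      if (cfg$projection_horizon <= t0) {
        abort("projection_horizon must exceed the jump-off cohort",
              class = "fertdiff_config_error")
      }
      jumpoff <- cfr[cfr$cohort == t0, ]
      target <- seq(t0 + 5, cfg$projection_horizon, by = 5)
      proj <- project_series(jumpoff, rates, slamys, target,
                             region = cfg$rates_region)
      write_table(proj, p$projected, "cohort_cfr")
      pipeline_log(cfg, "project: ", nrow(proj), " projected rows to cohort ",
                   cfg$projection_horizon)
      proj
    },
    validate = {
      cfr <- read_table(p$cohort_cfr, "cohort_cfr")
      slamys <- read_table(p$slamys, "slamys")
      weights <- read_table(p$weights, "education_weights")
      rep <- out_of_sample(cfr, slamys, weights, cfg$truncation, cfg$horizon,
                           region = cfg$rates_region)
      readr::write_csv(rep$details, p$validation, progress = FALSE)
      if (!identical(cfg$log_level, "quiet")) print(rep)
      rep
    },
    `strata-fit` = {
      md <- read_table(p$microdata, "microdata")
      fit <- fit_ifs_model(md, outcome = cfg$strata_fit$outcome,
                           mode = cfg$strata_fit$mode,
                           include_urban = isTRUE(cfg$strata_fit$urban))
      coefs <- tibble(
        term = c("beta0", paste0("beta1_", names(fit$beta1)), "beta2",
                 paste0("beta3_", names(fit$beta3))),
        estimate = c(fit$beta0, fit$beta1, fit$beta2, fit$beta3),
        se = c(fit$se$beta0, fit$se$beta1, fit$se$beta2, fit$se$beta3))
      readr::write_csv(coefs, p$coefficients, progress = FALSE)
      g <- cfg$strata_fit$grid
      grid <- seq(g$from, g$to, by = g$by)
      curves <- bind_rows(lapply(EDU_LEVELS, function(e) {
        predict_curves(fit, grid, e)
      }))
      readr::write_csv(curves, p$curves, progress = FALSE)
      pipeline_log(cfg, "strata-fit: n=", fit$n_obs, " beta2=",
                   format(fit$beta2, digits = 4))
      fit
    }
  )
  invisible(out)
}
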