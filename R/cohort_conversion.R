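# Period-to-cohort conversion along cohort diagonals.
#
# A birth cohort labelled t (born t..t+4) passes through age group 15-19 in
# period t+15, 20-24 in t+20, ..., 40-44 in t+40.  Completed cohort fertility
# is five times the sum of the six education-age-specific rates on that
# diagonal; ages 45-49 are never included in the sum even when present.

#' Cohort-diagonal cells for a birth cohort
#'
#' @param cohort Birth-cohort start year (multiple of 5).
#' @return A tibble of six `(age_group, period)` pairs, `period = cohort +
#'   age_group` for age groups 15, 20, ..., 40.
#' @export
#' @examples
#' cohort_cells(1955)
cohort_cells <- function(cohort) {
  stopifnot(length(cohort) == 1L, cohort %% 5 == 0)
  tibble(age_group = as.numeric(REPRO_AGES),
         period = as.numeric(cohort + REPRO_AGES))
}

incompleteness_error <- function(country, education, cohort, missing_cells) {
  abort(
    paste0("incomplete cohort diagonal for ", country, "/", education,
           "/cohort ", cohort, "; missing (age_group, period): ",
           paste0("(", missing_cells$age_group, ", ", missing_cells$period, ")",
                  collapse = ", ")),
    class = "fertdiff_incomplete",
    country = country, education = education, cohort = cohort,
    missing = missing_cells)
}

#' Completed cohort fertility for one country, education group and cohort
#'
#' Sums the six education-age-specific rates along the cohort diagonal and
#' multiplies by 5 (the width of each age group in years).
#'
#' @param surface A `fertility_surface` tibble.
#' @param country,education,cohort Cell selectors.
#' @return Children per woman (scalar).  If any of the six diagonal cells is
#'   absent, a `fertdiff_incomplete` error lists the missing
#'   `(age_group, period)` pairs; callers may route such cohorts to
#'   [complete_truncated_cohorts()].
#' @export
period_to_cohort_cfr <- function(surface, country, education, cohort) {
  cells <- cohort_cells(cohort)
  sub <- surface[surface$country == country & surface$education == education, ]
  found <- inner_join(cells, sub, by = c("age_group", "period"))
  if (nrow(found) < 6L) {
    missing_cells <- anti_join(cells, found, by = c("age_group", "period"))
    incompleteness_error(country, education, cohort, missing_cells)
  }
  5 * sum(found$rate)
}

#' Convert a fertility surface into a completed-cohort-fertility table
#'
#' One row per `(country, cohort, education)` whose six diagonal cells are all
#' present, with `status = "observed"`.  Incomplete combinations are reported
#' in the `incomplete` attribute (and a message), never silently dropped.
#'
#' @param surface A `fertility_surface` tibble.
#' @param cohorts Birth-cohort start years to convert.
#' @return A `cohort_cfr` tibble; `attr(, "incomplete")` is a tibble of
#'   combinations that could not be converted with their missing cell counts.
#' @export
convert_all <- function(surface, cohorts) {
  surface <- validate_table(surface, "fertility_surface")
  if (!nrow(surface)) {
    warn("empty fertility surface: nothing to convert")
    out <- tibble(country = character(), cohort = numeric(),
                  education = character(), cfr = numeric(),
                  status = character())
    attr(out, "incomplete") <- tibble(country = character(), cohort = numeric(),
                                      education = character(),
                                      n_missing = integer())
    return(out)
  }
  combos <- distinct(surface, .data$country, .data$education) |>
    tidyr::expand_grid(cohort = as.numeric(cohorts))
  res <- vector("list", nrow(combos))
  inc <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cc <- combos[i, ]
    cfr <- tryCatch(
      period_to_cohort_cfr(surface, cc$country, cc$education, cc$cohort),
      fertdiff_incomplete = function(e) e)
    if (inherits(cfr, "fertdiff_incomplete")) {
      inc[[i]] <- mutate(cc, n_missing = nrow(cfr$missing))
    } else {
      res[[i]] <- mutate(cc, cfr = cfr, status = "observed")
    }
  }
  out <- bind_rows(res) |>
    select(any_of(c("country", "cohort", "education", "cfr", "status")))
  incomplete <- bind_rows(inc)
  if (nrow(incomplete)) {
    inform(paste0(nrow(incomplete), " (country, cohort, education) ",
                  "combination(s) had incomplete diagonals; see ",
                  "attr(result, 'incomplete')"))
  } else {
    incomplete <- tibble(country = character(), cohort = numeric(),
                         education = character(), n_missing = integer())
  }
  out <- if (nrow(out)) validate_table(out, "cohort_cfr") else
    tibble(country = character(), cohort = numeric(), education = character(),
           cfr = numeric(), status = character())
  attr(out, "incomplete") <- incomplete
  out
}
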