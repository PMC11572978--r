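# Shared domain tables and validated CSV interchange.
#
# Every table in the pipeline is a plain tibble in long (tidy) format with one
# row per cell, read and written as CSV with a fixed header.  Cohorts and
# periods are labelled by the START year of the 5-year interval (1955 means
# 1955-1959); age groups by their start age (15 means 15-19).

# column type codes: d = double, i = integer-valued double, c = character,
# l = logical
fd_schemas <- function() {
  list(
    fertility_surface = list(
      columns = c(country = "c", period = "d", age_group = "d",
                  education = "c", rate = "d"),
      key = c("country", "period", "age_group", "education")
    ),
    cohort_cfr = list(
      columns = c(country = "c", cohort = "d", education = "c",
                  cfr = "d", status = "c"),
      key = c("country", "cohort", "education")
    ),
    slamys = list(
      columns = c(region = "c", cohort = "d", slamys = "d"),
      key = c("region", "cohort")
    ),
    education_weights = list(
      columns = c(country = "c", cohort = "d", education = "c", weight = "d"),
      key = c("country", "cohort", "education")
    ),
    microdata = list(
      columns = c(woman_id = "d", stratum_id = "c", cluster_id = "c",
                  education = "c", stratum_mys = "d", ideal_family_size = "d",
                  children_ever_born = "d", age = "d", urban = "l"),
      key = "woman_id"
    )
  )
}

validation_error <- function(msg, rule, rows = NULL) {
  loc <- if (length(rows)) paste0(" [row(s) ", paste(head(rows, 5L), collapse = ", "),
                                  if (length(rows) > 5L) ", ..." else "", "]") else ""
  abort(paste0(msg, loc), class = "fertdiff_validation_error",
        rule = rule, rows = rows)
}

check_unique_key <- function(tbl, key, schema) {
  if (!nrow(tbl)) return(invisible(tbl))
  dup <- duplicated(tbl[, key, drop = FALSE])
  if (any(dup)) {
    validation_error(
      paste0(schema, ": duplicated key (", paste(key, collapse = ", "), ")"),
      rule = "unique_key", rows = which(dup))
  }
  invisible(tbl)
}

check_range <- function(tbl, col, lo = -Inf, hi = Inf, schema,
                        allow_na = FALSE) {
  x <- tbl[[col]]
  bad <- (!is.na(x) & (x < lo | x > hi)) | (!allow_na & is.na(x))
  if (any(bad)) {
    validation_error(
      sprintf("%s: column '%s' must lie in [%s, %s]%s", schema, col,
              format(lo), format(hi), if (allow_na) " (or be missing)" else ""),
      rule = paste0(col, "_range"), rows = which(bad))
  }
}

check_multiple_of_5 <- function(tbl, col, schema) {
  x <- tbl[[col]]
  bad <- is.na(x) | x %% 5 != 0
  if (any(bad)) {
    validation_error(sprintf("%s: column '%s' must fall on multiples of 5",
                             schema, col),
                     rule = paste0(col, "_grid"), rows = which(bad))
  }
}

check_levels <- function(tbl, col, levels, schema) {
  x <- tbl[[col]]
  bad <- is.na(x) | !(x %in% levels)
  if (any(bad)) {
    validation_error(sprintf("%s: column '%s' must be one of {%s}", schema, col,
                             paste(levels, collapse = ", ")),
                     rule = paste0(col, "_levels"), rows = which(bad))
  }
}

check_counts <- function(tbl, col, schema, allow_na = FALSE) {
  x <- tbl[[col]]
  bad <- (!is.na(x) & (x < 0 | x != round(x))) | (!allow_na & is.na(x))
  if (any(bad)) {
    validation_error(sprintf("%s: column '%s' must hold nonnegative integers",
                             schema, col),
                     rule = paste0(col, "_count"), rows = which(bad))
  }
}

#' Validate a pipeline table against its schema
#'
#' Checks column presence, types and every schema invariant (value ranges,
#' 5-year grids, education categories, key uniqueness, weight normalisation,
#' cluster-to-stratum nesting).  Errors name the violated rule and the
#' offending rows.
#'
#' @param tbl A data frame.
#' @param schema One of `"fertility_surface"`, `"cohort_cfr"`, `"slamys"`,
#'   `"education_weights"`, `"microdata"`.
#' @return The validated table, invisibly, as a tibble in canonical key order.
#' @export
validate_table <- function(tbl, schema) {
  schemas <- fd_schemas()
  if (!schema %in% names(schemas)) {
    abort(paste0("unknown schema '", schema, "'"), class = "fertdiff_schema_error")
  }
  sc <- schemas[[schema]]
  missing_cols <- setdiff(names(sc$columns), names(tbl))
  extra_cols <- setdiff(names(tbl), names(sc$columns))
  if (length(missing_cols) || length(extra_cols)) {
    abort(paste0(schema, ": column mismatch",
                 if (length(missing_cols))
                   paste0("; missing: ", paste(missing_cols, collapse = ", ")),
                 if (length(extra_cols))
                   paste0("; unexpected: ", paste(extra_cols, collapse = ", "))),
          class = "fertdiff_schema_error")
  }
  tbl <- as_tibble(tbl)[, names(sc$columns)]
  for (col in names(sc$columns)) {
    tbl[[col]] <- switch(sc$columns[[col]],
      d = as.numeric(tbl[[col]]),
      c = as.character(tbl[[col]]),
      l = as.logical(tbl[[col]]))
  }

  switch(schema,
    fertility_surface = {
      check_range(tbl, "rate", 0, 1, schema)
      check_multiple_of_5(tbl, "period", schema)
      check_multiple_of_5(tbl, "age_group", schema)
      check_levels(tbl, "education", c(EDU_LEVELS, "total"), schema)
    },
    cohort_cfr = {
      check_range(tbl, "cfr", 0, 15, schema)
      check_multiple_of_5(tbl, "cohort", schema)
      check_levels(tbl, "education", c(EDU_LEVELS, "total"), schema)
      check_levels(tbl, "status", c("observed", "completed", "projected"),
                   schema)
    },
    slamys = {
      check_range(tbl, "slamys", 0, Inf, schema)
      check_multiple_of_5(tbl, "cohort", schema)
    },
    education_weights = {
      check_range(tbl, "weight", 0, Inf, schema)
      check_levels(tbl, "education", EDU_LEVELS, schema)
      if (nrow(tbl)) {
        sums <- tbl |>
          summarise(s = sum(.data$weight), .by = c("country", "cohort"))
        off <- abs(sums$s - 1) > 1e-9
        if (any(off)) {
          validation_error(
            paste0(schema, ": weights must sum to 1 within (country, cohort); ",
                   "first offender: ", sums$country[off][1], "/",
                   sums$cohort[off][1], " sums to ",
                   format(sums$s[off][1], digits = 12)),
            rule = "weight_sum")
        }
      }
    },
    microdata = {
      check_counts(tbl, "ideal_family_size", schema)
      check_counts(tbl, "children_ever_born", schema, allow_na = TRUE)
      check_range(tbl, "stratum_mys", 0, Inf, schema)
      check_levels(tbl, "education", EDU_LEVELS, schema)
      if (nrow(tbl)) {
        n_strata <- tbl |>
          summarise(k = n_distinct(.data$stratum_id), .by = "cluster_id")
        bad <- n_strata$k != 1L
        if (any(bad)) {
          validation_error(
            paste0(schema, ": cluster(s) mapped to more than one stratum: ",
                   paste(head(n_strata$cluster_id[bad], 5L), collapse = ", ")),
            rule = "cluster_nesting")
        }
      }
    }
  )
  check_unique_key(tbl, sc$key, schema)
  invisible(arrange(tbl, across(all_of(sc$key))))
}

#' Read a validated pipeline table from CSV
#'
#' @param path Path to a CSV file whose header matches the schema exactly.
#' @param schema Schema name (see [validate_table()]).
#' @return A validated tibble in canonical key order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' s <- tibble::tibble(country = "KEN", period = 1990, age_group = 20,
#'                     education = "primary", rate = 0.28)
#' write_table(s, tf, "fertility_surface")
#' read_table(tf, "fertility_surface")
read_table <- function(path, schema) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "fertdiff_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  out <- validate_table(tbl, schema)
  out
}

#' Write a pipeline table to CSV in canonical key order
#'
#' Values round-trip through [read_table()] exactly (readr writes the shortest
#' decimal representation that re-reads to the identical double).
#'
#' @param tbl Table satisfying the schema invariants.
#' @param path Output path.
#' @param schema Schema name (see [validate_table()]).
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path, schema) {
  out <- validate_table(tbl, schema)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
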