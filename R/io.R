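#' Read and write the pipeline's tables
#'
#' All tables are UTF-8, comma-delimited, dot-decimal, with a mandatory header
#' row. Readers validate the schema and report the offending column/row on
#' failure; writers round-trip at full precision.
#'
#' @name pharmprev_io
NULL

read_checked <- function(path, col_types, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  out <- readr::read_csv(path, col_types = col_types,
                         show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(names(col_types$cols), names(out))
  if (length(missing)) {
    abort(sprintf("%s file %s lacks column(s): %s.",
                  what, path, toString(missing)))
  }
  probs <- readr::problems(out)
  if (nrow(probs)) {
    abort(sprintf("%s file %s failed to parse at row %d, column %d (%s).",
                  what, path, probs$row[1], probs$col[1], probs$expected[1]))
  }
  if (!nrow(out)) abort(sprintf("%s file %s is empty.", what, path))
  out
}

#' @rdname pharmprev_io
#' @param path File path.
#' @return `read_dispensing_records()`: tibble `atc`, `n_units`, `strength`,
#'   `region`, `year`.
#' @export
read_dispensing_records <- function(path) {
  out <- read_checked(path, readr::cols(
    atc = readr::col_character(), n_units = readr::col_double(),
    strength = readr::col_double(), region = readr::col_character(),
    year = readr::col_integer()
  ), "Dispensing")
  assert_valid_atc(out$atc, what = "record code")
  bad <- which(out$n_units < 0 | out$strength <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Dispensing file %s: non-positive strength or negative units at row %d.",
      path, bad[1]))
  }
  out
}

#' @rdname pharmprev_io
#' @return `read_population()`: tibble `region`, `year`, `inhabitants`.
#' @export
read_population <- function(path) {
  out <- read_checked(path, readr::cols(
    region = readr::col_character(), year = readr::col_integer(),
    inhabitants = readr::col_double()
  ), "Population")
  bad <- which(!is.finite(out$inhabitants) | out$inhabitants <= 0)
  if (length(bad)) {
    abort(sprintf("Population file %s: inhabitants must be positive (row %d).",
                  path, bad[1]))
  }
  if (anyDuplicated(out[, c("region", "year")])) {
    abort(sprintf("Population file %s: duplicate (region, year) rows.", path))
  }
  out %>% mutate(region = trimws(.data$region))
}

#' @rdname pharmprev_io
#' @return `read_ddd_registry()`: a validated [ddd_registry()].
#' @export
read_ddd_registry <- function(path) {
  out <- read_checked(path, readr::cols(
    atc = readr::col_character(), ddd_quantity = readr::col_double(),
    ddd_unit = readr::col_character(), route = readr::col_character()
  ), "DDD registry")
  ddd_registry(out)
}

#' @rdname pharmprev_io
#' @details `read_model_params()` expects a flat key-value table with columns
#'   `key`, `value` and optional `year` (used for year-specific
#'   `undiagnosed_fraction` rows). Keys are the [model_params()] arguments;
#'   `pi2`, `pi3`, `pi4` rows may replace a `w` row.
#' @return `read_model_params()`: a [model_params()] object.
#' @export
read_model_params <- function(path) {
  out <- read_checked(path, readr::cols(
    key = readr::col_character(), value = readr::col_double()
  ), "Model parameter")
  args <- list()
  scalar_keys <- c("adherence_nad", "adherence_insulin", "w",
                   "insulin_t2dm_fraction")
  for (k in scalar_keys) {
    v <- out$value[out$key == k]
    if (length(v) > 1) abort(sprintf("Parameter `%s` given more than once.", k))
    if (length(v) == 1) args[[k]] <- v
  }
  pis <- vapply(c("pi2", "pi3", "pi4"),
                function(k) out$value[out$key == k][1], numeric(1))
  if (all(!is.na(pis))) {
    args$pis <- unname(pis)
    args$w <- NULL
  } else if (any(!is.na(pis))) {
    abort("Supply all of pi2, pi3, pi4 or none.")
  }
  u_rows <- out[out$key == "undiagnosed_fraction", ]
  if (nrow(u_rows)) {
    if ("year" %in% names(out) && !anyNA(u_rows$year)) {
      args$undiagnosed_fraction <- setNames(u_rows$value,
                                            as.character(u_rows$year))
    } else if (nrow(u_rows) == 1) {
      args$undiagnosed_fraction <- u_rows$value
    } else {
      abort("Multiple `undiagnosed_fraction` rows need a `year` column.")
    }
  }
  unknown <- setdiff(unique(out$key),
                     c(scalar_keys, "pi2", "pi3", "pi4",
                       "undiagnosed_fraction"))
  if (length(unknown)) {
    abort(sprintf("Unknown parameter key(s): %s.", toString(unknown)))
  }
  do.call(model_params, args)
}

# printed row order of the level-4 antidiabetic consumption report
.a10_report_order <- c("A10AB", "A10AC", "A10AD", "A10AE", "A10A",
                       "A10BA", "A10BB", "A10BD", "A10BF", "A10BG",
                       "A10BH", "A10BJ", "A10BK", "A10BX", "A10B", "A10")

#' Render report tables
#'
#' Writes up to three comma-delimited report files mirroring the standard
#' layouts: the level-4 consumption table (with class DIDs, their share of
#' total antidiabetic consumption, and the level-3 and total roll-ups, in the
#' conventional row order), the prevalence table (patient counts and one
#' decimal treated/overall percentages per scope and year), and the
#' sensitivity table (base row first). Reports carry full-precision companion
#' columns next to each rounded column and contain no timestamps, so identical
#' inputs give byte-identical files.
#'
#' @param estimates A `prevalence_estimate` from [run_model()], or `NULL`.
#' @param consumption A consumption table from [aggregate_consumption()], or
#'   `NULL`.
#' @param scenarios A `sensitivity_table` from [run_scenarios()], or `NULL`.
#' @param dir Output directory (created if needed).
#' @param precision Decimal places for reported percentages (default 1).
#' @return Invisibly, the paths written (named `consumption`, `prevalence`,
#'   `sensitivity`).
#' @export
render_reports <- function(estimates = NULL, consumption = NULL,
                           scenarios = NULL, dir = ".", precision = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  if (!is.null(consumption)) {
    check_columns(consumption, c("region", "year", "atc_class", "did"),
                  "consumption")
    # level-3 and total antidiabetic roll-ups appended to the level-4 rows;
    # assumes a single-level input table (as aggregate_consumption produces)
    a10 <- consumption %>%
      filter(substr(.data$atc_class, 1, 4) %in% c("A10A", "A10B"))
    roll3 <- a10 %>%
      group_by(.data$region, .data$year,
               atc_class = substr(.data$atc_class, 1, 4)) %>%
      summarise(across(dplyr::any_of(c("total_ddd", "did")), sum),
                .groups = "drop")
    roll_all <- roll3 %>%
      group_by(.data$region, .data$year) %>%
      summarise(across(dplyr::any_of(c("total_ddd", "did")), sum),
                .groups = "drop") %>%
      mutate(atc_class = "A10")
    totals <- roll_all %>%
      select("region", "year", total_did = "did")
    report <- bind_rows(consumption, roll3, roll_all) %>%
      left_join(totals, by = c("region", "year")) %>%
      mutate(
        share_pct = 100 * .data$did / .data$total_did,
        did_report = round_half_up(.data$did, precision),
        share_report = round_half_up(.data$share_pct, precision),
        .ord = match(.data$atc_class, .a10_report_order)
      ) %>%
      arrange(.data$region != "TOTAL", .data$region, .data$year,
              is.na(.data$.ord), .data$.ord, .data$atc_class) %>%
      select(-".ord")
    p <- file.path(dir, "consumption_report.csv")
    readr::write_csv(report, p)
    paths["consumption"] <- p
  }

  if (!is.null(estimates)) {
    check_columns(estimates, c("scope", "year", "patients_dm",
                               "patients_t2dm", "prev_treated_pct",
                               "prev_overall_pct"), "estimates")
    report <- as_tibble(estimates) %>%
      mutate(prev_treated_report = round_half_up(.data$prev_treated_pct,
                                                 precision),
             prev_overall_report = round_half_up(.data$prev_overall_pct,
                                                 precision))
    p <- file.path(dir, "prevalence_report.csv")
    readr::write_csv(report, p)
    paths["prevalence"] <- p
  }

  if (!is.null(scenarios)) {
    check_columns(scenarios, c("scenario", "varied", "scope", "year",
                               "prev_treated_pct", "prev_overall_pct"),
                  "scenarios")
    report <- as_tibble(scenarios) %>%
      mutate(
        prev_treated_report = round_half_up(.data$prev_treated_pct, precision),
        prev_overall_report = round_half_up(.data$prev_overall_pct, precision)
      ) %>%
      arrange(.data$scenario != "base")
    p <- file.path(dir, "sensitivity_report.csv")
    readr::write_csv(report, p)
    paths["sensitivity"] <- p
  }

  invisible(paths)
}
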