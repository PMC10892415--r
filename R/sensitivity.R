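#' Define a one-at-a-time sensitivity scenario
#'
#' A scenario overrides one (or more) model parameters while every other
#' parameter stays at its base-case value.
#'
#' @param name Scenario label.
#' @param ... Named overrides; names must be [model_params()] arguments
#'   (`adherence_nad`, `adherence_insulin`, `w`, `pis`,
#'   `insulin_t2dm_fraction`, `undiagnosed_fraction`).
#' @param years Optional years the scenario applies to (default: all).
#' @return A `pharmprev_scenario` list.
#' @examples
#' scenario("adherence 50%", adherence_nad = 0.50)
#' @export
scenario <- function(name, ..., years = NULL) {
  overrides <- list(...)
  if (!length(overrides)) abort("A scenario must override at least one parameter.")
  allowed <- setdiff(names(formals(model_params)), "")
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown) || is.null(names(overrides)) ||
      any(names(overrides) == "")) {
    abort(sprintf("Unknown or unnamed override(s): %s.",
                  toString(if (length(unknown)) unknown else "<unnamed>")))
  }
  structure(list(name = name, overrides = overrides, years = years),
            class = "pharmprev_scenario")
}

apply_overrides <- function(base_params, overrides) {
  args <- list(
    adherence_nad = base_params$adherence_nad,
    adherence_insulin = base_params$adherence_insulin,
    w = base_params$w,
    pis = base_params$pis,
    insulin_t2dm_fraction = base_params$insulin_t2dm_fraction,
    undiagnosed_fraction = base_params$undiagnosed_fraction
  )
  if (!is.null(args$pis)) args$w <- NULL
  if ("pis" %in% names(overrides)) args$w <- NULL
  if ("w" %in% names(overrides)) args$pis <- NULL
  args[names(overrides)] <- overrides
  do.call(model_params, args)
}

#' Run a one-at-a-time sensitivity analysis
#'
#' Re-runs the six-step model once per scenario, each time overriding only the
#' scenario's parameters; the base case is the first block of rows. For
#' scenarios that vary only the undiagnosed fraction, the treated columns are
#' by construction identical to base (the undiagnosed correction is the last
#' step); `varied` records which parameters moved.
#'
#' @inheritParams run_model
#' @param base_params Base-case [model_params()].
#' @param scenarios List of [scenario()] objects (may be empty: only the base
#'   row is returned).
#' @return A `sensitivity_table` tibble: `scenario`, `varied`, plus the
#'   [run_model()] columns.
#' @export
run_scenarios <- function(consumption, population,
                          base_params = model_params(),
                          scenarios = list(), scopes = NULL, years = NULL) {
  if (inherits(scenarios, "pharmprev_scenario")) scenarios <- list(scenarios)
  base <- run_model(consumption, population, base_params,
                    scopes = scopes, years = years)
  rows <- list(
    as_tibble(base) %>% mutate(scenario = "base", varied = "", .before = 1)
  )
  for (sc in scenarios) {
    if (!inherits(sc, "pharmprev_scenario")) {
      abort("`scenarios` must be a list of scenario() objects.")
    }
    est <- run_model(consumption, population,
                     apply_overrides(base_params, sc$overrides),
                     scopes = scopes,
                     years = if (is.null(sc$years)) years else sc$years)
    rows <- c(rows, list(
      as_tibble(est) %>%
        mutate(scenario = sc$name,
               varied = paste(sort(names(sc$overrides)), collapse = ","),
               .before = 1)
    ))
  }
  out <- bind_rows(rows)
  structure(out, base_params = base_params,
            class = c("sensitivity_table", class(out)))
}

#' Per-parameter outcome spread across scenarios
#'
#' For each varied parameter, the spread (max minus min, plus the extremes)
#' of the relevant outcome across its scenarios together with the base case:
#' the
#' treated-prevalence column for parameters acting before step 6, the overall
#' column for the undiagnosed fraction. Rows are ordered by decreasing spread,
#' ties broken alphabetically by parameter.
#'
#' @param table A `sensitivity_table` from [run_scenarios()].
#' @param scope,year Scope and year the spread is computed for (defaults:
#'   `"TOTAL"` and the first year present).
#' @return A `tornado_ranges` tibble: `parameter`, `outcome`, `min`, `max`,
#'   `spread`, `base`.
#' @export
tornado_ranges <- function(table, scope = "TOTAL", year = NULL) {
  check_columns(table, c("scenario", "varied", "scope", "year",
                         "prev_treated_pct", "prev_overall_pct"), "table")
  if (is.null(year)) year <- min(table$year)
  slice <- table %>%
    filter(.data$scope == !!scope, .data$year == !!year)
  if (!nrow(slice)) {
    abort(sprintf("No rows for scope %s, year %s.", scope, year))
  }
  base_row <- slice %>% filter(.data$scenario == "base")
  if (!nrow(base_row)) abort("`table` holds no base row for that slice.")

  varied <- slice %>%
    filter(.data$varied != "") %>%
    tidyr::separate_longer_delim("varied", delim = ",")
  if (!nrow(varied)) {
    out <- tibble(parameter = character(), outcome = character(),
                  min = numeric(), max = numeric(), spread = numeric(),
                  base = numeric())
    return(structure(out, class = c("tornado_ranges", class(out))))
  }

  out <- varied %>%
    mutate(
      outcome = ifelse(.data$varied == "undiagnosed_fraction",
                       "prev_overall_pct", "prev_treated_pct"),
      value = ifelse(.data$outcome == "prev_overall_pct",
                     .data$prev_overall_pct, .data$prev_treated_pct),
      base = ifelse(.data$outcome == "prev_overall_pct",
                    base_row$prev_overall_pct, base_row$prev_treated_pct)
    ) %>%
    group_by(parameter = .data$varied, .data$outcome, .data$base) %>%
    summarise(min = min(.data$value), max = max(.data$value),
              .groups = "drop") %>%
    mutate(min = pmin(.data$min, .data$base),
           max = pmax(.data$max, .data$base),
           spread = .data$max - .data$min) %>%
    select("parameter", "outcome", "min", "max", "spread", "base") %>%
    arrange(dplyr::desc(.data$spread), .data$parameter)
  structure(out, class = c("tornado_ranges", class(out)))
}

#' Tornado plot of sensitivity ranges
#'
#' @param object A `tornado_ranges` tibble.
#' @param ... Unused.
#' @return A ggplot with one horizontal bar per parameter spanning its
#'   scenario range, with the base-case value marked.
#' @export
autoplot.tornado_ranges <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(parameter = stats::reorder(.data$parameter, .data$spread))
  ggplot(dat, aes(y = .data$parameter)) +
    geom_segment(aes(x = .data$min, xend = .data$max,
                     yend = .data$parameter), linewidth = 4,
                 colour = "grey60") +
    geom_point(aes(x = .data$base), shape = 18, size = 3) +
    labs(x = "prevalence (%)", y = NULL,
         title = "One-at-a-time sensitivity of estimated prevalence") +
    theme_minimal()
}
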