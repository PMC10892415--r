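#' Total Defined Daily Doses implied by dispensing records
#'
#' Converts each aggregated sale line into the number of DDDs it represents:
#' `n_units * strength / ddd_quantity`. For fixed-dose combinations whose DDD
#' is expressed in unit doses (`UD`), the count of dose units is used directly:
#' `n_units / ddd_quantity`. `strength` must be expressed in the registry's
#' DDD unit for the code (mg or IU).
#'
#' @param records Data frame of dispensing records with columns `atc`
#'   (level-5 code), `n_units` (dose units dispensed, >= 0), `strength`
#'   (content per dose unit, > 0), `region`, `year`.
#' @param registry A [ddd_registry()].
#' @param permissive If `FALSE` (default) a record whose ATC code has no
#'   registry entry is an error. If `TRUE`, such records are dropped with a
#'   warning; the number of skipped records and their summed units are
#'   reported and attached as attribute `"skipped"`.
#' @return The records as a tibble with a `total_ddd` column appended.
#' @examples
#' reg <- ddd_registry(data.frame(
#'   atc = "A10BA02", ddd_quantity = 2000, ddd_unit = "mg", route = "oral"
#' ))
#' rec <- data.frame(atc = "A10BA02", n_units = 10000, strength = 500,
#'                   region = "PT", year = 2018)
#' record_total_ddd(rec, reg)$total_ddd # 2500
#' @export
record_total_ddd <- function(records, registry, permissive = FALSE) {
  check_columns(records, c("atc", "n_units", "strength", "region", "year"),
                "records")
  check_columns(registry, c("atc", "ddd_quantity", "ddd_unit"), "registry")
  records <- as_tibble(records)
  assert_valid_atc(records$atc, what = "record code")
  if (any(records$n_units < 0, na.rm = FALSE) || anyNA(records$n_units)) {
    abort("`n_units` must be non-negative and non-missing.")
  }
  if (any(!is.finite(records$strength) | records$strength <= 0)) {
    abort("`strength` must be positive and finite.")
  }

  unknown <- setdiff(unique(records$atc), registry$atc)
  skipped <- tibble(n_records = 0L, n_units = 0)
  if (length(unknown)) {
    if (!permissive) {
      abort(sprintf("No DDD entry for ATC code%s: %s.",
                    if (length(unknown) > 1) "s" else "", toString(unknown)),
            class = "pharmprev_missing_ddd")
    }
    drop <- records$atc %in% unknown
    skipped <- tibble(n_records = sum(drop), n_units = sum(records$n_units[drop]))
    warn(sprintf(
      "Skipping %d record(s) (%.0f units) with no DDD entry: %s.",
      skipped$n_records, skipped$n_units, toString(unknown)
    ))
    records <- records[!drop, , drop = FALSE]
  }

  out <- records %>%
    left_join(registry[, c("atc", "ddd_quantity", "ddd_unit")], by = "atc") %>%
    mutate(total_ddd = ifelse(
      .data$ddd_unit == "UD",
      .data$n_units / .data$ddd_quantity,
      .data$n_units * .data$strength / .data$ddd_quantity
    )) %>%
    select(-"ddd_quantity", -"ddd_unit")
  attr(out, "skipped") <- skipped
  out
}

#' DDD per 1000 inhabitants per day
#'
#' The standard population-normalized consumption rate:
#' `total_ddd * 1000 / (inhabitants * days)`. A DID of `x` means roughly `x`
#' per 1000 inhabitants receive the standard daily dose of the drug each day.
#'
#' @param total_ddd Total DDDs consumed over the period (non-negative).
#' @param inhabitants Population size (positive).
#' @param days Length of the period in days; fixed at 365 by convention
#'   regardless of calendar year.
#' @return Numeric vector of DID values.
#' @examples
#' did(365000, 1000) # the whole population on one DDD/day -> 1000
#' @export
did <- function(total_ddd, inhabitants, days = 365) {
  if (any(total_ddd < 0)) abort("`total_ddd` must be non-negative.")
  if (any(inhabitants <= 0)) abort("`inhabitants` must be positive.")
  if (any(days <= 0)) abort("`days` must be positive.")
  total_ddd * 1000 / (inhabitants * days)
}

#' Aggregate dispensing records into a consumption table
#'
#' Sums total DDDs by region, year and ATC class (at the requested hierarchy
#' level) and computes DID against the matching population. A `"TOTAL"` row
#' per (year, class) sums the regional DDDs and divides by the summed
#' population -- the national DID is a population-weighted quantity, not the
#' mean of regional DIDs.
#'
#' @inheritParams record_total_ddd
#' @param population Data frame with columns `region`, `year`, `inhabitants`
#'   (one row per region-year). Every record's region-year must be present.
#' @param level ATC hierarchy level for the class column (default 4, the
#'   chemical-subgroup reporting level; the prevalence model uses the level-3
#'   insulin/NAD split via [classify_ad()]).
#' @param coverage_factor Multiplicative correction applied to total DDDs for
#'   partial market coverage of the source database (default 1: the records
#'   are taken at face value).
#' @param days Days in the accounting period (default 365).
#' @return Tibble with columns `region`, `year`, `atc_class`, `total_ddd`,
#'   `did`, including the `"TOTAL"` rows.
#' @export
aggregate_consumption <- function(records, registry, population, level = 4,
                                  coverage_factor = 1, permissive = FALSE,
                                  days = 365) {
  check_columns(population, c("region", "year", "inhabitants"), "population")
  if (!is.numeric(coverage_factor) || length(coverage_factor) != 1 ||
      coverage_factor <= 0) {
    abort("`coverage_factor` must be a single positive number.")
  }
  population <- as_tibble(population) %>%
    mutate(region = trimws(.data$region))
  if (any(population$inhabitants <= 0)) {
    abort("`inhabitants` must be positive for every population row.")
  }
  if (anyDuplicated(population[, c("region", "year")])) {
    abort("Duplicate (region, year) rows in `population`.")
  }

  with_ddd <- record_total_ddd(records, registry, permissive = permissive) %>%
    mutate(region = trimws(.data$region))

  missing_pop <- with_ddd %>%
    distinct(.data$region, .data$year) %>%
    anti_join(population, by = c("region", "year"))
  if (nrow(missing_pop)) {
    abort(sprintf(
      "No population entry for: %s.",
      toString(paste0(missing_pop$region, "/", missing_pop$year))
    ))
  }

  regional <- with_ddd %>%
    mutate(atc_class = atc_level(.data$atc, level),
           total_ddd = .data$total_ddd * coverage_factor) %>%
    group_by(.data$region, .data$year, .data$atc_class) %>%
    summarise(total_ddd = sum(.data$total_ddd), .groups = "drop") %>%
    left_join(population, by = c("region", "year"))

  national <- regional %>%
    group_by(.data$year, .data$atc_class) %>%
    summarise(total_ddd = sum(.data$total_ddd), .groups = "drop") %>%
    left_join(
      population %>%
        group_by(.data$year) %>%
        summarise(inhabitants = sum(.data$inhabitants), .groups = "drop"),
      by = "year"
    ) %>%
    mutate(region = "TOTAL")

  bind_rows(regional, national) %>%
    mutate(did = did(.data$total_ddd, .data$inhabitants, days = days)) %>%
    select("region", "year", "atc_class", "total_ddd", "did") %>%
    arrange(.data$region != "TOTAL", .data$region, .data$year, .data$atc_class)
}
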