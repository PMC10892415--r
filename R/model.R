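#' Parameters of the six-step prevalence model
#'
#' Bundles the five adjustable quantities of the sequential estimator.
#' Defaults are the base-case values: 60% adherence for non-insulin
#' antidiabetics (NADs), 100% for insulins, concomitance weight factor
#' w = 0.608 (Portuguese cross-sectional survey), 7.5% insulin-user fraction,
#' and undiagnosed fractions of 44% (2018) and 35.7% (2021).
#'
#' Exactly one of `w` and `pis` may be supplied; when `pis` is given, `w` is
#' computed from the polytherapy shares via [weight_factor()].
#'
#' @param adherence_nad Fraction of prescribed NAD dosing actually consumed,
#'   in (0, 1]. Partial adherence means observed consumption under-counts
#'   patients, so the model divides by it.
#' @param adherence_insulin Same for insulins; base case 1.00.
#' @param w Concomitance weight factor in (0, 1] converting drug-class
#'   patient-equivalents into persons when patients combine NAD classes.
#' @param pis Optional numeric vector `c(pi2, pi3, pi4)` of probabilities of
#'   taking two, three or four NADs simultaneously; overrides `w`.
#' @param insulin_t2dm_fraction Fraction of insulin-derived patient counts
#'   retained as Type 2 insulin users (base 0.075); the remainder are excluded
#'   as insulin-only / non-T2DM users.
#' @param undiagnosed_fraction Share of true cases that are undiagnosed, in
#'   [0, 1). Either a single value or a vector named by year, e.g.
#'   `c("2018" = 0.44, "2021" = 0.357)` (the default).
#' @return A `model_params` list.
#' @examples
#' model_params()
#' model_params(w = NULL, pis = c(0.28, 0.19, 0.07))
#' @export
model_params <- function(adherence_nad = 0.60,
                         adherence_insulin = 1.00,
                         w = 0.608,
                         pis = NULL,
                         insulin_t2dm_fraction = 0.075,
                         undiagnosed_fraction = c("2018" = 0.44,
                                                  "2021" = 0.357)) {
  check_scalar_prob(adherence_nad, "adherence_nad", lower_open = TRUE)
  check_scalar_prob(adherence_insulin, "adherence_insulin", lower_open = TRUE)
  if (!is.null(pis)) {
    if (!is.null(w) && !identical(w, formals(model_params)$w)) {
      abort("Supply exactly one of `w` and `pis`, not both.")
    }
    if (length(pis) != 3) abort("`pis` must be c(pi2, pi3, pi4).")
    w <- weight_factor(pis[1], pis[2], pis[3])
  }
  check_scalar_prob(w, "w", lower_open = TRUE)
  check_scalar_prob(insulin_t2dm_fraction, "insulin_t2dm_fraction")
  if (!is.numeric(undiagnosed_fraction) || !length(undiagnosed_fraction) ||
      any(undiagnosed_fraction < 0 | undiagnosed_fraction >= 1)) {
    abort("`undiagnosed_fraction` must be in [0, 1).")
  }
  structure(
    list(
      adherence_nad = adherence_nad,
      adherence_insulin = adherence_insulin,
      w = w,
      pis = pis,
      insulin_t2dm_fraction = insulin_t2dm_fraction,
      undiagnosed_fraction = undiagnosed_fraction
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Six-step prevalence model parameters\n")
  cat(sprintf("  adherence (NAD / insulin): %.3g / %.3g\n",
              x$adherence_nad, x$adherence_insulin))
  cat(sprintf("  concomitance weight w:     %.4g%s\n", x$w,
              if (!is.null(x$pis)) " (from pi2..pi4)" else ""))
  cat(sprintf("  insulin T2DM fraction f:   %.3g\n", x$insulin_t2dm_fraction))
  u <- x$undiagnosed_fraction
  cat(sprintf("  undiagnosed fraction u:    %s\n",
              paste(if (is.null(names(u))) format(u)
                    else paste0(names(u), "=", u), collapse = ", ")))
  invisible(x)
}

# pick the undiagnosed fraction for a year (named lookup, or the single value)
u_for_year <- function(params, year) {
  u <- params$undiagnosed_fraction
  if (is.null(names(u)) || all(names(u) == "")) {
    if (length(u) != 1) abort("Unnamed `undiagnosed_fraction` must be scalar.")
    return(unname(u))
  }
  hit <- u[as.character(year)]
  if (anyNA(hit)) {
    abort(sprintf("No `undiagnosed_fraction` supplied for year %s.",
                  toString(year[is.na(hit)])))
  }
  unname(hit)
}

#' Concomitance weight factor from polytherapy shares
#'
#' Converts drug-class patient-equivalents into persons when patients take
#' several NAD classes at once: `w = 1 / (1 + pi2 + 2*pi3 + 3*pi4)`, where
#' `pi_k` is the probability that a treated patient takes `k` drug classes
#' simultaneously. All-monotherapy gives w = 1; everyone on two drugs gives
#' w = 0.5.
#'
#' @param pi2,pi3,pi4 Probabilities of two-, three- and four-drug regimens;
#'   non-negative, summing to at most 1.
#' @return The weight factor in (0, 1].
#' @examples
#' weight_factor(0, 0, 0)        # 1
#' weight_factor(0.28, 0.19, 0.07)
#' @export
weight_factor <- function(pi2, pi3, pi4) {
  p <- c(pi2, pi3, pi4)
  if (length(p) != 3 || any(!is.finite(p)) || any(p < 0)) {
    abort("`pi2`, `pi3`, `pi4` must be non-negative numbers.")
  }
  if (sum(p) > 1 + 1e-12) {
    abort("`pi2 + pi3 + pi4` must not exceed 1.")
  }
  1 / (1 + pi2 + 2 * pi3 + 3 * pi4)
}

#' Step 1: patients implied by a DID level
#'
#' A DID of `x` means `x` DDDs dispensed per 1000 inhabitants per day, i.e.
#' `x * inhabitants / 1000` persons consuming exactly one DDD per day.
#'
#' @param did DID value(s), non-negative.
#' @param inhabitants Population size(s), positive.
#' @return Patient-equivalents (real-valued).
#' @export
patients_from_did <- function(did, inhabitants) {
  if (any(did < 0)) abort("`did` must be non-negative.")
  if (any(inhabitants <= 0)) abort("`inhabitants` must be positive.")
  did * inhabitants / 1000
}

#' Step 2: adjust patient counts for partial adherence
#'
#' Observed consumption reflects only the dispensed fraction of prescribed
#' dosing, so the patient count behind it is inflated by dividing by the
#' adherence rate.
#'
#' @param patients Patient-equivalents, non-negative.
#' @param adherence Adherence rate in (0, 1].
#' @return Adjusted patient counts.
#' @export
adjust_adherence <- function(patients, adherence) {
  if (any(patients < 0)) abort("`patients` must be non-negative.")
  if (any(adherence <= 0 | adherence > 1)) {
    abort("`adherence` must be in (0, 1].")
  }
  patients / adherence
}

#' Step 3: collapse polytherapy with the concomitance weight
#'
#' @param patients NAD patient-class-equivalents, non-negative.
#' @param w Weight factor in (0, 1]; see [weight_factor()].
#' @return Persons after accounting for multi-drug regimens.
#' @export
apply_concomitance <- function(patients, w) {
  if (any(patients < 0)) abort("`patients` must be non-negative.")
  if (any(w <= 0 | w > 1)) abort("`w` must be in (0, 1].")
  patients * w
}

#' Step 4: retain the Type 2 share of insulin-derived patients
#'
#' Insulin consumption also reflects Type 1 diabetes and insulin-only users,
#' who are excluded; the fraction `f` of insulin-derived patient counts is
#' re-admitted as Type 2 insulin users and added to the adjusted NAD count.
#'
#' @param nad_patients_adj NAD persons after steps 1-3.
#' @param insulin_patients Insulin persons after steps 1-2.
#' @param f Retained Type 2 fraction in [0, 1].
#' @return Persons in treatment for Type 2 diabetes.
#' @export
t2dm_treated <- function(nad_patients_adj, insulin_patients, f) {
  if (any(nad_patients_adj < 0) || any(insulin_patients < 0)) {
    abort("Patient counts must be non-negative.")
  }
  if (any(f < 0 | f > 1)) abort("`f` must be in [0, 1].")
  nad_patients_adj + f * insulin_patients
}

#' Patients in treatment for diabetes of any type
#'
#' @inheritParams t2dm_treated
#' @return Sum of the NAD-adjusted and insulin-derived counts.
#' @export
patients_dm_total <- function(nad_patients_adj, insulin_patients) {
  if (any(nad_patients_adj < 0) || any(insulin_patients < 0)) {
    abort("Patient counts must be non-negative.")
  }
  nad_patients_adj + insulin_patients
}

#' Step 5: treated prevalence as a percentage of the population
#'
#' @param patients_t2dm Persons in treatment for Type 2 diabetes.
#' @param inhabitants Population size, positive.
#' @return Percentage (0-100 scale).
#' @export
prevalence_treated <- function(patients_t2dm, inhabitants) {
  if (any(patients_t2dm < 0)) abort("`patients_t2dm` must be non-negative.")
  if (any(inhabitants <= 0)) abort("`inhabitants` must be positive.")
  100 * patients_t2dm / inhabitants
}

#' Step 6: inflate treated prevalence by the undiagnosed fraction
#'
#' If a fraction `u` of true cases is undiagnosed (hence untreated), overall
#' prevalence is the treated prevalence divided by `1 - u`.
#'
#' @param prev_treated_pct Treated prevalence, percent.
#' @param u Undiagnosed fraction in [0, 1).
#' @return Overall prevalence, percent.
#' @export
prevalence_overall <- function(prev_treated_pct, u) {
  if (any(prev_treated_pct < 0)) abort("Prevalence must be non-negative.")
  if (any(u < 0 | u >= 1)) abort("`u` must be in [0, 1).")
  prev_treated_pct / (1 - u)
}

#' Run the six-step prevalence estimator
#'
#' Chains, per scope (region or `"TOTAL"`) and year:
#' DID-implied patient counts (step 1), adherence adjustment for NADs and
#' insulins separately (step 2), concomitance weighting of the NAD side
#' (step 3), exclusion of non-T2DM insulin users with re-admission of the
#' fraction `f` (step 4), treated prevalence (step 5), and the
#' undiagnosed-fraction correction (step 6).
#'
#' @param consumption Consumption table as produced by
#'   [aggregate_consumption()]: columns `region`, `year`, `atc_class`, `did`
#'   (any ATC level; classes are mapped to insulin/NAD via [classify_ad()] and
#'   summed). Both an insulin (`A10A...`) and a NAD (`A10B...`) cell must be
#'   present for every scope-year; scopes without A10 consumption at all are
#'   not estimated.
#' @param population Data frame `region`, `year`, `inhabitants`. The
#'   `"TOTAL"` scope uses the summed population per year unless an explicit
#'   `"TOTAL"` row is supplied.
#' @param params A [model_params()] object.
#' @param scopes,years Optional filters on the scopes and years estimated;
#'   default: everything present in `consumption`.
#' @return A `prevalence_estimate` tibble with full-precision columns
#'   `patients_dm`, `patients_t2dm`, `prev_treated_pct`, `prev_overall_pct`
#'   and one-decimal, half-up-rounded report columns `prev_treated_report`,
#'   `prev_overall_report`.
#' @examples
#' cons <- tibble::tibble(
#'   region = "TOTAL", year = 2018,
#'   atc_class = c("A10A", "A10B"), did = c(15.5, 75.4)
#' )
#' pop <- tibble::tibble(region = "PT", year = 2018, inhabitants = 10276617)
#' run_model(cons, pop, model_params())
#' @export
run_model <- function(consumption, population, params = model_params(),
                      scopes = NULL, years = NULL) {
  check_columns(consumption, c("region", "year", "atc_class", "did"),
                "consumption")
  check_columns(population, c("region", "year", "inhabitants"), "population")
  if (!inherits(params, "model_params")) {
    abort("`params` must be a model_params() object.")
  }
  consumption <- as_tibble(consumption)
  population <- as_tibble(population)
  if (any(population$inhabitants <= 0)) {
    abort("`inhabitants` must be positive.")
  }

  # explicit TOTAL rows win; otherwise the TOTAL population is the sum
  pop_all <- if ("TOTAL" %in% population$region) population else bind_rows(
    population,
    population %>%
      group_by(.data$year) %>%
      summarise(inhabitants = sum(.data$inhabitants), .groups = "drop") %>%
      mutate(region = "TOTAL")
  )

  by_class <- consumption %>%
    mutate(class = classify_ad(.data$atc_class)) %>%
    filter(.data$class %in% c("insulin", "nad")) %>%
    group_by(.data$region, .data$year, .data$class) %>%
    summarise(did = sum(.data$did), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "did")
  if (!nrow(by_class)) abort("`consumption` holds no A10A or A10B cells.")
  for (col in c("insulin", "nad")) {
    if (!col %in% names(by_class)) by_class[[col]] <- NA_real_
  }
  incomplete <- by_class %>%
    filter(is.na(.data$insulin) | is.na(.data$nad))
  if (nrow(incomplete)) {
    abort(sprintf(
      "Missing insulin or NAD consumption cell for: %s.",
      toString(paste0(incomplete$region, "/", incomplete$year))
    ))
  }
  if (!is.null(scopes)) by_class <- filter(by_class, .data$region %in% scopes)
  if (!is.null(years)) by_class <- filter(by_class, .data$year %in% years)
  if (!nrow(by_class)) abort("No scope/year left after filtering.")

  joined <- by_class %>%
    left_join(pop_all, by = c("region", "year"))
  if (anyNA(joined$inhabitants)) {
    bad <- joined %>% filter(is.na(.data$inhabitants))
    abort(sprintf("No population entry for: %s.",
                  toString(paste0(bad$region, "/", bad$year))))
  }

  out <- joined %>%
    mutate(
      u = u_for_year(params, .data$year),
      nad_adj = apply_concomitance(
        adjust_adherence(
          patients_from_did(.data$nad, .data$inhabitants),
          params$adherence_nad
        ),
        params$w
      ),
      insulin_patients = adjust_adherence(
        patients_from_did(.data$insulin, .data$inhabitants),
        params$adherence_insulin
      ),
      patients_dm = patients_dm_total(.data$nad_adj, .data$insulin_patients),
      patients_t2dm = t2dm_treated(.data$nad_adj, .data$insulin_patients,
                                   params$insulin_t2dm_fraction),
      prev_treated_pct = prevalence_treated(.data$patients_t2dm,
                                            .data$inhabitants),
      prev_overall_pct = prevalence_overall(.data$prev_treated_pct, .data$u),
      prev_treated_report = round_half_up(.data$prev_treated_pct, 1),
      prev_overall_report = round_half_up(.data$prev_overall_pct, 1)
    ) %>%
    rename(scope = "region") %>%
    select("scope", "year", "inhabitants", "patients_dm", "patients_t2dm",
           "prev_treated_pct", "prev_overall_pct",
           "prev_treated_report", "prev_overall_report") %>%
    arrange(.data$scope != "TOTAL", .data$scope, .data$year)

  structure(out, params = params,
            class = c("prevalence_estimate", class(out)))
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat("Indirect T2DM prevalence estimates (drug-consumption model)\n")
  NextMethod()
}

#' Tidy a prevalence estimate into long form
#'
#' @param x A `prevalence_estimate` from [run_model()].
#' @param ... Unused.
#' @return Long tibble with `scope`, `year`, `quantity`, `estimate`.
#' @export
tidy.prevalence_estimate <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(
      c("patients_dm", "patients_t2dm", "prev_treated_pct",
        "prev_overall_pct"),
      names_to = "quantity", values_to = "estimate"
    ) %>%
    select("scope", "year", "quantity", "estimate")
}

#' One-row summary of a prevalence estimate run
#'
#' @param x A `prevalence_estimate`.
#' @param ... Unused.
#' @return Tibble with the parameter values used and the scope/year counts.
#' @export
glance.prevalence_estimate <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_scopes = dplyr::n_distinct(x$scope),
    n_years = dplyr::n_distinct(x$year),
    adherence_nad = p$adherence_nad,
    adherence_insulin = p$adherence_insulin,
    w = p$w,
    insulin_t2dm_fraction = p$insulin_t2dm_fraction
  )
}

#' Plot treated and overall prevalence estimates
#'
#' @param object A `prevalence_estimate`.
#' @param ... Unused.
#' @return A ggplot: prevalence by year, faceted by scope, treated and overall
#'   side by side.
#' @export
autoplot.prevalence_estimate <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("prev_treated_pct", "prev_overall_pct"),
                        names_to = "measure", values_to = "prevalence") %>%
    mutate(measure = ifelse(.data$measure == "prev_treated_pct",
                            "treated", "overall"))
  ggplot(long, aes(x = factor(.data$year), y = .data$prevalence,
                   fill = .data$measure)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~scope) +
    labs(x = "year", y = "prevalence (%)", fill = NULL,
         title = "T2DM prevalence estimated from antidiabetic consumption") +
    theme_minimal()
}
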