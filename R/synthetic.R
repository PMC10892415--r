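#' Configure a synthetic cohort
#'
#' Describes a population with known diabetes structure from which dispensing
#' records can be simulated, providing ground truth for parameter-recovery
#' tests of the prevalence model. The generative split of the Type 2
#' population is: a fraction `1 - undiagnosed_fraction` of T2DM cases is
#' diagnosed and treated with non-insulin antidiabetics (NADs); insulin-treated
#' T2DM users are added as `insulin_t2dm_fraction` of the NAD-treated count;
#' the remainder of the T2DM population is undiagnosed. Type 1 cases are
#' insulin-only. Regimen sizes (1-4 concurrent NAD classes) follow
#' `regimen_probs`.
#'
#' @param n_pop Population size (default 100,000).
#' @param true_prevalence Overall T2DM prevalence in [0, 1); default 0.139,
#'   the 2018 national estimate.
#' @param undiagnosed_fraction Undiagnosed share parameter in [0, 1); default
#'   0.44 (2018 base case). Note the realized undiagnosed share of the cohort
#'   is `1 - (1-u)(1+f)`, slightly below `u`, because insulin users are
#'   generated on top of the NAD-treated block.
#' @param insulin_t2dm_fraction Insulin-treated T2DM users as a fraction of
#'   the NAD-treated count; default 0.075.
#' @param t1dm_prevalence Type 1 diabetes prevalence; default 0.005, so the
#'   insulin-only exclusion of the model is non-trivially exercised.
#' @param regimen_probs Probabilities of 1-4 concurrent NAD classes
#'   (`pi1..pi4`), summing to 1; default `c(0.46, 0.28, 0.19, 0.07)`,
#'   treatment-line shares from a multi-country European prescription-pattern
#'   study.
#' @param adherence_nad,adherence_insulin Fractions of the 365 yearly DDDs
#'   actually dispensed; defaults 0.60 and 1.00 (base case).
#' @param regions Named numeric vector of region population shares summing
#'   to 1; default `c(PT = 1)`.
#' @param year Calendar year stamped on the records (default 2018).
#' @param mode `"deterministic"` (largest-remainder apportionment of all
#'   counts, exact expected consumption) or `"stochastic"` (multinomial
#'   statuses, sampled regimens, binomial thinning of DDD-days).
#' @param pack_size Optional pack quantization: dispensed units are rounded up
#'   to whole packs of this many units per person-drug (default `NULL`, off).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_pop = 100000,
                          true_prevalence = 0.139,
                          undiagnosed_fraction = 0.44,
                          insulin_t2dm_fraction = 0.075,
                          t1dm_prevalence = 0.005,
                          regimen_probs = c(0.46, 0.28, 0.19, 0.07),
                          adherence_nad = 0.60,
                          adherence_insulin = 1.00,
                          regions = c(PT = 1),
                          year = 2018,
                          mode = c("deterministic", "stochastic"),
                          pack_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_pop >= 1)
  check_scalar_prob(true_prevalence, "true_prevalence", upper_open = TRUE)
  check_scalar_prob(undiagnosed_fraction, "undiagnosed_fraction",
                    upper_open = TRUE)
  check_scalar_prob(insulin_t2dm_fraction, "insulin_t2dm_fraction")
  check_scalar_prob(t1dm_prevalence, "t1dm_prevalence", upper_open = TRUE)
  check_scalar_prob(adherence_nad, "adherence_nad", lower_open = TRUE)
  check_scalar_prob(adherence_insulin, "adherence_insulin", lower_open = TRUE)
  if (length(regimen_probs) != 4 || any(regimen_probs < 0) ||
      abs(sum(regimen_probs) - 1) > 1e-8) {
    abort("`regimen_probs` must be four non-negative shares summing to 1.")
  }
  if (is.null(names(regions)) || any(regions <= 0) ||
      abs(sum(regions) - 1) > 1e-8) {
    abort("`regions` must be a named vector of positive shares summing to 1.")
  }
  u <- undiagnosed_fraction
  f <- insulin_t2dm_fraction
  if ((1 - u) * (1 + f) > 1 + 1e-12) {
    abort("Infeasible split: (1 - u) * (1 + f) exceeds 1, the insulin top-up outgrows the T2DM population.")
  }
  if (true_prevalence + t1dm_prevalence >= 1) {
    abort("`true_prevalence + t1dm_prevalence` must be below 1.")
  }
  if (!is.null(pack_size) && (pack_size < 1 || pack_size != round(pack_size))) {
    abort("`pack_size` must be a positive whole number.")
  }
  structure(
    list(n_pop = as.integer(n_pop), true_prevalence = true_prevalence,
         undiagnosed_fraction = u, insulin_t2dm_fraction = f,
         t1dm_prevalence = t1dm_prevalence, regimen_probs = regimen_probs,
         adherence_nad = adherence_nad, adherence_insulin = adherence_insulin,
         regions = regions, year = year, mode = mode, pack_size = pack_size),
    class = "cohort_config"
  )
}

# integer apportionment of `total` over expected shares: floor, then hand the
# leftover units to the largest fractional parts (stable on ties)
largest_remainder <- function(weights, total) {
  if (total == 0) return(rep(0L, length(weights)))
  expected <- weights / sum(weights) * total
  counts <- floor(expected)
  short <- total - sum(counts)
  if (short > 0) {
    frac <- expected - counts
    top <- order(-frac, seq_along(frac))[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

.statuses <- c("healthy", "t2dm_undiagnosed", "t2dm_nad", "t2dm_insulin",
               "t1dm")

status_probs <- function(config) {
  prev <- config$true_prevalence
  u <- config$undiagnosed_fraction
  f <- config$insulin_t2dm_fraction
  p_nad <- prev * (1 - u)
  p_ins <- p_nad * f
  p_undiag <- prev - p_nad - p_ins
  p_t1 <- config$t1dm_prevalence
  setNames(c(1 - prev - p_t1, p_undiag, p_nad, p_ins, p_t1), .statuses)
}

# split registry formulary into NAD codes per level-4 class, and insulin codes
formulary_split <- function(registry) {
  cls <- classify_ad(registry$atc)
  nad <- registry$atc[cls == "nad"]
  list(
    nad_by_class = split(nad, atc_level(nad, 4)),
    insulin = registry$atc[cls == "insulin"]
  )
}

#' Generate a person-level synthetic cohort
#'
#' Draws (or, in deterministic mode, apportions exactly) person statuses,
#' regions, regimen sizes and drug codes per the configuration. NAD-treated
#' persons carry 1-4 distinct level-4 NAD classes (never two drugs of the
#' same chemical subgroup); insulin statuses carry exactly one insulin code.
#'
#' @param config A [cohort_config()].
#' @param registry A [ddd_registry()] providing the formulary; needs at least
#'   four NAD level-4 classes and one insulin code.
#' @return Tibble of persons: `id`, `status`, `region`, `n_drugs`, `regimen`
#'   (list-column of ATC codes).
#' @export
generate_cohort <- function(config, registry) {
  stopifnot(inherits(config, "cohort_config"))
  form <- formulary_split(registry)
  classes <- names(form$nad_by_class)
  if (length(classes) < 4 && config$regimen_probs[4] > 0 ||
      length(classes) < 1) {
    abort("Registry formulary has too few NAD level-4 classes for the regimen sizes requested.")
  }
  if (!length(form$insulin) &&
      (config$insulin_t2dm_fraction > 0 || config$t1dm_prevalence > 0)) {
    abort("Registry formulary has no insulin codes.")
  }

  probs <- status_probs(config)
  n <- config$n_pop
  counts <- if (config$mode == "deterministic") {
    largest_remainder(probs, n)
  } else {
    as.integer(rmultinom(1, n, probs))
  }
  status <- rep(.statuses, counts)

  # regions assigned within each status block so regional structure is
  # independent of disease status
  region <- unlist(lapply(counts, function(k) {
    if (k == 0) return(character())
    if (config$mode == "deterministic") {
      rep(names(config$regions), largest_remainder(config$regions, k))
    } else {
      sample(names(config$regions), k, replace = TRUE,
             prob = config$regions)
    }
  }), use.names = FALSE)

  n_drugs <- integer(n)
  is_nad <- status == "t2dm_nad"
  n_nad <- sum(is_nad)
  if (n_nad) {
    n_drugs[is_nad] <- if (config$mode == "deterministic") {
      rep(1:4, largest_remainder(config$regimen_probs, n_nad))
    } else {
      sample(1:4, n_nad, replace = TRUE, prob = config$regimen_probs)
    }
  }
  uses_insulin <- status %in% c("t2dm_insulin", "t1dm")
  n_drugs[uses_insulin] <- 1L

  regimen <- vector("list", n)
  if (n_nad) {
    idx_nad <- which(is_nad)
    k_i <- n_drugs[idx_nad]
    if (config$mode == "deterministic") {
      # cycle class combinations so drug identity is reproducible without RNG
      regimen[idx_nad] <- lapply(seq_along(idx_nad), function(i) {
        k <- k_i[i]
        cls <- classes[((i - 1 + seq_len(k) - 1) %% length(classes)) + 1]
        vapply(cls, function(cl) form$nad_by_class[[cl]][1], character(1),
               USE.NAMES = FALSE)
      })
    } else {
      regimen[idx_nad] <- lapply(k_i, function(k) {
        cls <- sample(classes, k)
        vapply(cls, function(cl) {
          drugs <- form$nad_by_class[[cl]]
          drugs[sample.int(length(drugs), 1)]
        }, character(1), USE.NAMES = FALSE)
      })
    }
  }
  if (any(uses_insulin)) {
    idx_ins <- which(uses_insulin)
    if (config$mode == "deterministic") {
      regimen[idx_ins] <- as.list(
        form$insulin[((seq_along(idx_ins) - 1) %% length(form$insulin)) + 1]
      )
    } else {
      regimen[idx_ins] <- as.list(
        form$insulin[sample.int(length(form$insulin), length(idx_ins),
                                replace = TRUE)]
      )
    }
  }

  tibble(id = seq_len(n), status = status, region = region,
         n_drugs = n_drugs, regimen = regimen)
}

#' Simulate dispensing records from a cohort
#'
#' Each treated person contributes, per drug in their regimen,
#' `adherence * 365` DDD-equivalents of dispensed units over the year
#' (deterministic mode), or a Binomial(365, adherence) number of DDD-days
#' (stochastic mode). Output is aggregated to one row per (ATC code, region),
#' in the dispensing-record schema consumed by [aggregate_consumption()].
#'
#' @param persons Cohort tibble from [generate_cohort()].
#' @param registry The [ddd_registry()] used to generate the cohort.
#' @param config The generating [cohort_config()].
#' @return Tibble of dispensing records: `atc`, `n_units`, `strength`,
#'   `region`, `year`.
#' @export
simulate_dispensing <- function(persons, registry, config) {
  stopifnot(inherits(config, "cohort_config"))
  check_columns(persons, c("status", "region", "regimen"), "persons")
  treated <- persons %>%
    filter(.data$status %in% c("t2dm_nad", "t2dm_insulin", "t1dm"))
  if (!nrow(treated)) {
    return(tibble(atc = character(), n_units = numeric(),
                  strength = numeric(), region = character(),
                  year = integer()))
  }

  long <- treated %>%
    select("status", "region", "regimen") %>%
    tidyr::unnest_longer("regimen", values_to = "atc") %>%
    mutate(adherence = ifelse(.data$status == "t2dm_nad",
                              config$adherence_nad,
                              config$adherence_insulin))
  missing <- setdiff(unique(long$atc), registry$atc)
  if (length(missing)) {
    abort(sprintf("Regimen code(s) missing from registry: %s.",
                  toString(missing)), class = "pharmprev_missing_ddd")
  }

  long$ddd_days <- if (config$mode == "deterministic") {
    long$adherence * 365
  } else {
    rbinom(nrow(long), 365, long$adherence)
  }

  long <- long %>%
    left_join(as_tibble(registry)[, c("atc", "ddd_quantity", "ddd_unit")],
              by = "atc") %>%
    mutate(
      # one dispensed unit carries one DDD worth of drug, so totals invert
      # exactly through Eq. 1; UD-denominated DDDs need ddd_quantity units/day
      units = ifelse(.data$ddd_unit == "UD",
                     .data$ddd_days * .data$ddd_quantity, .data$ddd_days),
      strength = ifelse(.data$ddd_unit == "UD", 1, .data$ddd_quantity)
    )
  if (!is.null(config$pack_size)) {
    long$units <- ceiling(long$units / config$pack_size) * config$pack_size
  }

  long %>%
    group_by(.data$atc, .data$region, .data$strength) %>%
    summarise(n_units = sum(.data$units), .groups = "drop") %>%
    mutate(year = config$year) %>%
    select("atc", "n_units", "strength", "region", "year") %>%
    arrange(.data$atc, .data$region)
}

#' Ground-truth prevalence summary of a cohort
#'
#' Exact counts over person statuses, per region and in total. Treated T2DM
#' prevalence counts NAD-treated plus insulin-treated T2DM persons; overall
#' prevalence adds the undiagnosed. Also reports the drug-count and
#' insulin-user tallies needed to compute the effective model parameters
#' (realized concomitance weight `n_t2dm_nad / n_nad_drugs`, realized T2DM
#' share of insulin users, realized undiagnosed share).
#'
#' @param persons Cohort tibble from [generate_cohort()].
#' @return Tibble per region plus a `"TOTAL"` row: population and status
#'   counts, `prev_treated_pct`, `prev_overall_pct`.
#' @export
true_summary <- function(persons) {
  check_columns(persons, c("status", "region", "n_drugs"), "persons")
  summarise_block <- function(df, label) {
    tibble(
      region = label,
      n_pop = nrow(df),
      n_t2dm_undiagnosed = sum(df$status == "t2dm_undiagnosed"),
      n_t2dm_nad = sum(df$status == "t2dm_nad"),
      n_t2dm_insulin = sum(df$status == "t2dm_insulin"),
      n_t1dm = sum(df$status == "t1dm"),
      n_nad_drugs = sum(df$n_drugs[df$status == "t2dm_nad"])
    )
  }
  blocks <- bind_rows(
    summarise_block(persons, "TOTAL"),
    persons %>%
      group_by(.data$region) %>%
      dplyr::group_map(~ summarise_block(.x, .y$region)) %>%
      list_rbind()
  )
  blocks %>%
    mutate(
      n_treated = .data$n_t2dm_nad + .data$n_t2dm_insulin,
      n_t2dm = .data$n_treated + .data$n_t2dm_undiagnosed,
      prev_treated_pct = ifelse(.data$n_pop > 0,
                                100 * .data$n_treated / .data$n_pop, 0),
      prev_overall_pct = ifelse(.data$n_pop > 0,
                                100 * .data$n_t2dm / .data$n_pop, 0)
    )
}

#' Effective model parameters realized by a cohort
#'
#' The six-step model is exact on a synthetic cohort when its parameters
#' equal the cohort's *realized* quantities: the concomitance weight is the
#' inverse of the mean regimen size among NAD-treated persons, the insulin
#' fraction is the T2DM share among all insulin users (Type 1 included, since
#' the model sees only insulin consumption), and the undiagnosed fraction is
#' the realized undiagnosed share of T2DM cases.
#'
#' @param truth A [true_summary()] table (the `"TOTAL"` row is used).
#' @param config The generating [cohort_config()] (supplies the adherences).
#' @return A [model_params()] object.
#' @export
effective_params <- function(truth, config) {
  tot <- truth[truth$region == "TOTAL", ]
  n_insulin_users <- tot$n_t2dm_insulin + tot$n_t1dm
  model_params(
    adherence_nad = config$adherence_nad,
    adherence_insulin = config$adherence_insulin,
    w = if (tot$n_nad_drugs > 0) tot$n_t2dm_nad / tot$n_nad_drugs else 1,
    insulin_t2dm_fraction = if (n_insulin_users > 0) {
      tot$n_t2dm_insulin / n_insulin_users
    } else 0,
    undiagnosed_fraction = setNames(
      if (tot$n_t2dm > 0) tot$n_t2dm_undiagnosed / tot$n_t2dm else 0,
      as.character(config$year)
    )
  )
}
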