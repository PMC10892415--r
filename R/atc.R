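#' ATC code handling and the Defined Daily Dose registry
#'
#' The Anatomical Therapeutic Chemical (ATC) classification codes drugs in a
#' five-level hierarchy: anatomical main group (1 character, e.g. `"A"`),
#' therapeutic subgroup (3, `"A10"`), pharmacological subgroup (4, `"A10B"`),
#' chemical subgroup (5, `"A10BA"`) and active substance (7, `"A10BA02"`).
#' Antidiabetic drugs live under `A10`: `A10A` are insulins and analogues,
#' `A10B` the non-insulin blood-glucose-lowering drugs (NADs).
#'
#' @name atc
NULL

.atc_level_width <- c(1L, 3L, 4L, 5L, 7L)

# full-code shape: letter, 2 digits, 2 letters, 2 digits, truncated at a
# level boundary
.atc_regex <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

#' Validate ATC codes
#'
#' @param code Character vector of candidate ATC codes.
#' @return Logical vector: does each element have a structurally valid ATC
#'   code (length 1, 3, 4, 5 or 7, uppercase, letter/digit pattern)?
#' @examples
#' is_valid_atc(c("A10BA02", "A10", "A1", "a10ba02"))
#' @export
is_valid_atc <- function(code) {
  if (!is.character(code)) abort("`code` must be a character vector.")
  !is.na(code) & nchar(code) %in% .atc_level_width & grepl(.atc_regex, code)
}

assert_valid_atc <- function(code, what = "code") {
  bad <- unique(code[!is_valid_atc(code)])
  if (length(bad)) {
    abort(sprintf(
      "Malformed ATC %s: %s.", what, toString(utils::head(bad, 5))
    ))
  }
  invisible(code)
}

#' Truncate ATC codes to a hierarchy level
#'
#' @param code Character vector of valid ATC codes.
#' @param level Integer 1-5; the target hierarchy level. Must not be deeper
#'   than the level of any input code.
#' @return Character vector of prefixes (length 1, 3, 4, 5 or 7 characters).
#' @examples
#' atc_level("A10BA02", 4) # "A10BA"
#' atc_level(c("A10BA02", "A10AE04"), 3)
#' @export
atc_level <- function(code, level) {
  assert_valid_atc(code)
  if (length(level) != 1 || !level %in% 1:5) {
    abort("`level` must be a single integer between 1 and 5.")
  }
  width <- .atc_level_width[level]
  too_shallow <- nchar(code) < width
  if (any(too_shallow)) {
    abort(sprintf(
      "Cannot take level %d of code%s shallower than that level: %s.",
      level, if (sum(too_shallow) > 1) "s" else "",
      toString(unique(code[too_shallow]))
    ))
  }
  substr(code, 1L, width)
}

#' Classify a drug code as insulin, non-insulin antidiabetic, or other
#'
#' Insulins and analogues are ATC class `A10A`; non-insulin antidiabetics
#' (NADs) are `A10B`. Everything else -- including codes too shallow to decide
#' (e.g. `"A10"`) -- is `"other"`.
#'
#' @param code Character vector of valid ATC codes.
#' @return Character vector with values `"insulin"`, `"nad"` or `"other"`.
#' @examples
#' classify_ad(c("A10AE04", "A10BA02", "C10AA05"))
#' @export
classify_ad <- function(code) {
  assert_valid_atc(code)
  prefix <- substr(code, 1L, 4L)
  dplyr::case_when(
    prefix == "A10A" ~ "insulin",
    prefix == "A10B" ~ "nad",
    .default = "other"
  )
}

#' Build or read a Defined Daily Dose registry
#'
#' The registry maps level-5 ATC codes (active substances) to their Defined
#' Daily Dose (DDD): the assumed average maintenance dose per day for the
#' drug's main adult indication, the normalizing unit of drug-utilization
#' accounting. Units are `mg`, `IU` (insulins) or `UD` (unit doses, reserved
#' for fixed-dose combinations, whose DDD is expressed in counts of dose
#' units).
#'
#' @param entries Data frame with columns `atc`, `ddd_quantity`, `ddd_unit`,
#'   `route`.
#' @return A `ddd_registry`: a validated tibble with those four columns and
#'   unique level-5 `atc` keys.
#' @examples
#' ddd_registry(data.frame(
#'   atc = "A10BA02", ddd_quantity = 2000, ddd_unit = "mg", route = "oral"
#' ))
#' @export
ddd_registry <- function(entries) {
  check_columns(entries, c("atc", "ddd_quantity", "ddd_unit", "route"),
                "entries")
  entries <- as_tibble(entries)[, c("atc", "ddd_quantity", "ddd_unit", "route")]
  assert_valid_atc(entries$atc, what = "registry key")
  not_l5 <- entries$atc[nchar(entries$atc) != 7L]
  if (length(not_l5)) {
    abort(sprintf("Registry keys must be level-5 ATC codes; got: %s.",
                  toString(unique(not_l5))))
  }
  dup <- unique(entries$atc[duplicated(entries$atc)])
  if (length(dup)) {
    abort(sprintf("Duplicate ATC key%s in registry: %s.",
                  if (length(dup) > 1) "s" else "", toString(dup)))
  }
  if (any(!is.finite(entries$ddd_quantity) | entries$ddd_quantity <= 0)) {
    abort("All `ddd_quantity` values must be positive and finite.")
  }
  bad_unit <- setdiff(unique(entries$ddd_unit), c("mg", "IU", "UD"))
  if (length(bad_unit)) {
    abort(sprintf("Unknown DDD unit%s: %s (expected mg, IU or UD).",
                  if (length(bad_unit) > 1) "s" else "", toString(bad_unit)))
  }
  class(entries) <- c("ddd_registry", class(entries))
  entries
}

#' Look up the DDD entry for a level-5 ATC code
#'
#' @param registry A [ddd_registry()].
#' @param code Single level-5 ATC code.
#' @return One-row tibble with the stored entry.
#' @examples
#' reg <- ddd_registry(data.frame(
#'   atc = "A10BA02", ddd_quantity = 2000, ddd_unit = "mg", route = "oral"
#' ))
#' lookup_ddd(reg, "A10BA02")
#' @export
lookup_ddd <- function(registry, code) {
  check_columns(registry, c("atc", "ddd_quantity", "ddd_unit"), "registry")
  assert_valid_atc(code)
  if (length(code) != 1 || nchar(code) != 7L) {
    abort("`code` must be a single level-5 (7-character) ATC code.")
  }
  hit <- registry[registry$atc == code, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort(sprintf("No DDD entry for ATC code %s.", code),
          class = "pharmprev_missing_ddd")
  }
  as_tibble(hit)
}
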