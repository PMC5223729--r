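#' Patient subgroup configuration
#'
#' The model evaluates three subgroups of the recently hospitalised
#' heart-failure population, defined by left-ventricular ejection fraction
#' (reduced, HFrEF; preserved, HFpEF) and age at treatment inception:
#'
#' * `"HFrEF<75"` — reduced EF, mean start age 65, 30-year horizon
#'   (120 cycles);
#' * `"HFpEF<75"` — preserved EF, mean start age 65, 30-year horizon;
#' * `"HFrEF>=75"` — reduced EF, mean start age 81, 15-year horizon
#'   (60 cycles).
#'
#' Horizons are long enough that over 99% of each cohort has died by the
#' final cycle. (There is no evidence of benefit in HFpEF patients aged
#' >= 75, so that subgroup is not modelled.)
#'
#' @param label Subgroup name; `">=75"` may also be spelled `"75+"` or with
#'   a Unicode `≥`.
#' @return A `subgroup_config` list: `label`, `start_age` (years),
#'   `horizon` (cycles), `lvef_class` (`"reduced"`/`"preserved"`),
#'   `age_class` (`"under75"`/`"over75"`).
#' @examples
#' subgroup_config("HFrEF<75")
#' @export
subgroup_config <- function(label) {
  known <- c("HFrEF<75", "HFpEF<75", "HFrEF>=75")
  preserved <- grepl("hfpef", tolower(label))
  over75 <- grepl("≥|>=|75\\+", label)
  canon <- paste0(if (preserved) "HFpEF" else "HFrEF",
                  if (over75) ">=75" else "<75")
  if (!grepl("hfref|hfpef", tolower(label)) ||
      (!over75 && !grepl("<\\s*75", label)) || (preserved && over75)) {
    stop("unknown subgroup '", label, "'; valid subgroups: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(list(
    label = canon,
    start_age = if (over75) 81L else 65L,
    horizon = if (over75) 60L else 120L,
    lvef_class = if (grepl("HFpEF", canon)) "preserved" else "reduced",
    age_class = if (over75) "over75" else "under75"
  ), class = "subgroup_config")
}

#' @export
print.subgroup_config <- function(x, ...) {
  cat("<subgroup> ", x$label, ": start age ", x$start_age, ", ",
      x$horizon, " cycles (", x$horizon / 4, " years), ", x$lvef_class,
      " EF, ", x$age_class, "\n", sep = "")
  invisible(x)
}

#' Analysis scenario definitions
#'
#' The primary analysis and five one-way sensitivity analyses:
#'
#' * `"primary"` — exponential baseline survival, BNP treatment effect for
#'   4 years (16 cycles), BNP test cost £25.
#' * `"SA1"` — Weibull baseline survival (scale 0.017, shape 0.842) for the
#'   under-75 subgroups' first 8 model years.
#' * `"SA2"` — treatment effect and BNP-specific costs cease at 2 years
#'   (8 cycles).
#' * `"SA3"` — treatment effect sustained for the patient lifetime.
#' * `"SA4"` / `"SA5"` — BNP test cost halved (£12.50) / raised 50%
#'   (£37.50).
#'
#' @param name Scenario name (case-insensitive for the SA labels).
#' @return A `scenario_config` list: `name`, `survival_form`
#'   (`"exponential"`/`"weibull"`), `effect_window` (cycles, `Inf` for
#'   lifetime), `cost_clip` (cycle count after which BNP cost streams are
#'   truncated, `Inf` when untouched) and `overrides` (named parameter
#'   overrides applied to the registry values).
#' @examples
#' build_scenario("SA4")$overrides
#' @export
build_scenario <- function(name = "primary") {
  key <- toupper(name)
  if (key == "PRIMARY") key <- "primary"
  base <- list(name = key, survival_form = "exponential",
               effect_window = 16L, cost_clip = Inf,
               overrides = list())
  sc <- switch(key,
    "primary" = base,
    "SA1" = utils::modifyList(base, list(survival_form = "weibull")),
    "SA2" = utils::modifyList(base, list(effect_window = 8L, cost_clip = 8L)),
    "SA3" = utils::modifyList(base, list(effect_window = Inf)),
    "SA4" = utils::modifyList(base, list(overrides = list(bnp_test_cost = 12.5))),
    "SA5" = utils::modifyList(base, list(overrides = list(bnp_test_cost = 37.5))),
    stop("unknown scenario '", name, "'; valid scenarios: primary, SA1, ",
         "SA2, SA3, SA4, SA5", call. = FALSE)
  )
  structure(sc, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario> ", x$name, ": ", x$survival_form, " baseline survival, ",
      "effect window ",
      if (is.finite(x$effect_window)) paste0(x$effect_window, " cycles")
      else "lifetime",
      if (length(x$overrides))
        paste0("; overrides: ",
               paste(names(x$overrides), unlist(x$overrides), sep = " = ",
                     collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
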