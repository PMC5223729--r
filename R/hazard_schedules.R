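CYCLE_MONTHS <- 3
ACUTE_PHASE_CYCLES <- 32L  # first 8 model years use the HF-cohort hazard

#' Convert a monthly hazard rate to a cycle probability
#'
#' For a constant hazard `h` per month, the probability of the event within
#' a cycle of `months` months is `1 - exp(-h * months)`.
#'
#' @param h Hazard per month, >= 0 (vectorised).
#' @param months Cycle length in months (default 3).
#' @return Probability in `[0, 1)`.
#' @examples
#' cycle_prob_from_monthly_hazard(0.009) # 0.026639...
#' @export
cycle_prob_from_monthly_hazard <- function(h, months = CYCLE_MONTHS) {
  if (any(h < 0)) {
    stop("cycle_prob_from_monthly_hazard(): hazard must be non-negative",
         call. = FALSE)
  }
  1 - exp(-h * months)
}

#' Per-cycle death probability under a Weibull hazard
#'
#' With survival `S(t) = exp(-scale * t^shape)` (t in months,
#' proportional-hazards metric), the conditional probability of death in
#' cycle `k` (0-based) given survival to its start is
#' `1 - S(3 * (k + 1)) / S(3 * k)`. A shape below 1 gives a hazard that
#' decreases with time since the index admission.
#'
#' @param scale Weibull scale (hazard multiplier), > 0.
#' @param shape Weibull shape (ancillary parameter), > 0; shape 1 recovers
#'   the exponential.
#' @param cycle_index 0-based cycle index (vectorised), >= 0.
#' @return Conditional per-cycle death probability.
#' @examples
#' weibull_cycle_prob(0.017, 0.842, 0:3)
#' @export
weibull_cycle_prob <- function(scale, shape, cycle_index) {
  stopifnot(scale > 0, shape > 0)
  if (any(cycle_index < 0)) {
    stop("weibull_cycle_prob(): cycle_index must be >= 0", call. = FALSE)
  }
  t0 <- CYCLE_MONTHS * cycle_index
  t1 <- CYCLE_MONTHS * (cycle_index + 1)
  1 - exp(-scale * (t1^shape - t0^shape))
}

#' Relative risk from two interval survival proportions
#'
#' Converts each group's cumulative mortality over a common horizon to a
#' per-cycle probability via `1 - (1 - p)^(1 / horizon_cycles)` and returns
#' the ratio of the per-cycle probabilities. This is how a published
#' long-horizon survival contrast (e.g. 7-year survival of heart-failure
#' cases vs matched controls) is turned into the cycle-scale relative risk
#' the model multiplies onto life-table mortality.
#'
#' @param events_a,total_a Deaths and group size in the numerator group.
#' @param events_b,total_b Deaths and group size in the denominator group.
#' @param horizon_cycles Number of 3-month cycles in the observation
#'   horizon (28 for 7 years, 4 for 1 year).
#' @return Relative risk (per-cycle probability scale).
#' @examples
#' rr_from_interval_survival(199, 293, 176, 586, 28) # approx. 3.14
#' rr_from_interval_survival(766, 3631, 584, 2205, 4) # approx. 0.78
#' @export
rr_from_interval_survival <- function(events_a, total_a, events_b, total_b,
                                      horizon_cycles) {
  stopifnot(horizon_cycles >= 1)
  if (events_b <= 0) {
    stop("rr_from_interval_survival(): zero events in the denominator group",
         call. = FALSE)
  }
  for (pair in list(c(events_a, total_a), c(events_b, total_b))) {
    if (!(pair[1] > 0 && pair[1] < pair[2])) {
      stop("rr_from_interval_survival(): need 0 < events < total in both ",
           "groups", call. = FALSE)
    }
  }
  rr_from_interval_probs(events_a / total_a, events_b / total_b,
                         horizon_cycles)
}

# Same conversion starting from cumulative probabilities (used when the
# proportions themselves are sampled in the PSA).
rr_from_interval_probs <- function(p_a, p_b, horizon_cycles) {
  pc <- function(p) 1 - (1 - p)^(1 / horizon_cycles)
  pc(p_a) / pc(p_b)
}

#' Build the per-cycle mortality schedule
#'
#' Assembles the vector `d_t` of per-cycle death probabilities for one
#' (subgroup, strategy, scenario) combination:
#'
#' 1. **First 8 years (cycles 0–31):** constant probability from the
#'    heart-failure cohort's monthly hazard (or, under the Weibull scenario
#'    and an under-75 subgroup, a time-decreasing Weibull probability).
#'    For the over-75 subgroup the monthly hazard is multiplied by the age
#'    hazard ratio before conversion — both come from the same
#'    proportional-hazards fit.
#' 2. **Beyond 8 years:** general-population life-table mortality at the
#'    attained age (advancing one year of age every four cycles,
#'    two-thirds-male weighting), inflated by the heart-failure relative
#'    risk derived from the registry's interval-survival proportions.
#' 3. **HFpEF:** every cycle multiplied by the HFpEF-vs-HFrEF relative risk
#'    (derived from the 1-year mortality proportions).
#' 4. **BNP-guided strategy:** multiplied by the subgroup-specific
#'    treatment hazard ratio, on the probability scale, during the
#'    scenario's effect window.
#'
#' All entries are capped at 1.
#'
#' @param sub A [subgroup_config].
#' @param strategy `"clinical"` or `"bnp"`.
#' @param scenario A [scenario_config][build_scenario].
#' @param params A [parameter_set][point_estimate_set].
#' @param lt A [life_table]; required whenever the horizon exceeds 8 years.
#' @return Numeric vector `d_t` of length `sub$horizon`.
#' @export
mortality_schedule <- function(sub, strategy = c("clinical", "bnp"),
                               scenario = build_scenario("primary"),
                               params = point_estimate_set(),
                               lt = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(sub, "subgroup_config"),
            inherits(scenario, "scenario_config"))
  h <- sub$horizon
  n_acute <- min(ACUTE_PHASE_CYCLES, h)
  age_mult <- if (sub$age_class == "over75") params[["mortality_hr_over75"]] else 1

  if (scenario$survival_form == "weibull" && sub$age_class == "under75") {
    d_acute <- weibull_cycle_prob(params[["weibull_mortality_scale"]],
                                  params[["weibull_mortality_shape"]],
                                  seq_len(n_acute) - 1L)
  } else {
    rate <- params[["mortality_rate_under75"]] * age_mult
    d_acute <- rep(cycle_prob_from_monthly_hazard(rate), n_acute)
  }

  d <- d_acute
  if (h > n_acute) {
    if (is.null(lt)) {
      stop("mortality_schedule(): a life table is required when the ",
           "horizon exceeds 8 years", call. = FALSE)
    }
    rr_hf <- rr_from_interval_probs(params[["p_mort_7y_hf"]],
                                    params[["p_mort_7y_genpop"]], 28L)
    k <- seq.int(ACUTE_PHASE_CYCLES, h - 1L)
    attained_age <- sub$start_age + 8L + (k - ACUTE_PHASE_CYCLES) %/% 4L
    d <- c(d, life_table_cycle_prob(lt, attained_age, male_fraction = 2 / 3,
                                    rr = rr_hf))
  }

  if (sub$lvef_class == "preserved") {
    rr_pef <- rr_from_interval_probs(params[["p_mort_1y_hfpef"]],
                                     params[["p_mort_1y_hfref"]], 4L)
    d <- d * rr_pef
  }

  if (strategy == "bnp") {
    hr <- params[[bnp_mortality_hr_name(sub)]]
    w <- min(scenario$effect_window, h)
    if (w > 0) d[seq_len(w)] <- d[seq_len(w)] * hr
  }
  pmin(1, pmax(0, d))
}

bnp_mortality_hr_name <- function(sub) {
  if (sub$age_class == "over75") return("bnp_mortality_hr_hfref_over75")
  if (sub$lvef_class == "preserved") return("bnp_mortality_hr_hfpef_under75")
  "bnp_mortality_hr_hfref_under75"
}

#' Build the per-cycle hospitalisation schedule
#'
#' The probability `h_t` that a patient alive during cycle `t` is
#' hospitalised at least once in that cycle: constant over the lifetime,
#' from the monthly all-cause hospitalisation hazard (multiplied by the age
#' hazard ratio for the over-75 subgroup before conversion). The risk is
#' identical for HFrEF and HFpEF. The BNP-guided strategy multiplies the
#' probability by the hospitalisation hazard ratio during the same effect
#' window as the mortality effect.
#'
#' @inheritParams mortality_schedule
#' @return Numeric vector `h_t` of length `sub$horizon`.
#' @export
hospitalisation_schedule <- function(sub, strategy = c("clinical", "bnp"),
                                     scenario = build_scenario("primary"),
                                     params = point_estimate_set()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(sub, "subgroup_config"),
            inherits(scenario, "scenario_config"))
  rate <- params[["hospitalisation_rate_under75"]]
  if (sub$age_class == "over75") rate <- rate * params[["hospitalisation_hr_over75"]]
  p <- rep(cycle_prob_from_monthly_hazard(rate), sub$horizon)
  if (strategy == "bnp") {
    w <- min(scenario$effect_window, sub$horizon)
    if (w > 0) p[seq_len(w)] <- p[seq_len(w)] * params[["bnp_hospitalisation_hr"]]
  }
  pmin(1, pmax(0, p))
}

#' Bundle death and hospitalisation schedules
#'
#' @inheritParams mortality_schedule
#' @return A `hazard_schedule` list with components `d` (death) and `h`
#'   (hospitalisation), both of length `sub$horizon`.
#' @export
build_schedules <- function(sub, strategy = c("clinical", "bnp"),
                            scenario = build_scenario("primary"),
                            params = point_estimate_set(), lt = NULL) {
  strategy <- match.arg(strategy)
  structure(list(
    d = mortality_schedule(sub, strategy, scenario, params, lt),
    h = hospitalisation_schedule(sub, strategy, scenario, params),
    subgroup = sub$label, strategy = strategy, scenario = scenario$name
  ), class = "hazard_schedule")
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat("<hazard_schedule> ", x$subgroup, " / ", x$strategy, " / ",
      x$scenario, ", ", length(x$d), " cycles\n", sep = "")
  cat("  d_t: ", paste(signif(utils::head(x$d, 4), 4), collapse = " "),
      " ...\n  h_t: ",
      paste(signif(utils::head(x$h, 4), 4), collapse = " "), " ...\n",
      sep = "")
  invisible(x)
}
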