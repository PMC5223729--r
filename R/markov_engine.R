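CYCLE_DAYS <- 91.31
YEAR_DAYS <- 365.25

#' Per-cycle QALY accrual
#'
#' A cycle that includes a hospitalisation mixes the hospitalised and
#' stable utilities by length of stay:
#' `QALYs_h = (los * U_h + (91.31 - los) * U_nh) / 365.25`; a
#' hospitalisation-free cycle accrues `QALYs_nh = U_nh * 91.31 / 365.25`.
#' The cycle's total is `alive * (P_h * QALYs_h + (1 - P_h) * QALYs_nh)`.
#'
#' @param alive Fraction of the cohort alive through the cycle.
#' @param P_h Proportion of the alive hospitalised during the cycle.
#' @param U_h,U_nh Utility while hospitalised / not hospitalised, in
#'   `[0, 1]`.
#' @param los Mean in-hospital length of stay (days) within the cycle,
#'   `0 <= los <= 91.31`.
#' @return QALYs accrued in the cycle (undiscounted).
#' @examples
#' cycle_qalys(1, 1, 0.66, 0.77, 13.21) # 0.188515...
#' @export
cycle_qalys <- function(alive, P_h, U_h, U_nh, los) {
  stopifnot(P_h >= 0, P_h <= 1, U_h >= 0, U_h <= 1, U_nh >= 0, U_nh <= 1)
  if (los < 0 || los > CYCLE_DAYS) {
    stop("cycle_qalys(): length of stay must lie in [0, ", CYCLE_DAYS,
         "] days", call. = FALSE)
  }
  q_h <- (los * U_h + (CYCLE_DAYS - los) * U_nh) / YEAR_DAYS
  q_nh <- U_nh * CYCLE_DAYS / YEAR_DAYS
  alive * (P_h * q_h + (1 - P_h) * q_nh)
}

#' Strategy costing structure
#'
#' Collects the cost inputs for one strategy arm from a parameter set:
#' age-class-specific 3-monthly state costs (hospitalised / not), and for
#' the BNP-guided arm the add-on streams — a test per 3-month cycle over 18
#' months (6 tests), the incremental medication cost spread uniformly over
#' the same 18 months, and the incremental unscheduled outpatient visits
#' spread over 24 months (8 cycles) at the visit unit cost. The scenario's
#' `cost_clip` truncates all add-on streams (used when BNP-guided care
#' ceases early).
#'
#' @param params A [parameter_set][point_estimate_set].
#' @param sub A [subgroup_config].
#' @param strategy `"clinical"` or `"bnp"`.
#' @param scenario A [scenario_config][build_scenario].
#' @param n_tests Number of BNP tests (default 6: one per cycle, cycles
#'   0–5; set 7 for an additional baseline test).
#' @return A `strategy_costing` list: `cost_h`, `cost_nh` (GBP per cycle)
#'   and `addon` (GBP per alive person per cycle, length `sub$horizon`;
#'   all-zero for the clinical arm).
#' @export
strategy_costing <- function(params, sub, strategy = c("clinical", "bnp"),
                             scenario = build_scenario("primary"),
                             n_tests = 6L) {
  strategy <- match.arg(strategy)
  ac <- sub$age_class
  cost_h <- params[[paste0("cost_hospitalised_", ac)]]
  cost_nh <- params[[paste0("cost_not_hospitalised_", ac)]]
  addon <- numeric(sub$horizon)
  if (strategy == "bnp") {
    clip <- function(cycles) min(cycles, scenario$cost_clip, sub$horizon)
    test_cycles <- clip(n_tests)
    if (test_cycles > 0) {
      addon[seq_len(test_cycles)] <- addon[seq_len(test_cycles)] +
        params[["bnp_test_cost"]]
    }
    med_cycles <- clip(6L)
    if (med_cycles > 0) {
      addon[seq_len(med_cycles)] <- addon[seq_len(med_cycles)] +
        params[["med_cost_bnp"]] / 6
    }
    visit_cycles <- clip(8L)
    if (visit_cycles > 0) {
      extra_visits <- max(params[["visits_bnp"]] - params[["visits_clinical"]], 0)
      addon[seq_len(visit_cycles)] <- addon[seq_len(visit_cycles)] +
        extra_visits / 8 * params[["visit_unit_cost"]]
    }
  }
  structure(list(cost_h = cost_h, cost_nh = cost_nh, addon = addon,
                 strategy = strategy),
            class = "strategy_costing")
}

#' Per-cycle cost accrual
#'
#' State costs are `alive * (P_h * cost_h + (1 - P_h) * cost_nh)`; the
#' BNP-guided arm adds its per-person add-on stream (tests, medication
#' uptitration, incremental visits) scaled by the alive fraction — dead
#' patients accrue nothing.
#'
#' @inheritParams cycle_qalys
#' @param costing A [strategy_costing].
#' @param cycle_index 0-based cycle index (selects the add-on stream
#'   entry).
#' @return GBP accrued in the cycle (undiscounted).
#' @examples
#' sub <- subgroup_config("HFrEF<75")
#' cst <- strategy_costing(point_estimate_set(), sub, "clinical")
#' cycle_costs(1, 0, cst, 0) # 682
#' @export
cycle_costs <- function(alive, P_h, costing, cycle_index) {
  stopifnot(inherits(costing, "strategy_costing"), cycle_index >= 0)
  addon <- if (cycle_index < length(costing$addon))
    costing$addon[cycle_index + 1L] else 0
  alive * (P_h * costing$cost_h + (1 - P_h) * costing$cost_nh) + alive * addon
}

#' Run the two-state cohort simulation
#'
#' Tracks a closed cohort (starting fraction alive = 1) through the
#' Alive/Dead Markov process for `length(schedule$d)` 3-month cycles.
#' Transitions are assumed to occur halfway through each cycle: members
#' dying in a cycle contribute half a cycle of the not-hospitalised
#' utility and state cost; survivors contribute a full cycle, split between
#' hospitalised and not-hospitalised experience by `h_t`. Each cycle's cost
#' and QALY accruals are discounted at `(1 + discount_rate)^(-(t + 0.5)/4)`
#' — the mid-cycle exponent matching the transition convention.
#'
#' @param schedule A [hazard_schedule][build_schedules] (`d`, `h` vectors).
#' @param costing A [strategy_costing].
#' @param utilities List with `u_h`, `u_nh`, `los` (see [cycle_qalys()]).
#' @param discount_rate Annual discount rate for both costs and QALYs
#'   (default 0.035).
#' @param half_cycle If `FALSE`, deaths accrue nothing in their death cycle
#'   (end-of-cycle transitions) instead of the default half cycle.
#' @return A `cohort_trace`: list with per-cycle vectors `alive_start`,
#'   `alive_end`, `deaths`, `P_h`, `cost`, `qalys`, `disc_cost`,
#'   `disc_qalys`, plus `totals` (discounted sums) and bookkeeping fields.
#'   Coerce with `as.data.frame()` for a one-row-per-cycle table.
#' @export
run_cohort <- function(schedule, costing, utilities,
                       discount_rate = 0.035, half_cycle = TRUE) {
  stopifnot(inherits(schedule, "hazard_schedule"),
            inherits(costing, "strategy_costing"),
            all(c("u_h", "u_nh", "los") %in% names(utilities)),
            discount_rate >= 0)
  d <- schedule$d
  h <- schedule$h
  n <- length(d)
  if (length(h) != n) {
    stop("run_cohort(): death and hospitalisation schedules differ in ",
         "length", call. = FALSE)
  }
  if (length(costing$addon) != n) {
    stop("run_cohort(): costing add-on stream length (", length(costing$addon),
         ") does not match the horizon (", n, ")", call. = FALSE)
  }

  alive_start <- cumprod(c(1, 1 - d))[seq_len(n)]
  deaths <- alive_start * d
  alive_end <- alive_start - deaths

  u_h <- utilities$u_h
  u_nh <- utilities$u_nh
  los <- utilities$los
  if (los < 0 || los > CYCLE_DAYS) {
    stop("run_cohort(): length of stay must lie in [0, ", CYCLE_DAYS,
         "] days", call. = FALSE)
  }
  q_h <- (los * u_h + (CYCLE_DAYS - los) * u_nh) / YEAR_DAYS
  q_nh <- u_nh * CYCLE_DAYS / YEAR_DAYS
  death_frac <- if (half_cycle) 0.5 else 0

  qalys <- alive_end * (h * q_h + (1 - h) * q_nh) + deaths * death_frac * q_nh
  cost <- alive_end * (h * costing$cost_h + (1 - h) * costing$cost_nh) +
    deaths * death_frac * costing$cost_nh +
    alive_end * costing$addon

  t <- seq_len(n) - 1L
  disc <- (1 + discount_rate)^(-(t + 0.5) / 4)
  structure(list(
    alive_start = alive_start, alive_end = alive_end, deaths = deaths,
    P_h = h, cost = cost, qalys = qalys,
    disc_cost = cost * disc, disc_qalys = qalys * disc,
    discount_rate = discount_rate,
    totals = c(cost = sum(cost * disc), qalys = sum(qalys * disc)),
    subgroup = schedule$subgroup, strategy = schedule$strategy,
    scenario = schedule$scenario
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- length(x$alive_start)
  cat("<cohort_trace> ", x$subgroup %||% "?", " / ", x$strategy %||% "?",
      " / ", x$scenario %||% "?", ", ", n, " cycles\n", sep = "")
  cat(sprintf("  survivors at horizon: %.4f; discounted totals: £%.0f, %.3f QALYs\n",
              x$alive_end[n], x$totals["cost"], x$totals["qalys"]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_along(x$alive_start) - 1L,
             alive_start = x$alive_start, deaths = x$deaths,
             alive_end = x$alive_end, P_h = x$P_h,
             cost = x$cost, qalys = x$qalys,
             disc_cost = x$disc_cost, disc_qalys = x$disc_qalys)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle, full precision.
#'
#' @param trace A [run_cohort()] trace.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Median survival from a cohort trace
#'
#' Linearly interpolates the alive curve (evaluated at cycle boundaries)
#' across the cycle in which survival crosses 0.5, and reports the crossing
#' time in years (one cycle = 0.25 years).
#'
#' @param trace A [run_cohort()] trace.
#' @return Median survival in years; `NA` with attribute
#'   `censored = TRUE` when survival never falls below 0.5 within the
#'   horizon.
#' @export
median_survival <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  s <- c(trace$alive_start, trace$alive_end[length(trace$alive_end)])
  k <- which(s < 0.5)[1]
  if (is.na(k)) {
    return(structure(NA_real_, censored = TRUE))
  }
  # s[k - 1] >= 0.5 > s[k]; boundary k corresponds to (k - 1) cycles elapsed
  frac <- (s[k - 1] - 0.5) / (s[k - 1] - s[k])
  ((k - 2) + frac) * 0.25
}

#' Discounted lifetime totals of a trace
#'
#' @param trace A [run_cohort()] trace.
#' @return Named vector `c(cost = , qalys = )` of discounted sums.
#' @export
lifetime_totals <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  trace$totals
}
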