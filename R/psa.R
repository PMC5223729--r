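#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each iteration draws
#' one value of every registry parameter from its distribution
#' ([sample_parameter_set()]), rebuilds both strategies' hazard schedules,
#' costings and cohort traces, and records the lifetime discounted cost and
#' QALYs per arm and the incremental net monetary benefit at `lambda`.
#' Iterations are independent and seeded individually from
#' `(seed, iteration)`, so results do not depend on execution order.
#'
#' @param subgroup Subgroup label or [subgroup_config].
#' @param scenario Scenario name or [scenario_config][build_scenario].
#' @param n_iter Number of iterations (the reference analysis uses 10,000).
#' @param seed Integer base seed.
#' @param registry A [param_registry][load_registry].
#' @param lt A [life_table]; the synthetic default is used when `NULL`.
#' @param lambda Willingness-to-pay per QALY for the recorded iNMB.
#' @param lambda_grid Grid for the acceptability curve.
#' @param discount_rate Annual discount rate.
#' @return A `psa_result`: list with `draws` (data frame, one row per
#'   iteration: `cost_clinical`, `qalys_clinical`, `cost_bnp`, `qalys_bnp`,
#'   `delta_cost`, `delta_qalys`, `inmb`), `ceac`, `lambda`, `seed` and run
#'   metadata.
#' @examples
#' \donttest{
#' res <- run_psa("HFrEF<75", "primary", n_iter = 50, seed = 1)
#' summarise_psa(res)
#' }
#' @export
run_psa <- function(subgroup, scenario = "primary", n_iter = 10000L,
                    seed = 1L, registry = default_registry(), lt = NULL,
                    lambda = 20000, lambda_grid = seq(0, 50000, by = 500),
                    discount_rate = 0.035) {
  sub <- as_subgroup(subgroup)
  sc <- as_scenario(scenario)
  if (is.null(lt)) lt <- generate_life_table()
  stopifnot(n_iter >= 1)

  cols <- c("cost_clinical", "qalys_clinical", "cost_bnp", "qalys_bnp")
  out <- matrix(NA_real_, nrow = n_iter, ncol = 4L,
                dimnames = list(NULL, cols))
  for (i in seq_len(n_iter)) {
    params <- tryCatch(
      sample_parameter_set(registry, seed = seed, iteration = i),
      error = function(e) {
        stop("PSA iteration ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    params <- override_parameters(params, sc$overrides)
    res <- tryCatch(
      evaluate_strategies(sub, sc, params, lt, discount_rate),
      error = function(e) {
        stop("PSA iteration ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    out[i, ] <- res
  }
  draws <- as.data.frame(out)
  draws$delta_cost <- draws$cost_bnp - draws$cost_clinical
  draws$delta_qalys <- draws$qalys_bnp - draws$qalys_clinical
  draws$inmb <- lambda * draws$delta_qalys - draws$delta_cost

  structure(list(
    draws = draws,
    ceac = ceac(draws$delta_cost, draws$delta_qalys, lambda_grid),
    lambda = lambda, seed = seed, n_iter = n_iter,
    subgroup = sub$label, scenario = sc$name,
    life_table_provenance = attr(lt, "provenance")
  ), class = "psa_result")
}

# Shared deterministic core: lifetime totals for both arms under one
# parameter set.
evaluate_strategies <- function(sub, sc, params, lt, discount_rate = 0.035) {
  utilities <- list(u_h = params[["utility_hospitalised"]],
                    u_nh = params[["utility_not_hospitalised"]],
                    los = min(params[["length_of_stay_days"]], CYCLE_DAYS))
  vals <- numeric(4L)
  for (strategy in c("clinical", "bnp")) {
    schedule <- build_schedules(sub, strategy, sc, params, lt)
    costing <- strategy_costing(params, sub, strategy, sc)
    trace <- run_cohort(schedule, costing, utilities, discount_rate)
    idx <- if (strategy == "clinical") 1:2 else 3:4
    vals[idx] <- trace$totals
  }
  vals
}

as_subgroup <- function(x) {
  if (inherits(x, "subgroup_config")) x else subgroup_config(x)
}

as_scenario <- function(x) {
  if (inherits(x, "scenario_config")) x else build_scenario(x)
}

#' Summarise a probabilistic sensitivity analysis
#'
#' Mean iNMB with a percentile interval (2.5th/97.5th at the default 95%
#' level), plus mean costs and QALYs per arm and the probability of
#' cost-effectiveness at the run's `lambda`.
#'
#' @param result A [run_psa()] result.
#' @param level Interval coverage in (0, 1).
#' @return Named list: `mean_inmb`, `lower`, `upper`, `level`,
#'   `prob_cost_effective`, `mean_cost_clinical`, `mean_qalys_clinical`,
#'   `mean_cost_bnp`, `mean_qalys_bnp`, `lambda`, `n_iter`.
#' @export
summarise_psa <- function(result, level = 0.95) {
  stopifnot(inherits(result, "psa_result"), level > 0, level < 1)
  draws <- result$draws
  if (nrow(draws) < 2L) {
    stop("summarise_psa(): at least 2 iterations are required", call. = FALSE)
  }
  qs <- stats::quantile(draws$inmb, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(mean_inmb = mean(draws$inmb), lower = qs[1], upper = qs[2],
       level = level,
       prob_cost_effective = mean(draws$inmb > 0),
       mean_cost_clinical = mean(draws$cost_clinical),
       mean_qalys_clinical = mean(draws$qalys_clinical),
       mean_cost_bnp = mean(draws$cost_bnp),
       mean_qalys_bnp = mean(draws$qalys_bnp),
       lambda = result$lambda, n_iter = result$n_iter)
}

#' @export
print.psa_result <- function(x, ...) {
  s <- summarise_psa(x)
  cat("<psa_result> ", x$subgroup, " / ", x$scenario, ", ", x$n_iter,
      " iterations (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean iNMB(λ=%.0f): £%.0f (%.0f%% interval £%.0f to £%.0f)\n",
              s$lambda, s$mean_inmb, 100 * s$level, s$lower, s$upper))
  cat(sprintf("  P(cost-effective at λ): %.3f\n", s$prob_cost_effective))
  invisible(x)
}

#' Export PSA draws to CSV
#'
#' One row per iteration, full precision.
#'
#' @param result A [run_psa()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_psa_draws <- function(result, path) {
  utils::write.csv(result$draws, path, row.names = FALSE)
  invisible(path)
}
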