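#' Deterministic cost-effectiveness run
#'
#' Runs both strategy arms at the registry point estimates for one
#' subgroup and scenario, and returns the deterministic cost-effectiveness
#' result (lifetime discounted costs and QALYs per arm, increments, ICER
#' and iNMB), with the two cohort traces attached.
#'
#' @param subgroup Subgroup label or [subgroup_config].
#' @param scenario Scenario name or [scenario_config][build_scenario].
#' @param registry A [param_registry][load_registry].
#' @param lt A [life_table]; defaults to the synthetic
#'   [generate_life_table()] table. Headline totals comparable to analyses
#'   built on a national life table require supplying that table here.
#' @param lambda Willingness-to-pay per QALY.
#' @param discount_rate Annual discount rate.
#' @return A `ce_result` (see [inmb()], [icer()]); `$traces` holds the
#'   `clinical` and `bnp` [run_cohort()] traces.
#' @examples
#' run_deterministic("HFrEF<75", "primary")
#' @export
run_deterministic <- function(subgroup, scenario = "primary",
                              registry = default_registry(), lt = NULL,
                              lambda = 20000, discount_rate = 0.035) {
  sub <- as_subgroup(subgroup)
  sc <- as_scenario(scenario)
  if (is.null(lt)) lt <- generate_life_table()
  params <- override_parameters(point_estimate_set(registry), sc$overrides)
  utilities <- list(u_h = params[["utility_hospitalised"]],
                    u_nh = params[["utility_not_hospitalised"]],
                    los = params[["length_of_stay_days"]])
  traces <- lapply(c(clinical = "clinical", bnp = "bnp"), function(strategy) {
    schedule <- build_schedules(sub, strategy, sc, params, lt)
    costing <- strategy_costing(params, sub, strategy, sc)
    run_cohort(schedule, costing, utilities, discount_rate)
  })
  t0 <- traces$clinical$totals
  t1 <- traces$bnp$totals
  ce_result(t0["cost"], t0["qalys"], t1["cost"], t1["qalys"], lambda,
            sub$label, sc$name, traces = traces)
}

#' Full analysis: all subgroups and sensitivity analyses
#'
#' Reproduces the reference analysis layout: a subgroup table (three rows:
#' the two under-75 subgroups and the over-75 HFrEF subgroup; deterministic
#' cost/QALYs per arm, PSA mean iNMB with percentile interval,
#' deterministic ICER) and a sensitivity-analysis table (five rows, SA1–SA5,
#' for the under-75 HFrEF subgroup), plus the per-subgroup acceptability
#' curves.
#'
#' @param n_iter PSA iterations per run.
#' @param seed Integer base seed.
#' @param registry A [param_registry][load_registry].
#' @param lt A [life_table] (synthetic default when `NULL`).
#' @param lambda Willingness-to-pay per QALY.
#' @param psa If `FALSE`, skip the probabilistic runs (iNMB intervals are
#'   then `NA`); useful for quick deterministic tables.
#' @return A `full_analysis` list: `subgroup_table`, `sa_table` (data
#'   frames), `ceacs` (named list of [ceac] curves), `manifest`.
#' @export
run_full_analysis <- function(n_iter = 1000L, seed = 1L,
                              registry = default_registry(), lt = NULL,
                              lambda = 20000, psa = TRUE) {
  if (is.null(lt)) lt <- generate_life_table()
  subgroups <- c("HFrEF<75", "HFpEF<75", "HFrEF>=75")
  scenarios <- paste0("SA", 1:5)

  one_row <- function(subgroup, scenario) {
    det <- run_deterministic(subgroup, scenario, registry, lt, lambda)
    row <- data.frame(
      subgroup = subgroup, scenario = scenario,
      cost_clinical = det$cost_clinical, qalys_clinical = det$qalys_clinical,
      cost_bnp = det$cost_bnp, qalys_bnp = det$qalys_bnp,
      icer = as.numeric(det$icer),
      inmb_mean = NA_real_, inmb_lower = NA_real_, inmb_upper = NA_real_
    )
    curve <- NULL
    if (psa) {
      pr <- run_psa(subgroup, scenario, n_iter = n_iter, seed = seed,
                    registry = registry, lt = lt, lambda = lambda)
      s <- summarise_psa(pr)
      row$inmb_mean <- s$mean_inmb
      row$inmb_lower <- s$lower
      row$inmb_upper <- s$upper
      curve <- pr$ceac
    }
    list(row = row, ceac = curve)
  }

  sub_rows <- lapply(subgroups, one_row, scenario = "primary")
  sa_rows <- lapply(scenarios, function(sc) one_row("HFrEF<75", sc))

  ceacs <- stats::setNames(lapply(sub_rows, `[[`, "ceac"), subgroups)
  structure(list(
    subgroup_table = do.call(rbind, lapply(sub_rows, `[[`, "row")),
    sa_table = do.call(rbind, lapply(sa_rows, `[[`, "row")),
    ceacs = ceacs,
    manifest = run_manifest(seed = seed, n_iter = n_iter, lambda = lambda,
                            registry = registry, lt = lt)
  ), class = "full_analysis")
}

# Provenance block attached to rendered outputs.
run_manifest <- function(seed, n_iter, lambda, registry, lt) {
  list(seed = seed, n_iter = n_iter, lambda = lambda,
       registry = attr(registry, "path") %||% "in-memory",
       life_table = attr(lt, "provenance"),
       package_version = as.character(utils::packageVersion("bnpcea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.full_analysis <- function(x, ...) {
  cat("== Cost-effectiveness by subgroup (primary scenario) ==\n")
  print(format_results_table(x$subgroup_table))
  cat("\n== Sensitivity analyses (HFrEF<75) ==\n")
  print(format_results_table(x$sa_table))
  cat("\nLife table: ", x$manifest$life_table, "; seed ", x$manifest$seed,
      "; ", x$manifest$n_iter, " PSA iterations\n", sep = "")
  invisible(x)
}

#' Round a results table for display
#'
#' Internal values carry full precision; rounding happens only here, at
#' render time (costs to whole GBP, QALYs to 2 decimals).
#'
#' @param tab A `subgroup_table`/`sa_table` data frame from
#'   [run_full_analysis()].
#' @return A data frame of formatted character columns.
#' @export
format_results_table <- function(tab) {
  gbp <- function(x) ifelse(is.na(x), "-", sprintf("£%.0f", x))
  data.frame(
    tab[, c("subgroup", "scenario")],
    cost_clinical = gbp(tab$cost_clinical),
    qalys_clinical = sprintf("%.2f", tab$qalys_clinical),
    cost_bnp = gbp(tab$cost_bnp),
    qalys_bnp = sprintf("%.2f", tab$qalys_bnp),
    inmb = ifelse(is.na(tab$inmb_mean), "-",
                  sprintf("£%.0f (£%.0f to £%.0f)", tab$inmb_mean,
                          tab$inmb_lower, tab$inmb_upper)),
    icer = gbp(tab$icer),
    check.names = FALSE
  )
}

#' Export a full analysis to a directory
#'
#' Writes the subgroup and sensitivity tables (CSV, full precision), the
#' per-subgroup CEACs (tab-separated) and the run manifest (JSON).
#'
#' @param x A [run_full_analysis()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_full_analysis <- function(x, dir) {
  stopifnot(inherits(x, "full_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$subgroup_table, file.path(dir, "subgroup_results.csv"),
                   row.names = FALSE)
  utils::write.csv(x$sa_table, file.path(dir, "sensitivity_results.csv"),
                   row.names = FALSE)
  for (nm in names(x$ceacs)) {
    if (!is.null(x$ceacs[[nm]])) {
      safe <- gsub("[^A-Za-z0-9]+", "_", gsub(">=", "ge", gsub("<", "lt", nm)))
      write_ceac(x$ceacs[[nm]], file.path(dir, paste0("ceac_", safe, ".tsv")))
    }
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
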