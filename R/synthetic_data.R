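#' Gompertz-Makeham hazard parameters
#'
#' Parameter triple for the synthetic life-table generator: annual mortality
#' hazard at age `a` is `makeham + level * exp(slope * a)` — a constant
#' age-independent component plus an exponentially increasing senescent
#' component.
#'
#' @param makeham Age-independent annual hazard, >= 0.
#' @param level Sex-specific senescent hazard coefficient, > 0.
#' @param slope Per-year increase of the log senescent hazard, > 0 for an
#'   age-increasing table.
#' @return A `gompertz_params` list.
#' @export
gompertz_params <- function(makeham = 5e-4, level = 5.5e-6, slope = 0.117) {
  stopifnot(makeham >= 0, level > 0, slope >= 0)
  structure(list(makeham = makeham, level = level, slope = slope),
            class = "gompertz_params")
}

#' Generate a synthetic life table
#'
#' Builds an age/sex life table from Gompertz-Makeham hazards:
#' `q(age) = 1 - exp(-(makeham + level * exp(slope * age)))`, capped at 1,
#' with the terminal age forced to `q = 1`. The defaults give plausible
#' UK-scale magnitudes (male `q(65)` near 0.01 and `q(85)` near 0.1, women
#' somewhat lower) but are explicitly **synthetic**: they stand in for a
#' national life table wherever one is not supplied, and headline results
#' computed from them are not comparable to results computed from genuine
#' national tables.
#'
#' @param params_male,params_female [gompertz_params] for each sex.
#' @param max_age Terminal age of the table (default 110).
#' @param min_age First age covered (default 0).
#' @return A [life_table] with provenance `"synthetic"`.
#' @examples
#' lt <- generate_life_table()
#' lt[lt$age %in% c(65, 85), ]
#' @export
generate_life_table <- function(params_male = gompertz_params(),
                                params_female = gompertz_params(level = 4e-6),
                                max_age = 110L, min_age = 0L) {
  stopifnot(inherits(params_male, "gompertz_params"),
            inherits(params_female, "gompertz_params"),
            max_age > min_age)
  age <- seq.int(min_age, max_age)
  q_of <- function(p) {
    pmin(1, 1 - exp(-(p$makeham + p$level * exp(p$slope * age))))
  }
  life_table(age, q_of(params_male), q_of(params_female),
             provenance = "synthetic")
}

#' Simulate right-censored individual-patient survival records
#'
#' Emulates the statistical structure of a registry-linked heart-failure
#' cohort: event times drawn by inverse-transform sampling from an
#' exponential or Weibull proportional-hazards model with a binary age
#' covariate (>= 75 vs < 75 years), administratively censored at a fixed
#' follow-up time. Optionally applies left truncation at 7 days
#' (7 / 30.44 months) to mirror the exclusion of patients dying in hospital
#' or within a week of discharge.
#'
#' The Weibull is parameterised in the proportional-hazards metric: the
#' cumulative hazard is `scale * exp(beta * x) * t^shape` with `x = 1` for
#' the over-75 stratum and `exp(beta) = hr_over75`.
#'
#' @param n Number of patients.
#' @param model `"exponential"` or `"weibull"`.
#' @param rate Baseline hazard per month (exponential model).
#' @param scale,shape Weibull proportional-hazards parameters (Weibull
#'   model).
#' @param hr_over75 Hazard ratio for the over-75 stratum (1 = no effect).
#' @param prop_over75 Proportion of patients aged >= 75.
#' @param censor_time Administrative censoring time in months (`Inf` for
#'   none).
#' @param left_truncate If `TRUE`, resample any event time below 7/30.44
#'   months (early deaths excluded at source).
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @return A `survival_records` data frame with columns `time` (months,
#'   > 0), `event` (1 death observed / 0 censored) and `age_class`
#'   (`"under75"` / `"over75"`).
#' @examples
#' rec <- simulate_ipd_survival(500, rate = 0.009, seed = 1)
#' mean(rec$event)
#' @export
simulate_ipd_survival <- function(n, model = c("exponential", "weibull"),
                                  rate = 0.009, scale = 0.017, shape = 0.842,
                                  hr_over75 = 1, prop_over75 = 0.5,
                                  censor_time = Inf, left_truncate = FALSE,
                                  seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 1, hr_over75 > 0, prop_over75 >= 0, prop_over75 <= 1,
            censor_time >= 0)
  if (model == "exponential") {
    stopifnot(rate > 0)
  } else {
    stopifnot(scale > 0, shape > 0)
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  over75 <- stats::runif(n) < prop_over75
  mult <- ifelse(over75, hr_over75, 1)
  # Inverse-transform draw; for left truncation, resample from the
  # conditional distribution given survival past 7 days.
  t_event <- if (model == "exponential") {
    -log(stats::runif(n)) / (rate * mult)
  } else {
    (-log(stats::runif(n)) / (scale * mult))^(1 / shape)
  }
  if (left_truncate) {
    t0 <- 7 / 30.44
    repeat {
      early <- which(t_event <= t0)
      if (!length(early)) break
      u <- stats::runif(length(early))
      t_event[early] <- if (model == "exponential") {
        -log(u) / (rate * mult[early])
      } else {
        (-log(u) / (scale * mult[early]))^(1 / shape)
      }
    }
  }
  event <- t_event <= censor_time
  time <- pmin(t_event, censor_time)
  structure(
    data.frame(time = time, event = as.integer(event),
               age_class = ifelse(over75, "over75", "under75")),
    class = c("survival_records", "data.frame"),
    model = model
  )
}

#' Read / write survival records
#'
#' Tab-separated text with header `time` (months), `event` (1 = event
#' observed, 0 = censored) and `age_class` (`under75` / `over75`).
#'
#' @param path File path.
#' @param records A `survival_records` data frame (for writing).
#' @return `read_survival_records()` returns a `survival_records` data
#'   frame; the writer returns `path` invisibly.
#' @export
read_survival_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  need <- c("time", "event", "age_class")
  if (!all(need %in% names(df))) {
    stop("records file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$time <= 0)) stop("all times must be > 0", call. = FALSE)
  structure(df[need], class = c("survival_records", "data.frame"))
}

#' @rdname read_survival_records
#' @export
write_survival_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
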