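test_that("exponential MLE matches the events/person-time closed form", {
  rec <- data.frame(time = c(10, 20, 30, 40), event = c(1L, 1L, 0L, 0L),
                    age_class = "under75")
  fit <- fit_exponential(rec)
  expect_equal(fit$rate, 2 / 100, tolerance = 1e-12)
  expect_equal(fit$se_log_rate, 1 / sqrt(2), tolerance = 1e-12)
  expect_true(is.na(fit$hr_over75))

  # two strata: stratum rates and their ratio
  rec2 <- rbind(rec, data.frame(time = c(5, 5), event = c(1L, 1L),
                                age_class = "over75"))
  fit2 <- fit_exponential(rec2)
  expect_equal(fit2$rate, 0.02, tolerance = 1e-12)
  expect_equal(fit2$hr_over75, (2 / 10) / 0.02, tolerance = 1e-12)
  expect_equal(fit2$se_log_hr, sqrt(1 / 2 + 1 / 2), tolerance = 1e-12)

  # all-censored stratum is an error
  rec3 <- rec
  rec3$event <- 0L
  expect_error(fit_exponential(rec3), "no events")
  expect_error(fit_exponential(data.frame(time = -1, event = 1L,
                                          age_class = "under75")),
               "> 0")
})

test_that("exponential parameters are recovered from simulated cohorts", {
  rec <- simulate_ipd_survival(20000, "exponential", rate = 0.009,
                               hr_over75 = 2.801, prop_over75 = 0.5,
                               censor_time = 96, seed = 101)
  fit <- fit_exponential(rec)
  expect_lt(abs(log(fit$rate) - log(0.009)), 3 * fit$se_log_rate)
  expect_lt(abs(log(fit$hr_over75) - log(2.801)), 3 * fit$se_log_hr)

  # bias of the log-HR shrinks with sample size (averaged over replicates)
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      f <- fit_exponential(simulate_ipd_survival(
        n, "exponential", rate = 0.009, hr_over75 = 2.801,
        prop_over75 = 0.5, censor_time = 96, seed = s))
      log(f$hr_over75) - log(2.801)
    }, numeric(1)))
  }
  expect_lt(abs(bias_at(20000, 1:4)), abs(bias_at(2000, 1:4)) + 0.02)
})

test_that("Weibull proportional-hazards fit nests and beats the exponential", {
  rec <- simulate_ipd_survival(4000, "weibull", scale = 0.017, shape = 0.842,
                               hr_over75 = 2, prop_over75 = 0.4,
                               censor_time = 120, seed = 7)
  wb <- fit_weibull(rec)
  ex <- fit_exponential(rec)
  # nested model: the extra shape parameter cannot lower the likelihood
  expect_gte(wb$loglik, ex$loglik)

  # fixing the shape at 1 recovers the exponential fit
  wb1 <- fit_weibull(rec, shape_fixed = 1)
  expect_equal(wb1$scale, ex$rate, tolerance = 1e-5)
  expect_equal(wb1$hr_over75, ex$hr_over75, tolerance = 1e-4)
  expect_equal(wb1$loglik, ex$loglik, tolerance = 1e-7)
})

test_that("Weibull parameters are recovered from simulated cohorts", {
  rec <- simulate_ipd_survival(20000, "weibull", scale = 0.017,
                               shape = 0.842, hr_over75 = 2.801,
                               prop_over75 = 0.5, censor_time = Inf,
                               seed = 21)
  fit <- fit_weibull(rec)
  expect_lt(abs(log(fit$scale) - log(0.017)), 3 * fit$se_log_scale)
  expect_lt(abs(log(fit$shape) - log(0.842)), 3 * fit$se_log_shape)
  expect_lt(abs(log(fit$hr_over75) - log(2.801)), 3 * fit$se_log_hr)
})

test_that("the fit agrees with an independent accelerated-failure-time route", {
  rec <- simulate_ipd_survival(5000, "weibull", scale = 0.017, shape = 0.842,
                               hr_over75 = 2, prop_over75 = 0.5,
                               censor_time = 120, seed = 13)
  fit <- fit_weibull(rec)
  # survreg fits the same model in the AFT metric; convert and compare
  sr <- survival::survreg(
    survival::Surv(time, event) ~ I(age_class == "over75"),
    data = rec, dist = "weibull")
  ph <- aft_to_ph(unname(coef(sr)[1]), sr$scale)
  expect_equal(fit$shape, unname(ph["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(ph["scale"]), tolerance = 1e-2)
  expect_equal(log(fit$hr_over75), -unname(coef(sr)[2]) / sr$scale,
               tolerance = 1e-3)

  # metric conversions are mutual inverses
  aft <- ph_to_aft(0.017, 0.842)
  expect_equal(aft_to_ph(aft["intercept"], aft["reg_scale"]),
               c(scale = 0.017, shape = 0.842), tolerance = 1e-12)
})

test_that("survival records validate and round-trip through text files", {
  rec <- simulate_ipd_survival(50, rate = 0.01, seed = 5, censor_time = 48)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_survival_records(rec, path)
  back <- read_survival_records(path)
  expect_equal(back$time, rec$time, tolerance = 1e-9)
  expect_identical(back$event, rec$event)
  expect_error(fit_weibull(data.frame(time = c(1, 2), event = c(1L, 0L),
                                      age_class = "under75")),
               "distinct event times")
})
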