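test_that("hazard-to-probability conversion follows the exponential closed form", {
  expect_identical(cycle_prob_from_monthly_hazard(0), 0)
  expect_equal(cycle_prob_from_monthly_hazard(0.009), 1 - exp(-0.027),
               tolerance = 1e-12)
  expect_equal(cycle_prob_from_monthly_hazard(0.066), 1 - exp(-0.198),
               tolerance = 1e-12)
  expect_error(cycle_prob_from_monthly_hazard(-0.1), "non-negative")
})

test_that("Weibull cycle probabilities nest the exponential and telescope", {
  # shape 1 reduces to the exponential for every cycle
  k <- 0:39
  expect_equal(weibull_cycle_prob(0.009, 1, k),
               rep(cycle_prob_from_monthly_hazard(0.009), 40),
               tolerance = 1e-12)
  # shape < 1: hazard decreasing with time since admission
  p <- weibull_cycle_prob(0.017, 0.842, k)
  expect_equal(p[1], 1 - exp(-0.017 * 3^0.842), tolerance = 1e-12)
  expect_true(all(diff(p) < 0))
  # chaining the conditional probabilities reproduces S(t) exactly
  K <- 40
  expect_equal(prod(1 - weibull_cycle_prob(0.017, 0.842, 0:(K - 1))),
               exp(-0.017 * (3 * K)^0.842), tolerance = 1e-12)
  expect_error(weibull_cycle_prob(0.017, 0.842, -1), ">= 0")
})

test_that("interval-survival RR conversion reproduces the published relative risks", {
  expect_equal(rr_from_interval_survival(50, 100, 50, 100, 28), 1.0)
  # HF cases vs matched general population, 7-year horizon
  expect_equal(round(rr_from_interval_survival(199, 293, 176, 586, 28), 2),
               3.14)
  # HFpEF vs HFrEF, 1-year horizon
  expect_equal(round(rr_from_interval_survival(766, 3631, 584, 2205, 4), 2),
               0.78)
  expect_error(rr_from_interval_survival(10, 20, 0, 20, 4), "zero events")
  expect_error(rr_from_interval_survival(20, 20, 5, 20, 4), "0 < events")
})

test_that("clinical mortality schedule is flat over the first 8 years and matches the closed form", {
  sub <- subgroup_config("HFrEF<75")
  d <- mortality_schedule(sub, "clinical", lt = default_lt())
  expect_length(d, 120L)
  expect_equal(d[1:32], rep(1 - exp(-0.027), 32), tolerance = 1e-12)
  # implied 8-year survival equals exp(-0.009 * 96)
  expect_equal(prod(1 - d[1:32]), exp(-0.009 * 96), tolerance = 1e-9)
  # life-table phase: non-decreasing with attained age (synthetic table is
  # monotone)
  expect_true(all(diff(d[33:120]) >= 0))
})

test_that("subgroup and strategy multipliers act as specified", {
  lt <- default_lt()
  ref <- mortality_schedule(subgroup_config("HFrEF<75"), "clinical", lt = lt)
  pef <- mortality_schedule(subgroup_config("HFpEF<75"), "clinical", lt = lt)
  # HFpEF: every cycle scaled by the (sub-1) relative risk
  rr_pef <- rr_from_interval_survival(766, 3631, 584, 2205, 4)
  expect_equal(pef, ref * rr_pef, tolerance = 1e-12)
  expect_true(all(pef <= ref))

  bnp <- mortality_schedule(subgroup_config("HFrEF<75"), "bnp", lt = lt)
  expect_equal(bnp[1:16], ref[1:16] * 0.68, tolerance = 1e-12)
  expect_identical(bnp[17:120], ref[17:120])
  expect_true(all(bnp <= ref))

  # over-75: age HR on the hazard scale, 15-year horizon
  old <- mortality_schedule(subgroup_config("HFrEF>=75"), "clinical", lt = lt)
  expect_length(old, 60L)
  expect_equal(old[1], 1 - exp(-0.009 * 2.801 * 3), tolerance = 1e-12)
  # BNP effect window under the 2-year scenario
  sa2 <- mortality_schedule(subgroup_config("HFrEF<75"), "bnp",
                            build_scenario("SA2"), lt = lt)
  expect_identical(sa2[9:120], ref[9:120])
  expect_equal(sa2[1:8], ref[1:8] * 0.68, tolerance = 1e-12)

  expect_error(mortality_schedule(subgroup_config("HFrEF<75"), "clinical"),
               "life table")
})

test_that("Weibull and exponential schedule builders agree when shape is 1", {
  params <- point_estimate_set()
  params[["weibull_mortality_shape"]] <- 1
  params[["weibull_mortality_scale"]] <- params[["mortality_rate_under75"]]
  sub <- subgroup_config("HFrEF<75")
  expect_equal(
    mortality_schedule(sub, "clinical", build_scenario("SA1"), params,
                       default_lt()),
    mortality_schedule(sub, "clinical", build_scenario("primary"), params,
                       default_lt()),
    tolerance = 1e-12
  )
})

test_that("hospitalisation schedule is constant with the published multipliers", {
  sub <- subgroup_config("HFrEF<75")
  h <- hospitalisation_schedule(sub, "clinical")
  expect_equal(h, rep(1 - exp(-0.198), 120), tolerance = 1e-12)
  # identical for preserved EF
  expect_identical(h, hospitalisation_schedule(subgroup_config("HFpEF<75"),
                                               "clinical"))
  # over-75 age HR applied on the hazard scale
  old <- hospitalisation_schedule(subgroup_config("HFrEF>=75"), "clinical")
  expect_equal(old[1], 1 - exp(-0.066 * 1.248 * 3), tolerance = 1e-12)
  # BNP multiplier inside the effect window only
  b <- hospitalisation_schedule(sub, "bnp")
  expect_equal(b[1:16], h[1:16] * 0.94, tolerance = 1e-12)
  expect_identical(b[17:120], h[17:120])
})
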