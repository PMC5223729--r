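test_that("per-cycle QALY accrual mixes utilities by length of stay", {
  # hand arithmetic on the published utilities and stay length
  expect_equal(cycle_qalys(1, 1, 0.66, 0.77, 13.21),
               (13.21 * 0.66 + (91.31 - 13.21) * 0.77) / 365.25,
               tolerance = 1e-12)
  # zero-length stay: both arms accrue the stable-state value
  expect_equal(cycle_qalys(1, 1, 0.66, 0.77, 0),
               0.77 * 91.31 / 365.25, tolerance = 1e-12)
  expect_equal(cycle_qalys(1, 0.3, 0.66, 0.77, 0),
               cycle_qalys(1, 0.9, 0.66, 0.77, 0), tolerance = 1e-12)
  # equal utilities: independent of P_h and stay length
  expect_equal(cycle_qalys(0.5, 0.2, 0.7, 0.7, 40),
               cycle_qalys(0.5, 0.9, 0.7, 0.7, 5), tolerance = 1e-12)
  expect_error(cycle_qalys(1, 0.5, 0.66, 0.77, 95), "length of stay")
})

test_that("per-cycle costs combine state costs and BNP add-on streams", {
  sub <- subgroup_config("HFrEF<75")
  ps <- point_estimate_set()
  clin <- strategy_costing(ps, sub, "clinical")
  expect_equal(cycle_costs(1, 0, clin, 0), 682)
  expect_equal(cycle_costs(1, 1, clin, 0), 9104)
  expect_equal(cycle_costs(0, 0.5, clin, 3), 0)
  expect_true(all(clin$addon == 0))

  bnp <- strategy_costing(ps, sub, "bnp")
  # tests (25) + medication (58.32/6) + incremental visits (0.3/8 * 123)
  expect_equal(bnp$addon[1:6], rep(25 + 58.32 / 6 + 0.3 / 8 * 123, 6),
               tolerance = 1e-9)
  expect_equal(bnp$addon[7:8], rep(0.3 / 8 * 123, 2), tolerance = 1e-9)
  expect_true(all(bnp$addon[9:120] == 0))
  expect_equal(bnp$addon[1], 39.3325, tolerance = 1e-9)

  # over-75 state costs
  old <- strategy_costing(ps, subgroup_config("HFrEF>=75"), "clinical")
  expect_equal(cycle_costs(1, 0, old, 0), 569)
  expect_equal(cycle_costs(1, 1, old, 0), 8057)

  # sampled visit counts can invert; the increment is floored at zero
  ps2 <- ps
  ps2[["visits_bnp"]] <- 0.9
  noneg <- strategy_costing(ps2, sub, "bnp")
  expect_equal(noneg$addon[7], 0)
})

test_that("the cohort trace conserves mass and matches a per-cycle oracle", {
  sub <- subgroup_config("HFrEF<75")
  ps <- point_estimate_set()
  sched <- build_schedules(sub, "bnp", params = ps, lt = default_lt())
  costing <- strategy_costing(ps, sub, "bnp")
  utils_ <- list(u_h = 0.66, u_nh = 0.77, los = 13.21)
  tr <- run_cohort(sched, costing, utils_)

  # conservation: alive + cumulative deaths = 1 each cycle
  expect_equal(tr$alive_end + cumsum(tr$deaths), rep(1, 120),
               tolerance = 1e-12)
  expect_true(all(diff(tr$alive_start) <= 0))
  expect_true(all(tr$deaths >= 0))

  # survival through the 4-year BNP effect window: probability-scale HR
  p <- (1 - exp(-0.027)) * 0.68
  expect_equal(tr$alive_start[17], (1 - p)^16, tolerance = 1e-9)

  # independent per-cycle oracle: explicit loop over the accrual rules
  q_h <- (13.21 * 0.66 + (91.31 - 13.21) * 0.77) / 365.25
  q_nh <- 0.77 * 91.31 / 365.25
  alive <- 1
  cost_o <- qaly_o <- 0
  for (t in seq_len(120)) {
    d <- sched$d[t]; h <- sched$h[t]
    dead <- alive * d
    surv <- alive - dead
    disc <- 1.035^(-((t - 1) + 0.5) / 4)
    qaly_o <- qaly_o + disc *
      (surv * (h * q_h + (1 - h) * q_nh) + 0.5 * dead * q_nh)
    cost_o <- cost_o + disc *
      (surv * (h * costing$cost_h + (1 - h) * costing$cost_nh) +
         0.5 * dead * costing$cost_nh + surv * costing$addon[t])
    alive <- surv
  }
  expect_equal(unname(tr$totals["qalys"]), qaly_o, tolerance = 1e-12)
  expect_equal(unname(tr$totals["cost"]), cost_o, tolerance = 1e-12)
})

test_that("degenerate cohorts accrue closed-form totals", {
  # immortal, never hospitalised, undiscounted: one year at utility 0.77
  sched <- toy_schedule(rep(0, 4), rep(0, 4))
  costing <- toy_costing(0, 0, 4)
  tr <- run_cohort(sched, costing, list(u_h = 0.5, u_nh = 0.77, los = 0),
                   discount_rate = 0)
  expect_equal(unname(tr$totals["qalys"]), 0.77 * 4 * 91.31 / 365.25,
               tolerance = 1e-12)
  expect_equal(unname(tr$totals["cost"]), 0)

  # person-years with constant mortality, no discounting: the trace's
  # half-cycle-corrected occupancy sits between the start- and end-of-cycle
  # Riemann sums of the exponential survival curve
  d <- rep(0.2, 4)
  tr2 <- run_cohort(toy_schedule(d, rep(0, 4)), toy_costing(0, 0, 4),
                    list(u_h = 1, u_nh = 1, los = 0), discount_rate = 0)
  occupancy <- sum(tr2$alive_end + 0.5 * tr2$deaths)
  s <- cumprod(1 - d)
  expect_lte(occupancy, sum(c(1, s[1:3])))  # left sum (alive at cycle start)
  expect_gte(occupancy, sum(s))             # right sum (alive at cycle end)
})

test_that("discounting and parameter monotonicity behave as expected", {
  sub <- subgroup_config("HFrEF<75")
  ps <- point_estimate_set()
  sched <- build_schedules(sub, "clinical", params = ps, lt = default_lt())
  costing <- strategy_costing(ps, sub, "clinical")
  utils_ <- list(u_h = 0.66, u_nh = 0.77, los = 13.21)

  t0 <- run_cohort(sched, costing, utils_, discount_rate = 0)$totals
  t35 <- run_cohort(sched, costing, utils_, discount_rate = 0.035)$totals
  expect_gt(t0["qalys"], t35["qalys"])
  expect_gt(t0["cost"], t35["cost"])

  # lowering any death probability weakly increases lifetime QALYs
  sched_lo <- sched
  sched_lo$d[5] <- sched$d[5] * 0.5
  expect_gt(run_cohort(sched_lo, costing, utils_)$totals["qalys"],
            t35["qalys"])
  # raising a cost parameter weakly increases lifetime cost
  costing_hi <- costing
  costing_hi$cost_nh <- costing$cost_nh + 100
  expect_gt(run_cohort(sched, costing_hi, utils_)$totals["cost"],
            t35["cost"])

  # schedule/costing length mismatches are refused
  expect_error(run_cohort(toy_schedule(rep(0, 3), rep(0, 4)),
                          toy_costing(0, 0, 3), utils_), "differ in length")
  expect_error(run_cohort(toy_schedule(rep(0, 4), rep(0, 4)),
                          toy_costing(0, 0, 3), utils_), "add-on stream")
})

test_that("median survival interpolates the alive curve", {
  # constant per-cycle survival 0.5: median at the first cycle boundary
  tr <- run_cohort(toy_schedule(rep(0.5, 4), rep(0, 4)), toy_costing(0, 0, 4),
                   list(u_h = 1, u_nh = 1, los = 0))
  expect_equal(median_survival(tr), 0.25)

  # never crosses 0.5: censored flag
  tr2 <- run_cohort(toy_schedule(rep(0.01, 4), rep(0, 4)),
                    toy_costing(0, 0, 4), list(u_h = 1, u_nh = 1, los = 0))
  m <- median_survival(tr2)
  expect_true(is.na(m))
  expect_true(attr(m, "censored"))

  # clinical HFrEF<75: interpolated crossing agrees with the
  # piecewise-exponential closed form ln(2)/0.009 months to within the
  # linear-interpolation error of one cycle
  det <- run_deterministic("HFrEF<75")
  expect_equal(median_survival(det$traces$clinical), log(2) / 0.009 / 12,
               tolerance = 0.002)
})

test_that("traces export one row per cycle at full precision", {
  det <- run_deterministic("HFrEF<75")
  df <- as.data.frame(det$traces$clinical)
  expect_identical(nrow(df), 120L)
  expect_identical(df$cycle[1], 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(det$traces$clinical, path)
  back <- utils::read.csv(path)
  expect_equal(back$alive_end, df$alive_end, tolerance = 1e-12)
})
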