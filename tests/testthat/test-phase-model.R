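test_that("parameter constructors enforce the model invariants", {
  expect_s3_class(base_case_params(), "four_params")
  expect_error(four_params(0.007, 0.026, 159.6, 1599.6), class = "fermpump_unit_error")
  expect_error(four_params(-1, 0.026, 100, 1000, rate_unit = "mL/min"),
               class = "fermpump_param_error")
  expect_error(four_params(0.007, 0, 100, 1000, rate_unit = "mL/min"),
               class = "fermpump_param_error")
  expect_error(four_params(0.007, 0.026, 1000, 1000, rate_unit = "mL/min"),
               class = "fermpump_param_error")  # t_e must exceed t_i
  expect_error(six_params(0.007, 0.026, 100, 1000, t_s = 0, t_ds = 40,
                          rate_unit = "mL/min"), class = "fermpump_param_error")
  expect_error(six_params(0.007, 0.026, 100, 1000, t_s = 1200, t_ds = 40,
                          rate_unit = "mL/min"), class = "fermpump_param_error")
  expect_error(six_params(0.007, 0.026, 100, 1000, t_s = 500, t_ds = 0,
                          rate_unit = "mL/min"), class = "fermpump_param_error")
})

test_that("unit conversion multiplies s_f by exactly 1000 and round-trips", {
  p <- base_case_params()
  p_ul <- convert_rate_unit(p, "uL/min")
  expect_identical(p_ul$s_f, p$s_f * 1000)
  expect_identical(p_ul$rate_unit, "uL/min")
  expect_identical(convert_rate_unit(p_ul, "mL/min")$s_f, p$s_f)
  # identity when already in the target unit
  expect_identical(convert_rate_unit(p, "mL/min"), p)
})

test_that("startup sigmoid: midpoint, saturation limits, frozen arithmetic case", {
  p <- base_case_params()
  expect_equal(startup_factor(p$t_i, p), p$s_f / 2)
  expect_equal(startup_factor(1e9, p), p$s_f)
  expect_equal(startup_factor(-1e9, p), 0)
  # s_t*(t - t_i) = 3.705635 at t = 301.84; logistic = 0.975962
  expect_equal(startup_factor(301.84, p), 0.0071160549, tolerance = 1e-6)
  # strictly increasing and inside (0, s_f) while the logistic argument is
  # representable away from saturation
  tt <- seq(-500, 1200, by = 7)
  v <- startup_factor(tt, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < p$s_f))
})

test_that("stable-phase factor: midpoint 1.5, limits, frozen value at t_s + t_ds", {
  expect_equal(stable_factor(500, 500, 40), 1.5)
  expect_equal(stable_factor(1e9, 500, 40), 1)
  expect_equal(stable_factor(-1e9, 500, 40), 2)
  expect_equal(stable_factor(540, 500, 40), 1 + 1 / (1 + exp(1)))
  tt <- seq(-200, 1500, by = 13)  # |argument| < 30: away from saturation
  v <- stable_factor(tt, 500, 40)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 1 & v < 2))
  expect_error(stable_factor(100, 500, 0), class = "fermpump_param_error")
})

test_that("decline factor: value e-1 at 0, clamps to 0 at and after t_e", {
  expect_equal(decline_factor(0, 1599.6), exp(1) - 1)
  expect_equal(decline_factor(1599.6, 1599.6), 0)
  expect_equal(decline_factor(1e6, 1599.6), 0)
  expect_equal(decline_factor(1599.6 * log(2), 1599.6), exp(1) - 2)
  tt <- seq(0, 1599, by = 3)
  expect_true(all(diff(decline_factor(tt, 1599.6)) < 0))
  expect_error(decline_factor(100, -5), class = "fermpump_param_error")
})

test_that("four-parameter rate reproduces the worked base case and clamps at t_e", {
  p <- base_case_params()
  expect_equal(1000 * pump_rate(p, 301.84), 10.75, tolerance = 1e-3)
  expect_equal(pump_rate(p, c(p$t_e, p$t_e + 100, 5000)), c(0, 0, 0))
  p0 <- four_params(0, p$s_t, p$t_i, p$t_e, rate_unit = "mL/min")
  expect_equal(pump_rate(p0, seq(0, 2000, by = 50)), rep(0, 41))
  expect_error(pump_rate(p, -1), class = "fermpump_input_error")
})

test_that("six-parameter rate factorizes into its three phase terms", {
  withr::with_seed(101, {
    for (k in 1:20) {
      p4 <- random_four_params()
      p6 <- six_params(p4$s_f, p4$s_t, p4$t_i, p4$t_e,
                       t_s = runif(1, 0.2, 0.8) * p4$t_e,
                       t_ds = runif(1, 10, 80), rate_unit = "mL/min")
      tt <- sort(runif(25, 0, p4$t_e * 1.1))
      expect_equal(
        pump_rate(p6, tt),
        startup_factor(tt, p6) * stable_factor(tt, p6$t_s, p6$t_ds) *
          decline_factor(tt, p6$t_e)
      )
      # and the four-parameter model is the same product without the
      # diauxic term
      expect_equal(pump_rate(p4, tt),
                   pump_rate(p6, tt) / stable_factor(tt, p6$t_s, p6$t_ds))
    }
  })
})

test_that("six-parameter rate approaches twice the four-parameter rate for a late diauxic onset", {
  p4 <- base_case_params()
  p6 <- six_params(p4$s_f, p4$s_t, p4$t_i, p4$t_e,
                   t_s = p4$t_e * (1 - 1e-9), t_ds = 1e-3, rate_unit = "mL/min")
  tt <- seq(0, 0.9 * p4$t_e, by = 25)
  expect_equal(pump_rate(p6, tt), 2 * pump_rate(p4, tt), tolerance = 1e-9)
})

test_that("cumulative volume is zero at 0, non-decreasing, flat after t_e", {
  p <- base_case_params()
  expect_identical(cumulative_volume(p, 0), 0)
  tt <- c(0, 50, 200, 400, 800, 1200, p$t_e, p$t_e + 500)
  v <- cumulative_volume(p, tt)
  expect_true(all(diff(v) >= 0))
  expect_equal(v[7], v[8])
  expect_error(cumulative_volume(p, -3), class = "fermpump_input_error")
  expect_error(cumulative_volume(p, Inf), class = "fermpump_input_error")
})

test_that("cumulative volume matches a 0.05-min trapezoid oracle within 0.1% at t_e", {
  withr::with_seed(202, {
    for (k in 1:8) {
      p <- random_four_params()
      fine <- seq(0, p$t_e, by = 0.05)
      oracle <- pracma::trapz(fine, pump_rate(p, fine))
      expect_equal(cumulative_volume(p, p$t_e), oracle, tolerance = 1e-3)
    }
  })
})

test_that("closed-form peak time matches its formula and flags the undefined regime", {
  p <- base_case_params()
  expect_equal(peak_time(p), p$t_i + log(p$s_t * p$t_e - 1) / p$s_t)
  # s_t * t_e = 1 + e forces the log term to 1
  pe <- four_params(0.007, 0.01, 50, (1 + exp(1)) / 0.01, rate_unit = "mL/min")
  expect_equal(peak_time(pe), pe$t_i + 1 / pe$s_t)
  # s_t * t_e <= 1: analytic peak undefined, numeric_peak still works
  pu <- four_params(0.007, 0.001, 50, 900, rate_unit = "mL/min")
  expect_error(peak_time(pu), class = "fermpump_peak_undefined")
  expect_s3_class(numeric_peak(pu), "peak_estimate")
})

test_that("closed-form peak rate never exceeds the numeric maximum", {
  withr::with_seed(303, {
    for (k in 1:15) {
      p <- random_four_params()
      if (p$s_t * p$t_e <= 1) next
      np <- numeric_peak(p)
      expect_lte(peak_rate(p), np$q_max + 1e-9)
      expect_gt(np$t_max, 0)
      expect_lt(np$t_max, p$t_e)
    }
  })
})

test_that("numeric peak is interior, within 5% of the closed form on the printed regimes, and scale-invariant in time", {
  for (p in list(base_case_params(), sucrose3_params())) {
    np <- numeric_peak(p)
    tm <- peak_time(p)
    expect_gt(np$t_max, p$t_i)
    expect_lt(np$t_max, p$t_e)
    expect_lt(abs(np$t_max - tm) / tm, 0.05)
  }
  # rescaling s_f leaves the argmax unchanged
  p <- base_case_params()
  p10 <- four_params(10 * p$s_f, p$s_t, p$t_i, p$t_e, rate_unit = "mL/min")
  expect_equal(numeric_peak(p10)$t_max, numeric_peak(p)$t_max, tolerance = 1e-6)
})

test_that("phase factors stay numerically stable at extreme arguments", {
  p <- four_params(0.01, 0.05, 100, 2000, rate_unit = "mL/min")
  # exponent s_t*(t - t_i) ~ 95 would overflow a naive exp-ratio
  expect_equal(startup_factor(2000, p), p$s_f)
  expect_false(any(is.nan(pump_rate(p, seq(0, 1e5, length.out = 101)))))
  expect_equal(stable_factor(c(-1e8, 1e8), 500, 1e-3), c(2, 1))
})
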