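test_that("cycle grid has a 28-day first cycle then 21-day cycles", {
  g <- cycle_grid(5)
  expect_equal(g$n_cycles, 86L)
  expect_equal(g$intervals[1], 28)
  expect_true(all(g$intervals[-1] == 21))
  expect_true(all(diff(g$boundaries) > 0))
  # cycle-count formula across horizons
  for (h in c(0.5, 1, 2, 3.7, 5, 10)) {
    g <- cycle_grid(h)
    expect_equal(g$n_cycles, 1 + floor((h * 365.25 - 28) / 21))
    expect_lte(max(g$boundaries), h * 365.25)
  }
})

test_that("median-to-rate conversion matches the exponential definition", {
  # an interval equal to the median carries event probability 1/2
  med_21d <- 21 / 30.44  # months
  lam <- median_to_rate(med_21d)
  expect_equal(1 - exp(-lam * 21), 0.5, tolerance = 1e-12)
  # 8-month median on a 21-day cycle, closed form evaluated independently
  p <- 1 - exp(-median_to_rate(8) * 21)
  expect_equal(p, 1 - exp(-log(2) / 243.52 * 21), tolerance = 1e-12)
  # infinite-median limit
  expect_lt(1 - exp(-median_to_rate(1e9) * 21), 1e-9)
  expect_error(median_to_rate(0), "median > 0")
})

test_that("cause-specific split is a proper competing-risk conversion", {
  p <- cause_specific_cycle_probs(0.004, 0.001, 21)
  expect_equal(p$p_prog + p$p_death + p$p_stay, 1, tolerance = 1e-12)
  # single-risk limit
  p0 <- cause_specific_cycle_probs(0.003, 0, 21)
  expect_equal(p0$p_death, 0)
  expect_equal(p0$p_prog, 1 - exp(-0.003 * 21), tolerance = 1e-12)
  # symmetric hazards give symmetric probabilities
  ps <- cause_specific_cycle_probs(0.004, 0.002, 21)
  expect_equal(ps$p_prog, ps$p_death, tolerance = 1e-12)
  expect_error(cause_specific_cycle_probs(0.001, 0.002, 21), "inconsistent")
})

test_that("cause-specific split agrees with a two-risk microsimulation", {
  # independent oracle: simulate exponential times to progression and death
  n <- 1e6
  lam_prog <- 0.003; lam_death <- 0.001
  withr::with_seed(7, {
    t_prog <- rexp(n, lam_prog)
    t_death <- rexp(n, lam_death)
  })
  t_event <- pmin(t_prog, t_death)
  emp_prog <- mean(t_event <= 21 & t_prog < t_death)
  emp_death <- mean(t_event <= 21 & t_death <= t_prog)
  p <- cause_specific_cycle_probs(lam_prog + lam_death, lam_death, 21)
  se <- sqrt(0.25 / n)
  expect_lt(abs(p$p_prog - emp_prog), 3 * se)
  expect_lt(abs(p$p_death - emp_death), 3 * se)
})

test_that("piecewise hazards average correctly over cycles", {
  g <- cycle_grid(1)
  # constant piecewise spec reproduces the exponential path
  lam_day <- median_to_rate(9)
  pw <- surv_spec("piecewise_hazard", breakpoints = 0,
                  hazards = lam_day * 30.44)
  expect_equal(piecewise_cycle_hazards(pw, g),
               rep(lam_day, g$n_cycles), tolerance = 1e-12)

  # breakpoint exactly at the cycle-2 boundary (day 49): each cycle gets its
  # piece's hazard
  bp_day <- 49
  pw2 <- surv_spec("piecewise_hazard", breakpoints = c(0, bp_day / 30.44),
                   hazards = c(0.03, 0.09))
  h <- suppressWarnings(piecewise_cycle_hazards(pw2, g))
  expect_equal(h[1:2], rep(0.03 / 30.44, 2), tolerance = 1e-12)
  expect_equal(h[3:g$n_cycles], rep(0.09 / 30.44, g$n_cycles - 2),
               tolerance = 1e-12)

  # mid-cycle breakpoint: duration-weighted average, cross-checked against
  # numerical integration of the step hazard
  bp_day <- 60  # inside cycle 3 (days 49-70)
  pw3 <- surv_spec("piecewise_hazard", breakpoints = c(0, bp_day / 30.44),
                   hazards = c(0.03, 0.09))
  h3 <- suppressWarnings(piecewise_cycle_hazards(pw3, g))[3]
  quad <- stats::integrate(function(t)
    ifelse(t < bp_day, 0.03 / 30.44, 0.09 / 30.44), 49, 70,
    subdivisions = 1000L)$value / 21
  expect_equal(h3, quad, tolerance = 1e-3)
  expect_warning(piecewise_cycle_hazards(pw3, g), "does not cover")
})

test_that("survival reconstruction and monotonicity hold", {
  g <- cycle_grid(5)
  lam <- median_to_rate(14)
  p_event <- 1 - exp(-lam * g$intervals)
  surv <- cumprod(1 - p_event)
  expect_equal(surv, exp(-lam * g$boundaries[-1]), tolerance = 1e-9)
  # event probability nondecreasing in hazard and interval
  lams <- seq(0, 0.01, by = 0.001)
  expect_true(all(diff(1 - exp(-lams * 21)) >= 0))
  ts <- seq(1, 42, by = 1)
  expect_true(all(diff(1 - exp(-0.002 * ts)) >= 0))
})
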