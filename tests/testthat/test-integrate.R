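test_that("two-compartment loop relaxes with the closed-form time constant", {
  fx <- make_fixture("two-compartment-loop")
  expect_equal(fx$tau, 0.5)
  sol <- integrate_fixed_step(fx$rhs, fx$y0, dt = 0.001, duration = 3)
  dp <- sol$states[, 1] / fx$C[1] - sol$states[, 2] / fx$C[2]
  # simulated half-life within 1% of ln(2) * tau
  half_idx <- which(dp <= fx$dp(0) / 2)[1]
  expect_equal(sol$time[half_idx], log(2) * fx$tau,
               tolerance = 0.01)
  # full trajectory matches the analytic exponential
  expect_equal(dp, fx$dp(sol$time), tolerance = 1e-6)
  expect_equal(sol$states[nrow(sol$states), ], fx$equilibrium,
               tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("fixed-step integrator agrees with deSolve on the same system", {
  skip_if_not_installed("deSolve")
  fx <- make_fixture("two-compartment-loop")
  mine <- integrate_fixed_step(fx$rhs, fx$y0, dt = 0.001, duration = 2)
  ds <- deSolve::ode(y = fx$y0, times = seq(0, 2, by = 0.001),
                     func = function(t, y, parms) list(fx$rhs(t, y)),
                     parms = NULL, method = "rk4")
  expect_equal(mine$states[, 1], unname(ds[, 2]), tolerance = 1e-10)
  # and on the full CPR model over a short horizon
  p <- cpr_parameters(tpf = 0.75)
  proto <- cpr_protocol()
  rhs <- cprplr:::build_rhs(p, proto)
  mine2 <- integrate_fixed_step(rhs, p$compartments$V0, dt = 0.001,
                                duration = 2)
  ds2 <- deSolve::ode(y = p$compartments$V0, times = seq(0, 2, by = 0.001),
                      func = function(t, y, parms) list(rhs(t, y)),
                      parms = NULL, method = "rk4")
  expect_equal(max(abs(mine2$states - ds2[, 2:15])), 0, tolerance = 1e-9)
})

test_that("no-valves loop at uniform pressure has zero dynamics", {
  fx <- make_fixture("no-valves-loop")
  sol <- integrate_fixed_step(fx$rhs, fx$y0, dt = 0.01, duration = 1)
  expect_equal(sol$states[nrow(sol$states), ], fx$y0,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("arrest equilibrium is preserved without forcing", {
  p <- cpr_parameters()
  quiet <- cpr_protocol(amplitude = 0)
  tr <- simulate_cpr(p, quiet, dt = 0.001, duration = 5)
  dev <- abs(tr$volumes[nrow(tr$volumes), ] - p$compartments$V0)
  expect_lt(max(dev), 1e-9)
  expect_equal(unname(tr$pressures[nrow(tr$pressures), ]), rep(p$P0, 14))
})

test_that("simulated volumes are conserved, non-negative and valve-lawful", {
  tr <- cached_short_trace()
  total <- rowSums(tr$volumes)
  expect_lt(max(abs(total - total[1])), 1e-6)
  expect_true(all(tr$volumes >= 0))
  valve_cols <- tr$params$edges$name[tr$params$edges$valve]
  expect_true(all(tr$flows[, valve_cols] >= -1e-15))
  # coronary gating holds at every recorded step
  compressed <- tr$force > tr$protocol$force_gate_threshold
  expect_true(all(tr$flows[compressed, "C8_C1"] == 0))
  expect_true(any(tr$flows[!compressed, "C8_C1"] > 0))
})

test_that("periodic steady state is reached by 8 s", {
  tr <- cached_short_trace()
  # consecutive-cycle means of aortic pressure beyond 8 s differ < 0.5%
  cyc <- function(a) mean(tr$pressures[tr$time >= a & tr$time < a + 0.6, 8])
  starts <- seq(8, 11.4 - 0.6, by = 0.6)
  m <- vapply(starts, cyc, numeric(1))
  expect_true(all(abs(diff(m) / m[-length(m)]) < 0.005))
  # cycle-averaged CO on [8, 10] and [10, 12] agrees within 1%
  co1 <- summarize_window(tr, c(8, 10))$co
  co2 <- summarize_window(tr, c(10, 12))$co
  expect_equal(co1, co2, tolerance = 0.01)
})

test_that("explicit Euler and RK4 give the same cycle-averaged CO", {
  fx <- make_fixture("reference-short")
  tr_rk <- cached_short_trace()
  tr_eu <- cached_euler_short()
  co_rk <- summarize_window(tr_rk, c(8, 12))$co
  co_eu <- summarize_window(tr_eu, c(8, 12))$co
  expect_equal(co_eu, co_rk, tolerance = 0.02)
})

test_that("a diverging system aborts naming the offending component", {
  blowup <- function(t, y) 1e3 * y
  expect_error(
    integrate_fixed_step(blowup, c(a = 1, b = 2), dt = 0.5, duration = 400),
    "non-finite state in component a at t")
})
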