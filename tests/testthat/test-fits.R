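# Fitting primitives: exact recovery on model-generated data, degenerate
# input handling, diagnostics.

test_that("Boltzmann fit recovers exact parameters to 1e-6", {
  V <- seq(-80, 60, by = 10)
  for (p in list(c(-21.5, 10.0), c(7.8, 9.0), c(-4.3, 12.0))) {
    y <- 1 / (1 + exp(-(V - p[1]) / p[2]))
    f <- fit_boltzmann(V, y)
    expect_true(f$converged)
    expect_equal(f$V_half, p[1], tolerance = 1e-6)
    expect_equal(f$k, p[2], tolerance = 1e-6)
  }
})

test_that("Boltzmann fit rejects degenerate inputs", {
  expect_error(fit_boltzmann(c(-40, -20, 0, 20), rep(0.5, 4)), "degenerate")
  expect_error(fit_boltzmann(c(-40, -20, 0), c(0.1, 0.5, 0.9)), "4 points")
  expect_error(fit_boltzmann(seq(-40, 20, 10), rep(0.9, 7)), "degenerate")
})

test_that("single-exponential fit recovers tau and flags constants", {
  t <- seq(0, 100, by = 0.02)
  y <- -1.8 * exp(-t / 9.4) + 2
  f <- fit_single_exp(t, y)
  expect_true(f$converged)
  expect_equal(f$tau_ms, 9.4, tolerance = 1e-3)
  expect_equal(f$offset, 2, tolerance = 1e-6)
  fc <- fit_single_exp(t, rep(3, length(t)))
  expect_false(fc$converged)
  expect_true("amplitude_zero" %in% fc$flags)
})

test_that("single-exponential residual diagnostic fires on bi-exponential
           input", {
  t <- seq(0, 200, by = 0.02)
  y <- 1 * exp(-t / 5) + 1 * exp(-t / 60)
  f <- fit_single_exp(t, y)
  expect_true("poor_fit" %in% f$flags)
})

test_that("drift-augmented fit removes slow multiplicative droop bias", {
  t <- seq(0, 200, by = 0.02)
  droop <- 1 - 8e-5 * t  # ~1.6% over the window, as slow inactivation gives
  y <- (2 - 1.9 * exp(-t / 30)) * droop
  plain <- fit_single_exp(t, y)
  drift <- fit_single_exp(t, y, drift = TRUE)
  expect_lt(abs(drift$tau_ms - 30) / 30, abs(plain$tau_ms - 30) / 30)
  expect_lt(abs(drift$tau_ms - 30) / 30, 0.01)
})

test_that("tau(V) law fit is exact on law-generated points and guards
           voltage-independent input", {
  V <- seq(-30, 60, by = 10)
  for (tv in c(9.4, 31.7)) {
    tau <- tv * exp((V - -21.5) / -40)
    f <- fit_tau_law(V, tau, V_half = -21.5)
    expect_equal(f$tau_at_Vhalf, tv, tolerance = 1e-6)
    expect_equal(f$k_tau, -40, tolerance = 1e-6)
  }
  fc <- fit_tau_law(V, rep(12, length(V)), V_half = -21.5)
  expect_true("k_tau_unidentifiable" %in% fc$flags)
  expect_error(fit_tau_law(V, c(-1, rep(5, length(V) - 1)), -21.5),
               "positive")
})

test_that("double-exponential fit recovers both Table-style constant pairs
           within 2% and flags collapse", {
  t <- seq(0, 90, by = 0.01)
  for (p in list(c(4.9, 37.4), c(5.8, 42.1))) {
    y <- 0.3 * exp(-t / p[1]) + 0.7 * exp(-t / p[2])
    f <- fit_double_exp(t, y)
    expect_true(f$converged)
    expect_lt(abs(f$tau_fast_s - p[1]) / p[1], 0.02)
    expect_lt(abs(f$tau_slow_s - p[2]) / p[2], 0.02)
    expect_equal(f$frac_fast, 0.3, tolerance = 0.01)
    expect_true(f$tau_fast_s < f$tau_slow_s)
  }
  fs <- fit_double_exp(t, exp(-t / 10))
  expect_true("component_collapse" %in% fs$flags)
})

test_that("recovery fit recovers tau and guards flat or invalid curves", {
  dt <- seq(0.1, 17.1, by = 1)
  for (tv in c(3.4, 2.2)) {
    r <- 1 - 0.6 * exp(-dt / tv)
    f <- fit_recovery(dt, r)
    expect_true(f$converged)
    expect_lt(abs(f$tau_s - tv), 0.05)
  }
  # free plateau: a curve saturating at 0.99 is still fitted without bias
  r <- 0.99 * (1 - 0.6 * exp(-dt / 2.2))
  f <- fit_recovery(dt, r)
  expect_lt(abs(f$tau_s - 2.2) / 2.2, 0.001)
  expect_equal(f$plateau, 0.99, tolerance = 1e-4)
  fn <- fit_recovery(dt, rep(1, length(dt)))
  expect_true("no_inactivation" %in% fn$flags)
  expect_error(fit_recovery(dt, rep(1.3, length(dt))), "1.1")
  expect_error(fit_recovery(c(1, 2, 3), c(0.5, 0.7, 0.8)), "4 intervals")
})
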