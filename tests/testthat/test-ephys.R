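# Analysis pipeline on simulated recordings: IV amplitudes, tail curves,
# full characterization, cohort statistics and the t-test.

test_that("calibrated IV currents reproduce the measured +20 mV amplitudes", {
  for (spec in list(c("WT", 2.1), c("P403A", 0.4), c("WT+P403A", 0.55))) {
    fx <- char_fixture(spec[1])
    iv <- measure_iv(fx$recordings$iv)
    expect_equal(iv$current[iv$step_V == 20], as.numeric(spec[2]),
                 tolerance = 1e-8)
  }
  # the mutant is smaller at every activating potential
  iv_wt <- measure_iv(char_fixture("WT")$recordings$iv)
  iv_mut <- measure_iv(char_fixture("P403A")$recordings$iv)
  on_range <- iv_wt$step_V >= -20
  expect_true(all(iv_mut$current[on_range] < iv_wt$current[on_range]))
})

test_that("tail amplitudes normalize to 1 at +60 and reach 0.5 near the
           generative midpoint", {
  pts <- extract_tail_amplitudes(char_fixture("WT")$recordings$tail)
  expect_equal(pts$norm[pts$prepulse_V == 60], 1)
  expect_true(all(pts$norm >= -0.05 & pts$norm <= 1.05))
  mid <- approx(pts$prepulse_V, pts$norm, xout = -21.5)$y
  expect_equal(mid, 0.5, tolerance = 0.01)
})

test_that("noise-free characterization recovers every generative parameter", {
  tol_t <- 0.02
  cases <- list(
    WT = list(V_half = -21.5, k = 10.0, act = 9.4, deact = 41.5,
              tf = 4.9, ts = 37.4, rec = 3.4),
    P403A = list(V_half = 7.8, k = 9.0, act = 31.7, deact = 47.2,
                 tf = 5.8, ts = 42.1, rec = 2.2),
    `WT+P403A` = list(V_half = -4.3, k = 12.0, act = 14.7, deact = 41.5,
                      tf = 5.8, ts = 40.2, rec = 2.8))
  for (nm in names(cases)) {
    ch <- char_result(nm)
    gen <- cases[[nm]]
    expect_lt(abs(ch$V_half - gen$V_half), 0.5)
    expect_lt(abs(ch$k - gen$k), 0.5)
    expect_lt(abs(ch$act_tau_Vhalf - gen$act) / gen$act, tol_t)
    expect_lt(abs(ch$deact_tau_Vhalf - gen$deact) / gen$deact, tol_t)
    expect_lt(abs(ch$tau_fast - gen$tf) / gen$tf, tol_t)
    expect_lt(abs(ch$tau_slow - gen$ts) / gen$ts, tol_t)
    expect_lt(abs(ch$tau_recovery - gen$rec) / gen$rec, tol_t)
    # generator-only constants recovered too
    expect_lt(abs(ch$frac_fast - 0.3), 0.01)
    expect_lt(abs(ch$act_k_tau - -40) / 40, 0.05)
    expect_lt(abs(ch$deact_k_tau - 25) / 25, 0.05)
  }
})

test_that("characterization errors carry the failing stage name", {
  fx <- char_fixture("WT")
  recs <- fx$recordings["tail"]
  broken <- recs
  for (i in seq_along(broken$tail$traces))
    broken$tail$traces[[i]]$current[] <- 0
  expect_error(characterize_cell(broken), "tail")
})

test_that("cohort statistics use the n-1 SEM convention", {
  s <- cohort_stats(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$sem, 0); expect_equal(s$n, 3L)
  s2 <- cohort_stats(c(0, 2))
  expect_equal(s2$mean, 1); expect_equal(s2$sem, 1)
  s3 <- cohort_stats(c(5, NA, 7))
  expect_equal(s3$n, 2L)
})

test_that("pooled-variance Student's t-test matches a hand-computed
           reference and the degenerate convention", {
  expect_equal(kv_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-12)
  expect_identical(kv_t_test(c(2, 2), c(2, 2))$p, 1)
  sep <- kv_t_test(c(1, 2, 3), c(11.01, 12.02, 12.99))
  expect_true(sep$significant)
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1))
    got <- kv_t_test(a, b)
    # independent pooled-variance reference, written out from the formula
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    pref <- 2 * pt(-abs(tref), na + nb - 2)
    expect_equal(got$t, tref, tolerance = 1e-12)
    expect_equal(got$p, pref, tolerance = 1e-12)
    expect_equal(got$df, na + nb - 2)
  }
})
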