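# Closed-form simulator: determinism, sampling, analytic identities and
# the independent ODE oracle.

test_that("a 200 ms segment at 50 kHz yields exactly 10,000 samples", {
  wt <- kv11_species("WT")
  sw <- build_iv_protocol()$sweeps[[11]]  # +20 mV step
  tr <- simulate_sweep(wt, sw)
  expect_equal(sum(tr$command_mV == 20), 10000)
  expect_equal(length(tr$time_ms), length(tr$current))
  expect_true(all(diff(tr$time_ms) > 0))
})

test_that("noise-free simulation is deterministic; seeded noise reproduces", {
  wt <- kv11_species("WT")
  p <- build_iv_protocol()
  a <- simulate_protocol(wt, p, noise_sd = 0)
  b <- simulate_protocol(wt, p, noise_sd = 0)
  expect_identical(a$traces[[5]]$current, b$traces[[5]]$current)
  a <- simulate_protocol(wt, p, noise_sd = 0.02, seed = 42)
  b <- simulate_protocol(wt, p, noise_sd = 0.02, seed = 42)
  expect_identical(a$traces[[5]]$current, b$traces[[5]]$current)
  c <- simulate_protocol(wt, p, noise_sd = 0.02, seed = 43)
  expect_false(identical(a$traces[[5]]$current, c$traces[[5]]$current))
})

test_that("a sweep held at the reversal potential carries zero current", {
  wt <- kv11_species("WT")
  sw <- kv_sweep(list(voltage_segment(wt$E_rev, 10),
                      voltage_segment(wt$E_rev, 100),
                      voltage_segment(wt$E_rev, 10)),
                 holding = wt$E_rev, sampling_rate = 50000, label = "erev")
  tr <- simulate_sweep(wt, sw)
  expect_true(all(abs(tr$current) < 1e-12))
})

test_that("peak tail current after a saturating prepulse matches the
           analytic gate product", {
  wt <- kv11_species("WT")
  p <- build_tail_protocol(-50)
  tr <- simulate_protocol(wt, p)$traces[[15]]  # +60 mV prepulse
  # analytic states, written out independently of the simulator
  minf <- function(V) 1 / (1 + exp(-(V - -21.5) / 10))
  m0 <- minf(-80)
  tau60 <- 9.4 * exp((60 - -21.5) / -40)
  m_end <- minf(60) - (minf(60) - m0) * exp(-200 / tau60)
  tau_h <- function(tau_dep, V = 60) 1000 * exp(log(tau_dep))  # V >= 0
  hf_end <- exp(-200 / (1000 * 4.9))
  hs_end <- exp(-200 / (1000 * 37.4))
  occ <- 0.3 * hf_end + 0.7 * hs_end
  # first tail sample (t_rel = 0): gates unchanged, V = -50
  i_tail <- which(tr$command_mV == -50)[1]
  expected <- wt$g_max * m_end * occ * (-50 - wt$E_rev)
  expect_equal(tr$current[i_tail], expected, tolerance = 1e-9)
})

test_that("closed-form traces match independent ODE integration", {
  wt <- kv11_species("WT")
  sw <- build_tail_protocol(-50)$sweeps[[10]]   # +10 mV prepulse
  tr <- simulate_sweep(wt, sw)
  at <- tr$time_ms[seq(1, length(tr$time_ms), by = 200)]
  ode <- ode_current(wt, sw, at)
  sim <- tr$current[match(ode$time_ms, tr$time_ms)]
  expect_lt(max(abs(sim - ode$current)) / max(abs(tr$current)), 1e-6)
})

test_that("cohort jitter degenerates correctly and is reproducible", {
  wt <- kv11_species("WT")
  p <- build_iv_protocol()
  cells <- simulate_cohort(cohort_spec(3, wt, jitter_cv = 0, noise_sd = 0),
                           list(p))
  expect_identical(cells[[1]]$recordings$iv$traces[[5]]$current,
                   cells[[3]]$recordings$iv$traces[[5]]$current)
  a <- simulate_cohort(cohort_spec(2, wt, 0.2, 0.02, seed = 7), list(p))
  b <- simulate_cohort(cohort_spec(2, wt, 0.2, 0.02, seed = 7), list(p))
  expect_identical(a[[2]]$recordings$iv$traces[[3]]$current,
                   b[[2]]$recordings$iv$traces[[3]]$current)
})

test_that("jittered species keep their invariants at high CV", {
  wt <- kv11_species("WT")
  set.seed(11)
  for (i in 1:50) {
    sp <- jitter_species(wt, 0.5)
    expect_true(sp$inact$tau_fast < sp$inact$tau_slow)
    expect_true(sp$inact$frac_fast > 0 && sp$inact$frac_fast < 1)
    expect_true(sp$g_max >= 0)
  }
})

test_that("a jittered cohort's activation-midpoint SEM has the order of
           whole-cell scatter", {
  wt <- kv11_species("WT")
  cells <- simulate_cohort(cohort_spec(29, wt, jitter_cv = 0.2,
                                       noise_sd = 0.021, seed = 3),
                           list(build_tail_protocol(-50)))
  vh <- vapply(cells, function(cell) {
    pts <- extract_tail_amplitudes(cell$recordings$tail)
    fit_boltzmann(pts$prepulse_V, pts$norm)$V_half
  }, numeric(1))
  st <- cohort_stats(vh)
  expect_equal(st$n, 29)
  # printed cohort SEM is 0.4 mV over 29 cells; loose factor-3 band
  expect_gt(st$sem, 0.4 / 3)
  expect_lt(st$sem, 0.4 * 3)
  expect_lt(abs(st$mean - -21.5), 1.5)
})

test_that("trace CSV round-trip preserves recordings", {
  wt <- kv11_species("WT")
  p <- build_iv_protocol()
  rec <- simulate_protocol(wt, p, noise_sd = 0.01, seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_traces(rec, tmp)
  back <- read_traces(tmp, p)
  expect_length(back, 1)
  expect_equal(back[[1]]$traces[[7]]$current, rec$traces[[7]]$current)
  expect_identical(back[[1]]$traces[[7]]$label, rec$traces[[7]]$label)
  # analysis on re-read traces gives identical results
  expect_equal(measure_iv(back[[1]]), measure_iv(rec))
  unlink(tmp)
})
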