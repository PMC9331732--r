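# Shared fixtures. Heavy noise-free simulations are computed once per
# test run and cached in this environment.

.kv_cache <- new.env(parent = emptyenv())

kv_cached <- function(key, expr) {
  if (!exists(key, envir = .kv_cache))
    assign(key, force(expr), envir = .kv_cache)
  get(key, envir = .kv_cache)
}

# noise-free full characterization of one packaged species
char_fixture <- function(name) {
  kv_cached(paste0("char_", name), {
    sp <- kv11_species(name)
    list(species = sp,
         recordings = simulate_characterization_set(sp),
         char = NULL)
  })
}

char_result <- function(name) {
  kv_cached(paste0("charres_", name),
            characterize_cell(char_fixture(name)$recordings))
}

# Independent fine-tolerance ODE integration of the same gating scheme,
# used as the oracle for the closed-form simulator. Gate laws are
# written out from the species parameters here, independently of the
# package internals.
ode_open_fraction <- function(sp, sweep, at_times_ms) {
  m_inf <- function(V) 1 / (1 + exp(-(V - sp$activation$V_half) /
                                      sp$activation$k))
  tau_m <- function(V) {
    law <- if (V >= -40) sp$act_tau else sp$deact_tau
    law$tau_at_Vhalf * exp((V - law$V_half) / law$k_tau)
  }
  h_inf <- function(V) min(max(-V / 60, 0), 1)
  tau_h <- function(V, tau_dep) {
    f <- min(max((V + 60) / 60, 0), 1)
    1000 * exp((1 - f) * log(sp$inact$tau_recovery) + f * log(tau_dep))
  }
  derivs <- function(t, state, parms) {
    V <- parms$V
    list(c((m_inf(V) - state[1]) / tau_m(V),
           (h_inf(V) - state[2]) / tau_h(V, sp$inact$tau_fast),
           (h_inf(V) - state[3]) / tau_h(V, sp$inact$tau_slow)))
  }
  Vh <- sweep$holding
  state <- c(m_inf(Vh), h_inf(Vh), h_inf(Vh))
  dur <- vapply(sweep$segments, function(s) s$duration, numeric(1))
  lev <- vapply(sweep$segments, function(s) s$level, numeric(1))
  bounds <- c(0, cumsum(dur))
  out_t <- numeric(0); out_o <- numeric(0)
  for (j in seq_along(dur)) {
    inside <- at_times_ms[at_times_ms >= bounds[j] &
                            at_times_ms < bounds[j + 1]]
    times <- sort(unique(c(0, inside - bounds[j], dur[j])))
    sol <- deSolve::lsoda(state, times, derivs, parms = list(V = lev[j]),
                          rtol = 1e-11, atol = 1e-12)
    f <- sp$inact$frac_fast
    keep <- sol[, 1] %in% (inside - bounds[j])
    out_t <- c(out_t, sol[keep, 1] + bounds[j])
    out_o <- c(out_o, sol[keep, 2] *
                 (f * sol[keep, 3] + (1 - f) * sol[keep, 4]))
    state <- unname(sol[nrow(sol), 2:4])
  }
  list(time_ms = out_t, open = out_o)
}

ode_current <- function(sp, sweep, at_times_ms) {
  o <- ode_open_fraction(sp, sweep, at_times_ms)
  dur <- vapply(sweep$segments, function(s) s$duration, numeric(1))
  lev <- vapply(sweep$segments, function(s) s$level, numeric(1))
  V_at <- lev[findInterval(o$time_ms, c(0, cumsum(dur)),
                           rightmost.closed = FALSE)]
  list(time_ms = o$time_ms,
       current = sp$g_max * o$open * (V_at - sp$E_rev))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
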