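# Curve fitting primitives of the characterization pipeline.
#
# All nonlinear fits use Levenberg-Marquardt least squares
# (minpack.lm::nlsLM) seeded from analytic log-linear initial values,
# with a small multi-start fallback on non-convergence. Fitters never
# fail silently: degenerate inputs either raise an error or return a
# flagged result.

.try_nlsLM <- function(formula, data, start, maxiter = 200) {
  fit <- try(minpack.lm::nlsLM(
    formula, data = data, start = start,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12)),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  fit
}

# nlsLM with analytic start and up to 3 multiplicatively perturbed restarts
.fit_multistart <- function(formula, data, start, n_restarts = 3) {
  fit <- .try_nlsLM(formula, data, start)
  if (!is.null(fit)) return(fit)
  for (i in seq_len(n_restarts)) {
    pert <- lapply(start, function(v) v * stats::runif(1, 0.5, 2))
    fit <- .try_nlsLM(formula, data, pert)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' Fit a Boltzmann activation curve
#'
#' Least-squares fit of `y = 1 / (1 + exp(-(V - V_half) / k))` to
#' normalized activation data.
#'
#' @param V Prepulse potentials (mV).
#' @param y Normalized amplitudes.
#' @return List with `V_half`, `k`, `rss`, `converged`, `fitted`.
#' @export
fit_boltzmann <- function(V, y) {
  stopifnot(length(V) == length(y), all(is.finite(V)), all(is.finite(y)))
  if (length(V) < 4) stop("Boltzmann fit needs at least 4 points")
  if (!any(y < 0.5) || !any(y > 0.5))
    stop("degenerate activation curve: points do not bracket the midpoint")
  # logit-linear initialization on clipped amplitudes
  yc <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  init <- stats::lm(stats::qlogis(yc) ~ V)
  k0 <- 1 / coef(init)[[2]]
  V0 <- -coef(init)[[1]] * k0
  if (!is.finite(k0) || k0 == 0) { k0 <- 10; V0 <- stats::median(V) }
  dat <- data.frame(V = V, y = y)
  fit <- .fit_multistart(y ~ 1 / (1 + exp(-(V - Vh) / k)), dat,
                         list(Vh = V0, k = k0))
  if (is.null(fit))
    return(list(V_half = NA_real_, k = NA_real_, rss = NA_real_,
                converged = FALSE, fitted = rep(NA_real_, length(V))))
  cf <- coef(fit)
  list(V_half = cf[["Vh"]], k = cf[["k"]],
       rss = sum(stats::resid(fit)^2), converged = TRUE,
       fitted = stats::fitted(fit))
}

#' Fit a single-exponential relaxation
#'
#' Fits `I(t) = A exp(-(t - t0) / tau) + C` to one monotone relaxation.
#' The fit window is restricted iteratively to about `window_tau_mult`
#' fitted time constants, which keeps much slower superimposed processes
#' (C-type inactivation under a 200 ms activation step) from biasing the
#' fast time constant.
#'
#' @param time_ms Sample times (ms), relative or absolute.
#' @param current Current samples.
#' @param window_tau_mult Fit-window length in units of the fitted tau.
#' @param drift If `TRUE`, a linear baseline drift term `D t` is added to
#'   the model, absorbing the slow C-type inactivation that rides on
#'   200 ms activation/deactivation steps; recommended for gating
#'   kinetics, off by default.
#' @return List with `tau_ms`, `amplitude`, `offset`, `rss`,
#'   `rmse_over_amp` (residual diagnostic), `converged`, `flags`
#'   (character vector; `"amplitude_zero"`, `"poor_fit"` ...).
#' @export
fit_single_exp <- function(time_ms, current, window_tau_mult = 8,
                           drift = FALSE) {
  stopifnot(length(time_ms) == length(current), length(time_ms) >= 5)
  t0 <- time_ms[1]
  t <- time_ms - t0
  y <- current
  flags <- character(0)
  C0 <- mean(y[t >= max(t) * 0.9])
  r <- y - C0
  s <- sign(r[which.max(abs(r))])
  if (s == 0) s <- 1
  r <- s * r
  amp_scale <- max(abs(y - C0))
  if (amp_scale < 1e-12 || amp_scale < 1e-6 * max(abs(y), 1e-12)) {
    return(list(tau_ms = NA_real_, amplitude = 0, offset = C0,
                rss = 0, rmse_over_amp = NA_real_, converged = FALSE,
                flags = "amplitude_zero"))
  }
  ok <- r > max(r) * 1e-3 & t < max(t) * 0.9
  if (sum(ok) < 3) ok <- r > 0
  init <- stats::lm(log(r[ok]) ~ t[ok])
  tau0 <- -1 / coef(init)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 5
  A0 <- s * exp(coef(init)[[1]])
  fit <- NULL
  form <- if (drift) y ~ A * exp(-t / tau) + C + D * t
          else y ~ A * exp(-t / tau) + C
  for (pass in 1:3) {
    keep <- t <= min(max(t), window_tau_mult * tau0)
    if (sum(keep) < 10) keep <- seq_along(t) <= 10
    dat <- data.frame(t = t[keep], y = y[keep])
    start <- list(A = A0, tau = tau0, C = C0)
    if (drift) start$D <- 0
    fit <- .fit_multistart(form, dat, start)
    if (is.null(fit)) break
    tau_new <- coef(fit)[["tau"]]
    if (tau_new <= 0) break
    if (abs(tau_new - tau0) < 1e-4 * tau0) { tau0 <- tau_new; break }
    tau0 <- tau_new
  }
  if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
    return(list(tau_ms = NA_real_, amplitude = NA_real_, offset = NA_real_,
                rss = NA_real_, rmse_over_amp = NA_real_, converged = FALSE,
                flags = c(flags, "nonconvergent")))
  }
  cf <- coef(fit)
  rss <- sum(stats::resid(fit)^2)
  rmse_over_amp <- sqrt(rss / length(stats::resid(fit))) / abs(cf[["A"]])
  if (rmse_over_amp > 0.04) flags <- c(flags, "poor_fit")
  list(tau_ms = cf[["tau"]], amplitude = cf[["A"]], offset = cf[["C"]],
       rss = rss, rmse_over_amp = rmse_over_amp, converged = TRUE,
       flags = flags)
}

#' Fit the exponential voltage dependence of a time constant
#'
#' `tau(V) = tau_at_Vhalf exp((V - V_half) / k_tau)` is exactly
#' log-linear, so the fit is ordinary least squares of `log(tau)` on
#' `V - V_half` with the midpoint supplied from the same cell's
#' Boltzmann fit.
#'
#' @param V Potentials (mV).
#' @param tau Time constants (> 0), any consistent unit.
#' @param V_half Midpoint from the activation fit (mV).
#' @return List with `tau_at_Vhalf`, `k_tau`, `rss`, `flags`
#'   (`"k_tau_unidentifiable"` when tau does not depend on V).
#' @export
fit_tau_law <- function(V, tau, V_half) {
  stopifnot(length(V) == length(tau), length(V) >= 3, is.finite(V_half))
  if (any(!is.finite(tau) | tau <= 0))
    stop("tau_law fit needs finite positive time constants")
  x <- V - V_half
  fit <- stats::lm(log(tau) ~ x)
  slope <- coef(fit)[[2]]
  flags <- character(0)
  if (abs(slope) < 1e-8) {
    flags <- "k_tau_unidentifiable"
    k_tau <- Inf
  } else k_tau <- 1 / slope
  list(tau_at_Vhalf = exp(coef(fit)[[1]]), k_tau = k_tau,
       rss = sum(stats::resid(fit)^2), flags = flags)
}

#' Fit a double-exponential decay
#'
#' Fits `I(t) = A_f exp(-t/tau_f) + A_s exp(-t/tau_s) + C` to a slow
#' inactivation decay, initialized by peeling (log-linear fit of the late
#' decay for the slow component, then of the early residual for the fast
#' one). Time constants are returned ordered fast < slow.
#'
#' @param time_s Sample times (s), starting at the decay onset.
#' @param current Current samples.
#' @return List with `tau_fast_s`, `tau_slow_s`, `frac_fast` (fast share
#'   of the decaying amplitude), `offset`, `rss`, `converged`, `flags`
#'   (`"component_collapse"` when the two time constants agree within 5%).
#' @export
fit_double_exp <- function(time_s, current) {
  stopifnot(length(time_s) == length(current), length(time_s) >= 10)
  t <- time_s - time_s[1]
  y <- current
  T_end <- max(t)
  C0 <- min(0, min(y))
  # peel the slow component from the late half
  late <- t > T_end * 0.45
  r_late <- pmax(y[late] - C0, max(y) * 1e-9)
  sl <- stats::lm(log(r_late) ~ t[late])
  tau_s0 <- max(-1 / coef(sl)[[2]], T_end / 50)
  A_s0 <- exp(coef(sl)[[1]])
  # fast component from the early residual
  early <- t < T_end * 0.2
  r_early <- y[early] - C0 - A_s0 * exp(-t[early] / tau_s0)
  pos <- r_early > max(abs(r_early)) * 1e-3
  if (sum(pos) >= 3) {
    fl <- stats::lm(log(r_early[pos]) ~ t[early][pos])
    tau_f0 <- -1 / coef(fl)[[2]]
    A_f0 <- exp(coef(fl)[[1]])
    if (!is.finite(tau_f0) || tau_f0 <= 0) { tau_f0 <- tau_s0 / 8; A_f0 <- A_s0 / 2 }
  } else { tau_f0 <- tau_s0 / 8; A_f0 <- A_s0 / 2 }
  dat <- data.frame(t = t, y = y)
  fit <- .fit_multistart(
    y ~ Af * exp(-t / tf) + As * exp(-t / ts) + C, dat,
    list(Af = A_f0, tf = tau_f0, As = A_s0, ts = tau_s0, C = 0))
  if (is.null(fit))
    return(list(tau_fast_s = NA_real_, tau_slow_s = NA_real_,
                frac_fast = NA_real_, offset = NA_real_, rss = NA_real_,
                converged = FALSE, flags = "nonconvergent"))
  cf <- coef(fit)
  tf <- cf[["tf"]]; ts <- cf[["ts"]]; Af <- cf[["Af"]]; As <- cf[["As"]]
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; tmp <- Af; Af <- As; As <- tmp }
  flags <- character(0)
  if (ts > 0 && abs(ts - tf) / ts < 0.05) flags <- "component_collapse"
  frac <- Af / (Af + As)
  if (frac < 0.02 || frac > 0.98) flags <- union(flags, "component_collapse")
  list(tau_fast_s = tf, tau_slow_s = ts, frac_fast = frac,
       offset = cf[["C"]], rss = sum(stats::resid(fit)^2),
       converged = TRUE, flags = flags)
}

#' Fit an exponential recovery-from-inactivation curve
#'
#' Fits `R(dt) = A - (A - R0) exp(-dt / tau)` to double-pulse peak
#' ratios. The plateau `A` is free (normalization): when the probe pulse
#' is too short for slowly activating channels to reach their
#' conditioning-pulse peak, the ratio saturates slightly below 1, and
#' pinning the plateau at 1 would bias the time constant.
#'
#' @param interval_s Interpulse intervals (s).
#' @param ratio P2/P1 peak-current ratios.
#' @return List with `tau_s`, `R0`, `plateau`, `rss`, `converged`,
#'   `flags` (`"no_inactivation"` when the ratios carry no relaxation).
#' @export
fit_recovery <- function(interval_s, ratio) {
  stopifnot(length(interval_s) == length(ratio))
  if (length(interval_s) < 4) stop("recovery fit needs at least 4 intervals")
  if (any(ratio > 1.1)) stop("P2/P1 ratios above 1.1: input not a recovery curve")
  if (max(ratio) - min(ratio) < 1e-3)
    return(list(tau_s = NA_real_, R0 = mean(ratio), plateau = mean(ratio),
                rss = 0, converged = FALSE, flags = "no_inactivation"))
  A0 <- max(ratio)
  d <- A0 - ratio
  pos <- d > max(d) * 1e-3
  init <- stats::lm(log(d[pos]) ~ interval_s[pos])
  tau0 <- -1 / coef(init)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(interval_s) / 3
  dat <- data.frame(dt = interval_s, r = ratio)
  fit <- .fit_multistart(r ~ A - (A - R0) * exp(-dt / tau), dat,
                         list(A = A0, R0 = max(min(ratio), 1e-3),
                              tau = tau0))
  if (is.null(fit) || coef(fit)[["tau"]] <= 0)
    return(list(tau_s = NA_real_, R0 = NA_real_, plateau = NA_real_,
                rss = NA_real_, converged = FALSE, flags = "nonconvergent"))
  cf <- coef(fit)
  list(tau_s = cf[["tau"]], R0 = cf[["R0"]], plateau = cf[["A"]],
       rss = sum(stats::resid(fit)^2), converged = TRUE,
       flags = character(0))
}
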