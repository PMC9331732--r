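# From raw sweeps to the biophysical parameter table.
#
# The pipeline mirrors standard whole-cell analysis practice: steady
# currents from the last 10% of each step (baseline-subtracted against
# the pre-step holding window), peak tail currents normalized and fitted
# with a Boltzmann, single-exponential kinetics per voltage followed by
# the exponential tau(V) law, a double-exponential fit of the 90 s
# inactivation decay, and an exponential fit of double-pulse recovery
# ratios. Cohort summaries are mean +/- SEM over cells with two-sample
# Student's t-tests between groups.

.segment_times <- function(sweep) {
  dur <- vapply(sweep$segments, function(s) s$duration, numeric(1))
  lev <- vapply(sweep$segments, function(s) s$level, numeric(1))
  end <- cumsum(dur)
  data.frame(start_ms = c(0, end[-length(end)]), end_ms = end, level = lev)
}

.trace_window <- function(trace, from_ms, to_ms) {
  idx <- trace$time_ms >= from_ms & trace$time_ms < to_ms
  if (!any(idx)) stop("empty trace window")
  trace$current[idx]
}

# mean current over the leading holding baseline
.baseline <- function(trace, segs) {
  if (nrow(segs) < 2 || segs$end_ms[1] <= 0)
    stop("missing baseline window before the first command segment")
  mean(.trace_window(trace, 0, segs$end_ms[1]))
}

#' Current-voltage table from an IV recording
#'
#' Steady current per sweep, averaged over the last 10% of the 200 ms
#' step (these currents do not inactivate measurably on that timescale)
#' and baseline-subtracted using the pre-step holding window.
#'
#' @param recording A `kv_recording` from [build_iv_protocol()] traces.
#' @return `data.frame` with `step_V` (mV) and `current` (display units).
#' @export
measure_iv <- function(recording) {
  stopifnot(inherits(recording, "kv_recording"))
  rows <- mapply(function(trace, sweep) {
    segs <- .segment_times(sweep)
    b <- .baseline(trace, segs)
    step <- segs[2, ]
    w0 <- step$end_ms - 0.1 * (step$end_ms - step$start_ms)
    data.frame(step_V = step$level,
               current = mean(.trace_window(trace, w0, step$end_ms)) - b)
  }, recording$traces, recording$protocol$sweeps, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Peak tail amplitudes from a tail-protocol recording
#'
#' The tail amplitude is the baseline-subtracted current extremum in a
#' short window starting `skip_ms` after the tail-step onset (skipping
#' the capacitive-artifact settling time); amplitudes are normalized by
#' their maximum over prepulses. The measurement window is kept short
#' (`window_ms`, default 2 ms) so that prepulses leaving the channels
#' below their tail-potential equilibrium do not contribute slowly
#' re-activating current to the foot of the activation curve.
#'
#' @param recording A `kv_recording` from [build_tail_protocol()] traces.
#' @param skip_ms Settling time skipped after the voltage transition (ms).
#' @param window_ms Measurement window length after the skip (ms).
#' @return `data.frame` with `prepulse_V`, `amplitude` (raw, signed) and
#'   `norm` (normalized).
#' @export
extract_tail_amplitudes <- function(recording, skip_ms = 0.5,
                                    window_ms = 2) {
  stopifnot(inherits(recording, "kv_recording"))
  rows <- mapply(function(trace, sweep) {
    segs <- .segment_times(sweep)
    b <- .baseline(trace, segs)
    tail_seg <- segs[3, ]
    w <- .trace_window(trace, tail_seg$start_ms + skip_ms,
                       min(tail_seg$start_ms + skip_ms + window_ms,
                           tail_seg$end_ms))
    amp <- (w - b)[which.max(abs(w - b))]
    data.frame(prepulse_V = segs$level[2], amplitude = amp)
  }, recording$traces, recording$protocol$sweeps, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  peak <- max(abs(out$amplitude))
  if (peak < 1e-12) stop("no activation detected: all tail amplitudes zero")
  out$norm <- out$amplitude / out$amplitude[which.max(abs(out$amplitude))]
  out
}

#' Activation-kinetics time constants per voltage
#'
#' Single-exponential fits of the activating phase of IV-protocol steps
#' at test potentials at or above `min_V` (where the channels open
#' measurably), starting `skip_ms` after the step onset.
#'
#' @param recording IV-protocol `kv_recording`.
#' @param min_V Lowest fitted step potential (mV); default -30.
#' @param skip_ms Settling time skipped after the transition (ms).
#' @return `data.frame` with `V`, `tau_ms`, `converged`, `flags`.
#' @export
activation_time_constants <- function(recording, min_V = -30,
                                      skip_ms = 0.5) {
  rows <- mapply(function(trace, sweep) {
    segs <- .segment_times(sweep)
    V <- segs$level[2]
    if (V < min_V) return(NULL)
    idx <- trace$time_ms >= segs$start_ms[2] + skip_ms &
      trace$time_ms < segs$end_ms[2]
    f <- fit_single_exp(trace$time_ms[idx], trace$current[idx],
                        drift = TRUE)
    data.frame(V = V, tau_ms = f$tau_ms, converged = f$converged,
               flags = paste(f$flags, collapse = ";"))
  }, recording$traces, recording$protocol$sweeps, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Deactivation-kinetics time constants per voltage
#'
#' Single-exponential fits of the post-step decay of deactivation-protocol
#' sweeps at post potentials at or below `max_V`.
#'
#' @param recording Deactivation-protocol `kv_recording`.
#' @param max_V Highest fitted post potential (mV); default -50, i.e.
#'   strictly below the -40 mV activation/deactivation crossover of the
#'   gating model.
#' @param skip_ms Settling time skipped after the transition (ms).
#' @return `data.frame` with `V`, `tau_ms`, `converged`, `flags`.
#' @export
deactivation_time_constants <- function(recording, max_V = -50,
                                        skip_ms = 0.5) {
  rows <- mapply(function(trace, sweep) {
    segs <- .segment_times(sweep)
    V <- segs$level[3]
    if (V > max_V) return(NULL)
    idx <- trace$time_ms >= segs$start_ms[3] + skip_ms &
      trace$time_ms < segs$end_ms[3]
    f <- fit_single_exp(trace$time_ms[idx], trace$current[idx],
                        drift = TRUE)
    data.frame(V = V, tau_ms = f$tau_ms, converged = f$converged,
               flags = paste(f$flags, collapse = ";"))
  }, recording$traces, recording$protocol$sweeps, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Double-exponential inactivation fit from the 90 s pulse
#'
#' Locates the current peak within the +40 mV test pulse and fits the
#' decay from the peak onward.
#'
#' @param recording Inactivation-protocol `kv_recording`.
#' @return The [fit_double_exp()] result.
#' @export
measure_inactivation <- function(recording) {
  trace <- recording$traces[[1]]
  segs <- .segment_times(recording$protocol$sweeps[[1]])
  idx <- trace$time_ms >= segs$start_ms[2] & trace$time_ms < segs$end_ms[2]
  t <- trace$time_ms[idx]; y <- trace$current[idx]
  ip <- which.max(abs(y))
  fit_double_exp((t[ip:length(t)] - t[ip]) / 1000, y[ip:length(y)])
}

#' Recovery curve and exponential fit from double-pulse sweeps
#'
#' P2/P1 peak ratios per interpulse interval. Ratios marginally above 1
#' (noise) are capped at 1; no further renormalization is applied, since
#' dividing by the second pulse of the conditioning pair already
#' normalizes the curve.
#'
#' @param recording Recovery-protocol `kv_recording`.
#' @return List with `curve` (`data.frame`: `interval_s`, `ratio`) and
#'   `fit` (the [fit_recovery()] result).
#' @export
measure_recovery <- function(recording) {
  rows <- mapply(function(trace, sweep) {
    segs <- .segment_times(sweep)
    b <- .baseline(trace, segs)
    p1 <- max(abs(.trace_window(trace, segs$start_ms[2], segs$end_ms[2]) - b))
    p2 <- max(abs(.trace_window(trace, segs$start_ms[4], segs$end_ms[4]) - b))
    data.frame(interval_s = sweep$meta$interval_s, ratio = p2 / p1)
  }, recording$traces, recording$protocol$sweeps, SIMPLIFY = FALSE)
  curve <- do.call(rbind, rows)
  curve$ratio <- pmin(curve$ratio, 1)
  list(curve = curve, fit = fit_recovery(curve$interval_s, curve$ratio))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Full single-cell characterization
#'
#' Runs the complete chain (IV table, tail amplitudes, Boltzmann fit,
#' activation/deactivation kinetics with tau(V) laws, double-exponential
#' inactivation, recovery) on one cell's recordings and returns the
#' Table-style parameter set. Deterministic given its inputs; stage
#' failures are raised with the stage name.
#'
#' @param recordings Named list of `kv_recording`s with entries `iv`,
#'   `tail`, `deactivation`, `inactivation`, `recovery` (missing entries
#'   leave the corresponding parameters `NA`).
#' @return An object of class `kv_characterization`: list with fields
#'   `V_half`, `k`, `act_tau_Vhalf`, `act_k_tau`, `deact_tau_Vhalf`,
#'   `deact_k_tau`, `tau_fast`, `tau_slow`, `frac_fast`, `tau_recovery`,
#'   `iv`, `activation_curve`, `diagnostics`.
#' @export
characterize_cell <- function(recordings) {
  out <- list(V_half = NA_real_, k = NA_real_,
              act_tau_Vhalf = NA_real_, act_k_tau = NA_real_,
              deact_tau_Vhalf = NA_real_, deact_k_tau = NA_real_,
              tau_fast = NA_real_, tau_slow = NA_real_,
              frac_fast = NA_real_, tau_recovery = NA_real_,
              iv = NULL, activation_curve = NULL, diagnostics = list())

  if (!is.null(recordings$iv))
    out$iv <- .stage("iv", measure_iv(recordings$iv))

  if (!is.null(recordings$tail)) {
    pts <- .stage("tail", extract_tail_amplitudes(recordings$tail))
    bf <- .stage("boltzmann", fit_boltzmann(pts$prepulse_V, pts$norm))
    out$activation_curve <- pts
    out$V_half <- bf$V_half
    out$k <- bf$k
    out$diagnostics$boltzmann <- bf
  }

  if (!is.null(recordings$iv) && is.finite(out$V_half)) {
    taus <- .stage("activation_kinetics",
                   activation_time_constants(recordings$iv))
    taus <- taus[taus$converged & is.finite(taus$tau_ms), ]
    law <- .stage("activation_tau_law",
                  fit_tau_law(taus$V, taus$tau_ms, out$V_half))
    out$act_tau_Vhalf <- law$tau_at_Vhalf
    out$act_k_tau <- law$k_tau
    out$diagnostics$activation_taus <- taus
  }

  if (!is.null(recordings$deactivation) && is.finite(out$V_half)) {
    taus <- .stage("deactivation_kinetics",
                   deactivation_time_constants(recordings$deactivation))
    taus <- taus[taus$converged & is.finite(taus$tau_ms), ]
    law <- .stage("deactivation_tau_law",
                  fit_tau_law(taus$V, taus$tau_ms, out$V_half))
    out$deact_tau_Vhalf <- law$tau_at_Vhalf
    out$deact_k_tau <- law$k_tau
    out$diagnostics$deactivation_taus <- taus
  }

  if (!is.null(recordings$inactivation)) {
    f <- .stage("inactivation", measure_inactivation(recordings$inactivation))
    out$tau_fast <- f$tau_fast_s
    out$tau_slow <- f$tau_slow_s
    out$frac_fast <- f$frac_fast
    out$diagnostics$inactivation <- f
  }

  if (!is.null(recordings$recovery)) {
    r <- .stage("recovery", measure_recovery(recordings$recovery))
    out$tau_recovery <- r$fit$tau_s
    out$diagnostics$recovery <- r
  }

  structure(out, class = "kv_characterization")
}

#' @export
print.kv_characterization <- function(x, ...) {
  cat("Kv channel characterization\n")
  cat(sprintf("  V_1/2        %8.2f mV\n", x$V_half))
  cat(sprintf("  k            %8.2f mV\n", x$k))
  cat(sprintf("  tau_act      %8.2f ms (at V_1/2)\n", x$act_tau_Vhalf))
  cat(sprintf("  tau_deact    %8.2f ms (at V_1/2)\n", x$deact_tau_Vhalf))
  cat(sprintf("  tau_fast     %8.2f s\n", x$tau_fast))
  cat(sprintf("  tau_slow     %8.2f s\n", x$tau_slow))
  cat(sprintf("  frac_fast    %8.2f\n", x$frac_fast))
  cat(sprintf("  tau_recovery %8.2f s\n", x$tau_recovery))
  invisible(x)
}

#' Mean, SEM and n of per-cell estimates
#'
#' @param values Numeric vector of per-cell estimates; `NA`s dropped.
#' @return List with `mean`, `sem` (sd with n-1 denominator over sqrt(n))
#'   and `n`.
#' @export
cohort_stats <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 1) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  sem <- if (n == 1) NA_real_ else stats::sd(v) / sqrt(n)
  list(mean = mean(v), sem = sem, n = n)
}

.KV_PARAM_FIELDS <- c("V_half", "k", "act_tau_Vhalf", "deact_tau_Vhalf",
                      "tau_fast", "tau_slow", "frac_fast", "tau_recovery")

#' Characterize a simulated cohort
#'
#' @param cells Output of [simulate_cohort()].
#' @return List with `per_cell` (`data.frame` of per-cell estimates) and
#'   `summary` (`data.frame` with mean, sem, n per parameter).
#' @export
characterize_cohort <- function(cells) {
  per_cell <- do.call(rbind, lapply(cells, function(cell) {
    ch <- characterize_cell(cell$recordings)
    cbind(data.frame(cell_id = cell$cell_id),
          as.data.frame(ch[.KV_PARAM_FIELDS]))
  }))
  summary <- do.call(rbind, lapply(.KV_PARAM_FIELDS, function(f) {
    st <- cohort_stats(per_cell[[f]])
    data.frame(parameter = f, mean = st$mean, sem = st$sem, n = st$n)
  }))
  list(per_cell = per_cell, summary = summary)
}

#' Two-sample Student's t-test
#'
#' Classical pooled-variance, two-tailed two-sample t-test, with the
#' convention p = 1 for two groups with zero pooled variance and equal
#' means.
#'
#' @param groupA,groupB Numeric vectors (each n >= 2).
#' @param alpha Significance level for the `significant` flag.
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
kv_t_test <- function(groupA, groupB, alpha = 0.05) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0 &&
      mean(groupA) == mean(groupB))
    return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1,
                significant = FALSE))
  tt <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha)
}
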