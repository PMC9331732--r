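# Synthetic whole-cell recording engine.
#
# The gating model is piecewise-constant in voltage over a protocol, so
# every first-order gate relaxes in closed form within each segment:
# x(t) = x_inf - (x_inf - x0) exp(-t / tau(V)). The simulator evaluates
# that closed form on the sample grid, carries gate states across segment
# boundaries, and sums weighted component currents
# I = sum_c w_c g_c m_c (f h_f + (1 - f) h_s) (V - E_rev).
# Gates start at their steady state for the holding potential (long
# inter-sweep rests). Gaussian noise is added after signal synthesis; a
# noise-free run is fully deterministic.

.as_components <- function(model) {
  if (inherits(model, "channel_species"))
    return(list(list(species = model, weight = 1)))
  if (inherits(model, "mixture_model")) return(model$components)
  stop("model must be a channel_species or mixture_model")
}

# closed-form relaxation of one gate over one segment's sample grid
.relax <- function(x0, x_inf, tau_ms, t_rel) {
  x_inf - (x_inf - x0) * exp(-t_rel / tau_ms)
}

#' Simulate one voltage-clamp sweep
#'
#' @param model A [channel_species] or [mixture_model].
#' @param sweep A [kv_sweep].
#' @param noise_sd Standard deviation of additive Gaussian recording noise
#'   (display current units); 0 gives a deterministic trace.
#' @param seed Optional integer seed applied before noise generation.
#' @param cell_id Cell identifier stored in the trace.
#' @param lowpass_noise If `TRUE`, the noise (only) is low-pass filtered
#'   at 2 kHz with a 4-pole filter before being added, mimicking the
#'   acquisition bandwidth; off by default so fits see exact model output
#'   plus white noise.
#' @return An object of class `kv_trace` with fields `time_ms`, `current`,
#'   `command_mV`, `label`, `meta`, `cell_id`, `sampling_rate`.
#' @export
simulate_sweep <- function(model, sweep, noise_sd = 0, seed = NULL,
                           cell_id = "cell1", lowpass_noise = FALSE) {
  stopifnot(inherits(sweep, "kv_sweep"), noise_sd >= 0)
  comps <- .as_components(model)
  fs <- sweep$sampling_rate
  n_seg <- vapply(sweep$segments, function(s)
    round(s$duration * fs / 1000), numeric(1))
  if (any(n_seg < 1)) stop("segment shorter than one sample period")
  n_tot <- sum(n_seg)
  time_ms <- (seq_len(n_tot) - 1) / fs * 1000
  command <- rep(vapply(sweep$segments, function(s) s$level, numeric(1)),
                 times = n_seg)

  current <- numeric(n_tot)
  for (comp in comps) {
    sp <- comp$species
    if (comp$weight == 0 || sp$g_max == 0) next
    # gate states at sweep start: steady state at holding
    Vh <- sweep$holding
    m <- steady_state_open(Vh, sp$activation)
    hf <- .h_inf(Vh)
    hs <- .h_inf(Vh)
    O <- numeric(n_tot)
    idx0 <- 0
    for (j in seq_along(sweep$segments)) {
      seg <- sweep$segments[[j]]
      n <- n_seg[j]
      V <- seg$level
      t_rel <- (seq_len(n) - 1) / fs * 1000
      tm <- .tau_m(V, sp)
      thf <- .tau_h(V, sp, "fast")
      ths <- .tau_h(V, sp, "slow")
      m_inf <- steady_state_open(V, sp$activation)
      h_inf <- .h_inf(V)
      m_t <- .relax(m, m_inf, tm, t_rel)
      hf_t <- .relax(hf, h_inf, thf, t_rel)
      hs_t <- .relax(hs, h_inf, ths, t_rel)
      f <- sp$inact$frac_fast
      O[idx0 + seq_len(n)] <- m_t * (f * hf_t + (1 - f) * hs_t)
      # states at segment end (duration, not last sample time)
      dur <- seg$duration
      m <- .relax(m, m_inf, tm, dur)
      hf <- .relax(hf, h_inf, thf, dur)
      hs <- .relax(hs, h_inf, ths, dur)
      idx0 <- idx0 + n
    }
    current <- current + comp$weight * sp$g_max * O * (command - sp$E_rev)
  }

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- stats::rnorm(n_tot, sd = noise_sd)
    if (lowpass_noise) {
      bf <- signal::butter(4, min(2 * 2000 / fs, 0.99))
      noise <- as.numeric(signal::filter(bf, noise))
    }
    current <- current + noise
  }

  structure(list(time_ms = time_ms, current = current, command_mV = command,
                 label = sweep$label, meta = sweep$meta, cell_id = cell_id,
                 sampling_rate = fs),
            class = "kv_trace")
}

#' Simulate every sweep of a protocol
#'
#' @inheritParams simulate_sweep
#' @param protocol A [kv_protocol].
#' @return An object of class `kv_recording`: list with `protocol`,
#'   `traces` (one [simulate_sweep()] result per sweep), `cell_id`.
#' @export
simulate_protocol <- function(model, protocol, noise_sd = 0, seed = NULL,
                              cell_id = "cell1", lowpass_noise = FALSE) {
  stopifnot(inherits(protocol, "kv_protocol"))
  if (!is.null(seed)) set.seed(seed)
  traces <- lapply(protocol$sweeps, function(sw)
    simulate_sweep(model, sw, noise_sd = noise_sd, seed = NULL,
                   cell_id = cell_id, lowpass_noise = lowpass_noise))
  structure(list(protocol = protocol, traces = traces, cell_id = cell_id,
                 noise_sd = noise_sd),
            class = "kv_recording")
}

#' Cohort specification
#'
#' Describes a population of cells expressing one channel model, with
#' multiplicative log-normal inter-cell parameter jitter (additive normal
#' for the activation midpoint: sd = `jitter_cv` x 10 mV) and additive
#' recording noise.
#'
#' @param n_cells Number of cells, >= 1.
#' @param base A [channel_species] or [mixture_model].
#' @param jitter_cv Coefficient of variation of the per-cell parameter
#'   jitter; default 0.2 reproduces midpoint scatter of the order seen in
#'   whole-cell cohorts (sd ~2 mV).
#' @param noise_sd Recording noise sd (display units); default 1% of the
#'   wild-type peak amplitude scale (0.021).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells, base, jitter_cv = 0.2, noise_sd = 0.021,
                        seed = 1) {
  stopifnot(n_cells >= 1, jitter_cv >= 0, noise_sd >= 0)
  structure(list(n_cells = n_cells, base = base, jitter_cv = jitter_cv,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

# mean-preserving log-normal multiplicative factor with coefficient of
# variation cv
.ln_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Draw a jittered copy of a channel species
#'
#' Positive-definite parameters (time constants, slope magnitudes,
#' conductance) are scaled by independent mean-preserving log-normal
#' factors with coefficient of variation `cv`; the activation midpoint is
#' shifted by a normal deviate with sd `cv * 10` mV; `frac_fast` is
#' jittered multiplicatively and clamped to (0, 1).
#'
#' @param sp A [channel_species].
#' @param cv Coefficient of variation, >= 0.
#' @return A new [channel_species].
#' @export
jitter_species <- function(sp, cv) {
  stopifnot(inherits(sp, "channel_species"), cv >= 0)
  if (cv == 0) return(sp)
  f <- .ln_factor(9, cv)
  inact <- sp$inact
  tf <- inact$tau_fast * f[1]
  ts <- inact$tau_slow * f[2]
  if (ts <= tf) { tmp <- tf; tf <- ts; ts <- tmp }
  if (ts == tf) ts <- tf * 1.01
  channel_species(
    name = sp$name,
    activation = boltzmann_params(
      sp$activation$V_half + stats::rnorm(1, sd = cv * 10),
      sp$activation$k * f[3]),
    act_tau = tau_law(sp$act_tau$tau_at_Vhalf * f[4],
                      sp$act_tau$k_tau * f[5],
                      sp$act_tau$V_half),
    deact_tau = tau_law(sp$deact_tau$tau_at_Vhalf * f[6],
                        sp$deact_tau$k_tau * f[7],
                        sp$deact_tau$V_half),
    inact = inactivation_params(tf, ts,
                                min(max(inact$frac_fast * f[8], 0.01), 0.99),
                                inact$tau_recovery * f[9]),
    g_max = sp$g_max * .ln_factor(1, cv),
    E_rev = sp$E_rev)
}

.jitter_model <- function(model, cv) {
  if (inherits(model, "channel_species")) return(jitter_species(model, cv))
  mixture_model(lapply(model$components, function(comp)
    list(species = jitter_species(comp$species, cv), weight = comp$weight)),
    model$assembly_rule)
}

#' Simulate a cohort of cells
#'
#' @param spec A [cohort_spec].
#' @param protocols List of [kv_protocol]s recorded from every cell.
#' @return List with one entry per cell: `cell_id`, the jittered `model`,
#'   and `recordings` (named by protocol kind).
#' @export
simulate_cohort <- function(spec, protocols) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(protocols, "kv_protocol")) protocols <- list(protocols)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_cells), function(i) {
    model <- .jitter_model(spec$base, spec$jitter_cv)
    cell_id <- sprintf("cell%03d", i)
    recs <- lapply(protocols, function(p)
      simulate_protocol(model, p, noise_sd = spec$noise_sd,
                        cell_id = cell_id))
    names(recs) <- vapply(protocols, function(p) p$kind, character(1))
    list(cell_id = cell_id, model = model, recordings = recs)
  })
}

# --- trace IO -------------------------------------------------------------

#' Write recordings as a tidy CSV trace table
#'
#' Columns: `cell_id`, `sweep_label`, `time_ms`, `command_mV`, `current`.
#'
#' @param recordings A `kv_recording` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(recordings, path) {
  if (inherits(recordings, "kv_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(rec)
    do.call(rbind, lapply(rec$traces, function(tr)
      data.frame(cell_id = tr$cell_id, sweep_label = tr$label,
                 time_ms = tr$time_ms, command_mV = tr$command_mV,
                 current = tr$current))))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy trace CSV back into recordings
#'
#' @param path CSV written by [write_traces()].
#' @param protocol The [kv_protocol] the traces were recorded under
#'   (supplies segment structure and sweep metadata).
#' @return A list of `kv_recording` objects, one per cell.
#' @export
read_traces <- function(path, protocol) {
  stopifnot(inherits(protocol, "kv_protocol"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "sweep_label", "time_ms", "command_mV", "current")
  if (!all(need %in% names(tab))) stop("trace CSV lacks required columns")
  sweeps_by_label <- stats::setNames(protocol$sweeps,
    vapply(protocol$sweeps, function(s) s$label, character(1)))
  lapply(split(tab, tab$cell_id), function(cell_tab) {
    traces <- lapply(split(cell_tab, cell_tab$sweep_label), function(sw_tab) {
      sw_tab <- sw_tab[order(sw_tab$time_ms), ]
      label <- sw_tab$sweep_label[1]
      sw <- sweeps_by_label[[label]]
      if (is.null(sw)) stop("sweep label not in protocol: ", label)
      structure(list(time_ms = sw_tab$time_ms, current = sw_tab$current,
                     command_mV = sw_tab$command_mV, label = label,
                     meta = sw$meta, cell_id = sw_tab$cell_id[1],
                     sampling_rate = sw$sampling_rate),
                class = "kv_trace")
    })
    # restore protocol sweep order
    order_labels <- vapply(protocol$sweeps, function(s) s$label, character(1))
    traces <- traces[order_labels[order_labels %in% names(traces)]]
    structure(list(protocol = protocol, traces = unname(traces),
                   cell_id = cell_tab$cell_id[1], noise_sd = NA),
              class = "kv_recording")
  })
}
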