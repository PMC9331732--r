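# Machine-readable voltage-clamp protocols.
#
# A sweep is an ordered list of constant-voltage segments plus sampling
# metadata; a protocol is an ordered list of sweeps of one kind. All five
# protocols used for Kv1.1 characterization are provided as builders:
# current-voltage family, tail-current family, deactivation family, the
# 90 s C-type inactivation pulse and the double-pulse recovery family.
# Every sweep starts with a 10 ms holding baseline (so fitters have a
# pre-step window) and ends with a 20 ms return to holding.

.KV_HOLDING <- -80       # mV, holding potential used throughout
.KV_BASELINE_MS <- 10    # leading holding segment
.KV_TAIL_HOLD_MS <- 20   # trailing holding segment

#' A constant-voltage protocol segment
#'
#' @param level Command potential (mV).
#' @param duration Segment duration (ms), > 0.
#' @return An object of class `voltage_segment`.
#' @export
voltage_segment <- function(level, duration) {
  stopifnot(is.finite(level), duration > 0)
  structure(list(level = level, duration = duration),
            class = "voltage_segment")
}

#' A voltage-clamp sweep
#'
#' @param segments List of [voltage_segment]s; the first and last must sit
#'   at the holding potential.
#' @param holding Holding potential (mV).
#' @param sampling_rate Sampling rate (Hz), > 0.
#' @param label Sweep label.
#' @param meta Named list of sweep annotations used by the analysis (e.g.
#'   `step_V`, `tail_V`, `post_V`, `interval_s`).
#' @return An object of class `kv_sweep`.
#' @export
kv_sweep <- function(segments, holding = .KV_HOLDING, sampling_rate = 50000,
                     label = "", meta = list()) {
  stopifnot(length(segments) >= 1, sampling_rate > 0,
            all(vapply(segments, inherits, logical(1), "voltage_segment")))
  first <- segments[[1]]$level
  last <- segments[[length(segments)]]$level
  if (first != holding || last != holding)
    stop("sweep must start and end at the holding potential")
  structure(list(segments = segments, holding = holding,
                 sampling_rate = sampling_rate, label = label, meta = meta),
            class = "kv_sweep")
}

#' Total sweep duration
#' @param sweep A [kv_sweep].
#' @return Duration in ms.
#' @export
sweep_duration <- function(sweep) {
  sum(vapply(sweep$segments, function(s) s$duration, numeric(1)))
}

#' A voltage-clamp protocol
#'
#' @param sweeps List of [kv_sweep]s sharing one sampling rate.
#' @param kind One of `"iv"`, `"tail"`, `"deactivation"`, `"inactivation"`,
#'   `"recovery"`.
#' @return An object of class `kv_protocol`.
#' @export
kv_protocol <- function(sweeps, kind = c("iv", "tail", "deactivation",
                                         "inactivation", "recovery")) {
  kind <- match.arg(kind)
  stopifnot(length(sweeps) >= 1,
            all(vapply(sweeps, inherits, logical(1), "kv_sweep")))
  fs <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(fs)) != 1)
    stop("all sweeps of a protocol must share one sampling rate")
  structure(list(sweeps = sweeps, kind = kind), class = "kv_protocol")
}

.framed_sweep <- function(levels, durations, holding, sampling_rate,
                          label, meta) {
  segs <- c(list(voltage_segment(holding, .KV_BASELINE_MS)),
            mapply(voltage_segment, levels, durations, SIMPLIFY = FALSE),
            list(voltage_segment(holding, .KV_TAIL_HOLD_MS)))
  kv_sweep(segs, holding, sampling_rate, label, meta)
}

#' Current-voltage protocol
#'
#' 200 ms depolarizing commands from a holding potential of -80 mV to test
#' potentials -80 to +60 mV in 10 mV increments (15 sweeps).
#'
#' @param sampling_rate Sampling rate (Hz); default 50 kHz.
#' @return A [kv_protocol] of kind `"iv"`.
#' @export
build_iv_protocol <- function(sampling_rate = 50000) {
  steps <- seq(-80, 60, by = 10)
  sweeps <- lapply(steps, function(V)
    .framed_sweep(V, 200, .KV_HOLDING, sampling_rate,
                  label = sprintf("step_%+d", V), meta = list(step_V = V)))
  kv_protocol(sweeps, "iv")
}

#' Tail-current protocol
#'
#' The prepulse family of [build_iv_protocol()] with each 200 ms prepulse
#' followed by a 150 ms tail step. The tail potential convention is
#' -50 mV for wild-type and -30 mV for the P403A mutant and the
#' heteromer.
#'
#' @param tail_V Tail potential (mV); values other than -50/-30 are
#'   accepted with a warning.
#' @param sampling_rate Sampling rate (Hz); default 50 kHz.
#' @return A [kv_protocol] of kind `"tail"`.
#' @export
build_tail_protocol <- function(tail_V = -50, sampling_rate = 50000) {
  if (!tail_V %in% c(-50, -30))
    warning("tail potential outside the -50/-30 mV conventions")
  steps <- seq(-80, 60, by = 10)
  sweeps <- lapply(steps, function(V)
    .framed_sweep(c(V, tail_V), c(200, 150), .KV_HOLDING, sampling_rate,
                  label = sprintf("pre_%+d", V),
                  meta = list(step_V = V, tail_V = tail_V)))
  kv_protocol(sweeps, "tail")
}

#' Deactivation protocol
#'
#' A 200 ms conditioning pulse at +20 mV followed by 200 ms post-steps
#' from -80 to +20 mV in 10 mV increments (11 sweeps).
#'
#' @param sampling_rate Sampling rate (Hz); default 50 kHz.
#' @return A [kv_protocol] of kind `"deactivation"`.
#' @export
build_deactivation_protocol <- function(sampling_rate = 50000) {
  posts <- seq(-80, 20, by = 10)
  sweeps <- lapply(posts, function(V)
    .framed_sweep(c(20, V), c(200, 200), .KV_HOLDING, sampling_rate,
                  label = sprintf("post_%+d", V),
                  meta = list(cond_V = 20, post_V = V)))
  kv_protocol(sweeps, "deactivation")
}

#' C-type inactivation protocol
#'
#' A single 90 s test pulse to +40 mV. Sampled at 5 kHz by default: the
#' fitted time constants are seconds, so the full 50 kHz bandwidth adds
#' nothing but memory.
#'
#' @param sampling_rate Sampling rate (Hz); default 5 kHz.
#' @return A [kv_protocol] of kind `"inactivation"`.
#' @export
build_inactivation_protocol <- function(sampling_rate = 5000) {
  sweeps <- list(.framed_sweep(40, 90000, .KV_HOLDING, sampling_rate,
                               label = "inact_+40", meta = list(step_V = 40)))
  kv_protocol(sweeps, "inactivation")
}

#' Recovery-from-inactivation double-pulse protocol
#'
#' Each sweep holds 20 s at +20 mV (conditioning pulse), returns to the
#' holding potential for the interpulse interval, then probes with 100 ms
#' at +20 mV. Default intervals run 0.1 to 17.1 s in 1 s increments
#' (18 sweeps).
#'
#' @param intervals Interpulse intervals (s), strictly increasing.
#' @param sampling_rate Sampling rate (Hz); default 5 kHz.
#' @return A [kv_protocol] of kind `"recovery"`.
#' @export
build_recovery_protocol <- function(intervals = seq(0.1, 17.1, by = 1),
                                    sampling_rate = 5000) {
  stopifnot(length(intervals) >= 1)
  if (any(diff(intervals) <= 0))
    stop("interpulse intervals must be strictly increasing")
  sweeps <- lapply(intervals, function(gap)
    .framed_sweep(c(20, .KV_HOLDING, 20), c(20000, 1000 * gap, 100),
                  .KV_HOLDING, sampling_rate,
                  label = sprintf("rec_%.1fs", gap),
                  meta = list(interval_s = gap)))
  kv_protocol(sweeps, "recovery")
}

# --- JSON serialization ---------------------------------------------------

#' Write a protocol to a JSON descriptor
#' @param protocol A [kv_protocol].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "kv_protocol"))
  obj <- list(
    kind = protocol$kind,
    sweeps = lapply(protocol$sweeps, function(s) list(
      label = s$label,
      holding = s$holding,
      sampling_rate = s$sampling_rate,
      meta = s$meta,
      segments = lapply(s$segments, function(g)
        list(level = g$level, duration = g$duration)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a protocol from a JSON descriptor
#' @param path JSON file written by [write_protocol()].
#' @return A [kv_protocol].
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path)
  sweeps <- lapply(obj$sweeps, function(s) {
    segs <- lapply(s$segments, function(g)
      voltage_segment(g$level, g$duration))
    kv_sweep(segs, s$holding, s$sampling_rate, s$label,
             lapply(s$meta, function(x) x))
  })
  kv_protocol(sweeps, obj$kind)
}

#' Build a protocol by name
#'
#' Convenience dispatcher used by the command-line layer: `name` is one of
#' the protocol kinds, or a path to a JSON descriptor.
#'
#' @param name Protocol kind or JSON path.
#' @param tail_V Tail potential forwarded to [build_tail_protocol()].
#' @return A [kv_protocol].
#' @export
get_protocol <- function(name, tail_V = -50) {
  if (file.exists(name)) return(read_protocol(name))
  switch(name,
         iv = build_iv_protocol(),
         tail = build_tail_protocol(tail_V),
         deactivation = build_deactivation_protocol(),
         inactivation = build_inactivation_protocol(),
         recovery = build_recovery_protocol(),
         stop("unknown protocol: ", name))
}
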