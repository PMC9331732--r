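# Packaged generative species and conductance calibration.
#
# The three Kv1.1 populations measured in HEK 293 cells (homomeric
# wild-type, homomeric P403A, 1:1 heteromeric co-expression) ship as a
# JSON fixture. Current amplitudes are "display units": the conductance
# scale of each species is calibrated so that the analyzed steady
# current of a noise-free IV step to +20 mV reproduces the species'
# measured amplitude (2.1 WT, 0.4 P403A, 0.55 heteromer).

.species_from_json <- function(rec, g_max = 1, E_rev = NULL) {
  if (is.null(E_rev)) E_rev <- reversal_potential(2.8, 132)
  Vh <- rec$activation$V_half
  channel_species(
    name = rec$name,
    activation = boltzmann_params(Vh, rec$activation$k),
    act_tau = tau_law(rec$act_tau$tau_at_Vhalf, rec$act_tau$k_tau, Vh),
    deact_tau = tau_law(rec$deact_tau$tau_at_Vhalf, rec$deact_tau$k_tau, Vh),
    inact = inactivation_params(rec$inact$tau_fast, rec$inact$tau_slow,
                                rec$inact$frac_fast,
                                rec$inact$tau_recovery),
    g_max = g_max, E_rev = E_rev)
}

#' Calibrate the conductance scale to a measured amplitude
#'
#' Returns a copy of `sp` whose `g_max` makes the baseline-subtracted
#' steady current of a noise-free 200 ms step to `at_V` equal
#' `amplitude`, using the same steady-current measure as [measure_iv()].
#'
#' @param sp A [channel_species] (its current `g_max` is ignored).
#' @param amplitude Target amplitude (display units).
#' @param at_V Step potential of the calibration sweep (mV); default +20.
#' @return The calibrated [channel_species].
#' @export
calibrate_g_max <- function(sp, amplitude, at_V = 20) {
  stopifnot(amplitude > 0)
  unit <- sp
  unit$g_max <- 1
  sw <- kv_sweep(list(voltage_segment(-80, 10), voltage_segment(at_V, 200),
                      voltage_segment(-80, 20)),
                 holding = -80, sampling_rate = 50000, label = "cal",
                 meta = list(step_V = at_V))
  rec <- structure(list(protocol = kv_protocol(list(sw), "iv"),
                        traces = list(simulate_sweep(unit, sw)),
                        cell_id = "cal", noise_sd = 0),
                   class = "kv_recording")
  per_unit <- measure_iv(rec)$current
  if (per_unit <= 0) stop("calibration step produced no outward current")
  sp$g_max <- amplitude / per_unit
  sp
}

#' Packaged Kv1.1 channel species
#'
#' Loads one of the three generative parameter sets ("WT", "P403A",
#' "WT+P403A") from the packaged fixture, with `g_max` calibrated to the
#' species' measured +20 mV amplitude. The heteromeric entry is the
#' single-species representation of the 1:1 co-expression (its measured
#' parameters, not a mechanistic subunit mixture; see
#' [mix_coexpression()] for the binomial assembly model).
#'
#' @param name Species name.
#' @param path Optional path to an alternative species JSON.
#' @return A [channel_species] with attributes `tail_V` (the species'
#'   tail-potential convention) and `amplitude_20mV`.
#' @export
kv11_species <- function(name = c("WT", "P403A", "WT+P403A"), path = NULL) {
  name <- match.arg(name)
  if (is.null(path))
    path <- system.file("extdata", "kv11_species.json", package = "kvclamp",
                        mustWork = TRUE)
  recs <- jsonlite::read_json(path)$species
  rec <- NULL
  for (r in recs) if (r$name == name) rec <- r
  if (is.null(rec)) stop("species not in fixture: ", name)
  sp <- .species_from_json(rec)
  sp <- calibrate_g_max(sp, rec$amplitude_20mV)
  attr(sp, "tail_V") <- rec$tail_V
  attr(sp, "amplitude_20mV") <- rec$amplitude_20mV
  sp
}

#' Names of the packaged species
#' @return Character vector.
#' @export
kv11_species_names <- function() c("WT", "P403A", "WT+P403A")
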