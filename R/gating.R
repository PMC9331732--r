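# Parametric gating model shared by the simulator and the fitting pipeline.
#
# A channel species is described by a Boltzmann steady-state activation
# curve, exponential voltage dependence of the activation and deactivation
# time constants, bi-exponential C-type inactivation with a single
# recovery time constant, a maximal conductance scale and a reversal
# potential. Voltages are mV, activation/deactivation time constants ms,
# inactivation/recovery time constants s.

#' Boltzmann activation parameters
#'
#' @param V_half Half-maximal activation potential (mV).
#' @param k Slope factor (mV per e-fold); must be nonzero.
#' @return An object of class `boltzmann_params`.
#' @export
boltzmann_params <- function(V_half, k) {
  stopifnot(is.finite(V_half), is.finite(k), k != 0)
  structure(list(V_half = V_half, k = k), class = "boltzmann_params")
}

#' Exponential voltage dependence of a gating time constant
#'
#' The law is `tau(V) = tau_at_Vhalf * exp((V - V_half) / k_tau)`.
#' `k_tau` is signed: a negative slope gives time constants that shorten
#' with depolarization (typical for activation), a positive slope ones
#' that shorten with hyperpolarization (typical for deactivation).
#'
#' @param tau_at_Vhalf Time constant at the reference potential (ms), > 0.
#' @param k_tau Voltage slope of the time constant (mV, signed, nonzero).
#' @param V_half Reference potential (mV), usually the activation midpoint.
#' @return An object of class `tau_law`.
#' @export
tau_law <- function(tau_at_Vhalf, k_tau, V_half) {
  stopifnot(is.finite(tau_at_Vhalf), tau_at_Vhalf > 0,
            is.finite(k_tau), k_tau != 0, is.finite(V_half))
  structure(list(tau_at_Vhalf = tau_at_Vhalf, k_tau = k_tau, V_half = V_half),
            class = "tau_law")
}

#' C-type inactivation and recovery parameters
#'
#' @param tau_fast Fast inactivation time constant (s).
#' @param tau_slow Slow inactivation time constant (s); must exceed `tau_fast`.
#' @param frac_fast Fraction of the inactivating amplitude carried by the
#'   fast component, in `[0, 1]`.
#' @param tau_recovery Recovery time constant at hyperpolarized potentials (s).
#' @return An object of class `inactivation_params`.
#' @export
inactivation_params <- function(tau_fast, tau_slow, frac_fast, tau_recovery) {
  stopifnot(tau_fast > 0, tau_slow > tau_fast,
            frac_fast >= 0, frac_fast <= 1, tau_recovery > 0)
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow,
                 frac_fast = frac_fast, tau_recovery = tau_recovery),
            class = "inactivation_params")
}

#' Full generative parameter set for one channel species
#'
#' @param name Species label.
#' @param activation [boltzmann_params] of steady-state activation.
#' @param act_tau [tau_law] for the activation time constant (used at
#'   potentials >= -40 mV).
#' @param deact_tau [tau_law] for the deactivation time constant (used at
#'   potentials < -40 mV).
#' @param inact [inactivation_params].
#' @param g_max Maximal conductance scale (display current units per mV
#'   driving force); >= 0.
#' @param E_rev Reversal potential (mV).
#' @return An object of class `channel_species`.
#' @export
channel_species <- function(name, activation, act_tau, deact_tau, inact,
                            g_max, E_rev) {
  stopifnot(inherits(activation, "boltzmann_params"),
            inherits(act_tau, "tau_law"), inherits(deact_tau, "tau_law"),
            inherits(inact, "inactivation_params"),
            is.finite(g_max), g_max >= 0, is.finite(E_rev))
  structure(list(name = name, activation = activation, act_tau = act_tau,
                 deact_tau = deact_tau, inact = inact, g_max = g_max,
                 E_rev = E_rev),
            class = "channel_species")
}

#' Weighted mixture of channel species
#'
#' @param components List of `list(species =, weight =)` entries; weights
#'   must be nonnegative and sum to one.
#' @param assembly_rule Either `"independent_binomial"` or `"single_species"`.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(components,
                          assembly_rule = c("independent_binomial",
                                            "single_species")) {
  assembly_rule <- match.arg(assembly_rule)
  w <- vapply(components, function(x) x$weight, numeric(1))
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-12,
            all(vapply(components, function(x)
      inherits(x$species, "channel_species"), logical(1))))
  structure(list(components = components, assembly_rule = assembly_rule),
            class = "mixture_model")
}

#' Steady-state open fraction (Boltzmann)
#'
#' `1 / (1 + exp(-(V - V_half) / k))`: strictly inside (0, 1) for finite
#' voltages and exactly 0.5 at `V_half`.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param p A [boltzmann_params] object.
#' @return Open fraction(s) in (0, 1).
#' @export
steady_state_open <- function(V, p) {
  stopifnot(inherits(p, "boltzmann_params"), all(is.finite(V)))
  1 / (1 + exp(-(V - p$V_half) / p$k))
}

#' Gating time constant at a potential
#'
#' @param V Membrane potential (mV); vectorized.
#' @param law A [tau_law] object.
#' @return Time constant(s) in the units of `law$tau_at_Vhalf`.
#' @export
tau_of_V <- function(V, law) {
  stopifnot(inherits(law, "tau_law"), all(is.finite(V)))
  law$tau_at_Vhalf * exp((V - law$V_half) / law$k_tau)
}

#' Nernst reversal potential for potassium
#'
#' @param K_out External potassium concentration (mM).
#' @param K_in Internal potassium concentration (mM).
#' @param T_kelvin Absolute temperature (K); default 293.15 K (room
#'   temperature recordings).
#' @return Reversal potential (mV).
#' @export
reversal_potential <- function(K_out, K_in, T_kelvin = 293.15) {
  stopifnot(K_out > 0, K_in > 0, T_kelvin > 0)
  R <- 8.314462618   # J / (mol K)
  F <- 96485.33212   # C / mol
  1000 * R * T_kelvin / F * log(K_out / K_in)
}

#' Dominant-negative co-expression mixture
#'
#' Under `independent_binomial` assembly, subunits are drawn independently
#' into tetramers with per-slot mutant probability equal to the mutant
#' cDNA fraction. Any tetramer containing at least one mutant subunit
#' adopts the mutant gating parameters (dominant-negative rule), so the
#' mixture has a pure-wild-type component of weight `(1 - ratio)^4` and a
#' mutant-like component carrying the rest. Under `single_species` the
#' heteromeric population is represented by one externally measured
#' species (`het` argument).
#'
#' @param wt Wild-type [channel_species].
#' @param mut Mutant [channel_species].
#' @param cDNA_ratio Mutant cDNA fraction in (0, 1); 0.5 for 1:1
#'   co-transfection.
#' @param rule `"independent_binomial"` (default) or `"single_species"`.
#' @param het The measured heteromeric [channel_species]; required for
#'   `rule = "single_species"`.
#' @return A [mixture_model].
#' @export
mix_coexpression <- function(wt, mut, cDNA_ratio = 0.5,
                             rule = c("independent_binomial",
                                      "single_species"),
                             het = NULL) {
  rule <- match.arg(rule)
  if (!(cDNA_ratio > 0 && cDNA_ratio < 1))
    stop("cDNA_ratio must be strictly inside (0, 1)")
  if (rule == "single_species") {
    if (is.null(het))
      stop("single_species rule needs the measured heteromeric species")
    return(mixture_model(list(list(species = het, weight = 1)),
                         "single_species"))
  }
  w_wt <- (1 - cDNA_ratio)^4   # pure wild-type tetramers
  mixture_model(list(list(species = wt, weight = w_wt),
                     list(species = mut, weight = 1 - w_wt)),
                "independent_binomial")
}

#' Tetramer stoichiometry weights
#'
#' Binomial(4, ratio) probabilities of 0..4 mutant subunits per channel.
#'
#' @param cDNA_ratio Mutant cDNA fraction in (0, 1).
#' @return Named numeric vector of length 5 (`mut0` .. `mut4`).
#' @export
tetramer_weights <- function(cDNA_ratio = 0.5) {
  stopifnot(cDNA_ratio > 0, cDNA_ratio < 1)
  w <- stats::dbinom(0:4, size = 4, prob = cDNA_ratio)
  names(w) <- paste0("mut", 0:4)
  w
}

#' Dominant-negative amplitude prediction
#'
#' Predicted whole-cell current amplitude of a wild-type/mutant
#' co-expression, combining the two homomeric amplitudes with binomial
#' tetramer weights under the mutant-dominant rule: only pure wild-type
#' tetramers contribute wild-type current, every other stoichiometry
#' contributes mutant-level current.
#'
#' @param wt_amplitude Homomeric wild-type amplitude (display units).
#' @param mut_amplitude Homomeric mutant amplitude (display units).
#' @param cDNA_ratio Mutant cDNA fraction; default 0.5 (1:1).
#' @return Predicted mixture amplitude (display units).
#' @export
dominant_negative_amplitude <- function(wt_amplitude, mut_amplitude,
                                        cDNA_ratio = 0.5) {
  w_wt <- (1 - cDNA_ratio)^4
  w_wt * wt_amplitude + (1 - w_wt) * mut_amplitude
}

# --- internal gate laws shared with the simulator -------------------------

# Activation-gate time constant (ms): activation law at and above the
# -40 mV crossover, deactivation law below it.
.tau_m <- function(V, sp) {
  ifelse(V >= -40, tau_of_V(V, sp$act_tau), tau_of_V(V, sp$deact_tau))
}

# Inactivation-gate steady state: fully available at and below -60 mV,
# fully inactivating drive at and above 0 mV, linear in between.
.h_inf <- function(V) {
  pmin(pmax(-V / 60, 0), 1)
}

# Inactivation-gate time constants (ms): the measured fast/slow constants
# at depolarized potentials (V >= 0), the recovery constant at
# hyperpolarized potentials (V <= -60), log-linear interpolation between.
.tau_h <- function(V, sp, which = c("fast", "slow")) {
  which <- match.arg(which)
  tau_dep <- if (which == "fast") sp$inact$tau_fast else sp$inact$tau_slow
  tau_rec <- sp$inact$tau_recovery
  f <- pmin(pmax((V + 60) / 60, 0), 1)  # 0 at -60 mV, 1 at 0 mV
  1000 * exp((1 - f) * log(tau_rec) + f * log(tau_dep))
}
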