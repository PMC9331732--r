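---
title: "Models and methods behind kvclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kvclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvclamp)
```

# Purpose and scope

`kvclamp` packages the functional characterization workflow for Kv1.1
potassium channels — wild-type, the P403A pore mutant and their 1:1
co-expression — as a closed loop: a generative gating model with known
parameters drives a voltage-clamp simulator, and the analysis pipeline
must recover those parameters from the simulated sweeps. Raw
whole-cell recordings behind the published parameter table are not
public, so the simulator doubles as the test bed: every fitter in the
pipeline is validated by exact recovery on noise-free data and by
convergence of cohort means under realistic noise and cell-to-cell
scatter. A separate module measures pore-geometry observables (S6 kink
angle, four-fold symmetry angles at the pore top) on multi-model PDB
trajectories.

# The gating model

Each channel species carries a Boltzmann steady-state activation curve
$O_\infty(V) = 1/(1+e^{-(V-V_{1/2})/k})$, exponential voltage laws for
the activation and deactivation time constants
$\tau(V) = \tau_{V_{1/2}}\,e^{(V-V_{1/2})/k_\tau}$, bi-exponential
C-type inactivation and a single recovery time constant. Assumptions
worth making explicit:

- **A single first-order activation gate** (power 1, not $m^4$). The
  experimental activation curve is obtained by fitting tail currents
  directly with a Boltzmann; a first-power gate makes the conductance
  curve equal that Boltzmann exactly, so recovery tests are unbiased.
  The cost is that simulated activation onsets lack the sigmoidal delay
  of multi-gate channels — a feature the analysis never measures.
- **Signed $k_\tau$.** The τ(V) law is printed ambiguously in most
  papers; we interpret it as $\tau_{V_{1/2}}\exp((V-V_{1/2})/k_\tau)$
  with a signed slope, so the same functional form covers activation
  (τ falls with depolarization, $k_\tau<0$) and deactivation
  ($k_\tau>0$), and the fit decides the direction.
- **Two-regime inactivation.** Inactivation is only measured at
  +40 mV and recovery at −80 mV, so the voltage dependence between
  those regimes is unconstrained by data. The model uses: full
  availability drive below −60 mV, full inactivation drive above 0 mV,
  linear steady state in between; time constants equal the measured
  fast/slow pair above 0 mV and the recovery constant below −60 mV,
  with log-linear interpolation between. Both availability gates share
  the recovery constant, which is what makes the double-pulse ratio
  curve a clean single exponential.
- **Activation/deactivation crossover at −40 mV.** Depolarizing steps
  (≥ −40 mV) use the activation τ-law, hyperpolarized potentials the
  deactivation law, mirroring which protocol constrains which law.
- **Display units.** The published current amplitudes (2.1, 0.4, 0.55
  at +20 mV) carry no units; `g_max` of each species is calibrated so
  the analyzed steady +20 mV current reproduces its amplitude, and all
  currents are reported in these display units. The reversal potential
  is the Nernst potential of the recording solutions (2.8/132 mM K⁺ at
  293.15 K, ≈ −97.3 mV).

Generator constants that are not measured quantities — the τ-slopes
($k_\tau = -40$ mV activation, $+25$ mV deactivation, plausible
e-fold-per-40/25 mV voltage sensitivities for a Kv channel), the fast
amplitude fraction of inactivation (0.3) — are package defaults chosen
once and recorded in the species fixture; the recovery tests treat
them as generative truth to be re-estimated, not as tuning knobs.

# Simulation

Command waveforms are piecewise constant, so each first-order gate
relaxes in closed form within a segment,
$x(t) = x_\infty - (x_\infty - x_0)e^{-t/\tau(V)}$, with states carried
across segment boundaries and initialized at the holding-potential
steady state (long inter-sweep rests). The simulator is therefore
exact to machine precision; a deSolve-based ODE integration of the
same gate scheme exists only in the test suite as an independent
oracle (agreement < 10⁻⁶ of peak on all five protocols). Gaussian
recording noise is added after synthesis (default 1% of the wild-type
peak, 0.021 display units); an optional 4-pole 2 kHz Butterworth
filter can shape the noise to the acquisition bandwidth but is off by
default so fits see exact model output plus white noise.

Protocols follow the published set: 200 ms IV steps −80…+60 mV from
−80 mV holding; 150 ms tails at −50 mV (wild-type convention) or
−30 mV (mutant/heteromer); +20 mV conditioning with 200 ms post-steps
for deactivation; one 90 s pulse to +40 mV for inactivation; 20 s
conditioning / 100 ms probe double pulses with interpulse intervals
0.1–17.1 s (1 s grid — the published range with a sensible default
spacing). Every sweep gets a 10 ms holding baseline before the first
command segment (fitters need a baseline window) and a short return to
holding. The 200 ms protocols are sampled at the experimental 50 kHz;
the 90 s and ~30 s sweeps default to 5 kHz, since their fitted
constants are seconds and full bandwidth only costs memory.

Cohorts draw per-cell parameters with mean-preserving log-normal
multiplicative jitter (positive-definite parameters) and additive
normal jitter for the midpoint (sd = CV × 10 mV). The default CV of
0.2 gives midpoint scatter of ~2 mV, the order implied by the
published cohort SEM (0.4 mV over 29 cells). What the generator does
*not* emulate: capacitive transients, series-resistance and
liquid-junction errors, leak conductance drift, rundown, multi-state
(Markov) gating and single-channel noise. Passing recovery tests
therefore demonstrates correctness of the analysis under the model's
assumptions, not robustness to every artifact of real recordings.

# Analysis pipeline and numerical choices

- **Steady IV currents**: mean over the last 10% of the step,
  baseline-subtracted against the pre-step holding window.
- **Tail amplitudes**: extremum in a 2 ms window starting 0.5 ms after
  the tail step (the settling/capacitive-artifact skip). The window is
  deliberately short: with a −30 mV tail, prepulses that leave
  channels *below* the tail-potential equilibrium produce slowly
  rising tail currents, and a long window would inflate the foot of
  the activation curve (for the heteromer this biased the fitted slope
  by +0.5 mV before the window was shortened).
- **Boltzmann fit**: Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) seeded by a logit-linear regression;
  degenerate curves (no points on both sides of half-activation) are
  rejected, non-convergence is flagged, never silent.
- **Kinetics**: single-exponential fits start 0.5 ms after each
  transition, with the window iteratively restricted to ≈8 fitted time
  constants and an optional linear drift term (on for the kinetics
  stages). The drift term matters: slow inactivation multiplies a
  200 ms step by a ~1.5% droop, which biases a plain exponential fit
  by up to −2.4% in τ — outside the 2% recovery budget — and the drift
  term reduces that to < 0.6% at the worst voltage. Activation is
  fitted at steps ≥ −30 mV (channels measurably open); deactivation at
  post-steps ≤ −50 mV, strictly below the model's −40 mV crossover so
  a single τ-law governs every fitted point. τ(V) is fitted log-linear
  (exact under the model) with the midpoint supplied by the same
  cell's Boltzmann fit.
- **Inactivation**: double-exponential fit from the in-pulse peak
  onward, initialized by peeling (late-window log-linear fit for the
  slow component, early residual for the fast); constants are ordered
  and near-equal pairs flagged as collapsed.
- **Recovery**: P2/P1 peak ratios, capped at 1, fitted with
  $R(\Delta t) = A - (A - R_0)e^{-\Delta t/\tau}$ with a **free
  plateau** $A$. This is the package's normalization choice: a 100 ms
  probe cannot reproduce the 20 s conditioning peak for slowly
  activating channels, so the true plateau sits slightly below 1
  (≈0.99 for the mutant); pinning it at 1 biased τ by +6%, and
  dividing by the longest-interval ratio (another common convention)
  biased the wild-type τ by −2.2% because the curve is only 99.6%
  converged at 17.1 s. The free plateau recovers both within < 0.1%.
- **Statistics**: mean ± SEM (n−1 sd) over cells; classical
  pooled-variance two-tailed Student's t-test, with p = 1 by
  convention for two zero-variance identical groups.

A caveat inherited from the experimental design: wild-type and mutant
tails are measured at different tail potentials (−50 vs −30 mV), so
activation curves are comparable only after normalization; no
conductance conversion is attempted. The inactivation stage always
fits the double exponential (the single-exponential description that
sometimes accompanies such data is a simplification; the fast/slow
pair is the reported quantity).

# Geometry

Helix axes are estimated by smoothing Cα positions with a 4-residue
kernel whose weights solve $\sum_j w_j e^{i\,100°j} = 0$ — the helical
spiral cancels exactly at the canonical α-helical twist — followed by
a principal-component fit of the smoothed (collinear) points, oriented
N→C. Plain PCA of raw Cα positions carries a ~1.8° systematic tilt on
13-residue segments (the spiral is not integral over the window),
which would swamp a 0.5° recovery requirement; the kernel estimator is
exact (< 10⁻⁵ °) on ideal geometry and ~1.4° under 0.3 Å coordinate
noise, which averages out over trajectory frames.

The S6 kink angle is the angle between the axes of residues 389–401
(above) and 405–417 (below), excluding the 402–404 hinge motif; the
exact sub-segment boundaries used experimentally are not published, so
these windows (≥ 1.5 helical turns on either side) are package
defaults and configurable. Symmetry angles are measured at each
subunit's G385 Cα toward its two pore-adjacent neighbors, with
neighbors identified by azimuthal order about the ring's best-fit
plane normal — never by chain labels, which vary across structure
files. Windowed statistics follow the conventional reporting scheme:
observables evaluated on the frame nearest each 0.1 ns sample over the
final 50 ns (501 samples), mean ± SD.

The bundle generator builds ideal Cα-only helices (2.3 Å radius,
1.5 Å rise, 100°/residue) with exact C₄ symmetry and an imposed hinge
bend. The "asymmetric subunit" knob applies its extra bend to the
segment *above* the hinge so that it both increases that subunit's
kink and displaces its G385, breaking ring symmetry the way a strained
pore does; bending only the lower segment would leave the pore top
untouched. Only multi-model PDB is read (DCD/XTC are out of scope;
convert first).

# Problem sizes and runtime

Recovery runs characterize one noise-free cell per species under all
five protocols (~2 s per species); the cohort-scatter test uses 29
cells under the tail protocol; the ODE-oracle comparison uses one
sweep per protocol at a few hundred comparison points; geometry tests
use 1–701 frames of a 164-atom bundle. The full test suite runs in
about a minute on one core.

# Known limitations

- The gating model is the analysis model: it cannot reveal biases that
  arise when real channels violate first-order kinetics (sigmoidal
  activation delay, state-dependent inactivation coupling).
- The inactivation voltage dependence between −60 and 0 mV is an
  interpolation, not data.
- Mixed-stoichiometry tetramers are all-or-none (mutant-dominant);
  intermediate gating of heteromers is represented only by the
  measured single-species parameter set, not mechanistically.
- Current amplitudes are display-calibrated, not conductance
  densities; no capacitance normalization is attempted.
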