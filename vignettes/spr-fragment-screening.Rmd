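---
title: "Models and methods behind sprscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sprscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprscreen)
```

# Scope

`sprscreen` implements the analysis chain of a single-concentration SPR
fragment screen with dose-response confirmation, as run on multi-spot
capture-format biosensors: a forward 1:1 interaction model, a synthetic
screen generator, sensorgram preprocessing (double referencing, DMSO
solvent correction), 3-sigma hit triage with molecular-weight and
surface-activity normalisation, kinetic/steady-state confirmation fitting,
and fragment-library design utilities. This vignette explains the models,
the tunable parameters and the design decisions; the README shows the
worked end-to-end example.

# The 1:1 interaction model

All simulation and fitting rests on the pseudo-first-order Langmuir model.
During sample contact at concentration $C$, the complex signal $R$ (in
response units, RU) obeys

$$\frac{dR}{dt} = k_a C (R_\max - R) - k_d R,$$

whose solution from $R(0)=0$ is
$R(t) = R_{eq}\,(1 - e^{-(k_a C + k_d)t})$ with
$R_{eq} = R_\max C / (C + K_D)$ and $K_D = k_d/k_a$. After the injection
stops, $R(t) = R_{stop}\,e^{-k_d (t - t_{stop})}$. `simulate_cycle()`
evaluates this closed form; the test suite cross-checks it against
fourth-order Runge-Kutta integration of the rate equation on a fine grid
(agreement below $10^{-6}$ RU), and `fit_kinetic_1to1()` fits exactly the
same closed form, so noiseless round trips are limited only by optimiser
precision.

Derived quantities:

* **Theoretical Rmax** (`theoretical_rmax()`): assuming the refractive-index
  response is proportional to bound mass,
  $R_\max = \frac{MW_{analyte}}{MW_{protein}} R_{protein} \times
  \text{stoichiometry} \times \text{activity}$. The capture stoichiometry
  (e.g. 3:1 protein:antibody capture) is an explicit multiplier rather than
  being folded into the protein molecular weight, so the formula stays
  auditable and tests can toggle it.
* **Ligand efficiency** (`ligand_efficiency()`):
  $LE = -RT\ln(K_D)/N_h$ in kcal mol$^{-1}$ per heavy atom, with
  $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$K$^{-1}$ and $T = 298.15$ K by
  default (assays at 25 °C); $T$ is overridable. LE is reported rounded to
  two decimals in summaries.
* **Dissociation half-life** (`half_life()`): $t_{1/2} = \ln 2 / k_d$.
* **Detection limit** (`detection_limit_kd()`): the weakest affinity whose
  equilibrium response still reaches the limit of detection at the
  screening concentration, $K_{D,\max} = C(R_{\max,eff}/LOD - 1)$. The LOD
  is a parameter: published screens rarely state the value they used, so no
  fixed constant is baked in. A LOD at or above the effective Rmax is
  signalled as an explicit "undetectable" error.

# What the synthetic screens emulate

`generate_screen()` produces the structure a Biacore-4000-style campaign
has, with defaults chosen to mirror a realistic screen:

* one cycle per fragment at 25 uM, observed simultaneously on a target
  spot, a blank reference spot and two off-target promiscuity spots
  (carbonic anhydrase II and GST surfaces);
* the screen protocol samples at 1 Hz over a 10 s pre-injection baseline,
  50 s contact and 60 s dissociation (protein-ligand kinetics use 180 s /
  600 s);
* a running-buffer blank after every 6 fragment injections (the
  regeneration interval; the blank frequency is not independently
  documented, so it is configurable with this default);
* reference-ligand activity probes every 20 cycles, with one probe opening
  and one closing the run so the activity series brackets all screening
  cycles;
* surface activity decaying **linearly in cycle index** from 1 at the
  opening probe to $1 - 0.15$ at the closing probe. Only the endpoint loss
  (15%) is constrained by observation; linearity is the simplest monotone
  model consistent with it;
* i.i.d. Gaussian per-sample noise (default $\sigma = 0.3$ RU, a typical
  multi-spot instrument noise level), optional linear baseline drift, and a
  DMSO bulk refractive-index step during injection with a small
  spot-dependent mismatch (defaults ~2%), so solvent correction has a real
  excluded-volume artefact to remove. There is no 1/f component: the noise
  model is deliberately the one the 3-sigma machinery assumes.

What the generator does **not** emulate: mass-transport limitation,
bivalent or heterogeneous binding, regeneration chemistry, per-needle
dispensing effects, temperature dependence, or instrument binary formats.
Passing tests therefore demonstrate that the analysis chain is correct
under its own statistical assumptions - not that those assumptions hold
for any particular instrument run.

Fragment libraries (`generate_library()`) draw descriptors around a
CNS-lead-like profile (mean MW 250 Da, cLogP centred at 1.5, low TPSA,
few donors/acceptors); heavy-atom counts scale with MW (~13.4 Da per heavy
atom). Fingerprints are deterministic pseudo-random 256-bit vectors - a
stand-in for externally computed structural fingerprints (the published
selection used proprietary 2D fingerprints), sufficient for exercising
Tanimoto arithmetic and greedy selection but carrying no chemistry.

Ill-behaviour artifacts (`apply_artifact()`): `upward_drift` adds a linear
ramp to the association phase only; `carryover` raises the pre-injection
baseline; `super_stoichiometry` scales the binding response;
`slow_non11_dissociation` mixes a slower exponential (fixed rate
$2\times10^{-3}$ s$^{-1}$, magnitude = mixing fraction) into the
dissociation phase, continuous at injection stop.

# Triage

The triage chain follows the normalisation order: (1) the 3-sigma
background threshold is the mean plus three **sample** standard deviations
of the buffer-blank binding levels (the published rule names only "three-
fold sigma"; mean + 3 sigma with the $n-1$ SD is adopted); (2) levels are
background-subtracted and (3) normalised to %Rmax using the theoretical
Rmax of the fragment's molecular weight and the interpolated activity
factor at its cycle.

Binding levels are the mean response over the last 5 s of contact minus
the mean over the 10 s pre-injection baseline (no windows are published;
these are standard report-point choices and both are configurable).
Mismatched time grids are an error, never silently resampled -
interpolation hides exactly the artifacts QC is looking for.

"Visual inspection for ill-behaviour" is operationalised as four
quantitative metrics with configurable thresholds (`qc_thresholds()`),
applied to every above-threshold cycle:

| flag | metric | default |
|---|---|---|
| `upward_drift` | late-association slope | > 0.05 RU/s |
| `carryover` | pre-injection baseline | > 1 RU |
| `super_stoichiometry` | level / expected Rmax | > 1.2 |
| `non11_dissociation` | residual RMS of a single-exponential dissociation fit | > 0.8 RU |

The defaults were calibrated on the artifact generator at the default
noise: the dissociation-fit residual of clean or empty cycles stays below
~0.55 RU while a mixed slow component at fraction >= 0.2 exceeds 1 RU.
Note that a genuinely slow-equilibrating binder (observed rate constant
well below ~0.1 s$^{-1}$ in a 50 s injection) still rises at the report
point and legitimately trips the drift flag - an inspector would reject
the same trace. The dissociation fit skips the first second after
injection stop to avoid the bulk-shift transient.

A hit is an above-threshold, unflagged fragment. Promiscuity uses each
off-target spot's own buffer-derived 3-sigma threshold; promiscuous
fragments are reported but excluded from the clean hit list. Because the
3-sigma rule has a scale-invariant one-sided false-positive rate of
0.135%, a pure-noise screen is *expected* to call about 1.35 hits per
thousand cycles on every spot - the test suite checks this rate against
exact binomial bounds rather than pretending it is zero.

Solvent correction is fitted per active spot from the DMSO calibration
cycles (default polynomial degree 2, selectable 1-3) mapping the
reference-spot bulk step to the active-minus-reference excess, and is
applied automatically only when at least three calibration cycles span a
bulk range wider than 2 RU - fitting a "correction" to noise when no DMSO
titration was run would only add variance.

# Dose-response confirmation

Confirmation series default to six two-fold dilutions from 50 uM.
`fit_kinetic_1to1()` does nonlinear least squares (Levenberg-Marquardt)
on the closed-form model in $(\log k_a, \log k_d, R_\max)$; `global` mode
(the default) shares one parameter triplet across all concentrations,
`local` mode fits each curve separately and combines rate constants as
geometric means. Initialisation is deterministic and derivative-free: $k_d$
from a log-linear fit to the dissociation tail of the top concentration
(starting 1 s after injection stop), the $K_D$ guess set to the top
concentration, $R_\max$ from the largest observed level. Convergence is
declared by the optimiser's relative-change criteria (tolerances
$10^{-12}$, at most 500 iterations) and is always reported; degenerate
input (all-zero traces, a single concentration) yields
`converged = FALSE` with a diagnostic message, never a silent answer.
`fit_steady_state()` fits the two-parameter isotherm
$R_{eq}(C) = R_\max C/(C + K_D)$ and flags the affinity as poorly
determined when the sampled concentrations span less than $0.2 K_D$.

A hit is **confirmed** when (i) it binds concentration-dependently at
three or more concentrations - a level counts as increasing only when it
exceeds the previous (lower-concentration) level by more than one buffer
sigma, a tolerance the published rule leaves implicit; (ii) the %Rmax at
the top clean concentration is at least 10% (weaker responders are
recorded but "not pursued"); and (iii) no disqualifying QC occurs below
the top clean concentration. Ill-behaviour appearing only above some
concentration is recorded (`illbehaved_above`) and the rule is applied to
the clean range below it. Confirmed hits carry $K_D$, LE and $t_{1/2}$
(minutes); orthogonal NMR confirmation enters only as an imported boolean
annotation.

# Library design

`property_filter()` applies per-descriptor bounds plus the >= 100 uM
solubility gate and records exclusion reasons. The bounds are
configuration, not constants: the design intent (CNS lead-likeness) does
not pin numeric thresholds. `diversity_select()` is a greedy single pass
in input order accepting a fragment only if its Tanimoto similarity to
every accepted fragment is < 0.85; the published selection does not state
its picking algorithm, and the greedy pass is the simplest order-
deterministic procedure whose output provably satisfies the pairwise
constraint (tests verify it by exhaustive pairwise checking).
`compare_distributions()` builds normalised histograms on shared bins and
flags bins where an exact binomial test rejects the library fraction -
the device used to surface, e.g., hydrogen-bond-donor over-representation
among hits.

# Numerical and scale choices

* Problem sizes in the test suite: the false-positive-rate check uses a
  10,000-cycle pure-noise screen (one-sided tail 0.00135, exact binomial
  95% acceptance band); parameter-recovery sweeps use 100 random kinetic
  triplets; the promiscuity-counting check uses a noiseless 5,260-fragment
  screen with four planted off-target binders, isolating the bookkeeping
  from the (separately tested) noise tail.
* Concentrations are stored in molar units in all files; reports display
  uM. Fingerprints are stored as hex strings.
* Reproducibility: every stochastic generator takes a seed and restores
  the caller's RNG state; a pipeline run is a pure function of its
  configuration file plus the seed, and re-runs are byte-identical.

# Known limitations

The fitter assumes the 1:1 model it simulates; model misspecification
(mass transport, heterogeneity) surfaces only through QC flags and fit
residuals, not through alternative models. The synthetic fingerprints
carry no chemistry, so diversity selection on generated libraries tests
the algorithm, not chemical coverage. Published ligand-efficiency tables
rounded from unrounded affinities can disagree with LE recomputed from the
rounded printed $K_D$ by marginally more than half an ULP; `sprscreen`
always reports the exactly recomputed value.
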