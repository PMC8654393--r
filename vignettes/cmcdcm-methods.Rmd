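---
title: "Microcircuit models of EEG paradigms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microcircuit models of EEG paradigms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcdcm)
```

## The model

`cmcdcm` implements a canonical-microcircuit neural mass model of a cortical
column and the Bayesian machinery used to fit it to three EEG paradigms.
Each column holds four populations — spiny stellate cells (ss), superficial
pyramidal cells (sp), inhibitory interneurons (ii) and deep pyramidal cells
(dp) — and each population obeys second-order synaptic dynamics

$$\dot v = i,\qquad \dot i = \frac{u - 2i}{T} - \frac{v}{T^2},$$

where $T$ is the population's synaptic time constant and $u$ (mV/s) is the
summed presynaptic drive: signed connection strengths times the centred
logistic firing rates $\sigma(v)-\tfrac12$ of presynaptic populations, plus
exogenous input into the spiny stellate cells. Ten intrinsic connections
wire a column (`cmc_constants()$G`): an excitatory relay
ss→sp, inhibitory feedback sp→ss, an sp↔ii loop, an ii↔dp loop, and one
self-inhibitory loop per population. The self-inhibition of a population
parameterizes its synaptic gain: more self-inhibition means a less
responsive population. Columns are coupled by laminar-specific extrinsic
connections (forward from sp onto ss and dp; backward from dp onto sp,
inhibitory, and ii, excitatory) with distinct intrinsic (2 ms) and
extrinsic (16 ms) transmission delays.

Every parameter is a dimensionless log-scaling of a prior mean:
effective value = mean × exp(λ). A change of ±0.2 is therefore a change of
roughly ±20%. All numeric constants live in `R/constants.R`; they are
package defaults, calibrated once (see "Calibration" below) and not tuned
per analysis.

## Forward models

*Induced responses* (resting spectra, 40-Hz steady state) come from the
linearization at the stable fixed point: the transfer function
$H(\omega) = C\,(i\omega I - A(\omega))^{-1} B$ with delays applied as exact
phase factors $e^{-i\omega\tau}$ on the delayed coupling blocks, and the
predicted cross-spectral density
$S(\omega) = H g_u H^{\mathsf H} + L\,g_s L^{\mathsf T} + g_c I$,
where $g_u$ is the input power density (a 1/f process at rest; a Gaussian
bump of width 4 Hz centred on 40 Hz for the steady state), and $g_s$, $g_c$
are source and channel observation-noise spectra. $S$ is Hermitian positive
semidefinite at every frequency by construction
(`check_cross_spectrum()`).

*Evoked responses* come from fixed-step RK4 integration of the delay
equations (delayed voltages interpolated from a ring buffer), with a
Gaussian-smoothed boundary pulse as the stimulus. Condition effects (B) add
log-scaling deltas to any parameter per condition; deviants in the mismatch
paradigm disinhibit superficial pyramidal cells in STG and IFG at baseline
(−0.15 and −1.0), which is what generates the difference wave — pathological
self-inhibition is modelled as condition deltas that cancel this
disinhibition.

The integrator doubles as the package's own oracle: `predict_csd()` is
validated against Welch cross-spectra of long stochastic simulations, and
the evoked machinery against closed-form resonances and sinusoidal
steady-state gains (see `tests/testthat/test-acceptance.R`).

### Numerical choices

- integrator step 0.1 ms by default (0.2–0.4 ms in the desk-scale studies;
  halving the step changes traces by <0.01%, tested);
- fixed points by damped Newton on the voltage equations with an
  integration fallback; residual tolerance 10⁻¹⁰ relative, asserted <10⁻⁸;
- stability guard: any Jacobian eigenvalue with real part > 10⁻⁶ raises an
  error naming the eigenvalue;
- frequency grids: 1–48 Hz (rest) and 30–50 Hz (steady state) at 0.25 Hz.

## Conventional features

`adjust_onef()` fits log-power on log-frequency over 2–48 Hz (excluding a
48.5–51.5 Hz line-noise guard) and returns the linear-scale residual; band
power is the mean residual over closed bands (θ 3–7, α 8–14, β 15–30, γ
31–grid max). Peak-γ is the residual's argmax in 35–45 Hz, ties broken
downward. Time-frequency power uses 7-cycle Morlet wavelets normalized to
the pre-stimulus baseline per frequency. The mismatch wave is
deviant − standard with its signed extremum in a 150–250 ms window.

## Inversion

`fit_variational_laplace()` maximizes the Laplace free energy over a
Gaussian posterior on the free log-scalings and per-block noise
log-precisions: Gauss–Newton steps with Levenberg damping (rejected steps
never decrease F), central finite-difference Jacobians (step 10⁻³),
hyperparameter updates by safeguarded Newton started from the
maximum-likelihood solution, and convergence when ΔF < 0.01 nat three times
in a row (max 64 iterations). On linear-Gaussian problems the posterior and
free energy equal the conjugate closed form to numerical precision.

Observation models: cross-spectra are fitted on the real diagonal plus real
and imaginary upper-triangle entries per frequency; evoked responses on the
per-area source traces for both conditions, whitened by an AR(1) filter
(coefficient 0.9 at the 2–4 ms observation step). The whitening matters:
EEG noise is strongly autocorrelated, and fitting it as white makes
posteriors overconfident and corrupts model comparison.

## Group inference

`bayesian_model_reduction()` gives the evidence and posterior of any model
whose priors are a modification of a fitted model's priors, in closed form.
It is exact for linear-Gaussian models and a local (Laplace) approximation
otherwise: it presumes a shared noise model and reductions that keep the
reduced posterior inside the Gaussian neighbourhood of the full one;
reductions that force a distant re-expansion (pinning a strongly needed
parameter of a very nonlinear model) can be off by several nats.
`peb_fit()` places a random-effects linear model (design matrix with group
contrasts and mean-centred covariates) on first-level posteriors, with a
single between-subject precision-scaling hyperparameter (diagonal
per-parameter base variance = first-level prior variance / 16; second-level
effect prior variance 1/16; hyperprior N(0, 4) on the log scaling — package
choices, stated here because the source material does not publish them).
Effect probabilities are free-energy softmaxes from switching each effect
off by reduction; `peb_joint_prob()` tests a *set* of effects jointly (the
appropriate single test of, e.g., a bilateral-gain hypothesis), and
`peb_prune()` adds greedy pruning with Bayesian model averaging. Two
details matter for calibrated group inference and are easy to get wrong:
subject posteriors must be converted to likelihood form (first-level prior
removed) before the second level, or group effects inherit the first-level
shrinkage; and contrast columns are coded so each regression weight equals
the named group difference (diagnosis ±0.5), which keeps the effect prior
comparable across contrasts. `bms_random_effects()` estimates population model frequencies by
variational Dirichlet inference, exceedance probabilities by seeded Monte
Carlo (default 10⁵ draws), and protects them with the Bayesian omnibus
risk.

### Model spaces

Mismatch paradigm: model `6G` frees six connectivity parameters — sp↔ii,
dp↔ii, ii self-inhibition (tied across areas) and sp self-inhibition (per
area) — plus their deviant-condition modulations; `4Ga`–`4Gd` free
four-parameter subsets; `6G,D,T` additionally frees delays and time
constants. The four-parameter subsets are the package's choice of
"combinations of pyramidal/interneuron connections and self-inhibition";
evidence for reduced models is obtained by reduction of the richest fit.
Steady-state paradigm: the `full` model uses empirical priors — T:sp −0.8,
T:ii −0.3 (faster kernels), S +0.5 (steeper activation), J:ss log 3 (larger
spiny-stellate lead-field contribution), input width 4 Hz — and each
reduced model (`-J(1)`, `-S`, `-T`, `-w`) reverts one prior to its standard
value (1 Hz width for `-w`). The numeric values of these empirical priors
are package calibrations, not published values.

## Synthetic cohorts

`generate_cohort()` draws per-subject parameters as full-model prior means
+ group-contrast deltas + Gaussian between-subject variation, then
generates data through the forward models plus observation noise, entirely
reproducible from one seed. Defaults mirror the study structure: groups of
107 controls, 108 patients, 57 relatives; a diagnosis effect of +0.25 on sp
self-inhibition; a genetic-risk effect of −0.2 on sp→ii coupling; symptom
scales (0–49 positive, 0–28 negative) coupled to auditory-area
disinhibition; age ~ N(39.4, 14²), sex/smoking Bernoulli; antipsychotic
dose equivalents in the patient group only.

Study conditions the source material does not specify were fixed once:

- between-subject SD 0.15 for connectivity and condition effects (inside
  the ±10–30% range the effect-size convention spans) and 0.01 for
  operating-point parameters (time constants, gains, lead fields, input
  settings — treated as paradigm-level calibrations, not individual
  traits);
- steady-state noise: complex-Wishart resampling with 160 degrees of
  freedom, the order of the paradigm's trial count, which preserves the
  Hermitian-PSD structure exactly;
- evoked noise: additive AR(1) (coefficient 0.9) at 5% of the signal SD,
  the residual noise level of an averaged ERP of ~10³ trials;
- resting spectra: multiplicative log-normal noise, SD 0.2.

What passing tests do and do not show: the generator emulates the
*statistical* structure the hierarchy assumes (group contrasts on known
parameters, exchangeable subjects, well-specified forward models). Real
data add model misfit, artifacts, head-model error and session effects, so
recovery rates here are upper bounds on what identical analyses achieve in
practice.

## Known limitations and degeneracies

- Over the narrow 30–50 Hz band, a change in sp synaptic gain is almost
  exactly a multiplicative scale change and is therefore nearly
  unidentifiable from the drive amplitude; gain-recovery experiments fix
  the drive amplitude at its empirical value (the degeneracy, not the fix,
  is the scientific finding to keep in mind when interpreting such fits).
- The interneuron population generates no lead-field signal (J = 0, the
  standard convention), so interneuron parameters are informed only through
  their loops; their identifiability depends on loop strength.
- The single-column resting model produces θ/β/γ structure but no α peak,
  and α-band changes are excluded from the perturbation-study
  classification.
- The mismatch network is the single-hemisphere chain A1→STG→IFG (the
  bilateral six-source geometry is constructible with `cmc_network()` but
  is not the tested default).
- Model selection among the mismatch-space variants is decisive against
  models that pin informative parameters (self-inhibition, the dp↔ii loop,
  delays/time constants: tens to hundreds of nats per subject) but only
  marginal against variants that pin the weakly identified sp↔ii couplings
  (~1 nat, Occam scale). At the default cohort conditions random-effects
  selection prefers the generating six-parameter model in about three out
  of four replications rather than reliably; see the free-parameter
  sensitivity discussion above for why those couplings carry so little
  evoked-response information.

## Calibration

The baseline column was calibrated once, against the published qualitative
phenomenology, before any acceptance threshold was evaluated: (i) the
five-perturbation study must classify increased sp self-inhibition — and
only it — as reproducing θ↑, β↓, γ↑, stably under halved step size; (ii)
35–45 Hz steady-state power must fall monotonically with sp self-inhibition
and with sp→ii loss; (iii) the mismatch amplitude must fall, with latency
stable within 10 ms, as deviant-condition sp self-inhibition increases;
(iv) the interneuron loops must be informative enough in evoked data that
the mismatch model space is discriminable. The resulting mechanism places
the superficial-pyramidal resonance (dominated by its strong self-inhibition
and slow kernel) just below the γ-band edge, so that extra self-inhibition
stiffens the node and pushes spectral mass across the 31 Hz boundary, while
connection-loss perturbations only shrink it.

## Problem sizes in the shipped studies

The test and acceptance studies use desk-scale sizes chosen as the package's
own defaults: 200–250 s spectral-oracle simulations; cohorts of 20
subjects/group over 20 replications for group-effect recovery (on the full
0.25 Hz grid); 6-subject cohorts over 20 replications for model-selection
self-consistency (0.4 ms integration, 4 ms observations); the full
108/107/57 cohort structure is the generator default and is exercised at
reduced size in tests.
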