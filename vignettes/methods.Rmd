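---
title: "Inferring NMDA channel blockade from evoked responses: model, inversion and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring NMDA channel blockade from evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdadcm)
```

## The scientific problem

Voltage-dependent NMDA receptors are blocked by magnesium ions at
hyperpolarised membrane potentials; the block is relieved by
depolarisation. Drugs such as memantine strengthen this voltage-dependent
blockade, while neurodegeneration is thought to weaken it. `nmdadcm`
implements a generative modelling pipeline that infers the strength of the
blockade — a single latent per cortical region — from non-invasive evoked
sensor responses such as the auditory mismatch negativity (MMN): the
difference between the response to a deviant tone and to a repeated
(standard) tone.

The pipeline has four stages, each usable on its own:

1. a **conductance-based canonical microcircuit** neural mass model with a
   voltage-dependent NMDA magnesium switch parameterised by a blockade
   latent;
2. a **forward/observation model** projecting source depolarisation to a
   small number of windowed sensor modes;
3. **variational Laplace** inversion producing a Gaussian posterior over
   latents plus a free-energy bound on log evidence;
4. **Parametric Empirical Bayes** (PEB) for group-level inference, with
   Bayesian model reduction (BMR) over parameter-set hypotheses and
   Bayesian model averaging (BMA).

Because the kind of MEG data this method targets are typically under
managed access, the package ships a **synthetic cohort generator** that
emulates the two study designs of interest — a placebo-controlled drug
crossover and a longitudinal patient cohort — with known ground truth, so
every stage of the pipeline can be exercised and scored at desk scale.

## The microcircuit model

Each of two regions contains four populations — spiny stellate (ss),
superficial pyramidal (sp), inhibitory interneurons (ii) and deep
pyramidal (dp) cells. Each population carries a membrane potential $V$ and
three channel conductances (dimensionless multiples of the unit
conductance):

$$
\frac{dV}{dt} = \frac{1}{C}\Big[g_L (V_L - V) + g_{AMPA}(V_{AMPA} - V) +
g_{GABA}(V_{GABA} - V) + g_{NMDA}\, m(V) (V_{NMDA} - V)\Big] + u
$$

$$
\frac{dg_*}{dt} = \frac{1}{\tau_*}\Big(\sum_k S_k\,\sigma_k - g_*\Big) + u,
\qquad * \in \{AMPA, GABA, NMDA\}
$$

where $\sigma_k$ is the presynaptic firing of population $k$ (a logistic
sigmoid of its voltage), $S_k$ are the signed coupling gains, and $u$ is
the exogenous (thalamic) input, a Gaussian bump delivered to the spiny
stellate cells of both regions. The NMDA conductance is gated by the
magnesium switch

$$
m(V) = \frac{1.50265}{1 + 0.33\,\exp(-0.06\,\alpha\,V)}, \qquad
\alpha = e^{blk}
$$

with `blk` the blockade latent (prior $N(0, 1/64)$). Raising `blk`
steepens the voltage dependence: at hyperpolarised potentials the switch
output — and hence NMDA conductance — falls, while at $V = 0$ the output
is independent of the blockade. A standard (unmodified) form with
numerator 1.5 and $\alpha = 1$ is also provided (`mg_switch_standard()`);
the two numerators are exposed as the documented constants `MG_NUMERATOR`
(1.50265) and `MG_NUMERATOR_STANDARD` (1.5). The modified numerator is
used whenever the blockade latent is active; nothing in the package
depends on reconciling the two constants, which differ by 0.18%.

### Network structure and parameters

The intrinsic (within-region) topology follows the canonical microcircuit
convention: excitatory drive ss→sp, ss→ii, sp→ii, sp→dp, dp→ii carried by
AMPA and, at a quarter weight (`nmda_frac`), NMDA; GABAergic inhibition
ii→ss, ii→sp, ii→dp plus self-inhibition on every population. Between
regions, *forward* connections run from superficial pyramidal cells to the
spiny stellate and deep pyramidal cells of the other region, and
*backward* connections from deep pyramidal cells to superficial pyramidal
cells and interneurons; there is no lateral connection. The default gain
magnitudes (see `cmm_config()`) were chosen once so that the default model
produces a damped evoked transient: a peak depolarisation of a few mV that
decays well within the 300 ms epoch. All magnitudes are log-scaled by
latents, so estimated quantities are strictly positive by construction.

Fixed biophysical constants use standard values for this model family:
$V_L = -70$, $V_{AMPA} = V_{NMDA} = 60$, $V_{GABA} = -90$ mV; $C = 8$,
$g_L = 1$; $\tau_{AMPA} = 4$, $\tau_{GABA} = 16$, $\tau_{NMDA} = 100$ ms.
The firing sigmoid has slope 0.1 mV$^{-1}$ and threshold $-45$ mV (resting
potential + 25 mV), so baseline firing is low and the input transient
stays on the rising part of the sigmoid.

Two modelling choices deserve a note. First, the printed state equations
list the leak among the dynamic conductances; the package keeps the leak
conductance constant at $g_L$, which is the standard treatment in this
model family (a leak has no presynaptic drive to relax towards). Second,
the exogenous input enters both the voltage and the conductance equations
by default (`u_into_g = TRUE`), following the printed form; the flag is
configurable because the alternative (input to voltage only) is equally
defensible.

### Condition effects

The deviant and standard conditions differ only through a condition
modulation `B` (prior $N(0, 1/16)$) that log-scales the self-inhibition
gains of each region when the between-trial regressor is 1 (deviant).
With `B = 0` the two conditions are identical by construction.

## Forward and observation model

Trials are integrated with a fixed-step 4th-order Runge–Kutta scheme
(1 ms step over 0–300 ms), started at the input-free fixed point of the
condition-specific model, found by damped Newton iteration on the drift
(the package verifies drift norms below $10^{-8}$ and step-halving
convergence below $10^{-3}$ of the response range). Source activity is the
depolarisation of the pyramidal populations relative to equilibrium,
projected through a gain matrix to 8 sensor modes, then tapered by a
Hanning window over the epoch — predictions and data are windowed
identically, so residuals are formed in the same space. Because anatomical
lead fields are out of scope, the default gain is a fixed synthetic 8×4
mixing pattern (`default_gain()`); a single log-gain latent scales it,
shared across regions to echo hemispheric symmetry constraints. For
multichannel data, `reduce_to_modes()` provides the standard SVD
reduction with captured-variance reporting.

## Variational Laplace inversion

`invert_vl()` maximises the Laplace free energy

$$
F = \underbrace{E_q[\log p(y\,|\,\theta)]}_{\text{accuracy}} -
\underbrace{KL\big(q(\theta)\,\|\,p(\theta)\big)}_{\text{complexity}}
$$

over a Gaussian $q$ by Gauss–Newton ascent with Levenberg–Marquardt
damping: proposals that lower $F$ are rejected and damping increased.
Jacobians are central finite differences (step $10^{-3}$ on the latents;
the forward model is an ODE integral, so no analytic gradients are
available). Noise is IID Gaussian with one log-precision per sensor mode,
updated in closed form between parameter steps; since the update maximises
$F$ in the hyperparameters, the free energy is non-decreasing over
accepted steps. Convergence is declared when three consecutive accepted
steps improve $F$ by less than $10^{-2}$ nats (maximum 64 iterations);
hitting the cap flags the result unconverged rather than raising an
error. On linear observation models the scheme's fixed point equals exact
conjugate Bayesian linear regression — posterior mean, covariance and log
evidence — which the test suite verifies to $10^{-6}$ relative on random
instances.

Parameters are fixed by prior-variance masks: a latent with prior variance
exactly 0 is excluded from the search. The package's experiment drivers
estimate only the parameters of interest (blockade latents, optionally the
channel time constants); the condition modulation and observation gain are
fixed at their generative values in recovery analyses, because the
blockade and gain latents trade off (both scale response amplitude). This
identifiability limit is intrinsic to single-subject evoked data and is
the reason the crossover/longitudinal inferences are made on *within*- and
*between-subject contrasts* at the second level rather than on absolute
blockade values.

## Parametric Empirical Bayes

`fit_peb()` places a GLM over the first-level posteriors of selected
parameters: each subject/session posterior is converted to its
likelihood-equivalent Gaussian (posterior precision minus prior
precision), the second level models the implied estimates as
$\theta_i = B x_i + \varepsilon_i$ with between-subject covariance
$e^{-\gamma}\,\Sigma_0/16$, and the effects $B$ shrink to zero with prior
variance 1/16 per regressor. Given $\gamma$ the model is linear-Gaussian,
so the effect posterior and free energy are closed-form; $\gamma$ (prior
$N(0, 1/16)$) is optimised by a bounded 1-D search and held at its
optimum. These hyperparameter choices follow the conventions of the
widely used hierarchical implementations of this method; they are
documented defaults, not fitted constants, and are configurable through
`peb_design()`.

Hypotheses about *which* parameters carry a group effect are scored by
Bayesian model reduction: the prior variance of excluded effects is
reduced to $\sim 0$ and the reduced free energy obtained from the full
posterior without refitting (`bmr_gaussian()`; the no-op reduction
recovers the full free energy identically). Free energies map to model
probabilities through the softmax, which is invariant to common shifts.
`peb_bma_all()` enumerates all on/off combinations of the tested effects,
averages the posteriors by model probability (full mixture moments,
including between-model variance), and reports each effect's *presence
probability* — the summed probability of models containing it. The
conventional "meaningful effect" threshold (presence probability > 0.95)
is a reporting flag, never a decision inside estimation.

For the longitudinal design, the session (0/1) and standardised
scan-interval regressors are strongly collinear by construction (the
interval is zero at baseline), so the raw coefficients share a planted
session effect in a split determined mostly by the shrinkage priors. The
identified quantity is the **session contrast** — the model-implied
baseline→follow-up change at the average follow-up interval,
$\beta_{session} + \beta_{interval}\,\Delta z$ — which the progression
experiment reports with its posterior SD and sign probability alongside
the raw coefficients. Weighting of
per-subject lines in expected-value plots, where used, is by inverse
posterior variance of the blockade estimate — an interpretation, since a
precision weighting is conventional but not uniquely defined.

## Synthetic cohorts

`generate_crossover()` and `generate_longitudinal()` emulate the two study
designs (defaults in `cohort_spec()`):

* **Crossover**: n = 19 subjects, two sessions (placebo/drug); the drug
  session's blockade latent is the subject's baseline plus **+0.42** in
  both regions.
* **Longitudinal**: n = 42 at baseline, 30 completing follow-up (an
  attrition of about 29%); baseline blockade follows an MMSE-linked
  gradient of **0.06 per MMSE point** about the cohort mean, MMSE drawn
  from $N(24.9, 3.61^2)$ truncated to [10, 30]; follow-up adds a session
  shift of **−0.125**; scan intervals are uniform on 0.8–2.2 years.

Between-subject variation of the blockade latent has SD 0.125 (matching
the prior — the true between-subject variance is unreported, so the prior
value is the least-committal choice, flagged as an assumption). Only the
blockade latents vary across subjects; all other latents are fixed at
cohort-wide values (condition modulation `B = 0.3`). This is a deliberate
simplification of biological heterogeneity that keeps recovery well-posed
and attributes every group difference to the planted effects. Sensor noise
SD is 0.05, chosen once so that a single simulated subject shows a clear
MMN-like deflection between 100–200 ms against the noise floor (the
deviant response RMS is ~0.6 at default parameters, an SNR of roughly 12).

An empirical property of the generator worth stating: *reducing* the
blockade latent *increases* the magnitude of the simulated
deviant−standard difference (more NMDA conductance, larger responses), so
the longitudinal session shift of −0.125 makes the signed 140–160 ms
window amplitude more negative at follow-up. The sensor-level paired
t-test therefore detects the planted decline with a negative sign. This
direction is a property of this particular synthetic observation model,
not a claim about real MEG cohorts.

## What the tests do and do not show

The test suite demonstrates, on synthetic data at stated sizes: switch
function analytics (saturation at 1.50265/1.5, bounds, monotonicity);
drift correctness against an independent R implementation of the state
equations; fixed-point and integrator accuracy; exact oracle equivalence
of the inversion on linear models; recovery of planted blockade effects
(crossover +0.42/+0.4 at n = 12; longitudinal −0.125 at n = 30 pairs over
20 replicates; five-way model comparison over 10 seeds); calibration (null
cohorts rarely flagged); and sensor statistics identical to base R
references to $10^{-10}$. Problem sizes were chosen as the smallest that
exercise the estimators meaningfully. Passing these tests shows the
machinery is correct and well-calibrated *under the generator's
assumptions* — IID sensor noise, known gain, single-parameter
heterogeneity. It does not show that real MEG cohorts satisfy those
assumptions, and absolute effect sizes on real data would additionally
reflect lead-field error, trial-averaging noise structure and
between-subject variability in every parameter held fixed here.

## Numerical choices and degenerate inputs

Fixed points by damped Newton with finite-difference Jacobians (tolerance
$10^{-10}$, warm-started during finite differencing); integration
divergence (|V| > 400 mV or non-finite states) raises an error naming the
offending latents; MAD of zero in the outlier rule warns and excludes
nobody; zero-variance differences make the paired t-test error rather
than return infinity; rank-deficient PEB designs and empty hypothesis
sets are structural errors; likelihood-equivalent precisions are
eigenvalue-floored at $10^{-8}$ against numerically non-PD differences;
reduced priors use variance $10^{-8}$ rather than exactly 0 to stay
invertible.
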