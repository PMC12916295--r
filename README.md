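# nmdadcm

Dynamic causal modelling of voltage-dependent NMDA channel blockade from
evoked sensor responses.

## What this is for

NMDA receptors are blocked by magnesium ions at hyperpolarised membrane
potentials. Drugs such as memantine strengthen this voltage-dependent
blockade; neurodegeneration is thought to weaken it. `nmdadcm` is for
researchers who want to *infer* the strength of that blockade,
non-invasively, from evoked electrophysiological responses such as the
auditory mismatch negativity (MMN) — and to test drug, severity and
progression effects on it at the group level.

The package implements, end to end:

* a **two-region conductance-based canonical microcircuit** (spiny
  stellate, superficial pyramidal, inhibitory interneuron and deep
  pyramidal populations), where each population obeys

  ```
  dV/dt  = (1/C) [ gL (VL − V) + gA (VA − V) + gG (VG − V) + gN m(V) (VN − V) ] + u
  dg*/dt = (1/τ*) ( Σk Sk σk − g* ) + u
  ```

  with the NMDA conductance gated by the magnesium switch

  ```
  m(V) = 1.50265 / (1 + 0.33 exp(−0.06 e^blk V))
  ```

  `blk` is the **NMDA blockade latent** (one per region, prior
  N(0, 1/64)): larger values steepen the voltage dependence, so less NMDA
  current flows at a given depolarisation. The unmodified switch
  (numerator 1.5, `e^blk = 1`) is also provided.

* a **forward model**: RK4 integration from the numerically solved fixed
  point, projection of pyramidal depolarisation through a gain matrix to 8
  Hanning-windowed sensor modes, plus SVD mode reduction and a plain-text
  ERP exchange format (TSV + JSON sidecar);

* **variational Laplace** inversion (Gauss–Newton with
  Levenberg–Marquardt damping, finite-difference Jacobians, closed-form
  mode-wise noise-precision updates) returning a Gaussian posterior and a
  free-energy bound that is exact on linear models;

* **Parametric Empirical Bayes** over subject posteriors with Bayesian
  model reduction over parameter-set hypotheses, softmax model
  probabilities and Bayesian model averaging;

* **sensor-level MMN statistics** (difference waveforms, 140–160 ms window
  amplitude, 3-scaled-MAD two-session outlier rule, paired t, severity
  regression);

* a **synthetic cohort generator** for a placebo/drug crossover design
  (n = 19, drug shift +0.42 on the blockade) and a longitudinal patient
  design (n = 42 baseline / 30 follow-up, MMSE-linked gradient 0.06 per
  point, session shift −0.125), with ground truth saved for scoring.

## Worked example

Simulate a small drug crossover cohort, invert every session, and ask
which synaptic parameter set explains the drug effect:

```r
library(nmdadcm)
rep <- run_experiment(run_config("crossover", seed = 20260926))
rep$model_table
```

```
     hypothesis    F probability
1      GABA_tau -386   1.61e-173
2      AMPA_tau -387   7.63e-174
3      NMDA_tau -342   1.33e-154
4 NMDA_blockade   12    1.00e+00
5           All    0    6.29e-06
```

The five-way comparison (free energies relative to the full model,
softmax probabilities) identifies the NMDA-blockade model as the winner:
the simulated drug acts on the blockade parameter, not on the channel
time constants. The averaged drug effect on the blockade latent is

```r
unlist(rep$blk_effect)
#> blk_r1:drug blk_r2:drug
#>       0.402       0.413
```

recovering the planted shift of +0.42 with presence probability 1 in both
regions. The longitudinal experiment
(`run_experiment(run_config("progression", ...))`) similarly recovers the
planted −0.125 follow-up decline as a session contrast of −0.146
(SD 0.035, P(< 0) = 1.00), and the sensor-level paired t-test detects the
accompanying amplitude change (t(28) = −12.0, p = 1.4e-12).

The numbered scripts under `analysis/` run the four canonical analyses
(switch-function characterisation, sensor-level statistics, crossover
PEB, longitudinal PEB) and write their tables under `results/`.

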