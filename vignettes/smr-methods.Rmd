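---
title: "Estimating standard metabolic rate and testing genotype effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating standard metabolic rate and testing genotype effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrflow)
```

## The scientific problem

Standard metabolic rate (SMR) — the maintenance energy expenditure of a
resting, fasted ectotherm at a fixed temperature — is measured in small fish
by intermittent-flow respirometry: a fish sits in a sealed chamber that
alternates between an open *flush* phase (re-oxygenation) and a closed
*measurement* phase, during which the decline of dissolved oxygen yields the
oxygen consumption rate MO2. Over a ~19 h trial this produces 50–60
per-cycle MO2 values per fish, of which only the lowest, stable portion
reflects SMR; the rest are inflated by spontaneous activity and by the decay
of handling stress.

`smrflow` implements the full chain needed to test whether a genotype —
here the vgll3 age-at-maturity locus of Atlantic salmon, with homozygous EE
(early) and LL (late) families — associates with SMR:

1. a ground-truth simulator for cohorts and raw oxygen traces,
2. trace processing (cycle segmentation, per-cycle least-squares slopes,
   blank-based background correction, MO2 conversion, QC),
3. SMR estimation by the mean of the lowest normal distribution (MLND),
4. allometric linear mixed models with crossed family and batch random
   effects, Satterthwaite tests, AIC comparison, and held-out-batch
   cross-validation,
5. a simulation-based post hoc power analysis that bounds the smallest
   genotype effect the design could have detected.

Because the package is organised around a simulator with known truth, every
downstream stage is testable without any external data.

## The generating model

True whole-animal SMR (mg O2 h\(^{-1}\)) follows the allometric mixed model

\[
\log_{10} SMR_i = \log_{10} a + b \log_{10} M_i
 + \beta_{vgll3}\,LL_i + \beta_{sex}\,m_i + \beta_{int}\,LL_i m_i
 + \beta_{T}(T_i - \bar T) + u_{fam(i)} + v_{batch(i)} + e_i ,
\]

with \(u \sim N(0, \sigma_{fam}^2)\), \(v \sim N(0, \sigma_{batch}^2)\),
\(e \sim N(0, \sigma_{res}^2)\), all on the log10 scale. Defaults
(`cohort_params()`):

* 150 fish, 14 full-sib families (7 EE / 7 LL; genotype is constant within a
  family, so the genotype contrast is a *between-family* comparison), 10
  respirometry batches of up to 16 chambers;
* body mass log-normal with mean 1.08 g and range ~0.5–1.9 g; fork length
  follows an isometric cube-root law with 2% multiplicative noise;
* scaling exponent \(b = 0.88\), intercept \(a = 0.25\) mg O2 h\(^{-1}\) at
  1 g (≈250 mg O2 kg\(^{-1}\) h\(^{-1}\), a realistic resting rate for ~1 g
  salmonids near 10.5 °C);
* \(\sigma_{res} = 0.027\), matching the residual precision of careful
  intermittent-flow studies (a residual CV of
  \(0.027 \ln 10 \times 100 \approx 6.2\%\));
* \(\sigma_{fam} = 0.008\), \(\sigma_{batch} = 0.005\). These are the
  package's own defaults, chosen once for realism: a family intraclass
  correlation near 8% of phenotypic log-variance is typical for full-sib
  designs in which family and rearing tank are confounded, and batch (day)
  effects are smaller than family effects in temperature-controlled systems.
  They are configuration inputs, not estimates from any particular dataset;
* all genotype/sex effects default to zero (the null world), and the
  holding-temperature covariate varies at batch level (SD 0.3 °C) — a
  constant covariate would make the full model rank-deficient.

## The trace simulator

`simulate_trace()` integrates the chamber oxygen balance per cycle: during a
closed phase,

\[
\frac{dO_2}{dt} = -\frac{MO_{2,\mathrm{cycle}} + MO_{2,\mathrm{bg}}}{V_\mathrm{eff}},
\qquad V_\mathrm{eff} = V_\mathrm{chamber} - M/1000\ \mathrm{L},
\]

treating fish density as 1 g mL\(^{-1}\). Within a cycle MO2 is constant, so
the decline is exactly linear — which makes the generating slope available
in closed form for tests. Flush phases relax exponentially back to
saturation with a 60 s time constant (only closed phases are analysed, so
this only needs to look plausible). Per-cycle MO2 is
\(SMR \times (1 + \mathrm{activity} + \mathrm{acclimation}(t))\):

* activity: Bernoulli(0.3) per cycle times an Exponential elevation with
  mean 0.5 — this produces the right-skewed MO2 distribution the MLND
  estimator assumes;
* acclimation: amplitude 0.5 decaying with a 3 h e-folding time, emulating
  handling stress at the start of the trial.

Background (microbial) respiration starts at
\(f/(1-f) \times SMR\) with \(f = 0.075\), so that the background is 7.5% of
total chamber respiration for a resting fish, and grows linearly to 1.5×
that by trial end; blank (no-fish) traces expose the same model to the
correction stage. Chamber volume defaults to 0.25 L and is a free design
parameter: every MO2 computation is parameterised by it.

Sensor noise is Gaussian per 2 s sample with SD 0.005 mg/L. With a 0.25 L
chamber a resting ~1 g fish drops oxygen by only ~0.25 mg/L per closed
phase, and this noise level keeps the within-cycle regression \(R^2\) near
0.997 — the regime respirometry QC expects, in which essentially all cycles
pass the default \(R^2 \ge 0.95\) filter. A noise SD several-fold larger
would push \(R^2\) to the QC boundary and select systematically for
high-activity cycles, a pathology rather than a measurement model.

The simulator emits only complete flush+measure cycles, so a 19 h trial at
5 + 15 min cycling yields exactly 57 cycles and 34,200 two-second samples.
All randomness flows through explicit `seed` arguments; the global RNG
state is saved and restored around every simulation call.

What the simulator does **not** emulate: sensor drift and calibration error,
temperature-dependent oxygen solubility (saturation is a fixed constant),
within-cycle activity bursts (activity is cycle-constant), and chamber
volume uncertainty. Passing tests therefore demonstrate correctness of the
estimation chain under the stated model, not robustness to every field
artifact of real respirometry.

## Trace processing

`estimate_slopes()` removes the first 120 s of each closed phase
(`wait_trim_s`, configurable — a mixing/transition allowance), then fits
ordinary least squares of oxygen on time per window. The whole-trace path
uses grouped centred sufficient statistics; `estimate_slope()` fits a single
window by QR decomposition, and the two agree to numerical precision (a
property the tests assert against a closed-form oracle).

Background correction subtracts, by default, the time-linear interpolation
between the pre- and post-trial blank slopes of the same chamber evaluated
at each cycle's midpoint (`mode = "mean"` is available for sensitivity
analysis; a single missing blank falls back to a constant with a warning).
Conversion to whole-animal MO2 multiplies the corrected slope by
\(V_\mathrm{eff}\); mass-specific rates divide by mass in kg. QC excludes
cycles with \(R^2 < 0.95\) and flags — without excluding — cycles whose
oxygen dipped below 6 mg/L, since hypoxia can depress metabolism and such
cycles deserve inspection rather than silent use.

## SMR by MLND

`estimate_smr_mlnd()` fits univariate Gaussian mixtures with 1–4 components
to a fish's per-cycle MO2 values by EM, with both equal-variance and
free-variance models, and selects among them by BIC; SMR is the mean of the
lowest-mean component. Elevated cycles (activity, early acclimation) land in
the upper components, which is why no explicit early-cycle exclusion is
needed; an optional `drop_first_h` switch exists anyway.

Numerical choices: 10 restarts per model from quantile-spread initial means
(the first restart unjittered), log-likelihood tolerance 1e-8, at most 500
iterations; restarts are screened at tolerance 1e-4 and the BIC-selected
model is then polished to full tolerance — the standard multi-start economy.
Component SDs are floored at 1e-6 of the sample SD to prevent variance
collapse; a component that empties invalidates its restart. BIC ties break
toward fewer components, and equal component means break toward the larger
mixing weight. Hard assignment by maximum posterior defines the
within-component CV that accompanies each estimate.

One numerical caveat, established empirically: adding a single high value to
a sample can shift the *converged* lowest-component mean by ~1e-5 in either
direction (responsibilities reshuffle slightly), so monotonicity of the
estimator under added high values holds at that scale, not at machine
precision.

A quantile alternative (`estimate_smr_quantile()`, default q = 0.2, type 7
convention \(h = (n-1)q + 1\)) and a lowest-10 mean are provided; on default
simulations the q = 0.2 quantile and MLND agree within 10%.

## Mixed-model inference

`fit_mixed()` fits, via `lme4`/`lmerTest`, the model set

* `full`: `log10_smr ~ log10_mass + vgll3 + sex + vgll3:sex + avg_temp_C + (1|family) + (1|batch)`
* `no_interaction`, `sex_only`, `simple`: successive removals of the
  interaction, the genotype, and sex;
* `condition_full`: Fulton's condition factor `K = 100 * mass_g / length_mm^3`
  against genotype, sex and their interaction. The millimetre-based formula
  is kept exactly as stated in the study design this package emulates; it is
  10^3 times smaller than the conventional cm-based index, which
  `fulton_k(..., length_unit = "cm")` provides.

Treatment contrasts with reference levels EE and F are used throughout, so
`vgll3LL` is the LL-minus-EE shift at the reference sex and the interaction
coefficient is the extra shift in LL males. REML is used for estimation and
Satterthwaite-based inference (type III tests when the interaction is
present, type II otherwise; for single-df terms F = t²). AIC comparison
refits all candidates by ML, because REML likelihoods are not comparable
across fixed-effect structures. If the Satterthwaite denominator df is
numerically unstable the code falls back to residual df and labels the rows
accordingly — p-values always carry their df method.

Cross-validation follows the held-out-batch design: fit on even-numbered
batches, predict odd ones, and vice versa. Predictions carry the fixed
effects plus family random-effect predictions (families span both splits by
design); batch effects are zeroed for unseen batches, and a family absent
from the training half is predicted at the population level with a warning.
RMSE is reported per split and pooled, on the log10 scale, so with a correct
model it converges to \(\sigma_{res}\).

## Power analysis

`simulate_power()` reproduces the post hoc power logic: a candidate effect
of \(p\%\) on mass-adjusted (raw-scale) SMR maps to a log10 coefficient
\(\log_{10}(1 + p/100)\) — 4.25% ↦ 0.018, 6% ↦ 0.025 — which is injected
into the generating model; for each grid point `n_sims` cohorts are
simulated *at the model level* (the trace-processing stages contribute ≪
\(\sigma_{res}\) of noise, so simulating traces would only spend time), the
full model is fitted, and power is the fraction of type III Satterthwaite
tests with \(p < \alpha\). The minimum detectable effect is the smallest
grid effect reaching the target power (default 0.80), on a default grid of
1–10% in 0.25% steps.

Because genotype is a between-family factor, its test runs against ~12
denominator df and its standard error is inflated by the family variance:
with the default components the genotype coefficient SE is
\(\sqrt{4(\sigma_{fam}^2 + \sigma_{res}^2/10.7)/14} \approx 0.006\), which
places the 80%-power threshold near a 4.3% effect. The interaction is a
within-family contrast; its balanced-cells analytic threshold is ~5.9%, and
random sex imbalance within family-genotype cells pushes the simulated
value to 6–7%.

How an interaction effect is split between the sexes is genuinely ambiguous
(`effect_scope`): `"one_sex"` (default) gives the shift to LL males only —
under treatment coding this *is* the interaction coefficient — while
`"both_sexes"` splits it symmetrically around a null sex-average. The
type III interaction F tests the same coefficient under either scope, so
interaction power is scope-invariant; the scope matters only for how the
accompanying main effects are contaminated, which is why the package reports
the interaction threshold with a diagnostic rather than a hard equality.

Non-convergent fits are counted and excluded from the power denominator only
when they are below 5% of simulations at a grid point.

## Problem sizes and runtime

The test suite and the acceptance script size their experiments for a
desk-scale single-CPU run, as stated choices of this package: 100 cohorts
for the end-to-end exponent-recovery experiment, 200 activity-contamination
replicates for the MLND-versus-mean comparison, 1000 (tests) or 500
(script) null simulations for the size of the genotype test, and power
grids restricted to sub-ranges of the default grid that bracket the
detection threshold (power is monotone in effect size, so a bracketing
sub-grid yields the same minimum detectable effect as the full grid) with
150–400 simulations per point (Monte Carlo SE ≈ 0.02–0.03 near power 0.8;
the grid-crossing estimator of the minimum detectable effect needs the
tighter end of that range to keep its one-grid-step resolution).

## Known limitations

* The genotype test inherits the design's confounding of family and tank:
  with 14 families, family-level df dominate and no amount of within-family
  replication can rescue power for the between-family genotype contrast.
* MLND point estimates depend mildly on the mixture model space; results
  from other component ranges or variance models will differ at the
  per-fish level.
* The simulator's constant-within-cycle MO2 and fixed saturation constant
  are idealisations; real traces carry drift and solubility structure that
  the QC stage would have to absorb.
* Cross-validated RMSE uses family random-effect predictions; designs whose
  families do not span both batch halves would need the population-level
  fallback, which the code applies with a warning.
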