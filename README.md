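# smrflow

Standard metabolic rate (SMR) from intermittent-flow respirometry, with
mixed-model genotype inference and simulation-based power analysis.

`smrflow` is built for the kind of study that asks whether a genotype —
the motivating case is the vgll3 age-at-maturity locus of juvenile Atlantic
salmon, with full-sib families homozygous EE or LL — associates with
standard metabolic rate. It covers the whole computation:

* **Simulation with known truth.** Cohorts (families, genotypes, batches,
  chambers, body masses) and raw oxygen traces: 5 min flush / 15 min closed
  cycles sampled every 2 s for 19 h, spontaneous-activity and acclimation
  elevations of MO2, microbial background respiration with drift, sensor
  noise. Every downstream stage is testable against ground truth.
* **Trace processing.** Closed-phase segmentation with a mixing trim,
  per-cycle ordinary-least-squares slopes, background correction by
  time-interpolated blank slopes, conversion to whole-animal and
  mass-specific MO2 via the effective chamber volume, and QC (R² filter,
  low-oxygen flags).
* **SMR estimation by MLND.** A univariate Gaussian mixture (EM, 1–4
  components, equal- and free-variance models, BIC selection) fitted to a
  fish's per-cycle MO2; SMR is the mean of the lowest-mean component, so
  activity-elevated cycles are absorbed by upper components instead of
  biasing the estimate. Quantile and lowest-10 alternatives included.
* **Allometric mixed models.** `log10(SMR) ~ log10(mass) + vgll3*sex +
  temperature` with crossed family and batch random intercepts
  (lme4/lmerTest), Satterthwaite type II/III F tests, ML-based AIC
  comparison of reduced models, even/odd-batch cross-validation, Fulton's
  condition factor, and the residual coefficient of variation
  `CV% = sd(residuals) * ln(10) * 100`.
* **Power analysis.** Percent effects on mass-adjusted SMR translate to
  log10 coefficients via `log10(1 + p/100)`; simulated cohorts fitted with
  the full model give a power curve and the minimum effect detectable at
  80% power under the hierarchical design.

## Worked example

```r
library(smrflow)

p  <- cohort_params()   # 150 fish, 14 families (7 EE / 7 LL), 10 batches
tp <- trace_params()    # 5/15 min cycling, 2 s sampling, 19 h, 0.25 L chamber

cohort <- simulate_true_smr(generate_cohort(p, seed = 1), p, seed = 2)
fish   <- cohort[1, ]              # true SMR 0.2277 mg O2/h at 0.895 g

trace <- simulate_trace(fish, tp, seed = 3)
trace
#> <raw_trace> kind=fish chamber=1 fish=F001: 34200 samples, 57 cycles

bg0 <- with(tp, background_fraction / (1 - background_fraction)) *
  fish$true_smr_mg_h
rec <- process_trace(trace,
                     simulate_blank_trace(tp, bg0, "pre",  seed = 4),
                     simulate_blank_trace(tp, bg0, "post", seed = 5),
                     fish, protocol = tp)
rec$report
#>   n_input n_excluded_r2 n_flagged_low_o2 n_kept fish_id
#> 1      57             0                0     57    F001

estimate_smr_mlnd(rec$records$mo2_mg_h, seed = 6,
                  mass_g = fish$mass_g, fish_id = fish$fish_id)
#> <smr_estimate> F001 [mlnd]: SMR = 0.229 mg O2/h (255.9 mg/kg/h);
#>   4 component(s), 57 cycles, CV within 0.51%
```

The estimate (0.229) sits within ~0.6% of the generating truth (0.2277):
the mixture's lowest component has isolated the resting cycles. The full
pipeline over a cohort, ending in the mixed model:

```r
res <- run_pipeline(p, tp, seed = 42)
res$fit
#> <smr_model_fit> full (REML, n = 150) [singular]
#>           term   estimate       se     df        t        p
#> 1  (Intercept) -0.8861518 0.123918 133.86 -7.15109 5.06e-11
#> 2   log10_mass  0.8931086 0.020485 143.82 43.59915 8.68e-85
#> 3      vgll3LL -0.0001386 0.006794  30.39 -0.02041 9.84e-01
#> 4         sexM -0.0015007 0.006164 142.45 -0.24346 8.08e-01
#> 5   avg_temp_C  0.0278969 0.011999 133.76  2.32503 2.16e-02
#> 6 vgll3LL:sexM  0.0077852 0.008813 141.96  0.88342 3.79e-01
#> random effects (SD): family 0.005381, batch 0, residual 0.02653
#> logLik 307.85, AIC -597.70

residual_cv(res$fit)
#> [1] 5.929598                       # percent

compare_models(res$table)
#>         model_id k   logLik       AIC     dAIC
#> 1           full 9 332.1544 -646.3089 4.419730
#> 2 no_interaction 8 331.7669 -647.5337 3.194837
#> 3       sex_only 7 331.4737 -648.9473 1.781244
#> 4         simple 6 331.3643 -650.7286 0.000000
```

Read: the mass exponent is recovered (0.893 ± 0.020 around the generating
0.88), the genotype and interaction terms are null as generated, and AIC
prefers the models without genotype terms — the expected behaviour of a
null-effect world. Power analysis:

```r
d <- power_design(effect_grid = seq(3, 5.5, 0.25), n_sims = 250)
pr <- simulate_power(d, term = "vgll3", seed = 1)
min_detectable_effect(pr)   # ≈ 4.25–4.5 (% on mass-adjusted SMR)
```

With the default variance components the genotype contrast runs between
families (~12 denominator df), and the smallest effect detectable with 80%
power is ~4.3% on mass-adjusted SMR (coefficient ≈ 0.018 on log10 SMR); the
genotype-by-sex interaction threshold is ~6–7%.

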