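# cogtraj

Latent-class trajectory analysis of cognitive decline in preclinical
Alzheimer's disease, for biostatisticians designing or re-analysing
secondary-prevention studies.

Cognitively unimpaired, amyloid-positive adults decline on cognitive
composites *on average*, but individual courses diverge: most remain stable
over a trial-length window while minorities decline slowly or rapidly.
`cogtraj` models this heterogeneity with a **latent-class mixed-effects
model (LCMM)** of a longitudinal cognitive composite and follows it through
the downstream questions a trialist asks: who are the classes, can baseline
data find them prospectively, and what does the class structure do to trial
power?

The model couples two submodels. Conditional on latent class *g*, the
Box-Cox-transformed composite follows

y\*ᵢⱼ = β₉₀ + Σₖ β₉ₖ Bₖ(tᵢⱼ) + xᵢⱼᵀγ + bᵢ + εᵢⱼ,  bᵢ ~ N(0, σ_b²), εᵢⱼ ~ N(0, σ_e²),

with natural cubic spline time effects Bₖ per class and shared covariate
effects γ (treatment arm, plasma p-tau217, amyloid PET, APOE ε4, sex, age,
education, hippocampal atrophy, test version). Class membership is
multinomial-logistic in the baseline covariates, πᵢ₉ ∝ exp(ξ₀₉ + wᵢᵀξ₉).
The mixture likelihood (random intercept marginalised to a
compound-symmetry multivariate normal, Jacobian-corrected for the
transform) is maximised by multi-start BFGS with an analytic gradient;
classes are selected by BIC/ICL over a (classes × spline-df) grid and
labelled stable / slow decliner / fast decliner by trajectory ordering.

Around the core model the package provides:

* `simulate_cohort()` — a calibrated synthetic-cohort generator (1629
  subjects, 77/16/7 class mix, published covariate moments and membership
  odds-ratio targets), so the whole pipeline runs without restricted data;
* `cross_validate()` — 10-fold cross-validation stratified by class ×
  p-tau217 tertile, scoring held-out subjects from baseline data only, with
  precision-recall curves (average precision) per class;
* `class_trial_report()` / `two_sample_power()` — class-stratified trial
  power at 2- and 4-year horizons with attrition (noncentral-*t*, completers
  only) and "maximum possible benefit" deltas against the
  biomarker-negative stable reference;
* `grow_tree()` / `tune_tree()` — a CART profile of the classes with
  cross-validated complexity tuning, balanced accuracy and impurity-based
  variable importance;
* `class_summary_table()`, `label_cdr_progression()`, CSV/YAML readers and
  writers, broom-style `tidy()`/`glance()` and `autoplot()` methods, and
  `run_pipeline()` to chain every stage under one seed with a hashed
  artifact manifest.

## A worked example

```r
library(cogtraj)

cohort <- simulate_cohort(sim_params(seed = 2))
fit <- fit_lcmm(cohort$visits, cohort$baseline, model_spec(), n_starts = 2, seed = 2)
fit
#> <lcmm_fit> G=3, spline df=2, n=1629 subjects (16618 visits)
#>   loglik -28426.80 | BIC 57134.7 | ICL 57523.0 | lambda 1.00 (shift 27.65)
#>   sigma_b 1.989, sigma_e 1.098 | classes: stable 80.3%, slow 13.7%, fast 6.0%
```

The fitted mixture recovers the generative structure: about 80% of subjects
sit in the stable class (generative target 77%), the residual and
random-intercept SDs match the generating values (2.0 and 1.1), and the
mean posterior classification probability is about 0.95 — subjects are
assigned to classes with high confidence. `tidy(fit)` shows the membership
odds ratios per SD (p-tau217 and hippocampal atrophy carry the strongest
associations with decline), and `autoplot(fit)` draws the three class mean
trajectories on the composite scale.

```r
cv <- cross_validate(cohort$visits, cohort$baseline, fit$spec, seed = 2,
                     reference_fit = fit)
cv
#> <cv_report> 10-fold CV (mode baseline-visit; truth: full-data model MAP assignment)
#>   accuracy 0.867 (95% CI 0.849-0.883)
#>   AUPRC stable_vs_rest         0.978
#>   AUPRC slow_vs_rest           0.542
#>   AUPRC fast_vs_rest           0.525
#>   AUPRC decliner_vs_stable     0.817
```

Baseline data identify stable subjects almost perfectly but decliners only
partially — the central practical finding this analysis style exposes: the
overall accuracy is flattered by the stable majority, and the per-class
precision-recall curves tell the honest story.

```r
two_sample_power(delta = 1.14 - 0.88, sd = 2.19, n_per_arm = 500, attrition = 0.10)
#> [1] 0.4282579
two_sample_power(delta = 1.20 - 0.96, sd = 2.34, n_per_arm = 500, attrition = 0.20)
#> [1] 0.30492
```

From the published group means and SDs, a 500-per-arm trial in stable
amyloid-positive subjects has only ~43% power at 2 years (and ~30% at 4) to
detect even the *maximum* possible benefit (0.26 and 0.24 composite
points) — while `class_trial_report()` shows a decliner-enriched trial
powered above 98% for a fifth of its (much larger) maximum benefit.

See `vignettes/trajectory-classes.Rmd` for the model details, the
synthetic-cohort calibration and its limits, and the numerical design
choices.

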