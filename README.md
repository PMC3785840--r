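# osteoKDE

Kernel-density Bayes classification of late osteolysis risk after cemented
total hip arthroplasty (THA).

## The problem

Periprosthetic osteolysis — wear-particle-driven bone loss ending in aseptic
loosening and revision surgery — is the main factor limiting the survival of
cemented Charnley hip replacements. Epidemiological models (logistic
regression, wear quintiles) describe the population-level association
between polyethylene wear and osteolysis but do not give a clinician a
per-patient probability. This package implements a kernel-based Bayesian
risk model for that purpose, aimed at biostatisticians and implant-survivorship
researchers.

## The model

For classes `C₀` (control, well-functioning implant) and `C₁` (osteolysis /
revision), Bayes' theorem gives

    P(Cᵢ | x) = p(x | Cᵢ) P(Cᵢ) / Σⱼ p(x | Cⱼ) P(Cⱼ)

with priors `P(Cᵢ)` the relative class frequencies and each class-conditional
density estimated by a fixed-bandwidth kernel estimator

    p̂(x | Cᵢ) = (1 / nᵢ hᵈ) Σₖ K((x − xₖ) / h),   K(u) = (2π)^{−d/2} e^{−‖u‖²/2}

on features standardized to zero mean / unit variance (annual wear rate is
log-transformed first; its distribution is log-normal with a long right
tail). A single window width `h` is shared across dimensions; the default
`h = 0.7` can be compared against the normal-reference rule
`h = (4/3n)^{1/5} σ` and the MAD-robust rule `h = (4/3n)^{1/5} · MAD/0.6745`.
Classification is by maximum posterior (ties → control). Model quality is
measured by stratified 5-fold cross-validation repeated over random fold
permutations, overall and within each sex, plus a bandwidth sensitivity
sweep over `h ∈ [0.1, 10]`.

Because the underlying clinical cohort is not publicly deposited, the
package ships a calibrated synthetic cohort generator (283 controls / 180
osteolysis; log-normal wear; moment-matched truncated-normal demographics)
so the whole pipeline is testable end to end.

## Worked example

```r
library(osteoKDE)

cohort <- generate_cohort(cohort_config(seed = 7))
model  <- fit_classifier(cohort, feature_spec(c("annual_wear", "age_at_surgery")), h = 0.7)
model
#> Kernel Bayes classifier
#>   features: annual_wear, age_at_surgery (h = 0.7)
#>   control: n = 283, prior = 0.6112
#>   osteolysis: n = 180, prior = 0.3888

posterior(model, data.frame(annual_wear = 0.2, age_at_surgery = 60))
#>      control osteolysis
#> [1,]   0.484      0.516
```

A 60-year-old with an annual wear rate of 0.2 mm/yr sits near the decision
boundary: the posterior probability of osteolysis is 0.516 against a prior
of 0.389, i.e. the observed wear rate has shifted the odds toward failure.

```r
cv <- sex_stratified_cv(cohort, feature_spec(c("annual_wear", "age_at_surgery")),
                        h = 0.7, k = 5, n_permutations = 20, master_seed = 7)
for (r in cv) print(r)
#> repeated 5-fold CV, 20 permutations (h = 0.7): mean 27.5% (s.d. 0.8; range 26.6-29.2)
#> repeated 5-fold CV, 20 permutations (h = 0.7): mean 28.9% (s.d. 1.0; range 27.3-30.7)
#> repeated 5-fold CV, 20 permutations (h = 0.7): mean 25.1% (s.d. 1.2; range 23.1-27.1)

sw <- bandwidth_sweep(cohort, feature_spec(c("annual_wear", "age_at_surgery")),
                      h_grid = seq(0.1, 2, by = 0.1), k = 5,
                      n_permutations = 10, master_seed = 7)
sw
#> bandwidth sweep (all, 10 permutations, 20 h values): best h = 0.4 (mean error 26.8%)
```

The misclassification rates (all / male / female) are the model's headline
performance numbers on this synthetic cohort; the sweep reproduces the
characteristic shape — noisy densities at small `h`, a flat minimum near
`h ≈ 0.4–0.8`, and for very large `h` a plateau where the posterior
collapses to the priors and everyone is called control.

## Command line

```sh
inst/cli/osteokde simulate --seed 7 --out cohort.csv
inst/cli/osteokde fit --cohort cohort.csv --out model.json --h 0.7
inst/cli/osteokde predict --model model.json --wear 0.2 --age 60
inst/cli/osteokde run --config inst/extdata/run_config.json
```

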