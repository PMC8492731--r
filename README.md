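# ispyengine

A Bayesian adaptive platform-trial engine for neoadjuvant breast-cancer
studies with a binary pathologic complete response (pCR) endpoint,
together with the biomarker machinery that accompanies such trials:
IGF-axis gene-expression signature scoring, three-model biomarker
qualification, and longitudinal HbA1c glycemic-control analysis. It is
aimed at trial statisticians and translational researchers who want the
platform's decision rules — and the analyses around one of its arms —
as tested, reusable functions exercised end-to-end on synthetic data.

## The model

Each patient contributes a Bernoulli pCR outcome through a logistic
covariate model with calendar-drift offsets ("time machine"):

    logit p_i = β0 + β_HR·HR_i + β_HER2·HER2_i + β_MP·MP_i
                + γ_arm(i) + δ_s(i)(t_i)

Calendar time before the analysis is cut into 90-day bins (bin 1 = most
recent); each HER2 stratum `s` has its own drift path δ(t) with the most
recent four bins frozen at zero and a second-order normal dynamic linear
model beyond:

    δ(1) = … = δ(4) = 0
    δ(5) ~ N(μ0, τ0²),   δ(6) − δ(5) ~ N(μ1, τ1²)
    δ(t) − 2δ(t−1) + δ(t−2) ~ N(0, τ²)  for t > 6,   τ² ~ IG(α, β)

with defaults μ0 = μ1 = 0, τ0² = τ1² = 0.001, α = 1, β = 0.001. This
lets non-concurrent controls inform current comparisons while
discounting the deeper past. Posterior draws (adaptive
Metropolis-within-Gibbs, conjugate τ² updates, split-R-hat monitoring)
feed the platform's decision quantities: subtype pCR-rate
distributions, the probability an arm is superior to control, the
predictive probability of success in a hypothetical 300-patient 1:1
phase-3 trial (computed by exact binomial enumeration per draw),
graduation at ≥ 0.85 / futility below 0.10, and response-adaptive
randomization with exactly 20% to control.

The vignette (`vignettes/platform-trial-methods.Rmd`) documents every
modelling choice, the signature-score definitions, the qualification
rule, and what the synthetic generators do and do not emulate.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `05_hba1c.R`; run them in order from the repository
root — each writes its tables under `results/`). The core loop in
miniature:

```r
library(ispyengine)

cfg   <- scenario_config()                      # study-like defaults
pat   <- prepare_analysis_set(simulate_trial(cfg, seed = 20260901))
model <- build_model(pat, prior = tm_prior(), analysis_day = 1800)
draws <- sample_posterior(model, seed = 20260911, chains = 4,
                          warmup = 1200, iter = 1500)
arm_summary(draws, "PGM")
```

which for this seed prints (percent scale):

      signature rate_arm rate_control prob_superior pred_prob_phase3
    1 All HER2-     18.7         18.8          48.9              8.9
    2 HR+/HER2-     15.3         15.3          48.9              8.2
    3 HR-/HER2-     22.7         22.9          48.9              9.7

Read: in this simulated 234-patient trial the experimental arm's
estimated pCR rate is essentially the control rate in every
HER2-negative signature, the posterior probability of being superior to
control is near 50%, and the predictive probability of phase-3 success
is far below the 0.85 graduation bar — `evaluate_arm_status()` returns
`futility_stop`. (The generator's true arm log-odds ratio is 0.571;
this particular realization happened to land near the null, which is
exactly the kind of outcome the decision rules must handle.)

Stage 3 scores the simulated expression matrix: the ligand score stays
in [−0.95, 0.96], the activation score is z-scored to mean 0 / SD 1,
and the two anti-correlate at Pearson r = −0.81, reproducing the sign
and strength of the inverse relation seen on real data. Stage 4 runs
the 14-marker qualification panel under outcomes in which the
activation score is equally prognostic in both arms: both signatures
associate with response in each arm while every interaction p is null,
so 0 of 14 markers qualify as arm-specific predictors — and an injected
positive-control marker with a genuinely arm-specific effect qualifies.
Stage 5 reports the glycemic analysis for this seed: 22% of 103
baselines above 5.7%, 12 of 53 normal-baseline patients (23%) becoming
elevated on treatment — sampling noise around the calibrated 27% — and
a null pCR-by-glycemia comparison (Fisher p = 0.23).

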