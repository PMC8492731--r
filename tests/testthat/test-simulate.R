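test_that("generators are pure functions of (config, seed)", {
  cfg <- scenario_config()
  expect_identical(simulate_trial(cfg, seed = 1),
                   simulate_trial(cfg, seed = 1))
  expect_false(identical(simulate_trial(cfg, seed = 1),
                         simulate_trial(cfg, seed = 2)))
  e1 <- simulate_expression(cfg, seed = 3)
  e2 <- simulate_expression(cfg, seed = 3)
  expect_identical(e1$expr, e2$expr)
  expect_identical(simulate_hba1c(cfg, seed = 4),
                   simulate_hba1c(cfg, seed = 4))
  expect_error(simulate_trial(cfg), "seed")
})

test_that("default generated data passes input validation cleanly", {
  cfg <- scenario_config()
  expect_silent(pat <- simulate_trial(cfg, seed = 5))
  expect_s3_class(as_patient_table(pat), "data.frame")
  expect_true(all(pat$mp_class == mp_class(pat$mp_score)))
  expect_equal(unname(table(pat$arm)[c("PGM", "control")]),
               c(106L, 128L), ignore_attr = TRUE)
})

test_that("empirical pCR rates sit at the logistic model's targets", {
  # no drift, no arm effect, large n: marginal rate has a closed form
  cfg <- scenario_config(n_per_arm = c(PGM = 2000L, control = 2000L),
                         arm_logor = c(PGM = 0), deviation_rate = 0)
  pat <- simulate_trial(cfg, seed = 6)
  cf <- cfg$coef
  combos <- expand.grid(hr = 0:1, mp = 0:1)
  w <- with(combos,
            ifelse(hr == 1, cfg$hr_prev, 1 - cfg$hr_prev) *
              ifelse(mp == 1, cfg$mp_hi2_prev, 1 - cfg$mp_hi2_prev))
  target <- sum(w * plogis(cf[["intercept"]] + cf[["hr"]] * combos$hr +
                             cf[["mp"]] * combos$mp))
  se <- sqrt(target * (1 - target) / nrow(pat))
  expect_lt(abs(mean(pat$pcr) - target), 4 * se)
  # arm log-OR shifts the treated arm's rate
  cfg2 <- scenario_config(n_per_arm = c(PGM = 4000L, control = 4000L),
                          deviation_rate = 0)
  pat2 <- simulate_trial(cfg2, seed = 7)
  expect_gt(mean(pat2$pcr[pat2$arm == "PGM"]),
            mean(pat2$pcr[pat2$arm == "control"]))
})

test_that("a drift step shows up in bin-stratified empirical rates", {
  drift <- list("HER2-" = c(0, 0, 0, 0, rep(2, 16)))
  cfg <- scenario_config(n_per_arm = c(control = 6000L),
                         arm_logor = c(),
                         accrual = list(control = c(0, 1800)),
                         drift = drift, deviation_rate = 0)
  pat <- simulate_trial(cfg, seed = 8)
  bins <- assign_time_bin(pat$randomization_day, 1800)
  r_recent <- mean(pat$pcr[bins <= 4])
  r_old <- mean(pat$pcr[bins >= 5])
  expect_gt(r_old, r_recent + 0.2)
})

test_that("embedded signature blocks are recoverable from expression", {
  cfg <- scenario_config(expression = list(
    n_patients = 120L, ligand_size = 200L, creighton_size = 200L,
    n_other = 50L, loading = 0.9))
  sim <- simulate_expression(cfg, seed = 9)
  signs <- ternary_sign_vector(sim$expr, sim$ligand_signature$genes)
  sc <- igf1_ligand_score(sim$expr, signs)
  expect_gt(abs(cor(sc, sim$truth$ligand_factor)), 0.8)
  # opposite-signed latent factors: the two scores anti-correlate
  cre <- igfr_creighton_score(sim$expr, sim$creighton_signature)
  expect_lt(cor(sc, cre), 0)
})

test_that("no within-block correlation means no recoverable signal", {
  cfg <- scenario_config(expression = list(
    n_patients = 100L, ligand_size = 50L, creighton_size = 100L,
    n_other = 20L, loading = 0))
  sim <- simulate_expression(cfg, seed = 10)
  cre <- igfr_creighton_score(sim$expr, sim$creighton_signature)
  expect_lt(abs(cor(cre, sim$truth$activation_factor)), 0.3)
})

test_that("HbA1c transitions track the analytic crossing probability", {
  cfg0 <- scenario_config(hba1c = list(n = 600L, elevation = 0,
                                       p_missing_baseline = 0,
                                       p_no_on_treatment = 0))
  s <- simulate_hba1c(cfg0, seed = 11)
  tr <- transition_counts(analysis_cohort(s)$cohort)
  obs <- tr[["n_became_elevated"]] / tr[["n_normal_baseline"]]
  # oracle: P(any of 3 on-treatment values > 5.7 | baseline <= 5.7)
  hb <- cfg0$hba1c
  num <- integrate(function(b) {
    (1 - pnorm(5.7, b, hb$noise_sd)^3) * dnorm(b, hb$baseline_mean,
                                               hb$baseline_sd)
  }, 0, 5.7)$value
  analytic <- num / pnorm(5.7, hb$baseline_mean, hb$baseline_sd)
  expect_lt(abs(obs - analytic), 0.05)
  # a large elevation effect makes nearly everyone transition
  cfg_big <- scenario_config(hba1c = list(n = 200L, elevation = 2,
                                          p_missing_baseline = 0,
                                          p_no_on_treatment = 0))
  s2 <- simulate_hba1c(cfg_big, seed = 12)
  tr2 <- transition_counts(analysis_cohort(s2)$cohort)
  expect_gt(tr2[["n_became_elevated"]] / tr2[["n_normal_baseline"]],
            0.95)
})

test_that("default HbA1c settings emulate the studied glycemic profile", {
  s <- simulate_hba1c(scenario_config(hba1c = list(n = 2000L)), seed = 13)
  rep <- hba1c_report(s)
  expect_lt(abs(rep$frac_baseline_elevated - 0.27), 0.04)
  expect_lt(abs(rep$frac_became_elevated - 0.27), 0.05)
})
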