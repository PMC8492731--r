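test_that("subtype rates average profile-level rates by observed mix", {
  pat <- toy_patients(arm = c("control", "control", "A", "A"),
                      hr = c(0, 1, 0, 1), pcr = c(0, 1, 0, 1))
  beta <- matrix(c(-1.0, 0.5, 0.2, 0.8,
                   -0.4, -0.3, 0.1, 0.2,
                    0.3, 0.9, -0.2, -0.5), nrow = 3, byrow = TRUE)
  dr <- toy_draws(pat, beta)
  # brute force per draw: half the population HR-, half HR+
  expected <- sapply(1:3, function(i) {
    b <- beta[i, ]
    mean(c(plogis(b[1] + b[4]), plogis(b[1] + b[2] + b[4])))
  })
  got <- subtype_rate(dr, "A", signature_def("All HER2-", her2 = 0))
  expect_equal(got, expected, tolerance = 1e-12)
  # single-profile stratum: rate is the inverse-logit of its predictor
  got_hr1 <- subtype_rate(dr, "control", signature_def("HR+", hr = 1))
  expect_equal(got_hr1, plogis(beta[, 1] + beta[, 2]), tolerance = 1e-12)
  expect_error(subtype_rate(dr, "A", signature_def("HER2+", her2 = 1)),
               "empty signature stratum")
})

test_that("probability of superiority counts joint draws", {
  pat <- toy_patients(arm = c("control", "A"), hr = c(0, 0),
                      pcr = c(0, 1))
  b0 <- qlogis(0.25)
  bA <- qlogis(c(0.3, 0.2, 0.4)) - b0
  dr <- toy_draws(pat, cbind(rep(b0, 3), 0, 0, bA))
  expect_equal(prob_superior(dr, "A", signature_def("all")), 2 / 3)
  # arm always above control
  dr2 <- toy_draws(pat, cbind(rep(b0, 3), 0, 0, rep(1, 3)))
  expect_equal(prob_superior(dr2, "A", signature_def("all")), 1)
})

test_that("predictive phase-3 probability matches brute-force enumeration", {
  cfg <- trial_config(phase3_n = 300L, phase3_alpha = 0.025)
  # independent oracle: explicit double loop over the count grid
  power_oracle <- function(pa, pc, m, alpha) {
    crit <- qnorm(1 - alpha)
    tot <- 0
    for (xa in 0:m) {
      for (xc in 0:m) {
        pha <- xa / m; phc <- xc / m; pp <- (xa + xc) / (2 * m)
        se <- sqrt(pp * (1 - pp) * 2 / m)
        if (se > 0 && (pha - phc) / se > crit) {
          tot <- tot + dbinom(xa, m, pa) * dbinom(xc, m, pc)
        }
      }
    }
    tot
  }
  pat <- toy_patients(arm = c("control", "A"), hr = c(0, 0),
                      pcr = c(0, 1))
  # point-mass posterior at the null: pps equals the test's size
  dr_null <- toy_draws(pat, cbind(rep(qlogis(0.2), 2), 0, 0, rep(0, 2)))
  pps <- predictive_prob_phase3(dr_null, "A", signature_def("all"), cfg)
  expect_equal(pps, power_oracle(0.2, 0.2, 150, 0.025), tolerance = 1e-10)
  expect_lt(abs(pps - 0.025), 0.01)
  # overwhelming effect
  dr_big <- toy_draws(pat, cbind(rep(qlogis(0.1), 2), 0, 0,
                                 rep(qlogis(0.9) - qlogis(0.1), 2)))
  expect_gt(predictive_prob_phase3(dr_big, "A", signature_def("all"),
                                   cfg), 0.999)
})

test_that("graduation and futility rules follow the thresholds", {
  cfg <- trial_config()
  final <- c("All HER2-" = 0.33, "HR+/HER2-" = 0.21, "HR-/HER2-" = 0.51)
  expect_equal(evaluate_arm_status(final, cfg)$status, "continue")
  expect_equal(evaluate_arm_status(final, cfg,
                                   accrual_reached = TRUE)$status,
               "max_accrual_stop")
  expect_equal(evaluate_arm_status(c(0.05, 0.08, 0.02), cfg)$status,
               "futility_stop")
  dec <- evaluate_arm_status(c(a = 0.86, b = 0.10, c = 0.10), cfg)
  expect_equal(dec$status, "graduate")
  expect_equal(dec$graduating, "a")
  expect_error(evaluate_arm_status(c(0.5, 1.2), cfg), "\\[0, 1\\]")
})

test_that("adaptive randomization gives control exactly its fraction", {
  cfg <- trial_config()
  pat <- toy_patients(arm = c("control", "A", "B"), hr = c(0, 0, 0),
                      pcr = c(0, 1, 0))
  # arm A best in 3 of 4 draws
  beta <- cbind(rep(-1, 4), 0, 0, c(1, 1, 1, 0), c(0.5, 0.5, 0.5, 0.5))
  dr <- toy_draws(pat, beta)
  p <- randomization_probabilities(dr, signature_def("all"), c("A", "B"),
                                   cfg)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["control"]), 0.20)
  expect_equal(unname(p["A"]), 0.8 * 0.75)
  expect_equal(unname(p["B"]), 0.8 * 0.25)
  # single open arm gets the full remainder
  p1 <- randomization_probabilities(dr, signature_def("all"), "A", cfg)
  expect_equal(unname(p1), c(0.20, 0.80))
  expect_error(randomization_probabilities(dr, signature_def("all"),
                                           character(0), cfg),
               "no open")
})

test_that("exchangeable arms split the experimental share evenly", {
  cfg <- trial_config()
  pat <- toy_patients(arm = c("control", "A", "B"), hr = c(0, 0, 0),
                      pcr = c(0, 1, 0))
  set.seed(4)
  beta <- cbind(rep(-1, 4000), 0, 0, rnorm(4000, 0, 0.5),
                rnorm(4000, 0, 0.5))
  dr <- toy_draws(pat, beta)
  p <- randomization_probabilities(dr, signature_def("all"), c("A", "B"),
                                   cfg)
  expect_lt(abs(p[["A"]] - 0.40), 0.03)
})

test_that("arm summary reports percentages with probability intervals", {
  pat <- toy_patients(arm = rep(c("control", "PGM"), each = 20),
                      hr = rep(0:1, 20), pcr = rep(c(0, 1), 20))
  m <- build_model(pat, analysis_day = 1800)
  dr <- suppressWarnings(sample_posterior(m, seed = 12, chains = 1,
                                          warmup = 200, iter = 300))
  s <- arm_summary(dr, "PGM")
  expect_equal(s$signature, c("All HER2-", "HR+/HER2-", "HR-/HER2-"))
  expect_true(all(s$rate_arm_lo <= s$rate_arm & s$rate_arm <= s$rate_arm_hi))
  expect_true(all(s$prob_superior >= 0 & s$prob_superior <= 100))
  expect_true(all(s$pred_prob_phase3 >= 0 & s$pred_prob_phase3 <= 100))
})
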