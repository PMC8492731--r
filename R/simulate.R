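# Synthetic-data generators. Defaults emulate the study conditions: arm
# sizes 106/128, HR+ prevalence 0.535 and MP-Hi2 prevalence 0.505 (the two
# arms' baseline tables averaged), control subtype pCR rates near 21%
# (HR-/HER2-) and 12% (HR+/HER2-), an experimental-arm log-odds ratio of
# 0.571 (32% vs 21% in HR-/HER2-), staggered accrual spanning multiple
# 90-day bins, and HbA1c trajectories whose baseline distribution and
# on-treatment elevation reproduce the reported 27% baseline-elevated and
# 27% became-elevated fractions.

#' Scenario configuration for the synthetic generators
#'
#' @param n_per_arm named integer vector of arm sizes; must include
#'   `control`.
#' @param hr_prev,her2_prev,mp_hi2_prev marker prevalences.
#' @param coef logistic coefficients: `intercept` (control, HR-, Hi1),
#'   `hr`, `her2`, `mp` (Hi2 effect), on the log-odds scale.
#' @param arm_logor named log-odds ratios of the experimental arms vs
#'   control.
#' @param accrual named list of `(first_day, last_day)` accrual windows
#'   per arm.
#' @param analysis_day calendar day of the analysis.
#' @param drift named list (`"HER2-"`, `"HER2+"`) of true per-bin offsets
#'   delta(t) (bin 1 = most recent); `NULL` entries mean zero drift.
#' @param deviation_rate probability a patient has a protocol deviation
#'   (type drawn uniformly; outcome then unobserved).
#' @param expression list: `n_patients`, `ligand_size`, `creighton_size`,
#'   `n_other`, `loading` (factor loading, controls within-block
#'   correlation), `factor_cor` (correlation between the ligand and
#'   receptor-activation latent factors; negative by default),
#'   `base_mean`, `base_sd` (gene baselines, log2-like scale).
#' @param hba1c list: `n`, `baseline_mean`, `baseline_sd`, `elevation`
#'   (on-treatment shift, experimental arm only), `noise_sd`, `on_days`,
#'   `schedule_jitter_sd` (per-patient shift of the visit schedule),
#'   `p_missing_baseline`, `p_no_on_treatment`.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_per_arm = c(PGM = 106L, control = 128L),
                            hr_prev = 0.535, her2_prev = 0,
                            mp_hi2_prev = 0.505,
                            coef = c(intercept = -1.58, hr = -0.75,
                                     her2 = 0, mp = 0.5),
                            arm_logor = c(PGM = 0.571),
                            accrual = list(control = c(0, 1800),
                                           PGM = c(850, 1800)),
                            analysis_day = 1800,
                            drift = list(),
                            deviation_rate = 0.03,
                            expression = list(),
                            hba1c = list()) {
  stopifnot("control" %in% names(n_per_arm),
            hr_prev > 0, hr_prev < 1, her2_prev >= 0, her2_prev < 1,
            mp_hi2_prev > 0, mp_hi2_prev < 1,
            deviation_rate >= 0, deviation_rate < 1)
  expression <- utils::modifyList(
    list(n_patients = 233L, ligand_size = 274L, creighton_size = 802L,
         n_other = 200L, loading = 0.7, factor_cor = -0.8,
         base_mean = 8, base_sd = 1), expression)
  hba1c <- utils::modifyList(
    list(n = 106L, baseline_mean = 5.4, baseline_sd = 0.49,
         elevation = 0.13, noise_sd = 0.15, on_days = c(56, 84, 112),
         schedule_jitter_sd = 16, p_missing_baseline = 0.02,
         p_no_on_treatment = 0.3), hba1c)
  structure(list(n_per_arm = n_per_arm, hr_prev = hr_prev,
                 her2_prev = her2_prev, mp_hi2_prev = mp_hi2_prev,
                 coef = coef, arm_logor = arm_logor, accrual = accrual,
                 analysis_day = analysis_day, drift = drift,
                 deviation_rate = deviation_rate,
                 expression = expression, hba1c = hba1c),
            class = "scenario_config")
}

#' Simulate a platform-trial patient table
#'
#' Covariates are drawn at the configured prevalences, accrual days
#' uniformly over each arm's window, and the binary endpoint from the
#' logistic model with the configured true per-bin drift offsets applied
#' in the patient's HER2 stratum. Deviating patients have an unobserved
#' outcome (imputable by the deviation rule).
#'
#' @param config a [scenario_config()].
#' @param seed integer seed (mandatory).
#' @return patient table ([as_patient_table()]).
#' @export
simulate_trial <- function(config = scenario_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  arms <- names(config$n_per_arm)
  n <- sum(config$n_per_arm)
  arm <- rep(arms, config$n_per_arm)
  hr <- stats::rbinom(n, 1, config$hr_prev)
  her2 <- stats::rbinom(n, 1, config$her2_prev)
  hi2 <- stats::rbinom(n, 1, config$mp_hi2_prev)
  # 70-gene score drawn uniformly within the class range (threshold -0.573)
  mp_score <- ifelse(hi2 == 1, stats::runif(n, -1, -0.573 - 1e-9),
                     stats::runif(n, -0.573, 1))
  day <- numeric(n)
  for (a in arms) {
    w <- config$accrual[[a]]
    if (is.null(w)) w <- c(0, config$analysis_day)
    idx <- which(arm == a)
    day[idx] <- round(stats::runif(length(idx), w[1], w[2]))
  }
  eta <- config$coef[["intercept"]] + config$coef[["hr"]] * hr +
    config$coef[["her2"]] * her2 + config$coef[["mp"]] * hi2
  for (a in setdiff(arms, "control")) {
    eta <- eta + ifelse(arm == a, config$arm_logor[[a]], 0)
  }
  bins <- assign_time_bin(day, config$analysis_day)
  stratum <- ifelse(her2 == 1, "HER2+", "HER2-")
  for (s in names(config$drift)) {
    d <- config$drift[[s]]
    idx <- which(stratum == s & bins <= length(d))
    eta[idx] <- eta[idx] + d[bins[idx]]
  }
  pcr <- stats::rbinom(n, 1, stats::plogis(eta))
  deviation <- rep("none", n)
  dev <- stats::runif(n) < config$deviation_rate
  deviation[dev] <- sample(deviation_levels()[-1], sum(dev),
                           replace = TRUE)
  pcr[dev] <- NA
  as_patient_table(data.frame(
    patient_id = sprintf("P%04d", seq_len(n)), arm = arm, hr = hr,
    her2 = her2, mp_score = mp_score, randomization_day = day,
    pcr = pcr, deviation = deviation))
}

#' Simulate an expression matrix with embedded signed signature blocks
#'
#' A latent ligand factor drives a signed ligand-gene block (the anchor
#' gene IGF1 is its first member); a second latent factor, correlated with
#' the first at `factor_cor` (negative by default, emulating the observed
#' inverse relation between the two scores), drives a binary-signed
#' receptor-activation block with the published +/- proportion (364:438).
#' Remaining genes are noise. Gene baselines put values on a log-like
#' scale so centering matters.
#'
#' @param config a [scenario_config()]; uses the `expression` component.
#' @param seed integer seed (mandatory).
#' @return list: `expr` (genes x patients), `truth` (latent factors),
#'   `ligand_signature` (genes only, signs derived at run time),
#'   `creighton_signature` ([signed_signature()] with -1/+1 signs).
#' @export
simulate_expression <- function(config = scenario_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cf <- config$expression
  stopifnot(cf$ligand_size >= 2, cf$creighton_size >= 3)
  np <- cf$n_patients
  lam <- cf$loading
  f_lig <- stats::rnorm(np)
  f_act <- cf$factor_cor * f_lig +
    sqrt(max(0, 1 - cf$factor_cor^2)) * stats::rnorm(np)
  # IGF2 and IGFBP4 ride in the ligand block (the ligand signature tracks
  # them closely); the remaining axis genes are added below
  stopifnot(cf$ligand_size >= 4)
  lig_genes <- c("IGF1", "IGF2", "IGFBP4",
                 sprintf("LIG%03d", seq_len(cf$ligand_size - 3L)))
  lig_signs <- c(1, 1, 1, sample(c(1, -1), cf$ligand_size - 3L,
                                 replace = TRUE, prob = c(0.6, 0.4)))
  n_pos <- round(cf$creighton_size * 364 / 802)
  cre_genes <- sprintf("CRE%03d", seq_len(cf$creighton_size))
  cre_signs <- sample(c(rep(1L, n_pos),
                        rep(-1L, cf$creighton_size - n_pos)))
  oth_genes <- if (cf$n_other > 0) sprintf("OTH%03d", seq_len(cf$n_other))
  else character(0)
  block <- function(signs, fac) {
    g <- length(signs)
    signal <- outer(signs * lam, fac)
    signal + sqrt(1 - lam^2) * matrix(stats::rnorm(g * np), g, np)
  }
  # the activation score is the negated regression t-statistic, so the
  # signed block loads on -f_act for the score to recover +f_act
  # standalone IGF-axis genes: IGF1R tracks the activation factor, the
  # rest are unlinked
  axis_genes <- c("IGF1R", "INSR", "IGFBP2", "IRS1", "IRS2", "IGFBP3",
                  "IGFBP5", "CDH1")
  axis_vals <- matrix(stats::rnorm(length(axis_genes) * np),
                      length(axis_genes), np)
  axis_vals[1, ] <- lam * f_act + sqrt(1 - lam^2) * axis_vals[1, ]
  vals <- rbind(block(lig_signs, f_lig), block(cre_signs, -f_act),
                axis_vals,
                if (cf$n_other > 0)
                  matrix(stats::rnorm(cf$n_other * np), cf$n_other, np))
  genes <- c(lig_genes, cre_genes, axis_genes, oth_genes)
  vals <- vals + stats::rnorm(length(genes), cf$base_mean, cf$base_sd)
  dimnames(vals) <- list(genes, sprintf("S%04d", seq_len(np)))
  list(expr = as_expression_matrix(vals),
       truth = list(ligand_factor = stats::setNames(f_lig,
                                                    colnames(vals)),
                    activation_factor = stats::setNames(f_act,
                                                        colnames(vals))),
       ligand_signature = signed_signature("ligand_sim", lig_genes),
       creighton_signature = signed_signature("creighton_sim", cre_genes,
                                              cre_signs))
}

#' Simulate a binary endpoint linked to a marker with arm-specific effects
#'
#' Convenience generator for biomarker power / type-I-error studies:
#' logit P(pCR) = intercept + log-OR(arm) x marker.
#'
#' @param marker numeric marker values.
#' @param arm arm labels.
#' @param logor named log-OR per unit marker for each arm (default 0).
#' @param intercept baseline log-odds.
#' @return 0/1 outcome vector (uses the current RNG state).
#' @export
simulate_marker_pcr <- function(marker, arm, logor = c(), intercept = -1) {
  eta <- rep(intercept, length(marker))
  for (a in names(logor)) {
    eta <- eta + ifelse(arm == a, logor[[a]] * marker, 0)
  }
  stats::rbinom(length(marker), 1, stats::plogis(eta))
}

#' Simulate longitudinal HbA1c series
#'
#' Baselines are Normal (truncated positive); experimental-arm patients
#' get a persistent on-treatment elevation added to every on-treatment
#' value, plus measurement noise. Some patients miss the baseline or all
#' on-treatment visits, mimicking incomplete ascertainment.
#'
#' @param config a [scenario_config()]; uses the `hba1c` component.
#' @param seed integer seed (mandatory).
#' @param arm arm label for the simulated patients (elevation applies
#'   unless `"control"`).
#' @return long data.frame: `patient_id`, `day`, `value`, `phase`, `arm`.
#' @export
simulate_hba1c <- function(config = scenario_config(), seed,
                           arm = "PGM") {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cf <- config$hba1c
  stopifnot(length(cf$on_days) > 0)
  elev <- if (arm == "control") 0 else cf$elevation
  rows <- vector("list", cf$n)
  for (i in seq_len(cf$n)) {
    base <- -1
    while (base <= 0) {
      base <- stats::rnorm(1, cf$baseline_mean, cf$baseline_sd)
    }
    d <- data.frame(patient_id = sprintf("H%04d", i), day = 0,
                    value = base, phase = "baseline")
    if (stats::runif(1) < cf$p_missing_baseline) d <- d[0, ]
    if (stats::runif(1) >= cf$p_no_on_treatment) {
      v <- pmax(0.1, base + elev +
                  stats::rnorm(length(cf$on_days), 0, cf$noise_sd))
      # whole-schedule shift per patient: visit timing varies, values
      # (persistent elevation) do not depend on it
      days <- pmax(14, round(cf$on_days +
                               stats::rnorm(1, 0, cf$schedule_jitter_sd)))
      d <- rbind(d, data.frame(patient_id = sprintf("H%04d", i),
                               day = days, value = v,
                               phase = "on_treatment"))
    }
    rows[[i]] <- d
  }
  out <- do.call(rbind, rows)
  out$arm <- arm
  rownames(out) <- NULL
  out
}
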