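# Platform decision rules: subtype pCR-rate distributions, probability of
# superiority, predictive probability of phase-3 success, graduation /
# futility, and response-adaptive randomization.

#' Define a clinical signature (patient subset)
#'
#' A signature is a predicate over the clinical subtype markers. `NA` leaves
#' a marker unconstrained.
#'
#' @param name label, e.g. `"All HER2-"`.
#' @param hr,her2 0, 1 or `NA`.
#' @param mp `"Hi1"`, `"Hi2"` or `NA`.
#' @return object of class `signature_def`.
#' @export
signature_def <- function(name, hr = NA, her2 = NA, mp = NA) {
  structure(list(name = name, hr = hr, her2 = her2, mp = mp),
            class = "signature_def")
}

#' The three HER2-negative graduation signatures
#'
#' All HER2-negative patients plus the HR-positive and HR-negative splits —
#' the signatures in which a HER2-negative-only arm can graduate.
#'
#' @return list of [signature_def()]s.
#' @export
her2neg_signatures <- function() {
  list(signature_def("All HER2-", her2 = 0),
       signature_def("HR+/HER2-", hr = 1, her2 = 0),
       signature_def("HR-/HER2-", hr = 0, her2 = 0))
}

signature_match <- function(sig, patients) {
  keep <- rep(TRUE, nrow(patients))
  if (!is.na(sig$hr)) keep <- keep & patients$hr == sig$hr
  if (!is.na(sig$her2)) keep <- keep & patients$her2 == sig$her2
  if (!is.na(sig$mp)) keep <- keep & patients$mp_class == sig$mp
  keep
}

#' Trial configuration: decision thresholds and the phase-3 template
#'
#' @param signatures list of [signature_def()]s in which an arm may graduate.
#' @param graduation_threshold predictive probability at or above which an
#'   arm graduates (default 0.85).
#' @param futility_threshold predictive probability below which (in every
#'   signature) an arm is dropped (default 0.10).
#' @param control_fraction fixed share of randomization to control (0.20).
#' @param phase3_n total size of the hypothetical 1:1 confirmatory trial.
#' @param phase3_alpha one-sided level of the phase-3 success test.
#' @param max_accrual per-arm accrual cap (informational).
#' @return object of class `trial_config`.
#' @export
trial_config <- function(signatures = her2neg_signatures(),
                         graduation_threshold = 0.85,
                         futility_threshold = 0.10,
                         control_fraction = 0.20,
                         phase3_n = 300L, phase3_alpha = 0.025,
                         max_accrual = 120L) {
  stopifnot(futility_threshold > 0,
            futility_threshold < graduation_threshold,
            graduation_threshold < 1,
            control_fraction > 0, control_fraction < 1)
  if (phase3_n %% 2 != 0) stop("phase3_n must be even under 1:1 allocation")
  if (phase3_alpha <= 0 || phase3_alpha >= 1) stop("invalid phase3_alpha")
  structure(list(signatures = signatures,
                 graduation_threshold = graduation_threshold,
                 futility_threshold = futility_threshold,
                 control_fraction = control_fraction,
                 phase3_n = as.integer(phase3_n),
                 phase3_alpha = phase3_alpha,
                 max_accrual = as.integer(max_accrual)),
            class = "trial_config")
}

#' Posterior draws of the pCR rate for an arm within a signature
#'
#' The rate is evaluated at the current analysis time (drift offsets are
#' zero in the frozen bins) and averaged over the covariate-profile mix
#' observed among signature patients, weighting each (HR, HER2, MP) profile
#' by its empirical frequency.
#'
#' @param draws a [sample_posterior()] result.
#' @param arm arm label (control included).
#' @param signature a [signature_def()].
#' @return numeric vector, one pCR-rate draw per posterior draw.
#' @export
subtype_rate <- function(draws, arm, signature) {
  stopifnot(inherits(draws, "tm_draws"))
  model <- draws$model
  if (!arm %in% model$arms) stop("unknown arm: ", arm)
  pat <- model$patients[signature_match(signature, model$patients), ,
                        drop = FALSE]
  if (nrow(pat) == 0) stop("empty signature stratum: ", signature$name)
  prof <- unique(data.frame(hr = pat$hr, her2 = pat$her2,
                            mp = as.integer(pat$mp_class == "Hi2")))
  w <- apply(prof, 1, function(r)
    mean(pat$hr == r["hr"] & pat$her2 == r["her2"] &
           as.integer(pat$mp_class == "Hi2") == r["mp"]))
  P <- model$design_fun(prof$hr, prof$her2, prof$mp,
                        rep(arm, nrow(prof)))
  rates <- stats::plogis(draws$beta %*% t(P))
  as.vector(rates %*% w)
}

#' Posterior probability that an arm's pCR rate exceeds control's
#'
#' @inheritParams subtype_rate
#' @return scalar in \[0, 1\]: fraction of joint posterior draws with
#'   rate(arm) > rate(control) within the signature.
#' @export
prob_superior <- function(draws, arm, signature) {
  r_arm <- subtype_rate(draws, arm, signature)
  r_ctl <- subtype_rate(draws, draws$model$control, signature)
  mean(r_arm > r_ctl)
}

#' Success region of the phase-3 two-proportion test
#'
#' Precomputes, over the grid of possible pCR counts (x_arm, x_ctrl) with m
#' patients per arm, whether the one-sided pooled two-proportion z-test
#' rejects at level alpha. Degenerate tables (pooled rate 0 or 1) never
#' reject.
#'
#' @param m patients per phase-3 arm.
#' @param alpha one-sided level.
#' @return (m+1) x (m+1) 0/1 matrix, rows = x_arm, cols = x_ctrl.
#' @keywords internal
phase3_success_region <- function(m, alpha) {
  x <- 0:m
  pa <- outer(x / m, rep(1, m + 1))
  pc <- outer(rep(1, m + 1), x / m)
  pp <- (pa + pc) / 2
  se <- sqrt(pp * (1 - pp) * 2 / m)
  z <- ifelse(se > 0, (pa - pc) / se, 0)
  (z > stats::qnorm(1 - alpha)) * 1
}

#' Predictive probability of success in the confirmatory phase-3 trial
#'
#' For each posterior draw of (rate_arm, rate_control) within the
#' signature, computes exactly (by binomial enumeration over the count
#' grid) the probability that a 1:1 phase-3 trial of `phase3_n` patients
#' rejects under the one-sided pooled z-test at `phase3_alpha`, then
#' averages over draws.
#'
#' @inheritParams subtype_rate
#' @param config a [trial_config()].
#' @return scalar in \[0, 1\].
#' @export
predictive_prob_phase3 <- function(draws, arm, signature, config) {
  stopifnot(inherits(config, "trial_config"))
  r_arm <- subtype_rate(draws, arm, signature)
  r_ctl <- subtype_rate(draws, draws$model$control, signature)
  mean(phase3_power(r_arm, r_ctl, config$phase3_n, config$phase3_alpha))
}

#' Exact power of the phase-3 test at given true rates
#'
#' @param p_arm,p_ctrl true pCR rates (vectorized, recycled).
#' @param phase3_n total phase-3 size (1:1).
#' @param alpha one-sided level.
#' @return success probability per (p_arm, p_ctrl) pair.
#' @export
phase3_power <- function(p_arm, p_ctrl, phase3_n = 300L, alpha = 0.025) {
  m <- phase3_n %/% 2
  R <- phase3_success_region(m, alpha)
  k <- max(length(p_arm), length(p_ctrl))
  p_arm <- rep_len(p_arm, k); p_ctrl <- rep_len(p_ctrl, k)
  A <- t(vapply(p_arm, function(p) stats::dbinom(0:m, m, p),
                numeric(m + 1)))
  C <- t(vapply(p_ctrl, function(p) stats::dbinom(0:m, m, p),
                numeric(m + 1)))
  rowSums((A %*% R) * C)
}

#' Graduation / futility decision for an arm
#'
#' @param pps named numeric vector: predictive probability of phase-3
#'   success per signature.
#' @param config a [trial_config()].
#' @param accrual_reached has the arm hit its accrual cap?
#' @return list with `status` (`graduate`, `futility_stop`,
#'   `max_accrual_stop` or `continue`), `per_signature_pps`, and the
#'   graduating signatures if any.
#' @export
evaluate_arm_status <- function(pps, config, accrual_reached = FALSE) {
  stopifnot(inherits(config, "trial_config"), length(pps) > 0)
  if (any(pps < 0 | pps > 1)) stop("pps must lie in [0, 1]")
  status <- if (any(pps >= config$graduation_threshold)) {
    "graduate"
  } else if (all(pps < config$futility_threshold)) {
    "futility_stop"
  } else if (accrual_reached) {
    "max_accrual_stop"
  } else {
    "continue"
  }
  list(status = status, per_signature_pps = pps,
       graduating = names(pps)[pps >= config$graduation_threshold])
}

#' Response-adaptive randomization probabilities within a subtype
#'
#' Control receives exactly `control_fraction`; open experimental arms
#' share the remainder in proportion to the (tempered) posterior
#' probability of being the best arm in the subtype.
#'
#' @param draws a [sample_posterior()] result.
#' @param signature the subtype ([signature_def()]).
#' @param open_arms experimental arms still accruing.
#' @param config a [trial_config()].
#' @param temper exponent applied to the best-arm probabilities before
#'   normalization (1 = proportional).
#' @return named probability vector (control first), summing to 1.
#' @export
randomization_probabilities <- function(draws, signature, open_arms,
                                        config, temper = 1) {
  if (length(open_arms) == 0) stop("no open experimental arms")
  ctl <- draws$model$control
  if (ctl %in% open_arms) stop("open_arms must be experimental arms only")
  rates <- vapply(open_arms, function(a) subtype_rate(draws, a, signature),
                  numeric(nrow(draws$beta)))
  if (length(open_arms) == 1) {
    p_best <- 1
  } else {
    best <- max.col(rates, ties.method = "first")
    p_best <- tabulate(best, nbins = length(open_arms)) / nrow(rates)
  }
  wt <- p_best^temper
  if (sum(wt) == 0) wt <- rep(1, length(open_arms))
  share <- (1 - config$control_fraction) * wt / sum(wt)
  stats::setNames(c(config$control_fraction, share), c(ctl, open_arms))
}

#' Per-signature efficacy summary (final-analysis report schema)
#'
#' For each configured signature: estimated pCR rate (posterior mean, %)
#' with a central 95% probability interval for the experimental arm and
#' control, the probability the arm is superior to control, and the
#' predictive probability of phase-3 success.
#'
#' @param draws a [sample_posterior()] result.
#' @param arm experimental arm label.
#' @param config a [trial_config()].
#' @return data.frame, one row per signature; percentages on the 0-100
#'   scale.
#' @export
arm_summary <- function(draws, arm, config = trial_config()) {
  ctl <- draws$model$control
  rows <- lapply(config$signatures, function(sig) {
    ra <- subtype_rate(draws, arm, sig)
    rc <- subtype_rate(draws, ctl, sig)
    qa <- stats::quantile(ra, c(0.025, 0.975))
    qc <- stats::quantile(rc, c(0.025, 0.975))
    data.frame(signature = sig$name,
               rate_arm = 100 * mean(ra),
               rate_arm_lo = 100 * qa[[1]], rate_arm_hi = 100 * qa[[2]],
               rate_control = 100 * mean(rc),
               rate_control_lo = 100 * qc[[1]],
               rate_control_hi = 100 * qc[[2]],
               prob_superior = 100 * mean(ra > rc),
               pred_prob_phase3 = 100 *
                 mean(phase3_power(ra, rc, config$phase3_n,
                                   config$phase3_alpha)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
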