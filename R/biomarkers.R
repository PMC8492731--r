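# Qualifying biomarker evaluation: per-arm logistic association models,
# marker x treatment interaction testing by likelihood-ratio test, optional
# HR-status adjustment, and the exact 2x2 test for categorical markers.

#' Likelihood-ratio test between nested logistic models
#'
#' Fits both models by maximum likelihood (`stats::glm`, binomial logit)
#' and compares deviances on a chi-square with df equal to the difference
#' in parameter counts. Quasi-separation is flagged (huge coefficients),
#' and the p-value is still reported, with a warning.
#'
#' @param full,reduced model formulas (reduced nested in full).
#' @param data data.frame holding the outcome and terms.
#' @return list: `stat`, `df`, `p`, `separation` flag.
#' @export
lr_test_logistic <- function(full, reduced, data) {
  f_full <- suppressWarnings(stats::glm(full, data = data,
                                        family = stats::binomial()))
  f_red <- suppressWarnings(stats::glm(reduced, data = data,
                                       family = stats::binomial()))
  stat <- max(0, f_red$deviance - f_full$deviance)
  df <- f_red$df.residual - f_full$df.residual
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  separation <- any(abs(stats::coef(f_full)) > 15, na.rm = TRUE)
  if (separation) {
    warning("possible separation: p-value reported but unstable")
  }
  list(stat = stat, df = df, p = p, separation = separation)
}

#' Qualifying biomarker evaluation for one marker
#'
#' Three-model scheme: M1 regresses pCR on the marker within the
#' experimental arm; M2 the same within control; M3 fits
#' `pCR ~ marker + arm + marker:arm` on both arms and tests the
#' interaction. All tests are likelihood-ratio tests against the nested
#' model without the term of interest; no multiplicity adjustment. With
#' `hr` supplied, HR-adjusted variants (marker tests adjusted for HR in
#' each arm, and the interaction model with HR as covariate) are also
#' fitted. A marker qualifies as a specific predictor for the experimental
#' arm when both its within-arm association (M1) and the interaction (M3)
#' are significant at `alpha`.
#'
#' @param marker numeric or factor marker values.
#' @param pcr 0/1 outcome.
#' @param arm arm labels.
#' @param treatment label of the experimental arm; the remaining label is
#'   control.
#' @param hr optional 0/1 HR status for the adjusted variants.
#' @param standardize center/scale continuous markers before fitting.
#' @param alpha significance level of the qualification rule.
#' @return one-row data.frame: `lr_p_pgm`, `lr_p_control`,
#'   `lr_p_interaction`, HR-adjusted analogues (or `NA`), `qualified`.
#' @export
evaluate_marker <- function(marker, pcr, arm, treatment, hr = NULL,
                            standardize = TRUE, alpha = 0.05) {
  stopifnot(length(marker) == length(pcr), length(pcr) == length(arm))
  arms <- unique(arm)
  if (!treatment %in% arms) stop("treatment arm not present")
  if (is.numeric(marker) && standardize && stats::sd(marker) > 0) {
    marker <- as.numeric(scale(marker))
  }
  d <- data.frame(pcr = pcr, marker = marker,
                  tx = as.integer(arm == treatment))
  if (!is.null(hr)) d$hr <- hr
  single_arm <- length(arms) < 2

  p_in_arm <- function(sub, adjust) {
    if (nrow(sub) < 10 || length(unique(sub$pcr)) < 2 ||
        (is.numeric(sub$marker) && stats::sd(sub$marker) == 0)) {
      return(NA_real_)
    }
    if (adjust) {
      lr_test_logistic(pcr ~ marker + hr, pcr ~ hr, sub)$p
    } else {
      lr_test_logistic(pcr ~ marker, pcr ~ 1, sub)$p
    }
  }
  constant_marker <- is.numeric(d$marker) && stats::sd(d$marker) == 0
  p1 <- if (constant_marker) 1 else p_in_arm(d[d$tx == 1, ], FALSE)
  p2 <- if (constant_marker) 1 else p_in_arm(d[d$tx == 0, ], FALSE)
  p3 <- if (single_arm || constant_marker) {
    if (constant_marker) 1 else NA_real_
  } else {
    lr_test_logistic(pcr ~ marker * tx, pcr ~ marker + tx, d)$p
  }
  p1b <- p2b <- p3b <- NA_real_
  if (!is.null(hr) && !constant_marker) {
    p1b <- p_in_arm(d[d$tx == 1, ], TRUE)
    p2b <- p_in_arm(d[d$tx == 0, ], TRUE)
    if (!single_arm) {
      p3b <- lr_test_logistic(pcr ~ hr + marker * tx,
                              pcr ~ hr + marker + tx, d)$p
    }
  }
  data.frame(lr_p_pgm = p1, lr_p_control = p2, lr_p_interaction = p3,
             lr_p_pgm_hradj = p1b, lr_p_control_hradj = p2b,
             lr_p_interaction_hradj = p3b,
             qualified = isTRUE(p1 < alpha) && isTRUE(p3 < alpha))
}

#' Evaluate a panel of markers
#'
#' @param markers data.frame of marker columns (patients in rows).
#' @param pcr,arm,treatment,hr,alpha see [evaluate_marker()].
#' @return data.frame, one row per marker.
#' @export
evaluate_marker_panel <- function(markers, pcr, arm, treatment, hr = NULL,
                                  alpha = 0.05) {
  rows <- lapply(names(markers), function(m) {
    cbind(marker = m,
          evaluate_marker(markers[[m]], pcr, arm, treatment, hr = hr,
                          alpha = alpha))
  })
  do.call(rbind, rows)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric p under the probability-mass rule: the sum of the
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. Implemented directly over the hypergeometric
#' support so it is cheap inside simulation loops. An empty margin gives
#' p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || k == m + n) {
    warning("empty margin: p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  # relative slack guards against ties broken by floating-point noise
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}
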