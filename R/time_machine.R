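#' Prior for the calendar-drift ("time machine") offsets
#'
#' Calendar time before an analysis is partitioned into bins of
#' `bin_width_days`; the most recent `frozen_bins` bins carry no drift
#' (offsets fixed at zero), the first free offset is Gaussian, the first
#' increment is Gaussian, and deeper history follows a second-order normal
#' dynamic linear model (NDLM): second differences are N(0, tau^2) with
#' tau^2 given an inverse-gamma prior. Two independent paths are used, one
#' per HER2 stratum.
#'
#' @param mu0,tau0_sq mean/variance of the first free offset.
#' @param mu1,tau1_sq mean/variance of the first increment.
#' @param alpha,beta inverse-gamma shape/rate for the innovation variance.
#' @param bin_width_days width of a calendar bin in days.
#' @param frozen_bins number of most-recent bins pinned at zero drift.
#' @return object of class `tm_prior`.
#' @export
tm_prior <- function(mu0 = 0, mu1 = 0, tau0_sq = 0.001, tau1_sq = 0.001,
                     alpha = 1, beta = 0.001, bin_width_days = 90L,
                     frozen_bins = 4L) {
  stopifnot(tau0_sq > 0, tau1_sq > 0, alpha > 0, beta > 0,
            bin_width_days > 0, frozen_bins >= 0)
  structure(list(mu0 = mu0, mu1 = mu1, tau0_sq = tau0_sq,
                 tau1_sq = tau1_sq, alpha = alpha, beta = beta,
                 bin_width_days = as.integer(bin_width_days),
                 frozen_bins = as.integer(frozen_bins)),
            class = "tm_prior")
}

#' A drift path for one HER2 stratum
#'
#' @param stratum `"HER2+"` or `"HER2-"`.
#' @param delta numeric vector of per-bin offsets, index 1 = most recent bin.
#' @param tau_sq innovation variance (> 0).
#' @return object of class `drift_path`.
#' @export
drift_path <- function(stratum, delta, tau_sq) {
  stopifnot(stratum %in% c("HER2+", "HER2-"), is.numeric(delta))
  if (!is.numeric(tau_sq) || length(tau_sq) != 1 || tau_sq <= 0) {
    stop("tau_sq must be a positive scalar")
  }
  structure(list(stratum = stratum, delta = as.numeric(delta),
                 tau_sq = tau_sq), class = "drift_path")
}

#' Map a randomization day to its calendar bin at an analysis
#'
#' Time is set to 0 at each analysis and counted backwards: the bin for the
#' previous `bin_width` days is 1, the bin before that is 2, and so on.
#' A patient randomized on the analysis day itself falls in bin 1.
#'
#' @param randomization_day,analysis_day integer calendar days.
#' @param bin_width bin width in days (default 90).
#' @return integer bin index (>= 1), vectorized over `randomization_day`.
#' @export
assign_time_bin <- function(randomization_day, analysis_day,
                            bin_width = 90L) {
  stopifnot(bin_width > 0)
  back <- analysis_day - randomization_day
  if (any(back < 0)) {
    stop("randomization_day after analysis_day: future-dated record")
  }
  pmax(1L, as.integer(ceiling(back / bin_width)))
}

#' Log prior density of a drift path
#'
#' Sums the Gaussian log densities of the first free offset, the first
#' increment, and every second difference deeper in the past, plus the
#' inverse-gamma log density of the innovation variance. Returns `-Inf` if
#' any frozen-bin offset is nonzero.
#'
#' @param path a [drift_path()].
#' @param prior a [tm_prior()].
#' @return scalar log density.
#' @export
drift_log_prior <- function(path, prior) {
  stopifnot(inherits(path, "drift_path"), inherits(prior, "tm_prior"))
  delta <- path$delta
  tau_sq <- path$tau_sq
  if (tau_sq <= 0) stop("tau_sq must be > 0")
  fb <- prior$frozen_bins
  if (length(delta) < fb + 1L) {
    stop("path must extend past the frozen bins (length >= ", fb + 1L, ")")
  }
  if (any(delta[seq_len(fb)] != 0)) return(-Inf)
  lp <- dinvgamma_log(tau_sq, prior$alpha, prior$beta)
  lp <- lp + stats::dnorm(delta[fb + 1L], prior$mu0, sqrt(prior$tau0_sq),
                          log = TRUE)
  if (length(delta) >= fb + 2L) {
    lp <- lp + stats::dnorm(delta[fb + 2L] - delta[fb + 1L], prior$mu1,
                            sqrt(prior$tau1_sq), log = TRUE)
  }
  if (length(delta) >= fb + 3L) {
    t_idx <- (fb + 3L):length(delta)
    d2 <- delta[t_idx] - 2 * delta[t_idx - 1L] + delta[t_idx - 2L]
    lp <- lp + sum(stats::dnorm(d2, 0, sqrt(tau_sq), log = TRUE))
  }
  lp
}

# inverse-gamma log pdf, shape a, rate b
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Build the time-machine logistic model
#'
#' Specifies logit p_i = intercept + HR + HER2 + MP-class main effects +
#' one additive log-odds effect per experimental arm (control carries no
#' arm effect) + the drift offset of patient i's HER2 stratum at their
#' calendar bin. The most recent `frozen_bins` bins carry zero offset, so a
#' trial whose accrual all falls there collapses to a plain covariate
#' logistic model.
#'
#' @param patients analyzed patient table (complete `pcr`; see
#'   [prepare_analysis_set()]).
#' @param arms character vector of arm labels to model; arms without
#'   patients are dropped with a warning.
#' @param prior a [tm_prior()].
#' @param analysis_day calendar day of the analysis.
#' @param control label of the control arm (no arm effect).
#' @param coef_sd prior SD of the Normal(0, coef_sd^2) prior on each
#'   non-drift coefficient.
#' @param include_drift set `FALSE` to drop the drift terms entirely
#'   (plain covariate logistic model).
#' @param arm_subtype_interactions add arm x HR, arm x MP interaction
#'   terms for each experimental arm.
#' @return object of class `tm_model`.
#' @export
build_model <- function(patients, arms = unique(patients$arm),
                        prior = tm_prior(), analysis_day,
                        control = "control", coef_sd = 2,
                        include_drift = TRUE,
                        arm_subtype_interactions = FALSE) {
  patients <- as_patient_table(patients)
  if (any(is.na(patients$pcr))) {
    stop("patients must have complete pcr; run prepare_analysis_set() first")
  }
  if (!control %in% arms) stop("control arm '", control, "' not in arms")
  present <- arms %in% patients$arm
  if (any(!present)) {
    warning("arm(s) without patients excluded: ",
            paste(arms[!present], collapse = ", "))
    arms <- arms[present]
  }
  if (!control %in% patients$arm) stop("at least one control patient required")
  patients <- patients[patients$arm %in% arms, , drop = FALSE]
  exp_arms <- setdiff(arms, control)

  mp01 <- as.integer(patients$mp_class == "Hi2")
  design_fun <- function(hr, her2, mp, arm) {
    n <- length(hr)
    X <- cbind(`(Intercept)` = rep(1, n), hr = hr, her2 = her2, mp = mp)
    for (a in exp_arms) {
      X <- cbind(X, as.integer(arm == a))
      colnames(X)[ncol(X)] <- paste0("arm:", a)
      if (arm_subtype_interactions) {
        X <- cbind(X, as.integer(arm == a) * hr, as.integer(arm == a) * mp)
        colnames(X)[ncol(X) - 1:0] <- paste0("arm:", a, c(":hr", ":mp"))
      }
    }
    X
  }
  X <- design_fun(patients$hr, patients$her2, mp01, patients$arm)
  if (all(patients$her2 == patients$her2[1])) {
    # single HER2 stratum: column is constant, drop it from the design
    X <- X[, colnames(X) != "her2", drop = FALSE]
    design_fun_final <- function(hr, her2, mp, arm) {
      M <- design_fun(hr, her2, mp, arm)
      M[, colnames(M) != "her2", drop = FALSE]
    }
  } else {
    design_fun_final <- design_fun
  }

  bins <- assign_time_bin(patients$randomization_day, analysis_day,
                          prior$bin_width_days)
  stratum <- ifelse(patients$her2 == 1, "HER2+", "HER2-")
  drift <- list()
  if (include_drift) {
    for (s in unique(stratum)) {
      Tmax <- max(bins[stratum == s])
      if (Tmax > prior$frozen_bins) {
        drift[[s]] <- list(T = Tmax,
                           free = (prior$frozen_bins + 1L):Tmax)
      }
    }
  }
  structure(list(X = X, y = patients$pcr, bins = bins, stratum = stratum,
                 drift = drift, prior = prior, coef_sd = coef_sd,
                 arms = arms, control = control, exp_arms = exp_arms,
                 include_drift = include_drift,
                 design_fun = design_fun_final,
                 patients = patients, analysis_day = analysis_day),
            class = "tm_model")
}

#' @export
print.tm_model <- function(x, ...) {
  cat("time-machine logistic model\n")
  cat("  patients:", length(x$y), " arms:", paste(x$arms, collapse = ", "),
      "\n")
  cat("  coefficients:", ncol(x$X), "\n")
  if (length(x$drift) == 0) {
    cat("  drift: none (all accrual in frozen bins or disabled)\n")
  } else {
    for (s in names(x$drift)) {
      cat("  drift ", s, ": bins up to ", x$drift[[s]]$T, "\n", sep = "")
    }
  }
  invisible(x)
}
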