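# Posterior inference for the time-machine logistic model.
#
# Componentwise random-walk Metropolis on the regression coefficients and
# the free drift offsets (step sizes adapted toward a 0.44 acceptance rate
# during warm-up only), with a conjugate inverse-gamma Gibbs update for each
# stratum's innovation variance tau^2. The likelihood is Bernoulli-logit;
# the linear predictor is cached and updated incrementally.

# numerically stable Bernoulli-logit log likelihood at linear predictor eta
bernoulli_logit_ll <- function(y, eta) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# Gaussian part of the drift log prior (tau^2 fixed; IG term handled by Gibbs)
drift_gauss_lp <- function(delta, prior, tau_sq) {
  fb <- prior$frozen_bins
  lp <- stats::dnorm(delta[fb + 1L], prior$mu0, sqrt(prior$tau0_sq),
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

#' Draw from the posterior of a time-machine model
#'
#' @param model a [build_model()] specification.
#' @param seed integer seed; mandatory, every chain's stream derives from it.
#' @param chains number of independent chains (default 4).
#' @param warmup iterations discarded (and used for step-size adaptation).
#' @param iter retained iterations per chain.
#' @param rhat_threshold flag non-convergence when any split R-hat exceeds
#'   this (default 1.05); flagged via warning and `$converged`.
#' @return object of class `tm_draws`: `beta` (draws x coefficients),
#'   `delta` (per-stratum draws x bins matrices), `tau2`, `chain`, `rhat`,
#'   `converged`, and the model.
#' @export
sample_posterior <- function(model, seed, chains = 4L, warmup = 500L,
                             iter = 1000L, rhat_threshold = 1.05) {
  stopifnot(inherits(model, "tm_model"))
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(warmup > 0, iter > 0, chains >= 1)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- run_tm_chain(model, seed = seed + (ch - 1L) * 1009L,
                              warmup = warmup, iter = iter)
  }
  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  delta <- NULL
  if (length(model$drift) > 0) {
    delta <- lapply(names(model$drift), function(s) {
      do.call(rbind, lapply(res, function(r) r$delta[[s]]))
    })
    names(delta) <- names(model$drift)
  }
  tau2 <- do.call(rbind, lapply(res, `[[`, "tau2"))
  chain <- rep(seq_len(chains), each = iter)

  scalars <- beta
  if (!is.null(tau2) && ncol(tau2) > 0) {
    scalars <- cbind(scalars, log_tau2 = log(tau2))
  }
  rhat <- if (chains >= 2) split_rhat(scalars, chain) else
    stats::setNames(rep(NA_real_, ncol(scalars)), colnames(scalars))
  converged <- !(chains >= 2 && any(rhat > rhat_threshold, na.rm = TRUE))
  if (!converged) {
    warning("possible non-convergence: max split R-hat = ",
            signif(max(rhat, na.rm = TRUE), 4))
  }
  structure(list(beta = beta, delta = delta, tau2 = tau2, chain = chain,
                 rhat = rhat, converged = converged, model = model,
                 seed = seed),
            class = "tm_draws")
}

run_tm_chain <- function(model, seed, warmup, iter) {
  set.seed(seed)
  X <- model$X; y <- model$y
  p <- ncol(X)
  prior <- model$prior
  coef_sd <- model$coef_sd
  strata <- names(model$drift)

  beta <- stats::rnorm(p, 0, 0.1)
  delta <- list(); tau2 <- c()
  bin_idx <- list()
  for (s in strata) {
    Tm <- model$drift[[s]]$T
    delta[[s]] <- rep(0, Tm)
    tau2[s] <- prior$beta / (prior$alpha + 1)
    bin_idx[[s]] <- lapply(seq_len(Tm), function(t)
      which(model$stratum == s & model$bins == t))
  }
  offset <- rep(0, length(y))
  eta <- as.vector(X %*% beta) + offset
  ll <- bernoulli_logit_ll(y, eta)

  step_beta <- rep(0.3, p)
  step_delta <- lapply(strata, function(s)
    rep(0.1, length(model$drift[[s]]$free)))
  names(step_delta) <- strata
  acc_beta <- rep(0L, p)
  acc_delta <- lapply(step_delta, function(v) rep(0L, length(v)))
  batch <- 50L
  # joint coefficient proposal: covariance learned over the second half of
  # warm-up (Haario-style adaptive Metropolis), then frozen
  hist_beta <- matrix(NA_real_, warmup, p)
  joint_chol <- NULL
  joint_scale <- 2.38 / sqrt(p)

  total <- warmup + iter
  out_beta <- matrix(NA_real_, iter, p, dimnames = list(NULL, colnames(X)))
  out_delta <- lapply(strata, function(s)
    matrix(NA_real_, iter, model$drift[[s]]$T))
  names(out_delta) <- strata
  out_tau2 <- matrix(NA_real_, iter, length(strata),
                     dimnames = list(NULL, strata))

  for (it in seq_len(total)) {
    # regression coefficients
    for (j in seq_len(p)) {
      prop <- beta[j] + step_beta[j] * stats::rnorm(1)
      eta_new <- eta + X[, j] * (prop - beta[j])
      ll_new <- bernoulli_logit_ll(y, eta_new)
      lr <- ll_new - ll +
        stats::dnorm(prop, 0, coef_sd, log = TRUE) -
        stats::dnorm(beta[j], 0, coef_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta[j] <- prop; eta <- eta_new; ll <- ll_new
        acc_beta[j] <- acc_beta[j] + 1L
      }
    }
    # joint coefficient move along the learned posterior covariance
    if (!is.null(joint_chol)) {
      prop <- beta + joint_scale *
        as.vector(joint_chol %*% stats::rnorm(p))
      eta_new <- eta + as.vector(X %*% (prop - beta))
      ll_new <- bernoulli_logit_ll(y, eta_new)
      lr <- ll_new - ll +
        sum(stats::dnorm(prop, 0, coef_sd, log = TRUE)) -
        sum(stats::dnorm(beta, 0, coef_sd, log = TRUE))
      if (log(stats::runif(1)) < lr) {
        beta <- prop; eta <- eta_new; ll <- ll_new
      }
    }
    # drift offsets and innovation variances
    for (s in strata) {
      free <- model$drift[[s]]$free
      for (k in seq_along(free)) {
        t <- free[k]
        d_old <- delta[[s]]
        d_new <- d_old
        d_new[t] <- d_old[t] + step_delta[[s]][k] * stats::rnorm(1)
        idx <- bin_idx[[s]][[t]]
        eta_new <- eta
        if (length(idx) > 0) eta_new[idx] <- eta[idx] + (d_new[t] - d_old[t])
        ll_new <- if (length(idx) > 0) bernoulli_logit_ll(y, eta_new) else ll
        lr <- ll_new - ll +
          drift_gauss_lp(d_new, prior, tau2[s]) -
          drift_gauss_lp(d_old, prior, tau2[s])
        if (log(stats::runif(1)) < lr) {
          delta[[s]] <- d_new; eta <- eta_new; ll <- ll_new
          acc_delta[[s]][k] <- acc_delta[[s]][k] + 1L
        }
      }
      # conjugate update of tau^2 from the second differences beyond fb+2
      fb <- prior$frozen_bins
      Tm <- model$drift[[s]]$T
      if (Tm >= fb + 3L) {
        t_idx <- (fb + 3L):Tm
        d2 <- delta[[s]][t_idx] - 2 * delta[[s]][t_idx - 1L] +
          delta[[s]][t_idx - 2L]
        shape <- prior$alpha + length(d2) / 2
        rate <- prior$beta + sum(d2^2) / 2
      } else {
        shape <- prior$alpha; rate <- prior$beta
      }
      tau2[s] <- 1 / stats::rgamma(1, shape = shape, rate = rate)
    }
    # step-size adaptation, warm-up only
    if (it <= warmup && it %% batch == 0L) {
      adj <- min(0.25, sqrt(batch / it))
      step_beta <- step_beta *
        exp(ifelse(acc_beta / batch > 0.44, adj, -adj))
      acc_beta[] <- 0L
      for (s in strata) {
        step_delta[[s]] <- step_delta[[s]] *
          exp(ifelse(acc_delta[[s]] / batch > 0.44, adj, -adj))
        acc_delta[[s]][] <- 0L
      }
    }
    if (it <= warmup) {
      hist_beta[it, ] <- beta
      if (it == warmup %/% 2 || it == warmup) {
        S <- stats::cov(hist_beta[seq(max(1, it %/% 2), it), , drop = FALSE])
        ch <- tryCatch(chol(S + diag(1e-8, p)), error = function(e) NULL)
        if (!is.null(ch)) joint_chol <- t(ch)
      }
    }
    if (it > warmup) {
      i <- it - warmup
      out_beta[i, ] <- beta
      for (s in strata) out_delta[[s]][i, ] <- delta[[s]]
      if (length(strata) > 0) out_tau2[i, ] <- tau2
    }
  }
  list(beta = out_beta, delta = out_delta, tau2 = out_tau2)
}

# split R-hat (each chain halved) per column of a draws matrix
split_rhat <- function(draws, chain) {
  apply(draws, 2, function(x) {
    seqs <- unlist(lapply(split(x, chain), function(v) {
      h <- length(v) %/% 2
      list(v[seq_len(h)], v[(h + 1):(2 * h)])
    }), recursive = FALSE)
    m <- length(seqs); n <- length(seqs[[1]])
    means <- vapply(seqs, mean, 0); vars <- vapply(seqs, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' @export
print.tm_draws <- function(x, ...) {
  cat("posterior draws:", nrow(x$beta), "total (",
      length(unique(x$chain)), "chains )\n")
  pm <- colMeans(x$beta)
  cat("coefficient posterior means:\n")
  print(round(pm, 3))
  if (!is.null(x$rhat) && !all(is.na(x$rhat))) {
    cat("max split R-hat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}
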