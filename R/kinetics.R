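# Excited-state decay kinetics from per-trajectory hop records: Kaplan-Meier
# survival, right-censored exponential-mixture maximum likelihood, AIC model
# comparison, and the photoisomerization quantum yield with a Wilson score
# interval.

#' Kaplan-Meier survival curve of the excited state
#'
#' Product-limit estimate of S(t), the probability of still being in the
#' excited state at time t. Censored trajectories (no hop before their
#' censoring horizon) contribute at-risk time up to `censor_time_ps`.
#'
#' @param records Hop-record tibble (see [read_hop_records()]).
#' @return Tibble of class `hop_survival` with columns `time_ps`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`; evaluate it with [survival_at()].
#' @export
survival_curve <- function(records) {
  records <- validate_hop_records(records)
  if (nrow(records) == 0) abort("no hop records supplied")
  time <- ifelse(is.na(records$hop_time_ps), records$censor_time_ps,
                 records$hop_time_ps)
  event <- !is.na(records$hop_time_ps)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(tibble(time_ps = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, n_censor = fit$n.censor,
                   survival = fit$surv),
            class = c("hop_survival", class(tibble())),
            n = nrow(records))
}

#' Evaluate a survival curve
#'
#' Right-continuous step-function evaluation: S(0) = 1 and S drops at event
#' times.
#'
#' @param curve A `hop_survival` object.
#' @param t Times in ps.
#' @return Survival probabilities.
#' @export
survival_at <- function(curve, t) {
  ev <- curve[curve$n_event > 0, ]
  if (nrow(ev) == 0) return(rep(1, length(t)))
  stats::stepfun(ev$time_ps, c(1, ev$survival), right = FALSE)(t)
}

# ---- censored exponential mixture -----------------------------------------

#' Log-likelihood of a right-censored exponential mixture
#'
#' Survival model `S(t) = sum_j a_j exp(-t / tau_j) + pi_ll` where `pi_ll`
#' is an optional long-lived plateau mass (trajectories that do not decay on
#' the observation window) and `sum_j a_j + pi_ll = 1`. Uncensored records
#' contribute the mixture density, censored records the survival at their
#' horizon.
#'
#' @param records Hop-record tibble.
#' @param lifetimes Component lifetimes in ps.
#' @param amplitudes Component amplitudes (non-negative).
#' @param long_lived Plateau mass (default 0); `amplitudes` and `long_lived`
#'   are normalized to sum to 1.
#' @return Log-likelihood in nats.
#' @export
mixture_loglik <- function(records, lifetimes, amplitudes, long_lived = 0) {
  records <- validate_hop_records(records)
  tot <- sum(amplitudes) + long_lived
  a <- amplitudes / tot
  pll <- long_lived / tot
  t_unc <- records$hop_time_ps[!is.na(records$hop_time_ps)]
  c_cens <- records$censor_time_ps[is.na(records$hop_time_ps)]
  ll <- 0
  if (length(t_unc) > 0) {
    dens <- rowSums(vapply(seq_along(lifetimes), function(j) {
      a[j] / lifetimes[j] * exp(-t_unc / lifetimes[j])
    }, numeric(length(t_unc))))
    ll <- ll + sum(log(dens))
  }
  if (length(c_cens) > 0) {
    surv <- rowSums(vapply(seq_along(lifetimes), function(j) {
      a[j] * exp(-c_cens / lifetimes[j])
    }, numeric(length(c_cens)))) + pll
    ll <- ll + sum(log(surv))
  }
  ll
}

#' Fit a right-censored exponential-mixture decay model
#'
#' Maximum-likelihood fit of a k-component exponential mixture to hop times,
#' with right censoring and (when censored records are present) an estimated
#' long-lived plateau mass for trajectories that never decay on the
#' observation window. The likelihood is multimodal, so the optimizer runs
#' from multiple quantile-spaced, seeded starting points and keeps the best
#' optimum. The k = 1 uncensored case uses the closed-form MLE (the sample
#' mean).
#'
#' @param records Hop-record tibble; needs at least 10 uncensored records.
#' @param k Number of exponential components (1, 2 or 3).
#' @param n_starts Number of multi-start initializations (default 8).
#' @param seed Seed for the start jitter (default 1).
#' @param long_lived Estimate the plateau mass? Default: only when censored
#'   records are present.
#' @param min_amplitude Smallest resolvable component fraction
#'   (default 0.02). Mixture likelihoods admit degenerate solutions in which
#'   a vanishing-amplitude component spikes on the smallest observations;
#'   bounding the amplitudes away from zero removes them.
#' @return A `decay_fit`: `k`, `lifetimes` (ascending, ps), `amplitudes`
#'   (same order), `long_lived`, `log_likelihood`, `aic`, `n_used`
#'   (uncensored), `n_censored`.
#' @export
fit_exponential_mixture <- function(records, k = 2, n_starts = 8, seed = 1,
                                    long_lived = NULL,
                                    min_amplitude = 0.02) {
  records <- validate_hop_records(records)
  if (!k %in% 1:3) abort("k must be 1, 2 or 3")
  t_unc <- records$hop_time_ps[!is.na(records$hop_time_ps)]
  c_cens <- records$censor_time_ps[is.na(records$hop_time_ps)]
  if (length(t_unc) < 10) abort("need at least 10 uncensored records")
  if (is.null(long_lived)) long_lived <- length(c_cens) > 0

  if (k == 1 && length(c_cens) == 0 && !long_lived) {
    tau <- mean(t_unc)
    ll <- sum(stats::dexp(t_unc, rate = 1 / tau, log = TRUE))
    return(new_decay_fit(1L, tau, 1, 0, ll, length(t_unc), 0L))
  }

  m <- k + as.integer(long_lived)      # mixture masses incl. plateau
  # decay amplitudes live on a floored simplex scaled by (1 - plateau)
  unpack <- function(theta) {
    b <- softmax(c(theta[seq_len(k - 1)], 0))
    pll <- if (long_lived) stats::plogis(theta[k]) else 0
    a <- (1 - pll) * (min_amplitude + (1 - k * min_amplitude) * b)
    list(a = a, pll = pll, taus = exp(theta[m:(m + k - 1)]))
  }
  negll <- function(theta) {
    p <- unpack(theta)
    val <- mixture_loglik_fast(t_unc, c_cens, p$taus, p$a, p$pll)
    if (!is.finite(val)) return(1e10)
    -val
  }
  base_taus <- quantile(t_unc, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  base_taus <- pmax(base_taus, 1e-3)
  cens_frac <- length(c_cens) / nrow(records)
  starts <- run_with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      jitter <- if (s == 1) rep(1, k) else {
        void <- rnorm(k)  # keep stream aligned regardless of branch
        exp(void * 0.5)
      }
      taus0 <- base_taus * jitter
      p0 <- if (long_lived) stats::qlogis(min(max(cens_frac, 0.005),
                                              0.5)) else NULL
      c(rep(0, k - 1), p0, log(taus0))
    })
  })
  best <- NULL
  diagnostics <- list()
  for (th0 in starts) {
    opt <- tryCatch(
      optim(th0, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    # polish with Nelder-Mead in case BFGS stalled on a kink
    opt2 <- tryCatch(
      optim(opt$par, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) opt)
    if (opt2$value < opt$value) opt <- opt2
    diagnostics[[length(diagnostics) + 1]] <- opt
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value)) {
    abort(paste0("mixture fit failed to converge from ", length(starts),
                 " starts; best objective: ",
                 if (is.null(best)) "none" else best$value))
  }
  p <- unpack(best$par)
  ord <- order(p$taus)
  new_decay_fit(as.integer(k), p$taus[ord], p$a[ord], p$pll, -best$value,
                length(t_unc), length(c_cens))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# vectorized likelihood core used inside the optimizer
mixture_loglik_fast <- function(t_unc, c_cens, taus, a, pll) {
  dens <- 0
  for (j in seq_along(taus)) dens <- dens + a[j] / taus[j] * exp(-t_unc / taus[j])
  ll <- sum(log(dens))
  if (length(c_cens) > 0) {
    surv <- pll
    for (j in seq_along(taus)) surv <- surv + a[j] * exp(-c_cens / taus[j])
    ll <- ll + sum(log(surv))
  }
  ll
}

new_decay_fit <- function(k, lifetimes, amplitudes, long_lived, ll,
                          n_used, n_censored) {
  p <- (k + (long_lived > 0) - 1) + k   # free masses + lifetimes
  structure(list(k = k, lifetimes = lifetimes,
                 amplitudes = amplitudes / (sum(amplitudes) + long_lived),
                 long_lived = long_lived / (sum(amplitudes) + long_lived),
                 log_likelihood = ll, aic = 2 * p - 2 * ll,
                 n_parameters = p, n_used = n_used,
                 n_censored = as.integer(n_censored)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Censored exponential-mixture fit (k = %d)\n", x$k))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: tau = %.4g ps, amplitude = %.3f\n",
                j, x$lifetimes[j], x$amplitudes[j]))
  }
  if (x$long_lived > 0) {
    cat(sprintf("  long-lived plateau: %.4f\n", x$long_lived))
  }
  cat(sprintf("  logLik = %.3f, AIC = %.3f, n = %d (+%d censored)\n",
              x$log_likelihood, x$aic, x$n_used, x$n_censored))
  invisible(x)
}

#' @rdname fit_exponential_mixture
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c(paste0("tau", seq_len(x$k)),
                  if (x$long_lived > 0) "long_lived"),
         estimate = c(x$lifetimes, if (x$long_lived > 0) x$long_lived),
         amplitude = c(x$amplitudes, if (x$long_lived > 0) NA_real_),
         unit = c(rep("ps", x$k), if (x$long_lived > 0) "fraction"))
}

#' @rdname fit_exponential_mixture
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(k = x$k, logLik = x$log_likelihood, AIC = x$aic,
         nobs = x$n_used + x$n_censored, n_censored = x$n_censored)
}

#' Select the number of decay components by AIC
#'
#' Fits mixtures with `k = 1 .. k_max` components and selects the minimal
#' AIC.
#'
#' @inheritParams fit_exponential_mixture
#' @param k_max Largest component count to try (default 3).
#' @return Tibble of class `decay_model_comparison` with columns `k`,
#'   `log_likelihood`, `aic`, `delta_aic`; the selected k is in
#'   `attr(, "selected_k")` and the fits in `attr(, "fits")`.
#' @export
compare_models <- function(records, k_max = 3, n_starts = 8, seed = 1) {
  fits <- lapply(seq_len(k_max), function(k) {
    fit_exponential_mixture(records, k = k, n_starts = n_starts, seed = seed)
  })
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  out <- tibble(k = seq_len(k_max),
                log_likelihood = vapply(fits, function(f) f$log_likelihood,
                                        numeric(1)),
                aic = aic, delta_aic = aic - min(aic))
  structure(out, class = c("decay_model_comparison", class(tibble())),
            selected_k = which.min(aic), fits = fits)
}

#' Selected component count of a model comparison
#'
#' @param comparison A `decay_model_comparison`.
#' @return Integer k with minimal AIC.
#' @export
selected_k <- function(comparison) {
  attr(comparison, "selected_k")
}

# ---- quantum yield ---------------------------------------------------------

#' Photoisomerization quantum yield with Wilson interval
#'
#' Point estimate `n_reactive / n_total` over all trajectories, censored
#' trajectories counting as non-reactive in the denominator, with a 95%
#' Wilson score confidence interval.
#'
#' @param records Hop-record tibble.
#' @param conf_level Confidence level (default 0.95).
#' @return A `yield_estimate`: `n_reactive`, `n_total`, `point`, `ci_low`,
#'   `ci_high`.
#' @export
quantum_yield <- function(records, conf_level = 0.95) {
  records <- validate_hop_records(records)
  n <- nrow(records)
  if (n == 0) abort("no hop records supplied")
  x <- sum(records$reactive)
  # only the Wilson score conf.int is used; the chi-squared test (and its
  # small-n approximation warning) is irrelevant here
  ci <- suppressWarnings(stats::prop.test(x, n, conf.level = conf_level,
                                          correct = FALSE))$conf.int
  structure(list(n_reactive = as.integer(x), n_total = as.integer(n),
                 point = x / n, ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf(
    "Quantum yield: %.4f (%d/%d), %d%% Wilson CI [%.4f, %.4f]\n",
    x$point, x$n_reactive, x$n_total, round(100 * x$conf_level),
    x$ci_low, x$ci_high))
  invisible(x)
}

#' @rdname quantum_yield
#' @param x A `yield_estimate`.
#' @param ... Unused.
#' @export
tidy.yield_estimate <- function(x, ...) {
  tibble(n_reactive = x$n_reactive, n_total = x$n_total, estimate = x$point,
         conf_low = x$ci_low, conf_high = x$ci_high)
}
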