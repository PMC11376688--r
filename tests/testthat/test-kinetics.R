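test_that("survival curve matches empirical and hand product-limit tables", {
  rec <- hop_tibble(c(1, 2, 3, 4), censor = 10)
  sc <- survival_curve(rec)
  expect_equal(survival_at(sc, 2.5), 0.5)
  expect_equal(survival_at(sc, 0), 1)

  all_cens <- hop_tibble(rep(NA_real_, 5), censor = 20)
  sc2 <- survival_curve(all_cens)
  expect_true(all(survival_at(sc2, c(0, 5, 19.9)) == 1))

  # 10 records with interleaved censoring against the hand-computed table
  hop <- c(0.5, NA, 1.2, 1.2, NA, 2.0, 3.5, NA, 4.1, 6.0)
  cens <- c(20, 1.0, 20, 20, 2.5, 20, 20, 5.0, 20, 20)
  rec3 <- tibble::tibble(trajectory_id = sprintf("t%02d", 1:10),
                         hop_time_ps = hop, censor_time_ps = cens,
                         reactive = FALSE)
  sc3 <- survival_curve(rec3)
  time <- ifelse(is.na(hop), cens, hop)
  event <- !is.na(hop)
  t_eval <- c(0.4, 0.6, 1.3, 2.2, 3.9, 4.5, 7)
  expect_equal(survival_at(sc3, t_eval), km_oracle(time, event, t_eval),
               tolerance = 1e-12)
  expect_error(survival_curve(rec3[0, ]), "no hop records")
})

test_that("k = 1 uncensored MLE equals the sample mean exactly", {
  set.seed(5)
  rec <- hop_tibble(rexp(40, rate = 1 / 2.3), censor = 1e6)
  fit <- fit_exponential_mixture(rec, k = 1)
  expect_equal(fit$lifetimes, mean(rec$hop_time_ps))
  expect_equal(fit$amplitudes, 1)
  expect_equal(fit$long_lived, 0)
})

test_that("fitted likelihood dominates truth and the exhaustive grid", {
  set.seed(17)
  n <- 200
  comp <- runif(n) < 0.6
  t_obs <- ifelse(comp, rexp(n, 1 / 0.7), rexp(n, 1 / 4.2))
  rec <- hop_tibble(t_obs, censor = 1e6)
  fit <- fit_exponential_mixture(rec, k = 2)
  expect_gte(fit$log_likelihood,
             mixture_loglik(rec, c(0.7, 4.2), c(0.6, 0.4)) - 1e-9)
  # exhaustive 0.01-resolution grid around the optimum cannot beat the MLE,
  # and the MLE cannot sit more than a hair above the grid's best point
  ctr <- function(x, half, lo) seq(max(lo, round(x - half, 2)),
                                   round(x + half, 2), by = 0.01)
  grid_best <- grid_loglik_max(
    t_obs,
    tau1_grid = ctr(fit$lifetimes[1], 0.15, 0.05),
    tau2_grid = ctr(fit$lifetimes[2], 0.8, 0.5),
    a_grid = ctr(fit$amplitudes[1], 0.15, 0.01))
  expect_gte(fit$log_likelihood, grid_best - 1e-6)
  expect_lt(fit$log_likelihood - grid_best, 0.05)
})

test_that("MLE dominance holds on censored synthetic ensembles", {
  for (s in 1:6) {
    ens <- generate_sh_ensemble(small_sh_config(n = 400, seed = s),
                                geometry = FALSE)
    fit <- fit_exponential_mixture(ens$hops, k = 2)
    ll_true <- mixture_loglik(ens$hops, c(0.71, 4.25), c(0.6, 0.35),
                              long_lived = 0.05)
    expect_gte(fit$log_likelihood, ll_true - 1e-9)
    expect_lt(fit$lifetimes[1], fit$lifetimes[2])
  }
})

test_that("lifetimes are recovered across seeds at ensemble scale", {
  res <- t(vapply(1:20, function(s) {
    ens <- generate_sh_ensemble(preset_config("agp2-sh", seed = 1000 + s),
                                geometry = FALSE)
    fit_exponential_mixture(ens$hops, k = 2)$lifetimes
  }, numeric(2)))
  rel_fast <- abs(res[, 1] - 0.71) / 0.71
  rel_slow <- abs(res[, 2] - 4.25) / 4.25
  expect_lt(median(rel_fast), 0.10)
  expect_lt(median(rel_slow), 0.10)
  expect_true(all(res[, 1] < res[, 2]))
})

test_that("quantum yield counts, intervals, and invariances behave", {
  rec0 <- hop_tibble(rep(NA_real_, 10))
  qy0 <- quantum_yield(rec0)
  expect_equal(qy0$point, 0)
  expect_equal(qy0$ci_low, 0)

  rec <- hop_tibble(c(1, 2, 3, 9), reactive = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(quantum_yield(rec)$point, 0.25)

  shuf <- rec[c(3, 1, 4, 2), ]
  expect_equal(quantum_yield(shuf)$point, quantum_yield(rec)$point)
  expect_error(quantum_yield(rec[0, ]), "no hop records")
})

test_that("the Wilson interval matches its closed form and covers", {
  n <- 40
  for (x in 0:n) {
    rec <- hop_tibble(rep(1, n), reactive = seq_len(n) <= x)
    qy <- quantum_yield(rec)
    ref <- wilson_interval(x, n)
    expect_equal(c(qy$ci_low, qy$ci_high), ref, tolerance = 1e-9)
    expect_true(qy$ci_low <= qy$point && qy$point <= qy$ci_high)
  }
  # exact binomial enumeration of coverage across the parameter range
  coverage <- vapply(seq(0.05, 0.95, by = 0.05), function(p) {
    covered <- vapply(0:n, function(x) {
      ci <- wilson_interval(x, n)
      p >= ci[1] && p <= ci[2]
    }, logical(1))
    sum(dbinom(0:n, n, p)[covered])
  }, numeric(1))
  expect_true(all(coverage > 0.90))
  expect_lt(abs(mean(coverage) - 0.95), 0.03)
})

test_that("interval width shrinks like n^(-1/2)", {
  width <- function(n) {
    rec <- hop_tibble(rep(1, n), reactive = seq_len(n) <= round(0.28 * n))
    qy <- quantum_yield(rec)
    qy$ci_high - qy$ci_low
  }
  ratio <- width(500) / width(50000)
  expect_lt(abs(ratio / 10 - 1), 0.2)
})

test_that("AIC selection finds the true component count", {
  set.seed(31)
  rec <- hop_tibble(rexp(5000, 1 / 2.5), censor = 1e6)
  cmp <- compare_models(rec, k_max = 3)
  expect_equal(selected_k(cmp), 1)
  expect_true(all(diff(cmp$k) > 0))
  expect_error(fit_exponential_mixture(hop_tibble(c(1, 2, 3)), k = 2),
               "at least 10")
})
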