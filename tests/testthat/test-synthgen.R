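test_that("generators are deterministic given config and seed", {
  cfg <- small_sh_config(n = 25, seed = 77)
  e1 <- generate_sh_ensemble(cfg)
  e2 <- generate_sh_ensemble(cfg)
  expect_equal(e1$hops, e2$hops)
  expect_equal(e1$trajectories[[5]]$x, e2$trajectories[[5]]$x)
  r1 <- generate_relaxation_ensemble(preset_config("lumi-f-63"))
  r2 <- generate_relaxation_ensemble(preset_config("lumi-f-63"))
  expect_equal(r1$bookkeeping, r2$bookkeeping)
  p1 <- generate_pocket_frames(preset_config("pocket-3"))
  p2 <- generate_pocket_frames(preset_config("pocket-3"))
  expect_equal(p1$features, p2$features)
})

test_that("zero reaction probability yields zero reactive records", {
  cfg <- sh_ensemble_config(n_traj = 4, reaction_probability = 0,
                            tau_fast = 1, tau_slow = 4, amp_fast = 0.5,
                            long_lived_fraction = 0, censor_time = 50,
                            seed = 3)
  ens <- generate_sh_ensemble(cfg, geometry = FALSE)
  expect_equal(sum(ens$hops$reactive), 0)
})

test_that("config invariants are enforced before sampling", {
  expect_error(sh_ensemble_config(10, 0.3, tau_fast = 4, tau_slow = 1,
                                  amp_fast = 0.5, long_lived_fraction = 0,
                                  censor_time = 20), "tau_fast")
  expect_error(sh_ensemble_config(10, 0.3, 1, 4, amp_fast = 0.9,
                                  long_lived_fraction = 0.2,
                                  censor_time = 20), "amp_fast")
  expect_error(relaxation_ensemble_config(10, 5, 4, 2), "equal n_traj")
  expect_error(pocket_ensemble_config(n_frames = 10, n_clusters = 2,
                                      cluster_centers = rbind(c(3, 3),
                                                              c(3.1, 3)),
                                      cluster_spread = 0.2), "separated")
})

test_that("hop-time sample mean matches the closed-form mixture mean", {
  cfg <- sh_ensemble_config(n_traj = 50000, reaction_probability = 0.3,
                            tau_fast = 1, tau_slow = 4, amp_fast = 0.5,
                            long_lived_fraction = 0, censor_time = 1000,
                            seed = 101, composition = "binomial")
  ens <- generate_sh_ensemble(cfg, geometry = FALSE)
  t <- ens$hops$hop_time_ps
  expect_true(all(!is.na(t)))
  mix_mean <- 0.5 * 1 + 0.5 * 4
  se <- sd(t) / sqrt(length(t))
  expect_lt(abs(mean(t) - mix_mean), 3 * se)
})

test_that("empirical hop-time survival converges to the configured mixture", {
  cfg <- sh_ensemble_config(n_traj = 50000, reaction_probability = 0.28,
                            tau_fast = 0.71, tau_slow = 4.25,
                            amp_fast = 0.6,
                            long_lived_fraction = 61 / 3028,
                            censor_time = 20, seed = 55)
  ens <- generate_sh_ensemble(cfg, geometry = FALSE)
  t <- ens$hops$hop_time_ps
  grid <- seq(0, 19.9, by = 0.05)
  s_emp <- vapply(grid, function(g) {
    mean(is.na(t) | t > g)
  }, numeric(1))
  s_cfg <- cfg$amp_fast * exp(-grid / cfg$tau_fast) +
    cfg$amp_slow * exp(-grid / cfg$tau_slow) + cfg$long_lived_fraction
  expect_lt(max(abs(s_emp - s_cfg)), 0.02)
})

test_that("relaxation members end inside their population's D5 window", {
  rel <- generate_relaxation_ensemble(preset_config("lumi-f-63"))
  w <- hulatwist:::classification_windows()
  for (i in seq_along(rel$trajectories)) {
    dh <- compute_dihedrals(rel$trajectories[[i]])
    d5 <- wrap_angle(dh$d5[nrow(dh)])
    pop <- rel$bookkeeping$population[i]
    dist_pr <- abs(wrap_angle(d5 - w$d5_pr_center))
    if (pop == "BV_PR") {
      expect_lte(dist_pr, w$d5_half_width)
    } else {
      expect_gt(dist_pr, w$d5_half_width)
      expect_lte(abs(wrap_angle(d5 - 180)), 40)
    }
  }
})

test_that("a pure BV-Pr ensemble classifies as all BV_PR", {
  cfg <- relaxation_ensemble_config(n_traj = 8, n_pr = 8, n_pr_prime = 0,
                                    n_pr_dprime = 0, seed = 4)
  rel <- generate_relaxation_ensemble(cfg)
  lab <- classify_ensemble(rel$trajectories)
  expect_true(all(lab$label == "BV_PR"))
})

test_that("pocket blobs degenerate correctly and recover labels", {
  one <- generate_pocket_frames(pocket_ensemble_config(n_frames = 30,
                                                       n_clusters = 1,
                                                       seed = 2))
  expect_true(all(one$labels == 0))
  tiny <- generate_pocket_frames(pocket_ensemble_config(
    n_frames = 9, n_clusters = 3, cluster_spread = 1e-9, seed = 2))
  centers <- hulatwist:::default_pocket_centers()
  expect_equal(as.matrix(tiny$features),
               centers[tiny$labels + 1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  pf <- generate_pocket_frames(preset_config("pocket-3"))
  cl <- cluster_pocket(pf$features, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$labels, pf$labels), 1)
})

test_that("helix pairs reproduce their construction tilt", {
  for (th in c(0, 30)) {
    hp <- generate_helix_pair(th, seed = 8)
    expect_lt(abs(spine_tilt(hp$helix_a, hp$helix_b) - th), 0.5)
  }
  hp <- generate_helix_pair(30, seed = 8)
  set.seed(99)
  R <- random_rotation()
  shift <- rnorm(3, sd = 10)
  a2 <- sweep(hp$helix_a %*% t(R), 2, shift, "+")
  b2 <- sweep(hp$helix_b %*% t(R), 2, shift, "+")
  expect_equal(spine_tilt(a2, b2), spine_tilt(hp$helix_a, hp$helix_b),
               tolerance = 1e-6)
})
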