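test_that("dihedral matches planar references and the dual-formula oracle", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(0, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(2, 1, 0)), 180)
  set.seed(42)
  for (i in 1:1000) {
    p <- matrix(rnorm(12, sd = 2), nrow = 4)
    # skip nearly-collinear draws: they are a precondition violation
    ok <- tryCatch({
      ours <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    oracle <- dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("dihedral is rigid-motion invariant and reflection-antisymmetric", {
  set.seed(7)
  for (i in 1:50) {
    p <- matrix(rnorm(12, sd = 2), nrow = 4)
    ref <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    R <- random_rotation()
    tr <- rnorm(3)
    q <- sweep(p %*% t(R), 2, tr, "+")
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-9)
    m <- p
    m[, 3] <- -m[, 3]   # mirror through z = 0
    got <- dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])
    if (abs(abs(ref) - 180) > 1e-6) {
      expect_equal(got, -ref, tolerance = 1e-9)
    }
  }
  expect_error(
    dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear")
})

test_that("unwrapping minimizes steps and inverts exactly under rewrap", {
  expect_equal(unwrap_angles(c(20, 20, 20)), c(20, 20, 20))
  expect_equal(unwrap_angles(c(170, -170)), c(170, 190))
  set.seed(1)
  for (i in 1:20) {
    walk <- cumsum(runif(100, -160, 160))
    wrapped <- wrap_angle(walk)
    un <- unwrap_angles(wrapped)
    expect_equal(wrap_angle(un), wrap_angle(wrapped), tolerance = 1e-10)
    expect_true(all(abs(diff(un)) < 180))
  }
})

test_that("stereo codes render the Pfr/Pr taxonomy and wrap invariance", {
  expect_equal(stereo_code(c(0, 0, 0, 0, 180, 180))$rendered, "ZZEssa")
  expect_equal(stereo_code(c(0, 0, 0, 0, 180, 0))$rendered, "ZZZssa")
  expect_equal(stereo_code(rep(0, 6))$rendered, "ZZZsss")
  # exact 90 tie-breaks to E / a
  expect_equal(stereo_code(c(90, 90, 90, 90, 90, 90))$rendered, "EEEaaa")
  set.seed(3)
  d <- runif(6, -180, 180)
  expect_equal(stereo_code(d)$rendered,
               stereo_code(d + 360 * sample(-2:2, 6, TRUE))$rendered)
})

test_that("rotation sense reads the signed net change", {
  t <- seq(0, 2, by = 0.1)
  down <- dihedral_series(t, seq(180, 0, length.out = length(t)), "D6")
  flat <- dihedral_series(t, rep(100, length(t)), "D6")
  expect_equal(rotation_sense(down), "ccw")
  expect_equal(rotation_sense(flat), "none")
  set.seed(11)
  for (i in 1:20) {
    sgn <- sample(c(-1, 1), 1)
    v <- seq(0, sgn * 137, length.out = length(t))
    s <- dihedral_series(t, wrap_angle(v), "D6")
    expect_equal(rotation_sense(s), if (sgn < 0) "ccw" else "cw")
  }
})

test_that("isomerization detection recovers injected crossing times", {
  t <- seq(0, 10, by = 0.05)
  set.seed(21)
  for (i in 1:200) {
    tc <- runif(1, 1.5, 8.5)
    phase <- pmin(pmax((t - tc + 0.75) / 1.5, 0), 1)
    d6 <- dihedral_series(t, wrap_angle(90 * (1 + cos(pi * phase))), "D6")
    d5 <- dihedral_series(t, wrap_angle(120 + 60 * phase), "D5", "single")
    ev <- detect_isomerization(d5, d6)
    expect_equal(nrow(ev), 1)
    expect_lt(abs(ev$crossing_time_ps - tc), 0.05 + 1e-9)
    expect_equal(ev$sense, "ccw")
    expect_equal(ev$partner_sense, "cw")
    expect_true(ev$hula_twist)
  }
})

test_that("flat trajectories yield no events and time bases must match", {
  t <- seq(0, 5, by = 0.1)
  d6 <- dihedral_series(t, rep(180, length(t)), "D6")
  d5 <- dihedral_series(t, rep(120, length(t)), "D5", "single")
  expect_equal(nrow(detect_isomerization(d5, d6)), 0)
  d5b <- dihedral_series(t + 0.05, rep(120, length(t)), "D5", "single")
  expect_error(detect_isomerization(d5b, d6), "time base")
})

test_that("reactive trajectories flip the D6 letter from E to Z", {
  ens <- generate_sh_ensemble(small_sh_config(n = 30, seed = 13))
  ids <- ens$hops$trajectory_id[ens$hops$reactive]
  expect_gt(length(ids), 0)
  for (id in ids) {
    dh <- compute_dihedrals(ens$trajectories[[id]])
    first <- stereo_code(unlist(dh[1, c("d1", "d2", "d3", "d4", "d5", "d6")]))
    last <- stereo_code(unlist(dh[nrow(dh),
                                  c("d1", "d2", "d3", "d4", "d5", "d6")]))
    expect_equal(substr(first$rendered, 3, 3), "E")
    expect_equal(substr(last$rendered, 3, 3), "Z")
  }
})
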