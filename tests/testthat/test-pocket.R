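test_that("distance features are Euclidean and validate their labels", {
  fr <- tiny_trajectory()
  expect_error(distance_features(fr, list(c("C12", "C12"))), "degenerate")
  expect_error(distance_features(fr, list(c("C12", "Xq9"))), "Xq9")

  at <- tibble::tibble(
    frame = rep(1:2, each = 2), time_ps = rep(c(0, 1), each = 2),
    state = "S0", label = rep(c("A", "B"), 2),
    x = c(0, 3, 0, 3), y = c(0, 4, 0, 4), z = 0)
  tr <- new_trajectory(at, id = "tri")
  f <- distance_features(tr, list(c("A", "B")))
  expect_equal(f[["A-B"]], c(5, 5))

  # controlled pocket distances are reproduced exactly
  ctrl <- hulatwist:::build_bridge_frames(
    times = c(0, 1), states = c("S0", "S0"), d4 = c(10, 10),
    d5 = c(120, 120), d6 = c(0, 0),
    pocket = list(his_dist = 2.9, gln_dist = 3.2), id = "ctrl")
  f2 <- distance_features(ctrl, list(c("D_ring_O", "His278_NE2"),
                                     c("D_ring_O", "Gln190_NE2")))
  expect_equal(f2[["D_ring_O-His278_NE2"]], c(2.9, 2.9), tolerance = 1e-9)
  expect_equal(f2[["D_ring_O-Gln190_NE2"]], c(3.2, 3.2), tolerance = 1e-9)
})

test_that("PCA is orthonormal, ordered, and matches power iteration", {
  set.seed(9)
  one_axis <- cbind(rnorm(40), 0, 0) %*% random_rotation()
  colnames(one_axis) <- c("a", "b", "c")
  p1 <- pocket_pca(one_axis, scale = FALSE)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-12)

  x <- matrix(rnorm(50 * 8), 50, 8)
  x[, 1] <- x[, 1] * 3 + x[, 2]
  colnames(x) <- paste0("d", 1:8)
  p <- pocket_pca(x)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
  cv <- cov(as.matrix(p$scores))
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  expect_equal(crossprod(p$loadings), diag(ncol(x)), tolerance = 1e-9,
               ignore_attr = TRUE)

  z <- scale(x)
  po <- power_iteration_eigen(cov(z), n_vec = 2)
  expect_equal(p$sdev[1:2]^2, po$values, tolerance = 1e-6)
  for (j in 1:2) {
    expect_equal(abs(sum(p$loadings[, j] * po$vectors[, j])), 1,
                 tolerance = 1e-6)
  }
  # full reconstruction of the standardized matrix
  rec <- as.matrix(p$scores) %*% t(p$loadings)
  expect_equal(rec, unclass(z), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Ward clustering is optimal on tiny data and well-behaved", {
  # Ward is greedy, so the brute-force equality is checked on data with
  # genuine group structure, where the greedy merge attains the optimum
  set.seed(15)
  x <- rbind(matrix(rnorm(6, sd = 0.8), 3, 2),
             matrix(rnorm(6, mean = 3, sd = 0.8), 3, 2))
  cl <- ward_cluster(x, k = 2)
  expect_equal(partition_wss(x, cl$labels), min_bipartition_wss(x),
               tolerance = 1e-9)
  expect_true(all(diff(cl$linkage_heights) >= -1e-12))
  expect_equal(sort(unique(cl$labels)), 0:1)
  expect_equal(ward_cluster(x, k = 1)$labels, rep(0L, 6))
  expect_error(ward_cluster(x, k = 7), "exceeds")

  # label invariance under row permutation (up to relabelling)
  pf <- generate_pocket_frames(pocket_ensemble_config(n_frames = 60,
                                                      seed = 6))
  perm <- sample(60)
  c1 <- ward_cluster(pf$features, 3)
  c2 <- ward_cluster(pf$features[perm, ], 3)
  expect_equal(mclust::adjustedRandIndex(c1$labels[perm], c2$labels), 1)
})

test_that("the three-cluster cut maximizes the silhouette on the preset", {
  pf <- generate_pocket_frames(preset_config("pocket-3"))
  cl <- cluster_pocket(pf$features, k = 3)
  expect_gt(cl$silhouette[["k3"]], cl$silhouette[["k2"]])
  expect_gt(cl$silhouette[["k3"]], cl$silhouette[["k4"]])
  expect_equal(mclust::adjustedRandIndex(cl$labels, pf$labels), 1)
})

test_that("lifetime stratification separates slow from fast pockets", {
  rec <- hop_tibble(c(1, 2, NA, 4), censor = 20)
  one <- stratify_lifetimes(rec, rep("all", 4))
  expect_equal(one$n, 4L)
  expect_equal(one$n_censored, 1L)

  wins <- vapply(1:20, function(s) {
    set.seed(300 + s)
    ta <- rexp(40, 1 / 8)   # strong NH-Asp196 + water-coordinated CO
    tb <- rexp(40, 1 / 2)   # Gln190 on the carbonyl
    rec <- hop_tibble(c(ta, tb), censor = 1e6)
    out <- stratify_lifetimes(rec, rep(c("asp_water", "gln"), each = 40))
    out$median_hop_ps[out$pattern == "asp_water"] >
      out$median_hop_ps[out$pattern == "gln"]
  }, logical(1))
  expect_gte(sum(wins), 19)

  pat <- factor(rep("present", 4), levels = c("present", "absent"))
  out <- stratify_lifetimes(rec, pat)
  expect_equal(out$n[out$pattern == "absent"], 0L)
  expect_true(is.na(out$median_hop_ps[out$pattern == "absent"]))
})
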