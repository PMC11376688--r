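test_that("hydrogen-bond detection applies distance and angle criteria", {
  fr <- point_frame(D_ring_N = c(0, 0, 0), D_ring_H = c(1, 0, 0),
                    Asp196_OD1 = c(2.8, 0, 0.3), Tyr165_OH = c(4, 0, 0))
  hb <- detect_hbonds(fr, donors = "D_ring_N",
                      acceptors = c("Asp196_OD1", "Tyr165_OH"),
                      hydrogens = c(D_ring_N = "D_ring_H"))
  expect_equal(hb$acceptor, "Asp196_OD1")
  expect_gt(hb$angle, 160)

  # angle below threshold rejects even a short contact
  fr2 <- point_frame(D_ring_N = c(0, 0, 0), D_ring_H = c(-1, 0, 0),
                     Asp196_OD1 = c(2.8, 0, 0))
  hb2 <- detect_hbonds(fr2, "D_ring_N", "Asp196_OD1",
                       hydrogens = c(D_ring_N = "D_ring_H"))
  expect_equal(nrow(hb2), 0)
})

test_that("hydrogen bonds equal the exhaustive-pair oracle on random frames", {
  set.seed(23)
  for (i in 1:500) {
    n <- 8
    labs <- c(paste0("don", 1:4), paste0("acc", 1:4))
    fr <- tibble::tibble(label = labs, x = runif(n, 0, 6),
                         y = runif(n, 0, 6), z = runif(n, 0, 6))
    ours <- detect_hbonds(fr, donors = labs[1:4], acceptors = labs[5:8])
    ref <- brute_hbonds(fr, labs[1:4], labs[5:8])
    expect_equal(nrow(ours), nrow(ref))
    if (nrow(ref) > 0) {
      expect_equal(paste(ours$donor, ours$acceptor),
                   paste(ref$donor, ref$acceptor))
      expect_equal(ours$distance, ref$distance, tolerance = 1e-12)
    }
  }
})

test_that("water bridges require both legs within the cutoff", {
  fr <- point_frame(D_ring_O = c(0, 0, 0), His278_NE2 = c(5, 0, 0),
                    WAT1_O = c(2.5, 0, 0), WAT2_O = c(2.5, 5, 0))
  br <- water_bridges(fr, "D_ring_O", "His278_NE2")
  expect_equal(br$bridging_water, "WAT1_O")
  expect_true(all(br$water_mediated))

  dry <- point_frame(D_ring_O = c(0, 0, 0), His278_NE2 = c(5, 0, 0))
  expect_equal(nrow(water_bridges(dry, "D_ring_O", "His278_NE2")), 0)
})

test_that("generator-placed bridging waters are all recovered", {
  rel <- generate_relaxation_ensemble(preset_config("lumi-f-63"))
  his_members <- rel$bookkeeping$trajectory_id[
    !is.na(rel$bookkeeping$hbond_partner) &
      rel$bookkeeping$hbond_partner == "His278"]
  expect_gt(length(his_members), 0)
  found <- vapply(his_members, function(id) {
    fr <- final_frame(rel$trajectories[[id]])
    nrow(water_bridges(fr, "D_ring_O", "His278_NE2")) >= 1
  }, logical(1))
  expect_true(all(found))
})

test_that("photoproduct classification follows dihedrals and H-bonds", {
  pfr <- c(d4 = 10, d5 = 120, d6 = 180)
  none <- detect_hbonds(point_frame(D_ring_O = c(0, 0, 0)),
                        "D_ring_O", "D_ring_O")
  expect_equal(classify_photoproduct(pfr, none)$value, "PFR")
  expect_error(classify_photoproduct(c(d4 = 1, d5 = 2), none), "d6")

  near <- point_frame(D_ring_O = c(0, 0, 0), His278_NE2 = c(2.9, 0, 0),
                      Tyr165_OH = c(6, 0, 0))
  hb <- detect_hbonds(near, donors = c("His278_NE2", "Tyr165_OH"),
                      acceptors = "D_ring_O")
  got <- classify_photoproduct(c(d4 = 15, d5 = -120, d6 = 5), hb)
  expect_equal(got$value, "BV_PR")
  expect_match(paste(got$evidence, collapse = " "), "His278")
  # same geometry without the bond is only an intermediate
  expect_equal(classify_photoproduct(c(d4 = 15, d5 = -120, d6 = 5),
                                     none)$value, "PFR")
  expect_equal(classify_photoproduct(c(d4 = 30, d5 = 180, d6 = 8),
                                     none)$value, "BV_PR_PRIME")
  expect_equal(classify_photoproduct(c(d4 = 5, d5 = 178, d6 = 2),
                                     none)$value, "BV_PR_DPRIME")
})

test_that("classification agrees with the generator on every population", {
  rel <- generate_relaxation_ensemble(preset_config("lumi-f-63"))
  lab <- classify_ensemble(rel$trajectories)
  expect_equal(nrow(lab), 63)
  expect_equal(lab$label, rel$bookkeeping$population)
  # the taxonomy partitions the ensemble
  expect_equal(sum(table(lab$label)), length(rel$trajectories))
})

test_that("the Meta-F signature gates on all three criteria", {
  gln_ref <- c(3, 0, 0)
  open_frame <- point_frame(D_ring_O = c(0, 0, 0),
                            His278_NE2 = c(2.9, 0, 0),
                            Gln190_NE2 = c(3, 6, 0),
                            Trp440_CZ2 = c(3, 14, 0))
  sig <- metaF_signature(open_frame, gln_ref)
  expect_true(sig$meta_f)
  expect_equal(sig$score, 1)

  # Pfr-like: Gln proximal, no His bond, gate irrelevant
  pfr_frame <- point_frame(D_ring_O = c(0, 0, 0),
                           His278_NE2 = c(6, 0, 0),
                           Gln190_NE2 = c(3, 0.5, 0),
                           Trp440_CZ2 = c(3, 14, 0))
  sig2 <- metaF_signature(pfr_frame, gln_ref)
  expect_false(sig2$meta_f)
  expect_lte(sig2$score, 1 / 3)

  # Trp440 packed against Gln190 blocks the signature at 2/3
  gated <- point_frame(D_ring_O = c(0, 0, 0),
                       His278_NE2 = c(2.9, 0, 0),
                       Gln190_NE2 = c(3, 6, 0),
                       Trp440_CZ2 = c(3, 7, 0))
  sig3 <- metaF_signature(gated, gln_ref)
  expect_false(sig3$meta_f)
  expect_equal(sig3$score, 2 / 3)

  # monotonicity: opening the gate (satisfying a superset) keeps meta_f true
  expect_true(metaF_signature(open_frame, gln_ref)$meta_f)
  expect_gte(sig$score, sig3$score)
})

test_that("spine tilt is symmetric, folded, and rigid-motion invariant", {
  hp <- generate_helix_pair(30, seed = 12)
  expect_equal(spine_tilt(hp$helix_a, hp$helix_b),
               spine_tilt(hp$helix_b, hp$helix_a))
  wide <- generate_helix_pair(120, seed = 12, jitter_sd = 0)
  t_wide <- spine_tilt(wide$helix_a, wide$helix_b)
  expect_lte(t_wide, 90)
  expect_lt(abs(t_wide - 60), 0.5)
  expect_error(spine_tilt(hp$helix_a[1:3, ], hp$helix_b), "at least 4")
  fr <- hp$frame
  tilt_frame <- spine_tilt_frame(fr)
  expect_equal(tilt_frame, spine_tilt(hp$helix_a, hp$helix_b),
               tolerance = 1e-9)
})
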