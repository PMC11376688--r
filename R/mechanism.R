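# Hydrogen-bond detection, photoproduct/intermediate classification
# (BV-Pr / BV-Pr' / BV-Pr'' and the Meta-F pocket signature), and spine
# tilt geometry.

#' Extract the last frame of a trajectory
#'
#' @param traj A `bilin_trajectory`.
#' @return Tibble with columns `label`, `x`, `y`, `z`.
#' @export
final_frame <- function(traj) {
  last <- max(traj$frame)
  as_tibble(traj[traj$frame == last, c("label", "x", "y", "z")])
}

frame_positions <- function(frame, labels) {
  idx <- match(labels, frame$label)
  if (anyNA(idx)) {
    abort(paste0("unknown atom label: ", labels[is.na(idx)][1]))
  }
  as.matrix(frame[idx, c("x", "y", "z")])
}

#' Detect direct hydrogen bonds in a frame
#'
#' Geometric criterion: donor--acceptor distance at most
#' `criteria$distance` (default 3.5 angstrom) and, when a hydrogen atom is
#' modelled for the donor, D-H...A angle at least `criteria$angle`
#' (default 120 degrees). Pairs are reported sorted by distance.
#'
#' @param frame Tibble with columns `label`, `x`, `y`, `z` (one frame).
#' @param donors Character vector of donor labels.
#' @param acceptors Character vector of acceptor labels.
#' @param criteria List with `distance` (angstrom) and `angle` (degrees).
#' @param hydrogens Optional named character vector mapping donor labels to
#'   their hydrogen-atom labels.
#' @return Tibble with columns `donor`, `hydrogen`, `acceptor`, `distance`,
#'   `angle`, `water_mediated` (`FALSE`), `bridging_water` (`NA`).
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criteria = list(distance = 3.5, angle = 120),
                          hydrogens = NULL) {
  cutoff <- criteria$distance %||% 3.5
  angle_min <- criteria$angle %||% 120
  dp <- frame_positions(frame, donors)
  ap <- frame_positions(frame, acceptors)
  grid <- expand.grid(d = seq_along(donors), a = seq_along(acceptors))
  grid <- grid[donors[grid$d] != acceptors[grid$a], , drop = FALSE]
  delta <- dp[grid$d, , drop = FALSE] - ap[grid$a, , drop = FALSE]
  dist <- sqrt(rowSums(delta * delta))
  keep <- dist <= cutoff
  ang <- rep(NA_real_, length(dist))
  hyd <- rep(NA_character_, length(dist))
  if (!is.null(hydrogens)) {
    has_h <- donors[grid$d] %in% names(hydrogens)
    for (i in which(has_h & keep)) {
      hlab <- hydrogens[[donors[grid$d[i]]]]
      h <- frame_positions(frame, hlab)[1, ]
      v1 <- dp[grid$d[i], ] - h
      v2 <- ap[grid$a[i], ] - h
      ang[i] <- acos(pmin(pmax(sum(v1 * v2) /
        sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      hyd[i] <- hlab
    }
    keep <- keep & (is.na(ang) | ang >= angle_min)
  }
  out <- tibble(donor = donors[grid$d], hydrogen = hyd,
                acceptor = acceptors[grid$a], distance = dist,
                angle = ang, water_mediated = FALSE,
                bridging_water = NA_character_)[keep, ]
  out[order(out$distance), ]
}

#' Find water-mediated bridges between two partners
#'
#' Reports each water oxygen (labels matching `WAT<k>_O`) lying within
#' `cutoff` of both partners.
#'
#' @param frame Tibble with columns `label`, `x`, `y`, `z`.
#' @param partner_a,partner_b Labels of the bridged partners.
#' @param cutoff Distance cutoff in angstrom (default 3.5).
#' @return Tibble in the [detect_hbonds()] layout with
#'   `water_mediated = TRUE`; `distance` is the longer of the two legs.
#' @export
water_bridges <- function(frame, partner_a, partner_b, cutoff = 3.5) {
  waters <- grep("^WAT\\d*_O$", frame$label, value = TRUE)
  empty <- tibble(donor = character(), hydrogen = character(),
                  acceptor = character(), distance = numeric(),
                  angle = numeric(), water_mediated = logical(),
                  bridging_water = character())
  if (length(waters) == 0) return(empty)
  pa <- frame_positions(frame, partner_a)[1, ]
  pb <- frame_positions(frame, partner_b)[1, ]
  wp <- frame_positions(frame, waters)
  da <- sqrt(rowSums(sweep(wp, 2, pa)^2))
  db <- sqrt(rowSums(sweep(wp, 2, pb)^2))
  keep <- da <= cutoff & db <= cutoff
  if (!any(keep)) return(empty)
  out <- tibble(donor = partner_a, hydrogen = NA_character_,
                acceptor = partner_b,
                distance = pmax(da, db)[keep], angle = NA_real_,
                water_mediated = TRUE, bridging_water = waters[keep])
  out[order(out$distance), ]
}

# ---- photoproduct classification ------------------------------------------

wrapped_distance <- function(x, center) abs(wrap_angle(x - center))

near_planar <- function(x, tol) {
  pmin(wrapped_distance(x, 0), wrapped_distance(x, 180)) <= tol
}

#' Classify the photoproduct state of a relaxed chromophore
#'
#' Operational taxonomy of the relaxation outcomes, evaluated on wrapped
#' final dihedrals and the detected hydrogen bonds of the final frame:
#'
#' * `BV_PR`: D5 and D6 both inside their Pr windows and the D-ring carbonyl
#'   hydrogen-bonded to His278 or Tyr165;
#' * `BV_PR_DPRIME`: D4, D5 and D6 all within the planarity window
#'   (default 20 degrees of 0 or 180);
#' * `BV_PR_PRIME`: D6 in the Pr (Z) window with D5 in the intermediate
#'   region between the Pr and Pfr windows;
#' * `PFR`: anything else.
#'
#' @param final_dihedrals Named numeric vector (or one-row data frame) with
#'   at least `d4`, `d5`, `d6` in degrees.
#' @param hbonds Tibble of hydrogen bonds of the final frame (from
#'   [detect_hbonds()]).
#' @param windows Classification windows; see the package vignette. Defaults
#'   to the package constants shared with the generator.
#' @return A `state_label` list with fields `value` and `evidence`.
#' @export
classify_photoproduct <- function(final_dihedrals, hbonds,
                                  windows = classification_windows()) {
  d <- as.list(final_dihedrals)
  for (need in c("d4", "d5", "d6")) {
    if (is.null(d[[need]]) || is.na(d[[need]])) {
      abort(paste0("missing required dihedral: ", need))
    }
  }
  d4 <- wrap_angle(d$d4); d5 <- wrap_angle(d$d5); d6 <- wrap_angle(d$d6)
  w <- windows
  pr5 <- wrapped_distance(d5, w$d5_pr_center) <= w$d5_half_width
  pfr5 <- wrapped_distance(d5, w$d5_pfr_center) <= w$d5_half_width
  z6 <- abs(d6) < w$d6_z_boundary
  intermediate5 <- !pr5 & !pfr5 &
    wrapped_distance(d5, 180) <= 180 - w$d5_pfr_center - w$d5_half_width
  planar <- near_planar(d4, w$planarity_tol) &&
    near_planar(d5, w$planarity_tol) && near_planar(d6, w$planarity_tol)
  partners <- carbonyl_partners(hbonds)
  carbonyl_bond <- length(partners) > 0
  evidence <- character()
  if (z6) evidence <- c(evidence, "D6 in Pr (Z) window")
  if (pr5) evidence <- c(evidence, "D5 in Pr window")
  if (intermediate5) evidence <- c(evidence, "D5 intermediate")
  if (planar) evidence <- c(evidence, "bridge near-planar")
  if (carbonyl_bond) {
    evidence <- c(evidence, paste0("carbonyl H-bond: ",
                                   paste(partners, collapse = ", ")))
  }
  value <- if (pr5 && z6 && carbonyl_bond) "BV_PR"
    else if (planar) "BV_PR_DPRIME"
    else if (z6 && intermediate5) "BV_PR_PRIME"
    else "PFR"
  structure(list(value = value, evidence = evidence),
            class = "state_label")
}

carbonyl_partners <- function(hbonds) {
  if (is.null(hbonds) || nrow(hbonds) == 0) return(character())
  other <- ifelse(hbonds$donor == "D_ring_O", hbonds$acceptor, hbonds$donor)
  involved <- hbonds$donor == "D_ring_O" | hbonds$acceptor == "D_ring_O"
  partners <- other[involved & !hbonds$water_mediated]
  partners[grepl("^(His278|Tyr165)", partners)]
}

#' @export
print.state_label <- function(x, ...) {
  cat(sprintf("<state_label> %s  [%s]\n", x$value,
              paste(x$evidence, collapse = "; ")))
  invisible(x)
}

#' Classify a whole trajectory's photoproduct outcome
#'
#' Computes the final-frame dihedrals and the D-ring carbonyl hydrogen bonds
#' to His278/Tyr165, then applies [classify_photoproduct()].
#'
#' @param traj A `bilin_trajectory`.
#' @inheritParams classify_photoproduct
#' @return A `state_label`.
#' @export
classify_trajectory <- function(traj, windows = classification_windows()) {
  dh <- compute_dihedrals(traj)
  last <- dh[nrow(dh), ]
  fr <- final_frame(traj)
  hb <- detect_hbonds(fr, donors = c("His278_NE2", "Tyr165_OH"),
                      acceptors = "D_ring_O")
  classify_photoproduct(last, hb, windows = windows)
}

#' Classify every trajectory of a relaxation ensemble
#'
#' @param trajectories List of `bilin_trajectory` objects.
#' @inheritParams classify_photoproduct
#' @return Tibble with columns `trajectory_id`, `label`, `evidence`.
#' @export
classify_ensemble <- function(trajectories,
                              windows = classification_windows()) {
  rows <- lapply(trajectories, function(tr) {
    sl <- classify_trajectory(tr, windows = windows)
    tibble(trajectory_id = attr(tr, "id"), label = sl$value,
           evidence = paste(sl$evidence, collapse = "; "))
  })
  bind_rows(rows)
}

# ---- Meta-F signature ------------------------------------------------------

#' Meta-F pocket signature of a frame
#'
#' Three criteria distinguish the late (Meta-F-like) pocket arrangement from
#' the early Lumi-F one: (i) the D-ring carbonyl hydrogen-bonds His278,
#' (ii) Gln190 has moved away from its chromophore-proximal reference
#' position by more than `gln_displacement`, and (iii) the Trp440 gate is
#' open, i.e. Trp440 sits farther than `trp_gate` from Gln190 (when Trp440
#' packs against Gln190 it blocks the displacement). The signature is `TRUE`
#' only when all three hold; `score` is the satisfied fraction.
#'
#' @param frame Tibble with columns `label`, `x`, `y`, `z`.
#' @param gln_reference Length-3 reference position of `Gln190_NE2` (its
#'   position in the Pfr starting frame of the same trajectory).
#' @param thresholds List with `hbond` (angstrom, default 3.5),
#'   `gln_displacement` (default 4), `trp_gate` (default 6).
#' @return List with `meta_f` (logical), `score` (0..1), and the per-criterion
#'   logical vector `criteria`.
#' @export
metaF_signature <- function(frame, gln_reference,
                            thresholds = list(hbond = 3.5,
                                              gln_displacement = 4,
                                              trp_gate = 6)) {
  o <- frame_positions(frame, "D_ring_O")[1, ]
  his <- frame_positions(frame, "His278_NE2")[1, ]
  gln <- frame_positions(frame, "Gln190_NE2")[1, ]
  trp <- frame_positions(frame, "Trp440_CZ2")[1, ]
  crit <- c(
    his_carbonyl_hbond = sqrt(sum((o - his)^2)) <=
      (thresholds$hbond %||% 3.5),
    gln_displaced = sqrt(sum((gln - gln_reference)^2)) >
      (thresholds$gln_displacement %||% 4),
    trp_gate_open = sqrt(sum((trp - gln)^2)) >
      (thresholds$trp_gate %||% 6))
  list(meta_f = all(crit), score = mean(crit), criteria = crit)
}

# ---- spine tilt ------------------------------------------------------------

helix_axis <- function(ca) {
  if (nrow(ca) < 4) abort("need at least 4 C-alpha atoms per helix")
  centered <- sweep(ca, 2, colMeans(ca))
  ax <- prcomp(centered)$rotation[, 1]
  ax / sqrt(sum(ax^2))
}

#' Tilt angle between two helix axes
#'
#' Each axis is the principal axis of the helix's C-alpha point cloud; the
#' tilt is the angle between the axes folded to `[0, 90]` degrees, so it is
#' symmetric in its arguments and invariant under rigid motion of the
#' complex.
#'
#' @param helix_a,helix_b Matrices of C-alpha positions (rows are residues),
#'   at least 4 each.
#' @return Tilt angle in degrees in `[0, 90]`.
#' @export
spine_tilt <- function(helix_a, helix_b) {
  a <- helix_axis(as.matrix(helix_a))
  b <- helix_axis(as.matrix(helix_b))
  acos(pmin(abs(sum(a * b)), 1)) * 180 / pi
}

#' Spine tilt from a labelled frame
#'
#' @param frame Tibble with columns `label`, `x`, `y`, `z`.
#' @param pattern_a,pattern_b Regular expressions selecting the C-alpha
#'   labels of the two helices.
#' @return Tilt angle in degrees.
#' @export
spine_tilt_frame <- function(frame, pattern_a = "^A_CA", pattern_b = "^B_CA") {
  sel <- function(p) {
    as.matrix(frame[grepl(p, frame$label), c("x", "y", "z")])
  }
  spine_tilt(sel(pattern_a), sel(pattern_b))
}
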