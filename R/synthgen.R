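# Synthetic ensemble generators. These replace the surface-hopping and
# ground-state MD engines with constructions that carry the same statistical
# structure the downstream analyses assume: a biexponential hop-time mixture
# with an explicit long-lived censored subpopulation, hula-twist D5/D6
# kinematics for reactive trajectories, a three-way photoproduct relaxation
# partition with His278/Tyr165 hydrogen-bond partners, Gaussian pocket
# clusters, and ideal helix pairs at controlled tilt.

run_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- configs ---------------------------------------------------------------

#' Configuration for a synthetic surface-hopping ensemble
#'
#' The hop-time law is the mixture
#' `amp_fast * Exp(tau_fast) + amp_slow * Exp(tau_slow)` with
#' `amp_slow = 1 - amp_fast - long_lived_fraction`, plus a `long_lived_fraction`
#' of trajectories that are still excited at `censor_time` and enter the
#' records as censored. Hopped trajectories are reactive (photoproduct-forming)
#' with probability `reaction_probability`, counted against the full ensemble.
#'
#' @param n_traj Number of trajectories.
#' @param reaction_probability Fraction of the whole ensemble that is
#'   reactive, in `[0, 1]`.
#' @param tau_fast,tau_slow Component lifetimes in ps (`tau_fast < tau_slow`).
#' @param amp_fast Fast-component fraction of the whole ensemble.
#' @param long_lived_fraction Fraction censored at `censor_time`.
#' @param censor_time Censoring horizon in ps.
#' @param dt Frame spacing in ps for generated geometry.
#' @param seed Integer seed.
#' @param composition `"fixed"` realizes the configured fractions as exact
#'   counts (a quota ensemble, the natural emulation of a reported realized
#'   ensemble); `"binomial"` draws each trajectory's component and
#'   reactivity independently.
#' @param noise_deg Gaussian jitter (sd, degrees) added to dihedral channels.
#' @return An `sh_ensemble_config` list.
#' @export
sh_ensemble_config <- function(n_traj, reaction_probability, tau_fast,
                               tau_slow, amp_fast, long_lived_fraction,
                               censor_time, dt = 0.1, seed = 1,
                               composition = c("fixed", "binomial"),
                               noise_deg = 1.5) {
  composition <- match.arg(composition)
  if (tau_fast >= tau_slow) abort("tau_fast must be < tau_slow")
  if (reaction_probability < 0 || reaction_probability > 1) {
    abort("reaction_probability must lie in [0, 1]")
  }
  if (amp_fast < 0 || long_lived_fraction < 0 ||
      amp_fast + long_lived_fraction > 1) {
    abort("amp_fast + long_lived_fraction must lie in [0, 1]")
  }
  if (reaction_probability > 1 - long_lived_fraction + 1e-12) {
    abort("reaction_probability cannot exceed the hopped fraction")
  }
  if (censor_time <= 0 || dt <= 0) abort("censor_time and dt must be > 0")
  structure(list(
    n_traj = as.integer(n_traj),
    reaction_probability = reaction_probability,
    tau_fast = tau_fast, tau_slow = tau_slow, amp_fast = amp_fast,
    amp_slow = 1 - amp_fast - long_lived_fraction,
    long_lived_fraction = long_lived_fraction,
    censor_time = censor_time, dt = dt, seed = as.integer(seed),
    composition = composition, noise_deg = noise_deg),
    class = "sh_ensemble_config")
}

#' Configuration for a synthetic photoproduct relaxation ensemble
#'
#' Partitions `n_traj` ground-state relaxation trajectories into the three
#' photoproduct populations: `n_pr` reach the Pr D5 window and hydrogen-bond
#' the D-ring carbonyl to His278 or Tyr165 (split by `hbond_partner_split`),
#' `n_pr_prime` stop in the intermediate D5 region between the Pr and Pfr
#' windows, and `n_pr_dprime` reach a near-planar bridge geometry.
#'
#' @param n_traj Ensemble size; must equal `n_pr + n_pr_prime + n_pr_dprime`.
#' @param n_pr,n_pr_prime,n_pr_dprime Population counts.
#' @param hbond_partner_split Fraction of the Pr population using His278 (the
#'   rest use Tyr165).
#' @param dt Frame spacing in ps.
#' @param seed Integer seed.
#' @return A `relaxation_ensemble_config` list.
#' @export
relaxation_ensemble_config <- function(n_traj, n_pr, n_pr_prime, n_pr_dprime,
                                       hbond_partner_split = 0.5, dt = 0.5,
                                       seed = 1) {
  if (n_pr + n_pr_prime + n_pr_dprime != n_traj) {
    abort("n_pr + n_pr_prime + n_pr_dprime must equal n_traj")
  }
  structure(list(n_traj = as.integer(n_traj), n_pr = as.integer(n_pr),
                 n_pr_prime = as.integer(n_pr_prime),
                 n_pr_dprime = as.integer(n_pr_dprime),
                 hbond_partner_split = hbond_partner_split,
                 dt = dt, seed = as.integer(seed)),
            class = "relaxation_ensemble_config")
}

default_pocket_pairs <- function() {
  c("D_ring_N-Asp196_OD1", "D_ring_N-Gln190_NE2", "D_ring_N-His278_NE2",
    "D_ring_N-WAT1_O", "D_ring_O-Gln190_NE2", "D_ring_O-His278_NE2",
    "D_ring_O-Tyr165_OH", "D_ring_O-WAT1_O")
}

default_pocket_centers <- function() {
  m <- rbind(
    c(2.9, 3.2, 3.0, 3.1, 4.8, 3.0, 2.8, 3.3),
    c(2.9, 3.0, 5.8, 3.2, 3.0, 4.9, 5.5, 3.4),
    c(4.6, 5.0, 3.2, 5.6, 3.1, 3.2, 3.0, 5.2))
  colnames(m) <- default_pocket_pairs()
  m
}

#' Configuration for synthetic binding-pocket distance frames
#'
#' Gaussian blobs in D-ring distance-feature space, one blob per pocket
#' arrangement. Centers must be pairwise separated by more than
#' `3 * cluster_spread` so the generative labels are recoverable.
#'
#' @param n_frames Number of frames (feature rows).
#' @param n_clusters Number of pocket clusters (default 3).
#' @param cluster_centers Numeric matrix, one row per cluster, one column per
#'   distance pair (angstrom); default a three-arrangement pocket preset.
#' @param cluster_spread Per-coordinate Gaussian sd in angstrom.
#' @param seed Integer seed.
#' @return A `pocket_ensemble_config` list.
#' @export
pocket_ensemble_config <- function(n_frames = 300, n_clusters = 3,
                                   cluster_centers = NULL,
                                   cluster_spread = 0.2, seed = 1) {
  if (is.null(cluster_centers)) {
    cluster_centers <- default_pocket_centers()[seq_len(n_clusters), ,
                                                drop = FALSE]
  }
  cluster_centers <- as.matrix(cluster_centers)
  if (nrow(cluster_centers) != n_clusters) {
    abort("cluster_centers must have one row per cluster")
  }
  if (n_clusters > 1) {
    d <- as.matrix(dist(cluster_centers))
    if (min(d[upper.tri(d)]) <= 3 * cluster_spread) {
      abort("cluster centers must be pairwise separated by > 3 * spread")
    }
  }
  if (any(cluster_centers <= 0)) abort("distance centers must be positive")
  structure(list(n_frames = as.integer(n_frames),
                 n_clusters = as.integer(n_clusters),
                 cluster_centers = cluster_centers,
                 cluster_spread = cluster_spread, seed = as.integer(seed)),
            class = "pocket_ensemble_config")
}

#' Named generator presets
#'
#' * `"agp2-sh"`: surface-hopping ensemble of 3028 trajectories, censoring
#'   horizon 20 ps with a 61/3028 long-lived censored subpopulation,
#'   biexponential hop-time lifetimes 0.71 and 4.25 ps, and a 28% reactive
#'   fraction, the reported statistics of the Agp2 nonadiabatic ensemble.
#' * `"lumi-f-63"`: 63 relaxation trajectories partitioned 20 / 41 / 2 into
#'   BV-Pr / BV-Pr' / BV-Pr'' (seed 42).
#' * `"pocket-3"`: 300 frames around three pocket-arrangement centers.
#'
#' @param name Preset name.
#' @param seed Optional seed override.
#' @return The corresponding config object.
#' @export
preset_config <- function(name = c("agp2-sh", "lumi-f-63", "pocket-3"),
                          seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "agp2-sh" = sh_ensemble_config(
      n_traj = 3028, reaction_probability = 0.28,
      tau_fast = 0.71, tau_slow = 4.25, amp_fast = 0.60,
      long_lived_fraction = 61 / 3028, censor_time = 20,
      dt = 0.1, seed = 1, composition = "fixed"),
    "lumi-f-63" = relaxation_ensemble_config(
      n_traj = 63, n_pr = 20, n_pr_prime = 41, n_pr_dprime = 2,
      hbond_partner_split = 0.5, dt = 0.5, seed = 42),
    "pocket-3" = pocket_ensemble_config(
      n_frames = 300, n_clusters = 3, cluster_spread = 0.2, seed = 1))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

# ---- geometry construction -------------------------------------------------

unit_rows <- function(m) m / sqrt(rowSums(m * m))

# Vectorized internal-to-Cartesian (NeRF) step: place, for each row, the
# fourth atom at bond length `bond`, bond angle `angle` (deg) and dihedral
# `dihedral` (deg) relative to atoms p1-p2-p3.
place_next <- function(p1, p2, p3, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit_rows(p3 - p2)
  n <- unit_rows(cross3(p2 - p1, bc))
  m <- cross3(n, bc)
  d <- cbind(-bond * cos(ang), bond * sin(ang) * cos(dih),
             bond * sin(ang) * sin(dih))
  p3 + d[, 1] * bc + d[, 2] * m + d[, 3] * n
}

# Build one trajectory's atoms from per-frame dihedrals and pocket-probe
# distance specifications. Each `pocket` entry is a scalar or an n-frame
# vector of distances in angstrom.
build_bridge_frames <- function(times, states, d4, d5, d6,
                                pocket = list(), aux = NULL, id = "traj",
                                dt = NULL) {
  n <- length(times)
  rep_row <- function(v) matrix(rep(v, each = n), nrow = n)
  p <- list(
    his = pocket$his_dist %||% 6.0, tyr = pocket$tyr_dist %||% 6.0,
    asp = pocket$asp_dist %||% 3.0, gln = pocket$gln_dist %||% 3.2,
    trp = pocket$trp_gln_dist %||% 4.0,
    wat1 = pocket$wat1_dist %||% 8.0, wat2 = pocket$wat2_dist %||% 8.0)
  p <- lapply(p, function(v) rep_len(v, n))

  a1 <- rep_row(c(0, 0, 0))
  a2 <- rep_row(c(1.5, 0, 0))
  a3 <- rep_row(c(1.5 + 1.5 * cos(pi / 3), 1.5 * sin(pi / 3), 0))
  a4 <- place_next(a1, a2, a3, 1.5, 120, d4)
  a5 <- place_next(a2, a3, a4, 1.5, 120, d5)
  a6 <- place_next(a3, a4, a5, 1.5, 120, d6)          # D_ring_N
  oD <- place_next(a4, a5, a6, 2.3, 120, 180)         # D_ring_O (carbonyl)

  u1 <- unit_rows(oD - a5)
  un <- unit_rows(a6 - a5)
  u2 <- unit_rows(cross3(u1, un))
  u3 <- cross3(u1, u2)
  dir_his <- unit_rows(0.8 * u1 + 0.6 * u2)
  dir_tyr <- unit_rows(0.8 * u1 - 0.6 * u2)
  dir_gln <- unit_rows(0.6 * u1 + 0.8 * u3)
  dir_wat1 <- unit_rows(cos(50 * pi / 180) * dir_his +
                          sin(50 * pi / 180) * u3)
  dir_wat2 <- unit_rows(u3 - u2)
  his <- oD + p$his * dir_his
  tyr <- oD + p$tyr * dir_tyr
  gln <- oD + p$gln * dir_gln
  trp <- gln + p$trp * u3
  asp <- a6 + p$asp * unit_rows(a6 - a4)
  w1 <- oD + p$wat1 * dir_wat1
  w2 <- oD + p$wat2 * dir_wat2

  labels <- c("C12", "C13", "C14", "C15", "C16", "D_ring_N", "D_ring_O",
              "His278_NE2", "Tyr165_OH", "Gln190_NE2", "Trp440_CZ2",
              "Asp196_OD1", "WAT1_O", "WAT2_O")
  coords <- list(a1, a2, a3, a4, a5, a6, oD, his, tyr, gln, trp, asp, w1, w2)
  at <- tibble(
    frame = rep(seq_len(n), times = length(labels)),
    time_ps = rep(times, times = length(labels)),
    state = rep(states, times = length(labels)),
    label = rep(labels, each = n),
    x = unlist(lapply(coords, function(m) m[, 1])),
    y = unlist(lapply(coords, function(m) m[, 2])),
    z = unlist(lapply(coords, function(m) m[, 3])))
  new_trajectory(at, id = id, dt = dt, aux = aux)
}

# ---- surface-hopping ensemble ---------------------------------------------

# Exponential draw conditioned on t < cap (inverse CDF).
rexp_truncated <- function(n, tau, cap) {
  -tau * log(1 - runif(n) * (1 - exp(-cap / tau)))
}

#' Generate a synthetic surface-hopping ensemble
#'
#' Hop times are drawn from the configured biexponential mixture conditioned
#' on the censoring horizon; the long-lived subpopulation is censored at
#' `censor_time`. Reactive trajectories perform the hula twist: D6 rotates
#' counterclockwise from the Pfr E region (180 degrees) through the Z/E
#' boundary to 0, while D5 concomitantly rotates clockwise by about 60
#' degrees; non-reactive trajectories make a sub-threshold D6 excursion and
#' return to the E region. Deterministic given the config seed.
#'
#' @param config An [sh_ensemble_config()].
#' @param geometry If `FALSE`, skip building atomic trajectories and return
#'   hop records only (much faster for kinetics-only work).
#' @return List with elements `trajectories` (list of `bilin_trajectory`, or
#'   `NULL`), `hops` (hop-record tibble), and `bookkeeping` (per-trajectory
#'   truth: component, injected D6 crossing time).
#' @export
generate_sh_ensemble <- function(config, geometry = TRUE) {
  stopifnot(inherits(config, "sh_ensemble_config"))
  run_with_seed(config$seed, {
    n <- config$n_traj
    comp <- draw_components(config)
    th <- rep(NA_real_, n)
    is_fast <- comp == "fast"
    is_slow <- comp == "slow"
    th[is_fast] <- rexp_truncated(sum(is_fast), config$tau_fast,
                                  config$censor_time)
    th[is_slow] <- rexp_truncated(sum(is_slow), config$tau_slow,
                                  config$censor_time)
    hopped <- which(comp != "long_lived")
    reactive <- rep(FALSE, n)
    n_react_target <- round(config$reaction_probability * n)
    if (config$composition == "fixed") {
      reactive[sample(hopped, min(n_react_target, length(hopped)))] <- TRUE
    } else {
      reactive[hopped] <- runif(length(hopped)) < config$reaction_probability
    }
    ids <- sprintf("t%04d", seq_len(n))
    hops <- tibble(trajectory_id = ids, hop_time_ps = th,
                   censor_time_ps = config$censor_time, reactive = reactive)
    ramp_half <- 0.75
    crossing <- ifelse(reactive,
                       (pmax(0, th - ramp_half) + th + ramp_half) / 2,
                       NA_real_)
    bookkeeping <- tibble(trajectory_id = ids, component = comp,
                          reactive = reactive, hop_time_ps = th,
                          crossing_time_ps = crossing)
    trajectories <- NULL
    if (geometry) {
      trajectories <- lapply(seq_len(n), function(i) {
        make_sh_trajectory(ids[i], comp[i], reactive[i], th[i], config,
                           ramp_half)
      })
      names(trajectories) <- ids
    }
    list(trajectories = trajectories, hops = hops, bookkeeping = bookkeeping)
  })
}

draw_components <- function(config) {
  n <- config$n_traj
  if (config$composition == "fixed") {
    n_cens <- round(config$long_lived_fraction * n)
    n_fast <- round(config$amp_fast * n)
    n_slow <- n - n_cens - n_fast
    if (n_slow < 0) abort("amplitudes inconsistent with n_traj")
    sample(rep(c("fast", "slow", "long_lived"), c(n_fast, n_slow, n_cens)))
  } else {
    sample(c("fast", "slow", "long_lived"), n, replace = TRUE,
           prob = c(config$amp_fast, config$amp_slow,
                    config$long_lived_fraction))
  }
}

make_sh_trajectory <- function(id, component, reactive, th, config,
                               ramp_half = 0.75) {
  dt <- config$dt
  noise <- config$noise_deg
  if (component == "long_lived") {
    t_end <- config$censor_time
  } else {
    t_end <- min(th + ramp_half + 0.5, config$censor_time)
  }
  times <- seq(0, t_end, by = dt)
  if (length(times) < 2) times <- c(0, dt)
  n <- length(times)
  states <- if (component == "long_lived") rep("S1", n) else
    ifelse(times <= th, "S1", "S0")
  d6_0 <- 180
  d5_0 <- 120
  if (component == "long_lived") {
    d6 <- rep(d6_0, n)
    d5 <- rep(d5_0, n)
  } else {
    t0 <- max(0, th - ramp_half)
    t1 <- th + ramp_half
    phase <- pmin(pmax((times - t0) / (t1 - t0), 0), 1)
    if (reactive) {
      d6 <- 90 * (1 + cos(pi * phase))          # 180 -> 0, ccw, crosses 90
      d5 <- d5_0 + 60 * (1 - cos(pi * phase)) / 2   # +60, cw
    } else {
      d6 <- d6_0 - 45 * sin(pi * phase)         # excursion, returns to E
      d5 <- d5_0 + 20 * sin(pi * phase)
    }
  }
  d6 <- d6 + rnorm(n, sd = noise)
  d5 <- d5 + rnorm(n, sd = noise)
  d4 <- 10 + rnorm(n, sd = noise)
  aux <- tibble(frame = seq_len(n),
                d1 = 5 + rnorm(n, sd = noise),
                d2 = 5 + rnorm(n, sd = noise),
                d3 = 5 + rnorm(n, sd = noise))
  build_bridge_frames(times, states, d4, d5, d6,
                      pocket = list(asp_dist = 2.9, gln_dist = 3.2,
                                    wat1_dist = 2.6),
                      aux = aux, id = id, dt = dt)
}

# ---- relaxation ensemble ---------------------------------------------------

# Dihedral windows shared by the generator and the photoproduct classifier.
# D5 synthetic references: Pfr +120, Pr -120 (half-width 25); the hula-twist
# travel runs through the 180-degree intermediate region. Planarity: D4/D5/D6
# all within 20 degrees of 0 or 180.
classification_windows <- function() {
  list(d5_pr_center = -120, d5_pfr_center = 120, d5_half_width = 25,
       d6_z_boundary = 90, planarity_tol = 20)
}

#' Generate a synthetic photoproduct relaxation ensemble
#'
#' Each trajectory starts from a freshly isomerized (Lumi-F-like) bridge
#' geometry (D6 near 0, D5 in the intermediate region) and relaxes to its
#' population's defining window: BV-Pr members complete the D5 rotation into
#' the Pr window and hydrogen-bond the D-ring carbonyl to His278 or Tyr165;
#' BV-Pr' members stop with D5 between the Pr and Pfr windows; BV-Pr''
#' members reach a near-planar bridge. Deterministic given the config seed.
#'
#' @param config A [relaxation_ensemble_config()].
#' @return List with `trajectories` (named list of `bilin_trajectory`) and
#'   `bookkeeping` (tibble of intended population and H-bond partner).
#' @export
generate_relaxation_ensemble <- function(config) {
  stopifnot(inherits(config, "relaxation_ensemble_config"))
  run_with_seed(config$seed, {
    pops <- sample(rep(c("BV_PR", "BV_PR_PRIME", "BV_PR_DPRIME"),
                       c(config$n_pr, config$n_pr_prime,
                         config$n_pr_dprime)))
    n <- config$n_traj
    ids <- sprintf("r%03d", seq_len(n))
    partner <- rep(NA_character_, n)
    is_pr <- pops == "BV_PR"
    partner[is_pr] <- ifelse(runif(sum(is_pr)) < config$hbond_partner_split,
                             "His278", "Tyr165")
    trajectories <- lapply(seq_len(n), function(i) {
      make_relaxation_trajectory(ids[i], pops[i], partner[i], config)
    })
    names(trajectories) <- ids
    list(trajectories = trajectories,
         bookkeeping = tibble(trajectory_id = ids, population = pops,
                              hbond_partner = partner))
  })
}

make_relaxation_trajectory <- function(id, population, partner, config) {
  duration <- 10
  times <- seq(0, duration, by = config$dt)
  n <- length(times)
  ramp <- (1 - cos(pi * times / duration)) / 2    # 0 -> 1, smooth
  jit <- function(half) runif(1, -half, half)
  final <- switch(population,
    BV_PR = list(d4 = 15 + jit(4), d5 = -120 + jit(8), d6 = 5 + jit(4)),
    BV_PR_PRIME = list(d4 = 30 + jit(5), d5 = 180 + jit(12), d6 = 8 + jit(5)),
    BV_PR_DPRIME = list(d4 = 5 + jit(3), d5 = 180 + jit(4), d6 = 0 + jit(3)))
  start <- list(d4 = 28, d5 = 170, d6 = 12)
  # D5 relaxes along the continuing cw rotation: unwrapped target for BV-Pr
  # is +240 (== -120 wrapped).
  d5_target <- if (population == "BV_PR") 360 + final$d5 else final$d5
  d4 <- start$d4 + (final$d4 - start$d4) * ramp
  d5 <- start$d5 + (d5_target - start$d5) * ramp
  d6 <- start$d6 + (final$d6 - start$d6) * ramp
  noise <- 0.8
  d4 <- d4 + c(rnorm(n - 1, sd = noise), 0)
  d5 <- d5 + c(rnorm(n - 1, sd = noise), 0)
  d6 <- d6 + c(rnorm(n - 1, sd = noise), 0)
  his <- if (identical(partner, "His278")) 2.9 else 6.0
  tyr <- if (identical(partner, "Tyr165")) 2.9 else 6.0
  his_t <- 6.0 + (his - 6.0) * ramp
  tyr_t <- 6.0 + (tyr - 6.0) * ramp
  aux <- tibble(frame = seq_len(n),
                d1 = 5 + c(rnorm(n - 1, sd = noise), 0),
                d2 = 5 + c(rnorm(n - 1, sd = noise), 0),
                d3 = 5 + c(rnorm(n - 1, sd = noise), 0))
  build_bridge_frames(times, rep("S0", n), d4, d5, d6,
                      pocket = list(his_dist = his_t, tyr_dist = tyr_t,
                                    asp_dist = 3.0, gln_dist = 3.2,
                                    wat1_dist = 2.6),
                      aux = aux, id = id, dt = config$dt)
}

# ---- pocket frames ---------------------------------------------------------

#' Generate synthetic binding-pocket distance features
#'
#' Gaussian blobs around the configured cluster centers in D-ring
#' distance-feature space.
#'
#' @param config A [pocket_ensemble_config()].
#' @return List with `features` (tibble, one column per distance pair, in
#'   angstrom) and `labels` (integer generative labels in `0 .. k-1`).
#' @export
generate_pocket_frames <- function(config) {
  stopifnot(inherits(config, "pocket_ensemble_config"))
  run_with_seed(config$seed, {
    k <- config$n_clusters
    n <- config$n_frames
    base <- rep(seq_len(k) - 1L, length.out = n)
    labels <- sort(base)
    centers <- config$cluster_centers
    feat <- centers[labels + 1L, , drop = FALSE] +
      matrix(rnorm(n * ncol(centers), sd = config$cluster_spread), nrow = n)
    feat[feat <= 0.5] <- 0.5   # distances stay physical
    colnames(feat) <- colnames(centers) %||%
      paste0("pair", seq_len(ncol(centers)))
    list(features = as_tibble(as.data.frame(feat)), labels = labels)
  })
}

# ---- helix pair ------------------------------------------------------------

#' Generate an ideal two-helix spine at a controlled tilt
#'
#' Builds two ideal alpha-helical C-alpha traces (rise 1.5 angstrom per
#' residue, 100 degrees twist per residue, radius 2.3 angstrom) whose helical
#' axes subtend `tilt_deg`. Small seeded coordinate jitter emulates thermal
#' disorder.
#'
#' @param tilt_deg Angle between the two helix axes in degrees.
#' @param n_res Residues per helix (default 25).
#' @param seed Integer seed for the coordinate jitter.
#' @param jitter_sd Coordinate jitter sd in angstrom (default 0.05).
#' @return List with `frame` (tibble `label`, `x`, `y`, `z`), and matrices
#'   `helix_a`, `helix_b` of C-alpha positions.
#' @export
generate_helix_pair <- function(tilt_deg, n_res = 25, seed = 1,
                                jitter_sd = 0.05) {
  run_with_seed(seed, {
    i <- seq_len(n_res) - 1
    phase <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(phase), 2.3 * sin(phase), 1.5 * i)
    ca <- sweep(ca, 2, colMeans(ca))
    th <- tilt_deg * pi / 180
    rot_y <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0),
                   c(-sin(th), 0, cos(th)))
    helix_a <- ca + matrix(rnorm(length(ca), sd = jitter_sd), ncol = 3)
    helix_b <- ca %*% t(rot_y)
    helix_b <- sweep(helix_b, 2, c(12, 0, 0), "+") +
      matrix(rnorm(length(ca), sd = jitter_sd), ncol = 3)
    frame <- tibble(
      label = c(sprintf("A_CA%d", seq_len(n_res)),
                sprintf("B_CA%d", seq_len(n_res))),
      x = c(helix_a[, 1], helix_b[, 1]),
      y = c(helix_a[, 2], helix_b[, 2]),
      z = c(helix_a[, 3], helix_b[, 3]))
    list(frame = frame, helix_a = helix_a, helix_b = helix_b)
  })
}
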