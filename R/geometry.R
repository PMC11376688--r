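# Signed dihedrals, unwrapping, Z/E-s/a stereochemistry, and isomerization
# event detection for the bilin C--D bridge.

#' Wrap angles to (-180, 180] degrees
#'
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  out <- x - 360 * floor(x / 360 + 0.5)
  out[out == -180] <- 180
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowdot <- function(a, b) rowSums(a * b)

dihedral_matrix <- function(p1, p2, p3, p4, check = TRUE) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (check) {
    tol <- 1e-10
    if (any(rowdot(n1, n1) < tol * rowdot(b1, b1) * rowdot(b2, b2)) ||
        any(rowdot(n2, n2) < tol * rowdot(b2, b2) * rowdot(b3, b3))) {
      abort("degenerate geometry: three consecutive points are collinear")
    }
  }
  b2n <- b2 / sqrt(rowdot(b2, b2))
  x <- rowdot(n1, n2)
  y <- rowdot(cross3(n1, n2), b2n)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Signed torsion angle of four points
#'
#' Returns the dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180], with
#' the IUPAC sign convention: looking from p2 toward p3, a positive angle is
#' a clockwise rotation of the far bond relative to the near bond. The value
#' is invariant under rigid rotation and translation and changes sign under
#' mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors (angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as.numeric(dihedral_matrix(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
}

#' Unwrap a wrapped angle series
#'
#' Adds multiples of 360 degrees so that successive differences are minimal
#' in magnitude; the first value is preserved. Valid when the true per-step
#' change is below 180 degrees (a precondition, not checked).
#'
#' @param raw Wrapped angles in degrees.
#' @return Unwrapped (continuous) angles in degrees.
#' @export
unwrap_angles <- function(raw) {
  if (length(raw) <= 1) return(raw)
  steps <- wrap_angle(diff(raw))
  raw[1] + c(0, cumsum(steps))
}

#' Build an unwrapped dihedral time series
#'
#' @param times Frame times in ps.
#' @param values Wrapped dihedral values in degrees.
#' @param name Dihedral name, `"D1"` to `"D6"`.
#' @param bond_class `"single"` or `"double"`.
#' @return Tibble of class `dihedral_series` with columns `time_ps`,
#'   `value_deg` (unwrapped).
#' @export
dihedral_series <- function(times, values, name = "D6",
                            bond_class = c("double", "single")) {
  bond_class <- match.arg(bond_class)
  if (length(times) != length(values)) {
    abort("times and values must have equal length")
  }
  structure(tibble(time_ps = times, value_deg = unwrap_angles(values)),
            class = c("dihedral_series", class(tibble())),
            name = name, bond_class = bond_class)
}

# Role labels of the C--D methine-bridge atom chain. Consecutive quadruples
# define D4, D5 (C14-C15 single bond) and D6 (C15=C16 double bond).
bridge_chain_labels <- function() {
  c("C12", "C13", "C14", "C15", "C16", "D_ring_N")
}

#' Compute per-frame bilin dihedrals from a trajectory
#'
#' D4--D6 are computed geometrically from the bridge atom chain
#' (`C12 ... C16, D_ring_N`); D1--D3 are taken from the trajectory's scalar
#' `aux` channels when present (`NA` otherwise). Values are wrapped to
#' (-180, 180].
#'
#' @param traj A `bilin_trajectory`.
#' @return Tibble with columns `time_ps`, `state`, `d1` ... `d6` (degrees).
#' @export
compute_dihedrals <- function(traj) {
  chain <- bridge_chain_labels()
  missing_atoms <- setdiff(chain, unique(traj$label))
  if (length(missing_atoms) > 0) {
    abort(paste0("trajectory lacks bridge-chain atoms: ",
                 paste(missing_atoms, collapse = ", ")))
  }
  tracks <- lapply(chain, function(l) atom_track(traj, l))
  d4 <- dihedral_matrix(tracks[[1]], tracks[[2]], tracks[[3]], tracks[[4]])
  d5 <- dihedral_matrix(tracks[[2]], tracks[[3]], tracks[[4]], tracks[[5]])
  d6 <- dihedral_matrix(tracks[[3]], tracks[[4]], tracks[[5]], tracks[[6]])
  ft <- frame_table(traj)
  aux <- attr(traj, "aux")
  if (is.null(aux)) {
    d1 <- d2 <- d3 <- rep(NA_real_, nrow(ft))
  } else {
    aux <- aux[order(aux$frame), ]
    d1 <- wrap_angle(aux$d1); d2 <- wrap_angle(aux$d2); d3 <- wrap_angle(aux$d3)
  }
  tibble(time_ps = ft$time_ps, state = ft$state,
         d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5, d6 = d6)
}

#' Bilin stereochemistry code from six dihedrals
#'
#' Renders the standard six-letter code: one Z/E letter per methine-bridge
#' double bond followed by one s/a (syn/anti) letter per single bond. A
#' double bond is Z when its wrapped dihedral has magnitude below 90 degrees
#' and E otherwise; a single bond is s below 90 degrees and a otherwise
#' (values of exactly 90 tie-break to E and a). The dark-adapted Pfr state of
#' a bathy phytochrome reads ZZEssa, the Pr photoproduct ZZZssa.
#'
#' @param d Numeric vector of six dihedrals D1..D6 in degrees (any wrap).
#' @param double_bonds Indices of the double-bond dihedrals (default D2, D4,
#'   D6; the remaining three are single bonds).
#' @return List with fields `doubles`, `singles`, `rendered`.
#' @export
stereo_code <- function(d, double_bonds = c(2L, 4L, 6L)) {
  if (length(d) != 6) abort("stereo_code expects six dihedral values")
  w <- abs(wrap_angle(d))
  singles_idx <- setdiff(1:6, double_bonds)
  doubles <- ifelse(w[double_bonds] < 90, "Z", "E")
  singles <- ifelse(w[singles_idx] < 90, "s", "a")
  list(doubles = doubles, singles = singles,
       rendered = paste0(paste(doubles, collapse = ""),
                         paste(singles, collapse = "")))
}

#' Net rotation sense of a dihedral series over a window
#'
#' By this package's convention, counterclockwise (ccw) means a negative net
#' change of the signed dihedral (viewed from the C-ring side of the bridge)
#' of at least `threshold` degrees; clockwise (cw) is the positive
#' counterpart; anything smaller is `"none"`.
#'
#' @param series A `dihedral_series` (unwrapped).
#' @param window Length-2 time interval in ps; default the full series.
#' @param threshold Minimum net change in degrees (default 90).
#' @return `"ccw"`, `"cw"`, or `"none"`.
#' @export
rotation_sense <- function(series, window = NULL, threshold = 90) {
  t <- series$time_ps
  v <- series$value_deg
  if (is.null(window)) window <- range(t)
  inside <- t >= window[1] & t <= window[2]
  if (sum(inside) < 2) return("none")
  delta <- v[inside][sum(inside)] - v[inside][1]
  if (delta <= -threshold) "ccw" else if (delta >= threshold) "cw" else "none"
}

#' Detect the photoisomerization event of the C--D bridge
#'
#' Finds the first crossing of the (unwrapped) D6 double-bond dihedral
#' through the +/-90 degree family (90 + 360k or -90 + 360k), the Z/E
#' boundary. The rotation sense of D6 and of the paired single-bond dihedral
#' D5 is measured over a `neighborhood` window around the crossing;
#' `hula_twist` is `TRUE` iff D5 rotates with the opposite sense by at least
#' `partner_threshold` degrees, the concerted anticorrelated motion that
#' isomerizes the bridge without sweeping the D ring through the pocket.
#'
#' @param d5,d6 `dihedral_series` objects on the same time base.
#' @param neighborhood Half-width in ps of the window around the crossing
#'   (default 1 ps).
#' @param partner_threshold Minimum net D5 rotation in degrees (default 30).
#' @return Tibble with zero or one row: `dihedral`, `crossing_time_ps`,
#'   `sense`, `partner_sense`, `hula_twist`.
#' @export
detect_isomerization <- function(d5, d6, neighborhood = 1,
                                 partner_threshold = 30) {
  if (nrow(d5) != nrow(d6) ||
      max(abs(d5$time_ps - d6$time_ps)) > 1e-9) {
    abort("d5 and d6 series are on different time bases")
  }
  v <- d6$value_deg
  t <- d6$time_ps
  crossing <- find_first_crossing(t, v)
  empty <- tibble(dihedral = character(), crossing_time_ps = numeric(),
                  sense = character(), partner_sense = character(),
                  hula_twist = logical())
  if (is.null(crossing)) return(empty)
  tc <- crossing$time
  win <- c(tc - neighborhood, tc + neighborhood)
  sense <- rotation_sense(d6, window = win, threshold = 0 + 1e-9)
  partner_delta <- net_change(d5, win)
  partner_sense <- if (partner_delta > 0) "cw" else
    if (partner_delta < 0) "ccw" else "none"
  hula <- abs(partner_delta) >= partner_threshold &&
    partner_sense != sense && partner_sense != "none" && sense != "none"
  tibble(dihedral = "D6", crossing_time_ps = tc, sense = sense,
         partner_sense = partner_sense, hula_twist = hula)
}

net_change <- function(series, window) {
  t <- series$time_ps
  inside <- t >= window[1] & t <= window[2]
  if (sum(inside) < 2) return(0)
  v <- series$value_deg[inside]
  v[length(v)] - v[1]
}

# First time the unwrapped series crosses any member of {+-90 + 360k},
# linearly interpolated between frames.
find_first_crossing <- function(t, v) {
  family <- function(x) {
    k <- round((x - 90) / 180)
    90 + 180 * k  # nearest member of {...,-270,-90,90,270,...}
  }
  for (i in seq_len(length(v) - 1)) {
    lo <- min(v[i], v[i + 1]); hi <- max(v[i], v[i + 1])
    # candidate boundaries strictly inside the step
    ks <- seq(ceiling((lo - 90) / 180), floor((hi - 90) / 180))
    bounds <- 90 + 180 * ks
    bounds <- bounds[bounds > lo & bounds <= hi | bounds >= lo & bounds < hi]
    bounds <- bounds[abs(wrap_angle(bounds)) == 90]
    if (length(bounds) > 0) {
      b <- if (v[i + 1] >= v[i]) min(bounds) else max(bounds)
      frac <- (b - v[i]) / (v[i + 1] - v[i])
      return(list(time = t[i] + frac * (t[i + 1] - t[i]), value = b))
    }
  }
  NULL
}
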