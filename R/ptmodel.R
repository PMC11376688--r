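# One-dimensional model of the keto <-> enol proton transfer along the
# collective variable q = d(N-H) - d(O-H) (angstrom), with overdamped
# Langevin sampling and an adaptive well-tempered kernel bias for
# free-energy estimation.

KB_KCAL <- 0.0019872041      # kcal/mol/K
ACC_CONV <- 418.4            # kcal/mol -> amu A^2/ps^2

#' Double-well proton-transfer model surface
#'
#' Quartic potential with minima pinned exactly at `x_keto` (energy 0) and
#' `x_enol` (energy `delta_e`) and a barrier of height `barrier` above the
#' keto minimum. The gradient has the factored form
#' `c (x - x_keto)(x - x_barrier)(x - x_enol)`; the barrier position and the
#' overall scale are solved from the two energy constraints, so the per-well
#' stiffnesses are derived quantities reported on the object.
#'
#' @param x_keto,x_enol Minima positions on the collective variable
#'   (angstrom); defaults -0.8 and 0.8.
#' @param delta_e Energy of the enol minimum above the keto minimum,
#'   kcal/mol (>= 0).
#' @param barrier Barrier height above the keto minimum, kcal/mol; must
#'   exceed `delta_e`. Default `delta_e + 5`.
#' @return A `pt_surface` with fields including `x_barrier`,
#'   `stiffness_keto`, `stiffness_enol` (kcal/mol/angstrom^2), and the
#'   gradient polynomial coefficients.
#' @export
pt_surface <- function(x_keto = -0.8, x_enol = 0.8, delta_e = 27,
                       barrier = delta_e + 5) {
  if (x_keto >= x_enol) abort("x_keto must be < x_enol")
  if (delta_e < 0) abort("delta_e must be >= 0 (keto is the reference)")
  if (barrier <= delta_e || barrier <= 0) {
    abort("barrier must exceed max(delta_e, 0)")
  }
  P <- function(x, xb) {
    s1 <- x_keto + xb + x_enol
    s2 <- x_keto * xb + x_keto * x_enol + xb * x_enol
    s3 <- x_keto * xb * x_enol
    x^4 / 4 - s1 * x^3 / 3 + s2 * x^2 / 2 - s3 * x
  }
  if (delta_e == 0) {
    xb <- (x_keto + x_enol) / 2
    cc <- barrier / (P(xb, xb) - P(x_keto, xb))
  } else {
    ratio <- barrier / delta_e
    f <- function(xb) {
      (P(xb, xb) - P(x_keto, xb)) / (P(x_enol, xb) - P(x_keto, xb)) - ratio
    }
    # with the enol uphill, the barrier top lies on the enol side of the
    # midpoint (there the energy ratio runs monotonically from +Inf to 1)
    span <- x_enol - x_keto
    grid <- seq((x_keto + x_enol) / 2 + 1e-4 * span,
                x_enol - 1e-4 * span, length.out = 400)
    vals <- vapply(grid, f, numeric(1))
    sign_change <- which(diff(sign(vals)) != 0)
    if (length(sign_change) == 0) {
      abort("no barrier position satisfies the (delta_e, barrier) pair")
    }
    i <- sign_change[1]
    xb <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
    cc <- delta_e / (P(x_enol, xb) - P(x_keto, xb))
  }
  s1 <- x_keto + xb + x_enol
  s2 <- x_keto * xb + x_keto * x_enol + xb * x_enol
  s3 <- x_keto * xb * x_enol
  structure(list(
    x_keto = x_keto, x_enol = x_enol, x_barrier = xb,
    delta_e = delta_e, barrier = barrier, scale = cc,
    grad_coef = cc * c(-s3, s2, -s1, 1),
    offset = -cc * P(x_keto, xb),
    stiffness_keto = cc * (x_keto - xb) * (x_keto - x_enol),
    stiffness_enol = cc * (x_enol - x_keto) * (x_enol - xb),
    sim_range = c(x_keto - 0.7 * (x_enol - x_keto),
                  x_enol + 0.7 * (x_enol - x_keto))),
    class = "pt_surface")
}

#' Harmonic single-well reference surface
#'
#' @param stiffness Force constant in kcal/mol/angstrom^2.
#' @param center Well position (angstrom).
#' @param half_width Simulation wall distance from the center (default 5).
#' @return A `harmonic_well` usable with [simulate_pt()].
#' @export
harmonic_well <- function(stiffness, center = 0, half_width = 5) {
  structure(list(stiffness = stiffness, center = center,
                 grad_coef = c(-stiffness * center, stiffness, 0, 0),
                 sim_range = center + c(-half_width, half_width)),
            class = "harmonic_well")
}

#' Evaluate the model potential
#'
#' Analytic evaluation; the keto minimum (or well center) is the zero of
#' energy.
#'
#' @param surface A `pt_surface` or `harmonic_well`.
#' @param x Collective-variable values (angstrom).
#' @return Energies in kcal/mol.
#' @export
pt_potential <- function(surface, x) {
  if (inherits(surface, "harmonic_well")) {
    return(0.5 * surface$stiffness * (x - surface$center)^2)
  }
  g <- surface$grad_coef
  g[1] * x + g[2] * x^2 / 2 + g[3] * x^3 / 3 + g[4] * x^4 / 4 +
    surface$offset
}

#' Analytic gradient of the model potential
#'
#' @inheritParams pt_potential
#' @return dU/dx in kcal/mol/angstrom.
#' @export
pt_gradient <- function(surface, x) {
  g <- surface$grad_coef
  g[1] + g[2] * x + g[3] * x^2 + g[4] * x^3
}

# ---- adaptive bias ---------------------------------------------------------

#' Create an empty adaptive kernel bias
#'
#' Gaussian kernels are deposited along the trajectory every `stride` steps
#' with initial height `height` attenuated by the well-tempered factor
#' `exp(-V(x) / ((gamma - 1) kBT))`, so the bias converges toward
#' `(1 - 1/gamma)` times the negated free energy. `gamma = Inf` gives the
#' non-tempered (standard-metadynamics) limit.
#'
#' @param surface Surface whose `sim_range` sets the bias grid.
#' @param gamma Bias factor (> 1, possibly `Inf`); default 10.
#' @param height Initial kernel height, kcal/mol (default 1.2).
#' @param bandwidth Kernel sd in angstrom (default 0.05).
#' @param stride Deposition interval in integrator steps (default 500).
#' @param temperature Kelvin (default 300).
#' @param grid_n Bias grid resolution (default 1200).
#' @return An `opes_bias` object.
#' @export
opes_bias <- function(surface, gamma = 10, height = 1.2, bandwidth = 0.05,
                      stride = 500, temperature = 300, grid_n = 1200) {
  if (gamma <= 1) abort("gamma must exceed 1")
  grid_x <- seq(surface$sim_range[1], surface$sim_range[2],
                length.out = grid_n)
  structure(list(gamma = gamma, height0 = height, bandwidth = bandwidth,
                 stride = as.integer(stride),
                 kBT = KB_KCAL * temperature,
                 grid_x = grid_x, grid_v = numeric(grid_n),
                 kernels = tibble(center = numeric(), height = numeric())),
            class = "opes_bias")
}

#' Deposit one bias kernel
#'
#' Functional single-kernel update used by the sampler (the compiled run
#' performs the same update in place): a Gaussian of bandwidth
#' `bias$bandwidth` is added at `x` with height
#' `height0 * exp(-V(x) / ((gamma - 1) kBT))`.
#'
#' @param bias An `opes_bias`.
#' @param x Deposition position (angstrom).
#' @return The updated `opes_bias`.
#' @export
update_bias <- function(bias, x) {
  v <- bias_potential(bias, x)
  wt_fac <- if (is.infinite(bias$gamma)) 0 else
    1 / ((bias$gamma - 1) * bias$kBT)
  h <- bias$height0 * exp(-v * wt_fac)
  bias$grid_v <- bias$grid_v +
    h * exp(-(bias$grid_x - x)^2 / (2 * bias$bandwidth^2))
  bias$kernels <- bind_rows(bias$kernels, tibble(center = x, height = h))
  bias
}

#' Evaluate the bias potential
#'
#' Exact kernel sum (the sampler's inner loop uses the grid-interpolated
#' equivalent).
#'
#' @param bias An `opes_bias`.
#' @param x Positions (angstrom).
#' @return Bias energies in kcal/mol.
#' @export
bias_potential <- function(bias, x) {
  if (nrow(bias$kernels) == 0) return(rep(0, length(x)))
  vapply(x, function(xi) {
    sum(bias$kernels$height *
          exp(-(bias$kernels$center - xi)^2 / (2 * bias$bandwidth^2)))
  }, numeric(1))
}

# ---- sampling --------------------------------------------------------------

#' Overdamped Langevin sampling of the proton-transfer coordinate
#'
#' Euler-Maruyama integration of `dx = -mu dU/dx dt + sqrt(2 mu kBT dt) xi`
#' with mobility `mu = 1 / (mass * friction)`, on the model surface plus
#' (optionally) an adaptive bias that is deposited on the fly. Walls at the
#' edge of the surface's simulation range are reflective. Deterministic
#' given the seed.
#'
#' @param surface A `pt_surface` or `harmonic_well`.
#' @param n_steps Number of integration steps.
#' @param dt Time step in ps (default 0.001). An error with a suggested
#'   value is raised when `dt` is unstable for the surface's maximal
#'   curvature.
#' @param temperature Kelvin (default 300).
#' @param friction Friction coefficient in 1/ps (default 5).
#' @param mass Effective mass of the collective variable in amu
#'   (default 50).
#' @param x0 Start position; defaults to the keto minimum / well center.
#' @param bias Optional `opes_bias`; it is updated during the run and
#'   returned.
#' @param sample_stride Store every `sample_stride`-th position (default 10).
#' @param seed Integer seed.
#' @return A `pt_run` list: `samples` (tibble `time_ps`, `x`), `bias`
#'   (updated or `NULL`), `x_final`, and the run parameters.
#' @export
simulate_pt <- function(surface, n_steps, dt = 0.001, temperature = 300,
                        friction = 5, mass = 50, x0 = NULL, bias = NULL,
                        sample_stride = 10, seed = 1) {
  mu <- ACC_CONV / (mass * friction)
  kBT <- KB_KCAL * temperature
  grid_chk <- seq(surface$sim_range[1], surface$sim_range[2],
                  length.out = 400)
  g <- surface$grad_coef
  curv <- abs(g[2] + 2 * g[3] * grid_chk + 3 * g[4] * grid_chk^2)
  kmax <- max(curv)
  if (mu * kmax * dt > 1) {
    abort(sprintf(
      "dt = %g ps is unstable for this surface; use dt < %.2g ps",
      dt, 1 / (mu * kmax)))
  }
  if (is.null(x0)) {
    x0 <- if (inherits(surface, "harmonic_well")) surface$center else
      surface$x_keto
  }
  use_bias <- !is.null(bias)
  if (use_bias) {
    wt_fac <- if (is.infinite(bias$gamma)) 0 else
      1 / ((bias$gamma - 1) * bias$kBT)
    grid_min <- bias$grid_x[1]
    grid_dx <- bias$grid_x[2] - bias$grid_x[1]
    grid_v <- bias$grid_v
    dep_stride <- bias$stride
    height0 <- bias$height0
    bw <- bias$bandwidth
  } else {
    wt_fac <- 0; grid_min <- surface$sim_range[1]
    grid_dx <- diff(surface$sim_range) / 10; grid_v <- numeric(11)
    dep_stride <- 1L; height0 <- 0; bw <- 1
  }
  res <- run_with_seed(seed, {
    sim_langevin_cpp(x0, n_steps, dt, mu, kBT, g,
                     as.integer(sample_stride), use_bias, wt_fac, height0,
                     bw, as.integer(dep_stride), grid_min, grid_dx, grid_v,
                     surface$sim_range[1], surface$sim_range[2])
  })
  if (isTRUE(res$diverged)) {
    abort(sprintf(
      "trajectory diverged; reduce dt (current %g ps, try %.2g ps)",
      dt, dt / 10))
  }
  if (use_bias) {
    bias$grid_v <- res$grid_v
    bias$kernels <- bind_rows(
      bias$kernels,
      tibble(center = res$kernel_centers, height = res$kernel_heights))
  }
  samples <- tibble(
    time_ps = seq_along(res$samples) * dt * sample_stride,
    x = res$samples)
  structure(list(samples = samples, bias = if (use_bias) bias else NULL,
                 x_final = res$x_final, dt = dt, n_steps = n_steps,
                 temperature = temperature, surface = surface),
            class = "pt_run")
}

#' Count visits to the enol basin
#'
#' A sample counts as an enol visit when it lies beyond the barrier top on
#' the enol side.
#'
#' @param run A `pt_run`.
#' @return Number of stored samples in the enol basin.
#' @export
enol_visits <- function(run) {
  surface <- run$surface
  if (!inherits(surface, "pt_surface")) abort("run must use a pt_surface")
  sum(run$samples$x > surface$x_barrier)
}

# ---- free-energy estimation ------------------------------------------------

#' Free-energy difference between the enol and keto basins
#'
#' Primary estimate from the converged adaptive bias,
#' `deltaF = -(gamma / (gamma - 1)) * (V(x_enol) - V(x_keto))`, cross-checked
#' (when the run's samples are supplied) by a histogram reweighted with
#' `exp(V(x)/kBT)` and split at the barrier top. Errors when the bias never
#' explored both basins.
#'
#' @param bias A deposited `opes_bias`.
#' @param surface The `pt_surface` the bias was built on.
#' @param temperature Kelvin (default 300).
#' @param samples Optional sample tibble from [simulate_pt()] for the
#'   reweighted cross-check.
#' @return A `pt_free_energy` list: `delta_f` (kcal/mol, enol - keto),
#'   `delta_f_reweighted`, `discrepancy`.
#' @export
free_energy_difference <- function(bias, surface, temperature = 300,
                                   samples = NULL) {
  if (nrow(bias$kernels) == 0) abort("bias has no deposited kernels")
  span <- surface$x_enol - surface$x_keto
  near <- function(x0) any(abs(bias$kernels$center - x0) < 0.15 * span)
  if (!near(surface$x_keto) || !near(surface$x_enol)) {
    abort("not converged: both basins must be visited by the biased run")
  }
  gfac <- if (is.infinite(bias$gamma)) 1 else
    bias$gamma / (bias$gamma - 1)
  v <- bias_potential(bias, c(surface$x_keto, surface$x_enol))
  delta_f <- -gfac * (v[2] - v[1])
  delta_rw <- NA_real_
  if (!is.null(samples)) {
    kBT <- KB_KCAL * temperature
    vx <- bias_potential(bias, samples$x)
    w <- exp((vx - max(vx)) / kBT)
    enol <- samples$x > surface$x_barrier
    if (any(enol) && any(!enol)) {
      delta_rw <- -kBT * log(sum(w[enol]) / sum(w[!enol]))
    }
  }
  structure(list(delta_f = delta_f, delta_f_reweighted = delta_rw,
                 discrepancy = delta_rw - delta_f, gamma = bias$gamma,
                 n_kernels = nrow(bias$kernels)),
            class = "pt_free_energy")
}

#' @export
print.pt_free_energy <- function(x, ...) {
  cat(sprintf(
    "Delta F (enol - keto): %.2f kcal/mol (bias estimate, %d kernels)\n",
    x$delta_f, x$n_kernels))
  if (is.finite(x$delta_f_reweighted)) {
    cat(sprintf("  reweighted: %.2f kcal/mol (discrepancy %.2f)\n",
                x$delta_f_reweighted, x$discrepancy))
  }
  invisible(x)
}

#' Basin free-energy difference by direct quadrature
#'
#' Independent reference: `deltaF = -kBT log(Z_enol / Z_keto)` with basin
#' partition functions integrated on either side of the barrier top.
#'
#' @param surface A `pt_surface`.
#' @param temperature Kelvin (default 300).
#' @return Free-energy difference (enol - keto) in kcal/mol.
#' @export
free_energy_quadrature <- function(surface, temperature = 300) {
  kBT <- KB_KCAL * temperature
  zk <- integrate(function(x) exp(-pt_potential(surface, x) / kBT),
                  surface$sim_range[1], surface$x_barrier,
                  rel.tol = 1e-10)$value
  u_enol <- surface$delta_e
  ze <- integrate(function(x)
    exp(-(pt_potential(surface, x) - u_enol) / kBT),
    surface$x_barrier, surface$sim_range[2], rel.tol = 1e-10)$value
  -kBT * (log(ze) - u_enol / kBT + log(1 / zk))
}
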