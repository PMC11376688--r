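# ggplot2 visualisations for the main result types.

#' @export
autoplot.hop_survival <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ps)", y = "S1 survival",
                  title = "Excited-state survival (Kaplan-Meier)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decay_fit <- function(object, max_time = NULL, ...) {
  if (is.null(max_time)) max_time <- 6 * max(object$lifetimes)
  t <- seq(0, max_time, length.out = 400)
  s <- rowSums(vapply(seq_len(object$k), function(j) {
    object$amplitudes[j] * exp(-t / object$lifetimes[j])
  }, numeric(length(t)))) + object$long_lived
  ggplot2::ggplot(tibble(time_ps = t, survival = s),
                  ggplot2::aes(x = .data$time_ps, y = .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ps)", y = "model survival",
                  title = sprintf("Fitted %d-component decay", object$k)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pocket_clusters <- function(object, ...) {
  df <- tidy(object)
  cols <- names(object$pc_scores)[1:min(2, ncol(object$pc_scores))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[cols[1]]],
                                   y = .data[[cols[min(2, length(cols))]]],
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "cluster",
                  title = "Binding-pocket clusters in PC space") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pt_run <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$time_ps, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (ps)",
                  y = "q = d(N-H) - d(O-H) (Å)",
                  title = "Proton-transfer coordinate trace") +
    ggplot2::theme_minimal()
}

#' Free-energy profile implied by an adaptive bias
#'
#' Plots `F(q) = -(gamma/(gamma-1)) V(q)` (shifted to zero at the keto
#' minimum) together with the model surface.
#'
#' @param bias A deposited `opes_bias`.
#' @param surface The matching `pt_surface`.
#' @return A ggplot object.
#' @export
plot_fes <- function(bias, surface) {
  gfac <- if (is.infinite(bias$gamma)) 1 else bias$gamma / (bias$gamma - 1)
  fes <- -gfac * bias$grid_v
  fes <- fes - fes[which.min(abs(bias$grid_x - surface$x_keto))]
  df <- tibble(q = bias$grid_x, estimate = fes,
               model = pt_potential(surface, bias$grid_x))
  df <- tidyr::pivot_longer(df, c("estimate", "model"),
                            names_to = "curve", values_to = "energy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$energy,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "q = d(N-H) - d(O-H) (Å)",
                  y = "free energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Hula-twist correlation plot of D5 against D6
#'
#' @param dihedrals Per-frame dihedral tibble from [compute_dihedrals()]
#'   (or a row-bound set of them).
#' @return A ggplot object showing the anticorrelated D5/D6 path, coloured
#'   by electronic state.
#' @export
plot_hula_twist <- function(dihedrals) {
  d5 <- unwrap_angles(dihedrals$d5)
  d6 <- unwrap_angles(dihedrals$d6)
  df <- tibble(d5 = d5, d6 = d6, state = dihedrals$state)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d6, y = .data$d5,
                                   colour = .data$state)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::labs(x = "D6 (deg, unwrapped)", y = "D5 (deg, unwrapped)",
                  title = "Hula-twist D5/D6 correlation") +
    ggplot2::theme_minimal()
}
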