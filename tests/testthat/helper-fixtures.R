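# Small in-code fixtures.

# Two-frame trajectory with explicit bridge geometry and aux channels.
tiny_trajectory <- function(d6 = c(180, 170), d5 = c(120, 125),
                            d4 = c(10, 12), states = c("S1", "S1"),
                            dt = 0.5, id = "tiny") {
  n <- length(d6)
  hulatwist:::build_bridge_frames(
    times = seq(0, by = dt, length.out = n), states = rep_len(states, n),
    d4 = d4, d5 = d5, d6 = d6,
    aux = tibble::tibble(frame = seq_len(n), d1 = rep(5, n), d2 = rep(5, n),
                         d3 = rep(5, n)),
    id = id, dt = dt)
}

hop_tibble <- function(hop, censor = 20, reactive = NULL,
                       ids = sprintf("t%03d", seq_along(hop))) {
  if (is.null(reactive)) reactive <- !is.na(hop) & hop < censor / 2
  tibble::tibble(trajectory_id = ids, hop_time_ps = hop,
                 censor_time_ps = censor, reactive = reactive & !is.na(hop))
}

# Frame of labelled points at explicit positions.
point_frame <- function(...) {
  pts <- list(...)
  tibble::tibble(label = names(pts),
                 x = unname(vapply(pts, `[`, 0, 1)),
                 y = unname(vapply(pts, `[`, 0, 2)),
                 z = unname(vapply(pts, `[`, 0, 3)))
}

small_sh_config <- function(n = 40, seed = 5, ...) {
  sh_ensemble_config(n_traj = n, reaction_probability = 0.3,
                     tau_fast = 0.71, tau_slow = 4.25, amp_fast = 0.6,
                     long_lived_fraction = 0.05, censor_time = 20,
                     seed = seed, ...)
}
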