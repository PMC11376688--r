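# End-to-end analysis pipeline over synthetic ensembles: generate ->
# dihedrals/isomerization -> kinetics -> relaxation classification ->
# pocket clustering -> spine tilt -> proton-transfer free energy.

pipeline_stages <- function() {
  c("sh_ensemble", "kinetics", "isomerization", "relaxation", "pocket",
    "spine", "proton_transfer")
}

#' Pipeline configuration
#'
#' @param stages Character vector of stages to run, a subset of
#'   `"sh_ensemble"`, `"kinetics"`, `"isomerization"`, `"relaxation"`,
#'   `"pocket"`, `"spine"`, `"proton_transfer"`. The default runs all of
#'   them over the standard presets.
#' @param seed Global seed propagated to every stochastic stage.
#' @param out_dir Output directory for the report files.
#' @param sh_config,relax_config,pocket_config Optional generator configs;
#'   presets `agp2-sh` / `lumi-f-63` / `pocket-3` by default. The
#'   surface-hopping config seed is set from `seed`.
#' @param tilt_deg Spine-tilt angles to generate and re-measure.
#' @param pt Options for the proton-transfer stage: `delta_e`, `barrier`,
#'   `gamma`, `n_steps`, `dt`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(stages = pipeline_stages(), seed = 1,
                            out_dir = tempfile("hulatwist-report-"),
                            sh_config = NULL, relax_config = NULL,
                            pocket_config = NULL, tilt_deg = c(0, 30),
                            pt = list()) {
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad) > 0) {
    abort(paste0("unknown pipeline stage: ", paste(bad, collapse = ", ")))
  }
  bad_pt <- setdiff(names(pt),
                    c("delta_e", "barrier", "gamma", "n_steps", "dt"))
  if (length(bad_pt) > 0) {
    abort(paste0("unknown proton-transfer option: ",
                 paste(bad_pt, collapse = ", ")))
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("seed must be a single finite number")
  }
  structure(list(stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, sh_config = sh_config,
                 relax_config = relax_config,
                 pocket_config = pocket_config, tilt_deg = tilt_deg,
                 pt = pt),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order and writes a deterministic JSON
#' report (plus a survival-curve CSV when kinetics runs) to
#' `config$out_dir`. Identical config and seed give byte-identical reports.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are preserved in the partial report.
#'
#' @param config A [pipeline_config()].
#' @return The results list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = config$seed,
                  stages = paste(config$stages, collapse = ","))
  state <- new.env(parent = emptyenv())
  state$ens <- NULL
  write_partial <- function() {
    write_report(results, file.path(config$out_dir, "report.json"))
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      write_partial()
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  if ("sh_ensemble" %in% config$stages) {
    run_stage("sh_ensemble", {
      cfg <- config$sh_config %||% preset_config("agp2-sh",
                                                 seed = config$seed)
      need_geom <- "isomerization" %in% config$stages
      state$ens <- generate_sh_ensemble(cfg, geometry = need_geom)
      results$sh_n_traj <- nrow(state$ens$hops)
      results$sh_n_censored <- sum(is.na(state$ens$hops$hop_time_ps))
      results$sh_n_reactive <- sum(state$ens$hops$reactive)
    })
  }
  if ("kinetics" %in% config$stages) {
    run_stage("kinetics", {
      ens <- state$ens
      if (is.null(ens)) abort("kinetics requires the sh_ensemble stage")
      sc <- survival_curve(ens$hops)
      readr::write_csv(as_tibble(sc),
                       file.path(config$out_dir, "survival.csv"))
      fit <- fit_exponential_mixture(ens$hops, k = 2, seed = config$seed)
      cmp <- compare_models(ens$hops, k_max = 3, seed = config$seed)
      qy <- quantum_yield(ens$hops)
      results$tau_fast_ps <- fit$lifetimes[1]
      results$tau_slow_ps <- fit$lifetimes[2]
      results$selected_k <- selected_k(cmp)
      results$quantum_yield <- qy$point
      results$quantum_yield_ci <- c(qy$ci_low, qy$ci_high)
    })
  }
  if ("isomerization" %in% config$stages) {
    run_stage("isomerization", {
      ens <- state$ens
      if (is.null(ens$trajectories)) {
        abort("isomerization requires sh_ensemble geometry")
      }
      reactive_ids <- ens$hops$trajectory_id[ens$hops$reactive]
      ev <- lapply(ens$trajectories[reactive_ids], trajectory_events)
      ev <- bind_rows(ev)
      results$n_isomerization_events <- nrow(ev)
      results$hula_twist_fraction <-
        if (nrow(ev) > 0) mean(ev$hula_twist) else 0
      results$d6_ccw_fraction <-
        if (nrow(ev) > 0) mean(ev$sense == "ccw") else 0
    })
  }
  if ("relaxation" %in% config$stages) {
    run_stage("relaxation", {
      cfg <- config$relax_config %||% preset_config("lumi-f-63")
      rel <- generate_relaxation_ensemble(cfg)
      labels <- classify_ensemble(rel$trajectories)
      counts <- table(factor(labels$label,
                             levels = c("BV_PR", "BV_PR_PRIME",
                                        "BV_PR_DPRIME", "PFR")))
      results$state_counts <- as.list(setNames(as.integer(counts),
                                               names(counts)))
    })
  }
  if ("pocket" %in% config$stages) {
    run_stage("pocket", {
      cfg <- config$pocket_config %||% preset_config("pocket-3",
                                                     seed = config$seed)
      pf <- generate_pocket_frames(cfg)
      cl <- cluster_pocket(pf$features, k = cfg$n_clusters)
      results$pocket_cluster_sizes <- as.integer(table(cl$labels))
      results$pocket_silhouette <- unname(
        cl$silhouette[paste0("k", cfg$n_clusters)])
    })
  }
  if ("spine" %in% config$stages) {
    run_stage("spine", {
      tilts <- vapply(config$tilt_deg, function(th) {
        hp <- generate_helix_pair(th, seed = config$seed)
        spine_tilt(hp$helix_a, hp$helix_b)
      }, numeric(1))
      results$spine_tilt_deg <- as.list(setNames(
        tilts, paste0("generated_", config$tilt_deg)))
    })
  }
  if ("proton_transfer" %in% config$stages) {
    run_stage("proton_transfer", {
      pt <- config$pt
      surface <- pt_surface(delta_e = pt$delta_e %||% 27,
                            barrier = pt$barrier %||% (pt$delta_e %||% 27) + 5)
      bias <- opes_bias(surface, gamma = pt$gamma %||% 20)
      run <- simulate_pt(surface, n_steps = pt$n_steps %||% 4e6,
                         dt = pt$dt %||% 2e-4, bias = bias,
                         sample_stride = 50, seed = config$seed)
      fe <- free_energy_difference(run$bias, surface,
                                   samples = run$samples)
      results$delta_f_kcal_mol <- fe$delta_f
      results$delta_f_quadrature <- free_energy_quadrature(surface)
    })
  }
  write_partial()
  invisible(results)
}

# one-trajectory isomerization-event wrapper used by the pipeline
trajectory_events <- function(traj) {
  dh <- compute_dihedrals(traj)
  d5 <- dihedral_series(dh$time_ps, dh$d5, "D5", "single")
  d6 <- dihedral_series(dh$time_ps, dh$d6, "D6", "double")
  ev <- detect_isomerization(d5, d6)
  if (nrow(ev) > 0) ev$trajectory_id <- attr(traj, "id")
  ev
}
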