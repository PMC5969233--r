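#' Run the full three-experiment virtual-lesion study
#'
#' Generates the structural substrate (synthetic connectome plus damage
#' maps), then runs the white-matter, cortical and thalamic damage schedules
#' with [run_experiment()]. Defaults reproduce the full-scale protocol (78
#' regions, 20 iterations, 50 stochastic realizations per iteration); smaller
#' values give a scaled-down study with the same structure.
#'
#' All randomness (connectome, damage maps, simulation noise) derives from
#' `seed`.
#'
#' @param seed Master integer seed.
#' @param n_regions,edge_density Connectome size and density.
#' @param wm_site_fraction Fraction of edges marked as predilection sites.
#' @param n_iterations,n_realizations Schedule length and stochastic repeats.
#' @param duration,transient Simulated seconds per run (post-transient) and
#'   discarded startup seconds.
#' @param fs_out Output sampling rate, Hz.
#' @param velocity Conduction velocity, m/s.
#' @param params Intact model parameters.
#' @param kinds Which experiments to run.
#' @param verbose Per-cell progress.
#' @return A `ct_study`: `connectome`, `maps`, `params`, and `trajectories`
#'   (a named list of `damage_trajectory` objects).
#' @export
ms_damage_study <- function(seed = 1, n_regions = 78, edge_density = 0.15,
                            wm_site_fraction = 0.5,
                            n_iterations = 20, n_realizations = 50,
                            duration = 16, transient = 2, fs_out = 250,
                            velocity = 10, params = ct_params(),
                            kinds = c("white_matter", "cortical", "thalamic"),
                            verbose = FALSE) {
  seed <- as.integer(seed %% .Machine$integer.max)
  ctm <- generate_connectome(n_regions, edge_density, seed = seed)
  maps <- generate_damage_maps(ctm, wm_site_fraction = wm_site_fraction,
                               seed = seed + 1L)
  trajectories <- lapply(stats::setNames(kinds, kinds), function(kind) {
    run_experiment(
      damage_schedule(kind, maps, n_iterations = n_iterations),
      params, ctm,
      n_realizations = n_realizations, base_seed = seed,
      duration = duration, transient = transient, fs_out = fs_out,
      velocity = velocity, verbose = verbose
    )
  })
  structure(
    list(connectome = ctm, maps = maps, params = params,
         trajectories = trajectories, seed = seed),
    class = "ct_study"
  )
}

#' @export
print.ct_study <- function(x, ...) {
  cat(sprintf(
    "<ct_study> %d regions, experiments: %s (seed %d)\n",
    x$connectome$n_regions, paste(names(x$trajectories), collapse = ", "), x$seed
  ))
  invisible(x)
}

#' First damage fraction at which a measure departs its baseline
#'
#' The departure point is the smallest schedule fraction whose
#' across-realization mean differs from the baseline (first-iteration) mean
#' by more than `k` baseline standard deviations; `Inf` when the curve never
#' departs.
#'
#' @param traj A `damage_trajectory`.
#' @param measure Outcome column name.
#' @param k Departure threshold in baseline SDs.
#' @return A fraction in `[0, 1]`, or `Inf`.
#' @export
departure_fraction <- function(traj, measure = "diameter", k = 2) {
  agg <- traj$aggregates
  mu <- agg[[paste0(measure, "_mean")]]
  base_sd <- agg[[paste0(measure, "_sd")]][1]
  dep <- which(abs(mu - mu[1]) > k * base_sd)
  dep <- dep[dep > 1]
  if (length(dep) == 0) Inf else agg$fraction[min(dep)]
}
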