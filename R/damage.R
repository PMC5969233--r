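#' Virtual lesion operators
#'
#' Three kinds of graded structural damage, each applied as a fractional
#' reduction from the intact baseline (never compounded multiplicatively
#' across iterations, so the final step hits the stated maximum exactly):
#' * white matter: between-unit connection weights at predilection-site
#'   edges scaled by `1 - fraction`, up to 14%;
#' * cortical: within-cortical-unit densities (`ee`, `ei`, `ie`, `ii`)
#'   scaled region-wise by the atrophy map, emulating neuronal/synaptic loss;
#' * thalamic: within-thalamic-unit densities (`sr`, `rs`) scaled globally,
#'   up to the 11% volumetric reduction.
#'
#' @name damage
#' @keywords internal
NULL

#' Apply white-matter damage to a connectome
#'
#' Scales the adjacency weights on masked (predilection-site) edges by
#' `1 - fraction`; unmasked edges are untouched and symmetry is preserved.
#'
#' @param c The intact baseline `connectome`.
#' @param maps A `damage_maps` object.
#' @param fraction Fractional reduction in `[0, maps$wm_max_fraction]`.
#' @return A damaged `connectome`.
#' @export
apply_wm_damage <- function(c, maps, fraction) {
  if (fraction < 0 || fraction > maps$wm_max_fraction + 1e-12) {
    stop(sprintf(
      "fraction %g outside [0, %g]", fraction, maps$wm_max_fraction
    ))
  }
  out <- c
  out$adjacency[maps$wm_mask] <- out$adjacency[maps$wm_mask] * (1 - fraction)
  out
}

#' Apply cortical grey-matter damage to the parameter set
#'
#' Region j's within-cortical-unit synaptic densities are scaled by
#' `1 - step_fraction_of_max * cortical_map[j]`, turning the parameter set
#' region-wise. Thalamic and corticothalamic densities are untouched.
#'
#' @param p A `ct_params`.
#' @param maps A `damage_maps`.
#' @param step_fraction_of_max Position along the linear schedule, in [0, 1].
#' @param within_cortical Names of the densities treated as within-unit
#'   cortical connections.
#' @return A `ct_params` with a `nu_regional` matrix.
#' @export
apply_cortical_damage <- function(p, maps, step_fraction_of_max,
                                  within_cortical = c("ee", "ei", "ie", "ii")) {
  stopifnot(step_fraction_of_max >= 0, step_fraction_of_max <= 1)
  n <- length(maps$cortical_map)
  nu <- params_matrix(p, n)
  scale <- 1 - step_fraction_of_max * maps$cortical_map
  nu[, within_cortical] <- nu[, within_cortical] * scale
  out <- p
  out$nu_regional <- nu
  out
}

#' Apply thalamic grey-matter damage to the parameter set
#'
#' Within-thalamic-unit densities are scaled uniformly by
#' `1 - step_fraction_of_max * max_fraction` (default maximum 11%, the
#' relative thalamic volume reduction in longstanding MS).
#'
#' @param p A `ct_params`.
#' @param step_fraction_of_max Position along the linear schedule, in [0, 1].
#' @param max_fraction Maximal fractional reduction.
#' @param n Number of regions (needed to expand region-wise parameters).
#' @param within_thalamic Names of the densities treated as within-unit
#'   thalamic connections.
#' @return A `ct_params` with a `nu_regional` matrix.
#' @export
apply_thalamic_damage <- function(p, step_fraction_of_max,
                                  max_fraction = 1 - 18.50 / 20.78, n = 78,
                                  within_thalamic = c("sr", "rs")) {
  stopifnot(
    step_fraction_of_max >= 0, step_fraction_of_max <= 1,
    max_fraction >= 0, max_fraction <= 1
  )
  nu <- params_matrix(p, n)
  nu[, within_thalamic] <- nu[, within_thalamic] * (1 - step_fraction_of_max * max_fraction)
  out <- p
  out$nu_regional <- nu
  out
}

#' Define a linear damage schedule
#'
#' A schedule of `n_iterations` damage states whose fractional position runs
#' linearly from 0 (intact baseline, first iteration) to 1 (the configured
#' maximum, last iteration).
#'
#' @param kind One of `"white_matter"`, `"cortical"`, `"thalamic"`.
#' @param maps A `damage_maps`.
#' @param n_iterations Number of schedule points (>= 2 to include both
#'   baseline and maximum).
#' @return A `damage_schedule`: `kind`, `n_iterations`, `profile` (fractions
#'   of maximum per iteration), `maps`.
#' @export
damage_schedule <- function(kind = c("white_matter", "cortical", "thalamic"),
                            maps, n_iterations = 20) {
  kind <- match.arg(kind)
  stopifnot(n_iterations >= 1)
  profile <- if (n_iterations == 1) 0 else seq(0, 1, length.out = n_iterations)
  structure(
    list(kind = kind, n_iterations = n_iterations, profile = profile, maps = maps),
    class = "damage_schedule"
  )
}

# Damage state (connectome, params) at one schedule position.
damage_state <- function(schedule, step, p, c) {
  switch(schedule$kind,
    white_matter = list(
      params = p,
      connectome = apply_wm_damage(c, schedule$maps, step * schedule$maps$wm_max_fraction)
    ),
    cortical = list(
      params = apply_cortical_damage(p, schedule$maps, step),
      connectome = c
    ),
    thalamic = list(
      params = apply_thalamic_damage(
        p, step,
        max_fraction = schedule$maps$thalamic_max_fraction, n = c$n_regions
      ),
      connectome = c
    )
  )
}
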