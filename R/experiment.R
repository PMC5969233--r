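#' Run a virtual-lesion experiment
#'
#' For every schedule iteration and stochastic realization: apply the damage
#' state, simulate network activity, band-pass to the alpha band, and compute
#' the four outcome measures (mean activity, mean PLV, MST diameter, MST leaf
#' fraction). Realizations are repeated with independent noise (seeds derived
#' deterministically from `base_seed`), and per-iteration mean and standard
#' deviation across realizations are aggregated, mirroring the
#' repeat-and-average protocol used for the damage curves.
#'
#' A simulation blow-up in one cell is recorded (`ok = FALSE`, outcome NAs)
#' and the experiment continues.
#'
#' @param schedule A `damage_schedule`.
#' @param base_params Intact `ct_params`.
#' @param connectome Intact `connectome`.
#' @param n_realizations Realizations per iteration (the full-scale protocol
#'   uses 50).
#' @param base_seed Integer seed from which every cell's seed is derived.
#' @param duration Post-transient simulated time per run, s.
#' @param transient Discarded startup time, s.
#' @param fs_out Output sampling rate, Hz.
#' @param velocity Conduction velocity for the delay matrix, m/s.
#' @param band Analysis band, Hz.
#' @param verbose Print per-cell progress with timing.
#' @return A `damage_trajectory`: `cells` (one row per iteration x
#'   realization with the four measures), `aggregates` (per-iteration mean
#'   and sd), `schedule`, `base_seed`.
#' @export
run_experiment <- function(schedule, base_params, connectome,
                           n_realizations = 50, base_seed = 1,
                           duration = 16, transient = 2, fs_out = 500,
                           velocity = 10, band = c(8, 13), verbose = FALSE) {
  stopifnot(n_realizations >= 1)
  cells <- vector("list", schedule$n_iterations * n_realizations)
  k <- 0L
  for (i in seq_len(schedule$n_iterations)) {
    step <- schedule$profile[i]
    state <- damage_state(schedule, step, base_params, connectome)
    tau <- delay_matrix(state$connectome, velocity)
    init <- steady_state(state$params, state$connectome)
    for (r in seq_len(n_realizations)) {
      seed <- cell_seed(base_seed, i, r)
      t0 <- proc.time()[["elapsed"]]
      row <- tryCatch(
        {
          sim <- euler_maruyama_run(
            state$params, state$connectome,
            tau = tau, duration = duration, transient = transient,
            seed = seed, fs_out = fs_out, init = init
          )
          xf <- bandpass_alpha(sim$phi, sim$fs, band)
          fn <- plv_matrix(xf)
          tree <- mst_summary(fn)
          data.frame(
            iteration = i, realization = r, fraction = step, seed = seed,
            mean_activity = fn$mean_activity, mean_plv = fn$mean_plv,
            diameter = tree$diameter, leaf_fraction = tree$leaf_fraction,
            ok = TRUE
          )
        },
        error = function(e) {
          warning(sprintf(
            "cell (iteration %d, realization %d) failed: %s",
            i, r, conditionMessage(e)
          ), call. = FALSE)
          data.frame(
            iteration = i, realization = r, fraction = step, seed = seed,
            mean_activity = NA_real_, mean_plv = NA_real_,
            diameter = NA_integer_, leaf_fraction = NA_real_, ok = FALSE
          )
        }
      )
      if (verbose) {
        message(sprintf(
          "[%s] iteration %d/%d realization %d/%d (%.1f s)",
          schedule$kind, i, schedule$n_iterations, r, n_realizations,
          proc.time()[["elapsed"]] - t0
        ))
      }
      k <- k + 1L
      cells[[k]] <- row
    }
  }
  cells <- do.call(rbind, cells)
  structure(
    list(
      cells = cells,
      aggregates = aggregate_cells(cells),
      schedule = schedule,
      base_seed = base_seed
    ),
    class = "damage_trajectory"
  )
}

# Per-cell seed: a small multiplicative hash of (base_seed, iteration,
# realization), kept below 2^31 so it is a valid R integer seed. Every cell
# is independently reproducible.
cell_seed <- function(base_seed, iteration, realization) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(base_seed) %% m)
  h <- (h * 48271 + iteration * 1009) %% m
  h <- (h * 48271 + realization * 9176) %% m
  as.integer(h)
}

aggregate_cells <- function(cells) {
  measures <- c("mean_activity", "mean_plv", "diameter", "leaf_fraction")
  agg <- lapply(split(cells, cells$iteration), function(d) {
    out <- data.frame(iteration = d$iteration[1], fraction = d$fraction[1])
    for (m in measures) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]], na.rm = TRUE)
    }
    out$n_ok <- sum(d$ok)
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$iteration), ]
}

#' @export
print.damage_trajectory <- function(x, ...) {
  cat(sprintf(
    "<damage_trajectory> %s: %d iterations x %d realizations (%d/%d cells ok)\n",
    x$schedule$kind, x$schedule$n_iterations,
    max(x$cells$realization), sum(x$cells$ok), nrow(x$cells)
  ))
  invisible(x)
}

#' Persist a damage trajectory as TSV files
#'
#' Writes `<prefix>_cells.tsv` (iteration, realization, fraction, seed and
#' the four outcome measures) and `<prefix>_aggregates.tsv` (per-iteration
#' mean and sd).
#'
#' @param traj A `damage_trajectory`.
#' @param prefix File path prefix.
#' @export
write_trajectory <- function(traj, prefix) {
  utils::write.table(traj$cells, paste0(prefix, "_cells.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(traj$aggregates, paste0(prefix, "_aggregates.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(prefix)
}
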