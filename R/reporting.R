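#' Summarise a damage trajectory into curve statistics
#'
#' For each outcome measure: the per-iteration mean and SD, a monotone-trend
#' statistic (Spearman rank correlation of iteration versus per-iteration
#' mean, with a permutation p-value computed by shuffling iteration labels
#' across the per-realization values), and an inverted-U detector (an
#' interior maximum exceeding both endpoints by a margin).
#'
#' @param traj A `damage_trajectory` with at least 3 iterations.
#' @param peak_margin Minimum excess of an interior maximum over both
#'   endpoint means before a peak is declared (same units as the measure).
#' @param n_perm Permutations for the trend p-value.
#' @param perm_seed Seed used for the permutation draw.
#' @return A named list of `curve_summary` objects (one per measure), each
#'   with `measure`, `mean`, `sd`, `trend_rho`, `trend_p`, `peak_iteration`
#'   (NA when no qualifying interior peak exists).
#' @export
summarize_trajectory <- function(traj, peak_margin = 0, n_perm = 2000,
                                 perm_seed = 1) {
  agg <- traj$aggregates
  if (nrow(agg) < 3) stop("need at least 3 iterations to summarise")
  measures <- c("mean_activity", "mean_plv", "diameter", "leaf_fraction")
  out <- lapply(measures, function(m) {
    mu <- agg[[paste0(m, "_mean")]]
    sdv <- agg[[paste0(m, "_sd")]]
    tr <- trend_statistic(traj$cells, m, n_perm = n_perm, seed = perm_seed)
    structure(
      list(
        measure = m,
        iteration = agg$iteration,
        fraction = agg$fraction,
        mean = mu, sd = sdv,
        trend_rho = tr$rho, trend_p = tr$p,
        peak_iteration = interior_peak(mu, peak_margin)
      ),
      class = "curve_summary"
    )
  })
  names(out) <- measures
  out
}

# Spearman rho of iteration vs per-iteration mean; two-sided permutation p
# obtained by shuffling the iteration labels of the per-realization values.
trend_statistic <- function(cells, measure, n_perm = 2000, seed = 1) {
  ok <- cells[cells$ok, ]
  mu <- tapply(ok[[measure]], ok$iteration, mean)
  it <- as.numeric(names(mu))
  rho <- stats::cor(it, as.numeric(mu), method = "spearman")
  obs <- abs(rho)
  y <- ok[[measure]]
  lab <- ok$iteration
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      labp <- sample(lab)
      mup <- tapply(y, labp, mean)
      abs(stats::cor(as.numeric(names(mup)), as.numeric(mup), method = "spearman")) >= obs
    }, logical(1)))
  })
  list(rho = rho, p = (exceed + 1) / (n_perm + 1))
}

# Index of an interior maximum exceeding both endpoint means by `margin`;
# NA when none qualifies.
interior_peak <- function(mu, margin = 0) {
  k <- length(mu)
  interior <- 2:(k - 1)
  i <- interior[which.max(mu[interior])]
  if (mu[i] > mu[1] + margin && mu[i] > mu[k] + margin) i else NA_integer_
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf(
    "<curve_summary> %s: trend rho %.2f (p %.3g), peak %s\n",
    x$measure, x$trend_rho, x$trend_p,
    ifelse(is.na(x$peak_iteration), "none", paste("at iteration", x$peak_iteration))
  ))
  invisible(x)
}

#' Render outcome curves (mean line + SD band)
#'
#' One panel per outcome measure: dashed mean across realizations per
#' iteration with a shaded +/- SD band. Writes one figure file and one TSV of
#' the plotted values per trajectory; the TSV is byte-deterministic.
#'
#' @param summaries Result of [summarize_trajectory()].
#' @param path Output file path for the figure (extension selects the
#'   device, e.g. `.png` or `.svg`); the data TSV is written alongside with
#'   extension `.tsv`.
#' @param title Plot title (e.g. the experiment kind).
#' @return Invisibly, the paths written.
#' @export
render_curves <- function(summaries, path, title = "") {
  if (length(summaries) == 0) stop("no summaries to render")
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      measure = s$measure, iteration = s$iteration, fraction = s$fraction,
      mean = s$mean, sd = s$sd
    )
  }))
  rownames(df) <- NULL
  tsv <- sub("\\.[A-Za-z]+$", ".tsv", path)
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(linetype = "dashed", colour = "steelblue4") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(
      title = title, x = "damage iteration",
      y = "outcome (mean ± SD across realizations)"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, pl, width = 8, height = 6, dpi = 120)
  invisible(c(figure = path, data = tsv))
}
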