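#' Synthetic structural connectomes and damage maps
#'
#' Tools to generate, validate and persist the structural substrate of the
#' simulations: a sparse symmetric region-by-region adjacency matrix with 3-D
#' coordinates (used for distance-dependent conduction delays), a white-matter
#' "predilection site" edge mask, a per-region cortical atrophy map, and a
#' scalar thalamic reduction.
#'
#' @name connectome
#' @keywords internal
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

new_connectome <- function(adjacency, coordinates, labels, hemisphere) {
  structure(
    list(
      n_regions = nrow(adjacency),
      adjacency = adjacency,
      coordinates = coordinates,
      labels = labels,
      hemisphere = hemisphere
    ),
    class = "connectome"
  )
}

#' Validate a connectome object
#'
#' Checks the structural invariants: square symmetric non-negative adjacency
#' with zero diagonal, a connected graph, finite coordinates, and hemisphere
#' tags consistent with the sign of the first (x) coordinate.
#'
#' @param c A `connectome` object.
#' @return `c`, invisibly, if valid; otherwise an error.
#' @export
validate_connectome <- function(c) {
  A <- c$adjacency
  stopifnot(is.matrix(A), nrow(A) == ncol(A), nrow(A) == c$n_regions)
  if (any(!is.finite(A))) stop("adjacency contains non-finite entries")
  if (any(A < 0)) {
    bad <- which(A < 0, arr.ind = TRUE)
    stop(sprintf(
      "adjacency has negative entries, e.g. [%d, %d] = %g",
      bad[1, 1], bad[1, 2], A[bad[1, 1], bad[1, 2]]
    ))
  }
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12))) {
    bad <- which(abs(A - t(A)) > 1e-12, arr.ind = TRUE)
    stop(sprintf(
      "adjacency is not symmetric, e.g. entry [%d, %d] != [%d, %d]",
      bad[1, 1], bad[1, 2], bad[1, 2], bad[1, 1]
    ))
  }
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  if (!all(is.finite(c$coordinates))) stop("coordinates contain non-finite values")
  stopifnot(
    nrow(c$coordinates) == c$n_regions, ncol(c$coordinates) == 3,
    length(c$labels) == c$n_regions, length(c$hemisphere) == c$n_regions
  )
  if (!all(c$hemisphere %in% c("left", "right"))) {
    stop("hemisphere tags must be 'left' or 'right'")
  }
  sgn <- ifelse(c$hemisphere == "left", -1, 1)
  if (any(sign(c$coordinates[, 1]) * sgn < 0)) {
    stop("left/right regions must have negative/positive x coordinate")
  }
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  if (!igraph::is_connected(g)) stop("connectome graph is not connected")
  invisible(c)
}

#' @export
print.connectome <- function(x, ...) {
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf(
    "<connectome> %d regions, %d edges (density %.3f)\n",
    x$n_regions, ne, ne / choose(x$n_regions, 2)
  ))
  invisible(x)
}

# Brain-shaped synthetic coordinates: one hemisphere sampled, then mirrored in
# x so homotopic region pairs sit symmetrically about the midline (mm).
synth_coordinates <- function(n_half) {
  cbind(
    x = runif(n_half, 8, 65),
    y = runif(n_half, -95, 65),
    z = runif(n_half, -40, 70)
  )
}

#' Generate a synthetic structural connectome
#'
#' Builds a connected, symmetric, binary connectome with mirrored hemispheres
#' and distance-dependent connection probability (nearby regions are more
#' likely to be linked), emulating the gross organisation of atlas-based
#' cortical networks used in whole-brain modelling.
#'
#' @param n_regions Even integer >= 4; number of regions (default 78).
#' @param edge_density Fraction of possible undirected edges in (0, 1].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param length_scale_mm Spatial decay scale of the connection probability
#'   (`exp(-d/length_scale_mm)`), in mm.
#' @return A `connectome` object (see [validate_connectome()] for invariants).
#' @examples
#' ctm <- generate_connectome(20, edge_density = 0.3, seed = 1)
#' ctm
#' @export
generate_connectome <- function(n_regions = 78, edge_density = 0.15, seed = 1,
                                length_scale_mm = 45) {
  stopifnot(n_regions >= 4, n_regions %% 2 == 0, edge_density > 0, edge_density <= 1)
  n_pairs <- choose(n_regions, 2)
  n_edges <- round(edge_density * n_pairs)
  if (n_edges < n_regions - 1) {
    stop(sprintf(
      "edge_density %.3f yields %d edges; a connected graph on %d regions needs at least %d",
      edge_density, n_edges, n_regions, n_regions - 1
    ))
  }
  with_seed(seed, {
    half <- n_regions / 2
    xyz <- synth_coordinates(half)
    coords <- rbind(
      cbind(-xyz[, 1], xyz[, 2], xyz[, 3]), # left: negative x
      xyz # right
    )
    hemisphere <- rep(c("left", "right"), each = half)
    labels <- sprintf("region_%02d_%s", c(seq_len(half), seq_len(half)),
                      ifelse(hemisphere == "left", "L", "R"))
    D <- as.matrix(stats::dist(coords))
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    w <- exp(-D[pairs] / length_scale_mm)
    pick <- if (n_edges == n_pairs) {
      seq_len(n_pairs)
    } else {
      sample.int(n_pairs, n_edges, prob = w)
    }
    A <- matrix(0, n_regions, n_regions)
    A[pairs[pick, , drop = FALSE]] <- 1
    A <- A + t(A)
    A <- connectify(A, D)
    dimnames(A) <- list(labels, labels)
    rownames(coords) <- labels
    colnames(coords) <- c("x_mm", "y_mm", "z_mm")
    ctm <- new_connectome(A, coords, labels, hemisphere)
    validate_connectome(ctm)
    ctm
  })
}

# Re-wire a possibly disconnected binary graph into a connected one with the
# same edge count: join components through their nearest inter-component pair,
# compensating by deleting a random non-bridge edge.
connectify <- function(A, D) {
  repeat {
    g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no == 1) return(A)
    in1 <- comp$membership == 1
    Dx <- D
    Dx[in1, in1] <- Inf
    Dx[!in1, !in1] <- Inf
    Dx[A != 0] <- Inf
    add <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
    A[add[1], add[2]] <- A[add[2], add[1]] <- 1
    bridges <- igraph::bridges(g)
    removable <- igraph::as_edgelist(g, names = FALSE)
    if (length(bridges) > 0) removable <- removable[-as.integer(bridges), , drop = FALSE]
    if (nrow(removable) > 0) {
      drop <- removable[sample.int(nrow(removable), 1), ]
      A[drop[1], drop[2]] <- A[drop[2], drop[1]] <- 0
    }
  }
}

#' Inter-region conduction delay matrix
#'
#' Delays are Euclidean distance divided by a conduction velocity:
#' `tau[j, n] = ||x_j - x_n|| / velocity`, in seconds. The matrix is dense and
#' symmetric; only entries corresponding to structural connections are used by
#' the simulator.
#'
#' @param c A `connectome`.
#' @param velocity Conduction velocity in m/s (> 0). The default of 10 m/s is
#'   a typical myelinated cortico-cortical axonal velocity.
#' @return A symmetric `n x n` matrix of delays in seconds, zero diagonal.
#' @export
delay_matrix <- function(c, velocity = 10) {
  stopifnot(is.numeric(velocity), length(velocity) == 1, velocity > 0)
  if (!all(is.finite(c$coordinates))) stop("coordinates contain non-finite values")
  D_mm <- as.matrix(stats::dist(c$coordinates))
  D_mm / 1000 / velocity
}

new_damage_maps <- function(wm_mask, wm_max_fraction, cortical_map,
                            thalamic_max_fraction) {
  structure(
    list(
      wm_mask = wm_mask,
      wm_max_fraction = wm_max_fraction,
      cortical_map = cortical_map,
      thalamic_max_fraction = thalamic_max_fraction
    ),
    class = "damage_maps"
  )
}

#' Generate damage maps for the three lesion experiments
#'
#' Produces (i) a symmetric edge mask of white-matter predilection sites,
#' biased toward long-range (periventricular-like) connections, (ii) a
#' per-region cortical atrophy map of maximal fractional reductions, and
#' (iii) the scalar maximal thalamic reduction. The thalamic maximum is
#' computed from published mean thalamic volumes in longstanding MS versus
#' healthy controls (18.50 vs 20.78 mL), i.e. `1 - 18.50/20.78`, approximately
#' 11%.
#'
#' @param c A `connectome`.
#' @param wm_site_fraction Fraction of existing edges marked as predilection
#'   sites, in (0, 1].
#' @param seed Integer seed.
#' @param wm_max_fraction Maximal fractional reduction of masked edges
#'   (default 0.14, the tract-strength loss observed in MS tractography).
#' @param cortical_range Range of per-region maximal cortical reductions; the
#'   default 2--20% spans published regional cortical-thickness losses in
#'   longstanding MS.
#' @param thalamic_volumes Named numeric vector `c(ms = ..., hc = ...)` of
#'   thalamic volumes from which the thalamic maximum is derived.
#' @return A `damage_maps` object.
#' @export
generate_damage_maps <- function(c, wm_site_fraction = 0.5, seed = 1,
                                 wm_max_fraction = 0.14,
                                 cortical_range = c(0.02, 0.20),
                                 thalamic_volumes = c(ms = 18.50, hc = 20.78)) {
  stopifnot(
    wm_site_fraction > 0, wm_site_fraction <= 1,
    wm_max_fraction >= 0, wm_max_fraction <= 1,
    length(cortical_range) == 2, all(cortical_range >= 0), all(cortical_range <= 1),
    cortical_range[1] <= cortical_range[2],
    all(thalamic_volumes > 0), thalamic_volumes["ms"] <= thalamic_volumes["hc"]
  )
  n <- c$n_regions
  edges <- which(upper.tri(c$adjacency) & c$adjacency != 0, arr.ind = TRUE)
  n_sites <- max(1L, round(wm_site_fraction * nrow(edges)))
  D <- as.matrix(stats::dist(c$coordinates))
  with_seed(seed, {
    pick <- if (n_sites >= nrow(edges)) {
      seq_len(nrow(edges))
    } else {
      sample.int(nrow(edges), n_sites, prob = D[edges])
    }
    mask <- matrix(FALSE, n, n)
    mask[edges[pick, , drop = FALSE]] <- TRUE
    mask <- mask | t(mask)
    cortical_map <- stats::runif(n, cortical_range[1], cortical_range[2])
    names(cortical_map) <- c$labels
    new_damage_maps(
      wm_mask = mask,
      wm_max_fraction = wm_max_fraction,
      cortical_map = cortical_map,
      thalamic_max_fraction = unname(1 - thalamic_volumes["ms"] / thalamic_volumes["hc"])
    )
  })
}

#' Write / read a connectome as plain tabular files
#'
#' `write_connectome()` writes two TSV files, `<prefix>_adjacency.tsv` (dense
#' header-free n x n matrix) and `<prefix>_regions.tsv` (columns `label`,
#' `hemisphere`, `x_mm`, `y_mm`, `z_mm`). `read_connectome()` reads them back
#' and validates all invariants; asymmetric or negative adjacency and
#' non-finite coordinates are errors.
#'
#' @param c A `connectome`.
#' @param prefix File path prefix (directory must exist).
#' @return `write_connectome()` the prefix, invisibly; `read_connectome()` a
#'   validated `connectome`.
#' @export
write_connectome <- function(c, prefix) {
  # %.17g survives the decimal round trip bit-exactly for IEEE doubles
  A_chr <- matrix(sprintf("%.17g", c$adjacency), nrow = c$n_regions)
  utils::write.table(A_chr, paste0(prefix, "_adjacency.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  regions <- data.frame(
    label = c$labels, hemisphere = c$hemisphere,
    x_mm = sprintf("%.17g", c$coordinates[, 1]),
    y_mm = sprintf("%.17g", c$coordinates[, 2]),
    z_mm = sprintf("%.17g", c$coordinates[, 3])
  )
  utils::write.table(regions, paste0(prefix, "_regions.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(prefix)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(prefix) {
  A <- as.matrix(utils::read.table(paste0(prefix, "_adjacency.tsv"), sep = "\t"))
  regions <- utils::read.table(paste0(prefix, "_regions.tsv"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE
  )
  coords <- as.matrix(regions[, c("x_mm", "y_mm", "z_mm")])
  dimnames(A) <- list(regions$label, regions$label)
  rownames(coords) <- regions$label
  ctm <- new_connectome(A, coords, regions$label, regions$hemisphere)
  validate_connectome(ctm)
  ctm
}

#' Write / read damage maps as plain tabular files
#'
#' Writes `<prefix>_wm_mask.tsv` (0-based `i`, `j` index pairs of masked
#' edges, upper triangle), `<prefix>_cortical_map.tsv` (columns `label`,
#' `max_fraction`) and `<prefix>_damage.json` (the scalar maxima).
#'
#' @param maps A `damage_maps` object.
#' @param prefix File path prefix.
#' @param c The `connectome` the maps refer to (for labels and dimension).
#' @return `write_damage_maps()` the prefix, invisibly; `read_damage_maps()` a
#'   `damage_maps` object.
#' @export
write_damage_maps <- function(maps, prefix) {
  idx <- which(upper.tri(maps$wm_mask) & maps$wm_mask, arr.ind = TRUE)
  utils::write.table(
    data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L),
    paste0(prefix, "_wm_mask.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(
    data.frame(label = names(maps$cortical_map), max_fraction = maps$cortical_map),
    paste0(prefix, "_cortical_map.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(
      wm_max_fraction = maps$wm_max_fraction,
      thalamic_max_fraction = maps$thalamic_max_fraction
    ),
    paste0(prefix, "_damage.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_damage_maps
#' @export
read_damage_maps <- function(prefix, c) {
  idx <- utils::read.table(paste0(prefix, "_wm_mask.tsv"), sep = "\t", header = TRUE)
  cmap <- utils::read.table(paste0(prefix, "_cortical_map.tsv"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE
  )
  scalars <- jsonlite::read_json(paste0(prefix, "_damage.json"))
  n <- c$n_regions
  mask <- matrix(FALSE, n, n)
  mask[cbind(idx$i + 1L, idx$j + 1L)] <- TRUE
  mask <- mask | t(mask)
  if (any(mask & c$adjacency == 0)) stop("mask marks edges absent from the connectome")
  cortical_map <- stats::setNames(cmap$max_fraction, cmap$label)[c$labels]
  new_damage_maps(mask, scalars$wm_max_fraction, cortical_map,
                  scalars$thalamic_max_fraction)
}
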