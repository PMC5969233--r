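# Shared fixtures: small connectomes and short simulations keep unit tests
# fast; the full-scale study conditions live in helper-acceptance.R.

tiny_connectome <- function(n = 8, density = 0.5, seed = 11) {
  generate_connectome(n, density, seed = seed)
}

# A connectome object built by hand (bypasses the generator) for exact
# geometric tests.
manual_connectome <- function(coords, adjacency = NULL) {
  n <- nrow(coords)
  if (is.null(adjacency)) {
    adjacency <- matrix(1, n, n) - diag(n)
  }
  structure(
    list(
      n_regions = n, adjacency = adjacency, coordinates = coords,
      labels = sprintf("r%02d", seq_len(n)),
      hemisphere = ifelse(coords[, 1] < 0, "left", "right")
    ),
    class = "connectome"
  )
}

# Heavily damped, weakly coupled parameters whose fixed point is strongly
# stable: useful for integrator-accuracy tests where the dynamics must stay
# near (or relax to) the steady state.
damped_params <- function(...) {
  ct_params(
    nu = c(
      ee = 1.0, ei = -1.8, es = 0.6, ie = 1.0, ii = -1.8, is = 0.6,
      se = 1.2, sr = -0.8, re = 0.4, rs = 0.2, n = 0.5
    ),
    ei_scale = 1, epsilon = 0, sigma_n = 0, ...
  )
}

# Sinusoidal multichannel test signal, regions x samples.
sinusoid_matrix <- function(n_regions, freq, fs, duration, amplitude = 1,
                            phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  ph <- rep(phase, length.out = n_regions)
  t(vapply(seq_len(n_regions), function(j) {
    amplitude * sin(2 * pi * freq * t + ph[j])
  }, numeric(length(t))))
}

# Exhaustive maximum-weight spanning tree by enumerating all (n-1)-edge
# subsets: the brute-force oracle for Kruskal.
brute_force_mst <- function(w) {
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(idx)
  best <- NULL
  best_w <- -Inf
  for (comb in utils::combn(m, n - 1, simplify = FALSE)) {
    edges <- idx[comb, , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (!igraph::is_connected(g)) next
    tw <- sum(w[edges])
    if (tw > best_w) {
      best_w <- tw
      best <- edges
    }
  }
  list(edges = best, weight = best_w)
}

# Random tree on n nodes (random Pruefer-like attachment).
random_tree <- function(n, seed) {
  with_seed_test(seed, {
    edges <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1, 1), integer(1)))
    cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Tree diameter oracle: breadth-first distances from every node, in plain R.
bfs_diameter <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  dmax <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    dmax <- max(dmax, max(dist))
  }
  dmax
}
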