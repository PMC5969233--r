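#' Noise-free steady state of the corticothalamic network
#'
#' Solves the algebraic fixed-point system obtained by setting all time
#' derivatives (and the noise drive) to zero:
#' \deqn{V_e = \nu_{ee}\phi_e + \nu_{ei}Q(V_i) + \nu_{es}Q(V_s) + s,\quad
#'       \phi_e = Q(V_e)}
#' with the analogous equations for the inhibitory, relay and reticular
#' populations and the network input
#' \eqn{s_j = (\epsilon/N)\sum_n A_{jn} \phi_{e,n}}. A damped Newton
#' iteration with the analytic Jacobian is started from the uncoupled
#' single-unit solution on the low-firing branch (the resting working point
#' of the model; the sigmoid admits up to three fixed points and the lowest
#' is taken). The result initialises the integrator's history, which
#' minimises the startup transient.
#'
#' @param p A `ct_params` object (may carry region-wise densities from the
#'   damage operators).
#' @param c A `connectome`.
#' @param tol Convergence tolerance on the max-norm residual, mV.
#' @param max_iter Maximum Newton iterations.
#' @return A list with per-region vectors `V_e`, `V_i`, `V_s`, `V_r` (mV) and
#'   `phi_e` (s^-1), plus the achieved `residual`.
#' @export
steady_state <- function(p, c, tol = 1e-10, max_iter = 200) {
  n <- c$n_regions
  nu <- params_matrix(p, n)
  A <- c$adjacency
  Q <- function(V) firing_rate(V, p)
  Qp <- function(V) {
    q <- firing_rate(V, p)
    q * (1 - q / p$Q_max) / p$sigma
  }

  residual <- function(V, eps) {
    Ve <- V[1:n]; Vi <- V[n + 1:n]; Vs <- V[2 * n + 1:n]; Vr <- V[3 * n + 1:n]
    qe <- Q(Ve); qi <- Q(Vi); qs <- Q(Vs); qr <- Q(Vr)
    s <- (eps / n) * as.vector(A %*% qe)
    c(
      Ve - nu[, "ee"] * qe - nu[, "ei"] * qi - nu[, "es"] * qs - s,
      Vi - nu[, "ie"] * qe - nu[, "ii"] * qi - nu[, "is"] * qs,
      Vs - nu[, "se"] * qe - nu[, "sr"] * qr - nu[, "n"] * p$phi_n0,
      Vr - nu[, "re"] * qe - nu[, "rs"] * qs
    )
  }

  jacobian <- function(V, eps) {
    Ve <- V[1:n]; Vi <- V[n + 1:n]; Vs <- V[2 * n + 1:n]; Vr <- V[3 * n + 1:n]
    de <- Qp(Ve); di <- Qp(Vi); ds <- Qp(Vs); dr <- Qp(Vr)
    I <- diag(n)
    Z <- matrix(0, n, n)
    J11 <- I - diag(nu[, "ee"] * de, n) - (eps / n) * A %*% diag(de, n)
    rbind(
      cbind(J11, diag(-nu[, "ei"] * di, n), diag(-nu[, "es"] * ds, n), Z),
      cbind(diag(-nu[, "ie"] * de, n), I - diag(nu[, "ii"] * di, n),
            diag(-nu[, "is"] * ds, n), Z),
      cbind(diag(-nu[, "se"] * de, n), Z, I, diag(-nu[, "sr"] * dr, n)),
      cbind(diag(-nu[, "re"] * de, n), Z, diag(-nu[, "rs"] * ds, n), I)
    )
  }

  newton <- function(V, eps) {
    R <- residual(V, eps)
    for (iter in seq_len(max_iter)) {
      if (max(abs(R)) < tol) break
      delta <- tryCatch(solve(jacobian(V, eps), R), error = function(e) NULL)
      if (is.null(delta)) stop("singular Jacobian in steady-state solve")
      lambda <- 1
      improved <- FALSE
      while (lambda >= 1e-6) {
        Vn <- V - lambda * delta
        Rn <- residual(Vn, eps)
        if (max(abs(Rn)) < max(abs(R))) {
          improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (!improved) break # stalled; keep the best point found
      V <- Vn
      R <- Rn
    }
    list(V = V, res = max(abs(R)))
  }

  # warm start: single-unit solution for the most representative parameter
  # row, replicated; then continuation in the coupling strength so Newton
  # tracks the low-firing branch instead of jumping to another basin
  j0 <- which.min(rowSums(abs(nu - rep(colMeans(nu), each = n))))
  V <- rep(single_unit_fixed_point(nu[j0, ], p), each = n)
  res <- Inf
  for (eps in p$epsilon * c(0.25, 0.5, 0.75, 1)) {
    sol <- newton(V, eps)
    V <- sol$V
    res <- sol$res
  }
  if (res >= max(tol, 1e-8)) {
    warning(sprintf("steady state not fully converged (residual %.3g mV)", res))
  }
  Ve <- V[1:n]
  list(
    V_e = Ve, V_i = V[n + 1:n], V_s = V[2 * n + 1:n], V_r = V[3 * n + 1:n],
    phi_e = Q(Ve), residual = res
  )
}

# Uncoupled single-unit fixed point on the low-firing branch, by nested
# scalar root-finding: thalamic pair and inhibitory potential are solved as
# functions of the excitatory potential, whose own equation is then
# bracketed from below.
single_unit_fixed_point <- function(nuj, p, s_j = 0) {
  Q <- function(V) p$Q_max / (1 + exp(-(V - p$theta) / p$sigma))
  thal <- function(phi) {
    f <- function(Vs) {
      Vr <- nuj[["re"]] * phi + nuj[["rs"]] * Q(Vs)
      Vs - nuj[["se"]] * phi - nuj[["sr"]] * Q(Vr) - nuj[["n"]] * p$phi_n0
    }
    Vs <- lowest_root(f)
    c(Vs, nuj[["re"]] * phi + nuj[["rs"]] * Q(Vs))
  }
  inhib <- function(phi, Qs) {
    lowest_root(function(Vi) {
      Vi - nuj[["ie"]] * phi - nuj[["ii"]] * Q(Vi) - nuj[["is"]] * Qs
    })
  }
  excit_residual <- function(Ve) {
    phi <- Q(Ve)
    th <- thal(phi)
    Vi <- inhib(phi, Q(th[1]))
    Ve - nuj[["ee"]] * phi - nuj[["ei"]] * Q(Vi) - nuj[["es"]] * Q(th[1]) - s_j
  }
  Ve <- lowest_root(excit_residual)
  phi <- Q(Ve)
  th <- thal(phi)
  c(Ve, inhib(phi, Q(th[1])), th[1], th[2])
}

# Lowest root of a scalar function on a physiological bracket: scan for the
# first sign change from below and polish with uniroot.
lowest_root <- function(f, lower = -1500, upper = 1500, n_grid = 301) {
  grid <- seq(lower, upper, length.out = n_grid)
  fv <- vapply(grid, f, numeric(1))
  sc <- which(fv[-n_grid] * fv[-1] <= 0)
  if (length(sc) == 0) stop("no fixed point found in bracket [", lower, ", ", upper, "]")
  i <- sc[1]
  if (fv[i] == 0) return(grid[i])
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)$root
}
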