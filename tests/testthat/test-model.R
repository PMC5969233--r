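# The sigmoid, steady state and stochastic integrator. The scalar R
# re-implementation in r_unit_trajectory() is an independent oracle for the
# compiled stepper (same scheme, plain R, single unit).

r_unit_trajectory <- function(p, init_V, phi_hist, n_steps) {
  Q <- function(V) p$Q_max / (1 + exp(-(V - p$theta) / p$sigma))
  nu <- p$nu
  dt <- p$dt
  ab <- p$alpha * p$beta
  apb <- p$alpha + p$beta
  lag_ct <- as.integer(round(p$tau_ct / dt))
  depth <- lag_ct + 1L
  phi_buf <- rep(phi_hist, depth)
  qs_buf <- rep(Q(init_V[["Vs"]]), depth)
  Ve <- init_V[["Ve"]]; Vi <- init_V[["Vi"]]; Vs <- init_V[["Vs"]]; Vr <- init_V[["Vr"]]
  We <- Wi <- Ws <- Wr <- psi <- 0
  phi <- phi_hist
  out <- numeric(n_steps)
  for (t in 0:(n_steps - 1)) {
    slot_now <- t %% depth
    slot_del <- (slot_now - lag_ct + depth) %% depth
    qs_del <- qs_buf[slot_del + 1]
    phi_del <- phi_buf[slot_del + 1]
    in_e <- nu[["ee"]] * phi + nu[["ei"]] * Q(Vi) + nu[["es"]] * qs_del
    in_i <- nu[["ie"]] * phi + nu[["ii"]] * Q(Vi) + nu[["is"]] * qs_del
    in_s <- nu[["se"]] * phi_del + nu[["sr"]] * Q(Vr) + nu[["n"]] * p$phi_n0
    in_r <- nu[["re"]] * phi_del + nu[["rs"]] * Q(Vs)
    Qe <- Q(Ve)
    nVe <- Ve + dt * We; nWe <- We + dt * (ab * (in_e - Ve) - apb * We)
    nVi <- Vi + dt * Wi; nWi <- Wi + dt * (ab * (in_i - Vi) - apb * Wi)
    nVs <- Vs + dt * Ws; nWs <- Ws + dt * (ab * (in_s - Vs) - apb * Ws)
    nVr <- Vr + dt * Wr; nWr <- Wr + dt * (ab * (in_r - Vr) - apb * Wr)
    nphi <- phi + dt * psi
    npsi <- psi + dt * (p$gamma^2 * (Qe - phi) - 2 * p$gamma * psi)
    Ve <- nVe; We <- nWe; Vi <- nVi; Wi <- nWi; Vs <- nVs; Ws <- nWs
    Vr <- nVr; Wr <- nWr; phi <- nphi; psi <- npsi
    slot_next <- (t + 1L) %% depth
    phi_buf[slot_next + 1] <- phi
    qs_buf[slot_next + 1] <- Q(Vs)
    out[t + 1] <- phi
  }
  out
}

test_that("firing-rate sigmoid hits its midpoint, limits and derived value", {
  p <- ct_params()
  expect_equal(firing_rate(p$theta, p), p$Q_max / 2)
  expect_lt(firing_rate(-1e4, p), 1e-10)
  expect_equal(firing_rate(1e4, p), p$Q_max)
  expect_equal(firing_rate(p$theta + p$sigma, p), p$Q_max / (1 + exp(-1)))
  V <- seq(-80, 80, by = 0.5)
  expect_true(all(diff(firing_rate(V, p)) > 0)) # strictly increasing
  expect_true(all(firing_rate(V, p) > 0 & firing_rate(V, p) < p$Q_max))
})

test_that("parameter validation enforces sign conventions", {
  expect_error(ct_params(nu = c(ei = 0.5), ei_scale = 1), "inhibitory")
  expect_error(ct_params(nu = c(se = -1)), "excitatory")
  expect_error(ct_params(dt = -1e-4))
  p <- ct_params()
  expect_equal(p$nu[["is"]], p$nu[["es"]]) # random-connectivity tie
  p2 <- ct_params(nu = c(is = 0.3))
  expect_equal(p2$nu[["is"]], 0.3) # and the tie is overridable
})

test_that("steady state satisfies the fixed-point equations written independently", {
  ctm <- tiny_connectome(10, 0.4, seed = 4)
  for (p in list(ct_params(), damped_params())) {
    ss <- steady_state(p, ctm)
    Q <- function(V) p$Q_max / (1 + exp(-(V - p$theta) / p$sigma))
    nu <- p$nu
    s <- (p$epsilon / ctm$n_regions) * as.vector(ctm$adjacency %*% Q(ss$V_e))
    expect_equal(ss$V_e,
      nu[["ee"]] * Q(ss$V_e) + nu[["ei"]] * Q(ss$V_i) + nu[["es"]] * Q(ss$V_s) + s,
      tolerance = 1e-8, ignore_attr = TRUE
    )
    expect_equal(ss$V_i,
      nu[["ie"]] * Q(ss$V_e) + nu[["ii"]] * Q(ss$V_i) + nu[["is"]] * Q(ss$V_s),
      tolerance = 1e-8, ignore_attr = TRUE
    )
    expect_equal(ss$V_s, nu[["se"]] * Q(ss$V_e) + nu[["sr"]] * Q(ss$V_r),
      tolerance = 1e-8, ignore_attr = TRUE
    )
    expect_equal(ss$V_r, nu[["re"]] * Q(ss$V_e) + nu[["rs"]] * Q(ss$V_s),
      tolerance = 1e-8, ignore_attr = TRUE
    )
    expect_equal(ss$phi_e, Q(ss$V_e), ignore_attr = TRUE)
    expect_true(all(ss$phi_e > 0 & ss$phi_e < p$Q_max))
  }
})

test_that("a 2 s transient at dt 1e-4 discards exactly 20000 samples", {
  ctm <- generate_connectome(4, 1, seed = 0)
  p <- damped_params()
  sim <- euler_maruyama_run(p, ctm, duration = 0.1, transient = 2, seed = 1)
  expect_identical(sim$transient_samples, 20000L)
})

test_that("noise-free run started at the fixed point stays there", {
  ctm <- tiny_connectome(8, 0.5, seed = 11)
  p <- damped_params()
  ss <- steady_state(p, ctm)
  sim <- euler_maruyama_run(p, ctm, duration = 1, transient = 0, seed = 1, init = ss)
  expect_lt(max(abs(sim$phi - ss$phi_e)), 1e-6)
})

test_that("runs are bit-identical for a fixed seed, and seed-free when noiseless", {
  ctm <- tiny_connectome(8, 0.5, seed = 11)
  p <- ct_params()
  ss <- steady_state(p, ctm)
  a <- euler_maruyama_run(p, ctm, duration = 0.5, transient = 0.2, seed = 33, init = ss)
  b <- euler_maruyama_run(p, ctm, duration = 0.5, transient = 0.2, seed = 33, init = ss)
  expect_identical(a$phi, b$phi)
  d <- euler_maruyama_run(p, ctm, duration = 0.5, transient = 0.2, seed = 34, init = ss)
  expect_false(identical(a$phi, d$phi))

  p0 <- damped_params()
  ss0 <- steady_state(p0, ctm)
  ss0$V_e <- ss0$V_e + 1 # perturb so the trajectory is nontrivial
  x <- euler_maruyama_run(p0, ctm, duration = 0.3, transient = 0, seed = 1, init = ss0)
  y <- euler_maruyama_run(p0, ctm, duration = 0.3, transient = 0, seed = 99, init = ss0)
  expect_identical(x$phi, y$phi) # noise only enters the relay equation
})

test_that("with zero coupling each region is independent and A is irrelevant", {
  ctm <- tiny_connectome(8, 0.5, seed = 11)
  p <- damped_params() # epsilon = 0, sigma_n = 0
  ss <- steady_state(p, ctm)
  ss$V_e <- ss$V_e + 2
  base <- euler_maruyama_run(p, ctm, duration = 0.3, transient = 0, seed = 1, init = ss)

  # zeroing the adjacency changes nothing when epsilon is already 0
  ctm0 <- ctm
  ctm0$adjacency <- ctm$adjacency * 0
  expect_identical(
    euler_maruyama_run(p, ctm0, duration = 0.3, transient = 0, seed = 1, init = ss)$phi,
    base$phi
  )
  # so does epsilon > 0 on a zero matrix
  p_eps <- damped_params()
  p_eps$epsilon <- 0.7
  expect_identical(
    euler_maruyama_run(p_eps, ctm0, duration = 0.3, transient = 0, seed = 1, init = ss)$phi,
    base$phi
  )
  # and perturbing another region leaves region 1 untouched
  ss2 <- ss
  ss2$V_e[5] <- ss2$V_e[5] + 10
  alt <- euler_maruyama_run(p, ctm, duration = 0.3, transient = 0, seed = 1, init = ss2)
  expect_identical(alt$phi[1, ], base$phi[1, ])
  expect_false(identical(alt$phi[5, ], base$phi[5, ]))
})

test_that("the compiled stepper matches the scalar R oracle off the fixed point", {
  ctm <- generate_connectome(4, 1, seed = 0)
  p <- damped_params()
  ss <- steady_state(p, ctm)
  init <- ss
  init$V_e <- init$V_e + 2 # kick the excitatory potential
  sim <- euler_maruyama_run(p, ctm,
    duration = 0.2, transient = 0, seed = 1,
    init = init, fs_out = 1 / p$dt
  )
  oracle <- r_unit_trajectory(
    p,
    c(Ve = init$V_e[1], Vi = init$V_i[1], Vs = init$V_s[1], Vr = init$V_r[1]),
    phi_hist = init$phi_e[1], n_steps = ncol(sim$phi)
  )
  expect_equal(sim$phi[1, ], oracle, tolerance = 1e-10)
})

test_that("the deterministic stepper converges at first order in dt", {
  ctm <- generate_connectome(4, 1, seed = 0)
  run_dt <- function(dt) {
    p <- damped_params(dt = dt)
    ss <- steady_state(p, ctm)
    ss$V_e <- ss$V_e + 2
    euler_maruyama_run(p, ctm,
      duration = 0.5, transient = 0, seed = 1,
      init = ss, fs_out = 100
    )$phi
  }
  x1 <- run_dt(1e-4)
  x2 <- run_dt(5e-5)
  x4 <- run_dt(2.5e-5)
  d1 <- max(abs(x1 - x4))
  d2 <- max(abs(x2 - x4))
  # first order: |x_h - x_{h/4}| / |x_{h/2} - x_{h/4}| ~ (3/4)h / (1/4)h = 3
  expect_gt(d1 / d2, 2)
  expect_lt(d1 / d2, 4.5)
})

test_that("numerical blow-up aborts with step index and parameter dump", {
  ctm <- generate_connectome(4, 1, seed = 0)
  p <- damped_params()
  ss <- steady_state(p, ctm)
  ss$V_e <- ss$V_e + 1e307 # guaranteed overflow in the synaptic drive term
  expect_error(
    euler_maruyama_run(p, ctm, duration = 0.2, transient = 0, seed = 1, init = ss),
    "blow-up|non-finite"
  )
  err <- tryCatch(
    euler_maruyama_run(p, ctm, duration = 0.2, transient = 0, seed = 1, init = ss),
    error = conditionMessage
  )
  expect_match(err, "step")
  expect_match(err, "parameters")
})

test_that("simulation I/O round-trips the series and metadata", {
  ctm <- tiny_connectome(8, 0.5, seed = 11)
  p <- ct_params()
  sim <- euler_maruyama_run(p, ctm, duration = 0.5, transient = 0.1, seed = 5)
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_simulation(sim, prefix)
  back <- read_simulation(prefix)
  expect_equal(back$phi, sim$phi, tolerance = 1e-10)
  expect_identical(back$fs, sim$fs)
  expect_identical(back$transient_samples, sim$transient_samples)
  expect_equal(back$params$nu, sim$params$nu)
})

test_that("config files round-trip the parameter set", {
  p <- ct_params(epsilon = 0.42, sigma_n = 2e-3, nu = c(se = 3.9))
  path <- file.path(withr::local_tempdir(), "params.yaml")
  write_ct_params(p, path)
  q <- read_ct_params(path)
  expect_equal(q$nu, p$nu)
  expect_equal(q$epsilon, p$epsilon)
  expect_equal(q$sigma_n, p$sigma_n)
  expect_equal(q$tau_ct, p$tau_ct)
})
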