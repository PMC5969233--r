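make_maps <- function(ctm, cortical = NULL, seed = 7) {
  maps <- generate_damage_maps(ctm, wm_site_fraction = 0.5, seed = seed)
  if (!is.null(cortical)) maps$cortical_map[] <- cortical
  maps
}

test_that("white-matter damage scales only masked edges, preserving symmetry", {
  ctm <- tiny_connectome(10, 0.5, seed = 2)
  maps <- make_maps(ctm)
  expect_identical(apply_wm_damage(ctm, maps, 0)$adjacency, ctm$adjacency)

  dam <- apply_wm_damage(ctm, maps, 0.14)
  expect_identical(dam$adjacency, t(dam$adjacency))
  masked <- maps$wm_mask & upper.tri(maps$wm_mask)
  unmasked <- !maps$wm_mask & upper.tri(maps$wm_mask) & ctm$adjacency > 0
  # a masked unit edge ends at exactly 0.86
  expect_equal(unique(dam$adjacency[masked] / ctm$adjacency[masked]), 0.86)
  expect_identical(dam$adjacency[unmasked], ctm$adjacency[unmasked])

  expect_error(apply_wm_damage(ctm, maps, 0.2), "outside")
  expect_error(apply_wm_damage(ctm, maps, -0.01), "outside")
})

test_that("cortical damage scales the four intracortical densities region-wise", {
  ctm <- tiny_connectome(10, 0.5, seed = 2)
  maps <- make_maps(ctm, cortical = c(0.2, rep(0, 9)))
  p <- ct_params()
  nu0 <- ctlesion:::params_matrix(p, 10)

  expect_identical(ctlesion:::params_matrix(apply_cortical_damage(p, maps, 0), 10), nu0)

  dam <- ctlesion:::params_matrix(apply_cortical_damage(p, maps, 1), 10)
  within <- c("ee", "ei", "ie", "ii")
  outside <- setdiff(colnames(nu0), within)
  expect_equal(dam[1, within], nu0[1, within] * 0.8)
  expect_identical(dam[1, outside], nu0[1, outside])
  expect_identical(dam[2:10, ], nu0[2:10, ]) # zero-atrophy regions invariant

  half <- ctlesion:::params_matrix(apply_cortical_damage(p, maps, 0.5), 10)
  expect_equal(half[1, within], nu0[1, within] * 0.9)
  expect_error(apply_cortical_damage(p, maps, 1.2))
})

test_that("thalamic damage scales sr and rs globally by the volumetric maximum", {
  p <- ct_params()
  nu0 <- ctlesion:::params_matrix(p, 6)
  dam <- ctlesion:::params_matrix(apply_thalamic_damage(p, 1, max_fraction = 0.11, n = 6), 6)
  expect_equal(dam[, "sr"], nu0[, "sr"] * 0.89)
  expect_equal(dam[, "rs"], nu0[, "rs"] * 0.89)
  outside <- setdiff(colnames(nu0), c("sr", "rs"))
  expect_identical(dam[, outside], nu0[, outside])
  expect_identical(ctlesion:::params_matrix(apply_thalamic_damage(p, 0, n = 6), 6), nu0)
  # the default maximum derives from the thalamic volume ratio
  dflt <- ctlesion:::params_matrix(apply_thalamic_damage(p, 1, n = 6), 6)
  expect_equal(dflt[1, "sr"], nu0[1, "sr"] * (18.50 / 20.78))
})

test_that("schedules are linear from intact baseline to the configured maximum", {
  ctm <- tiny_connectome(10, 0.5, seed = 2)
  maps <- make_maps(ctm)
  for (kind in c("white_matter", "cortical", "thalamic")) {
    sch <- damage_schedule(kind, maps, n_iterations = 8)
    expect_equal(sch$profile, seq(0, 1, length.out = 8))
    expect_equal(sch$profile[1], 0)
    expect_equal(sch$profile[8], 1)
  }
  # damage is monotone non-increasing in every affected quantity
  sch <- damage_schedule("white_matter", maps, n_iterations = 6)
  p <- ct_params()
  prev <- NULL
  for (step in sch$profile) {
    st <- ctlesion:::damage_state(sch, step, p, ctm)
    if (!is.null(prev)) expect_true(all(st$connectome$adjacency <= prev + 1e-12))
    prev <- st$connectome$adjacency
  }
  sch_c <- damage_schedule("cortical", maps, n_iterations = 6)
  prev <- NULL
  for (step in sch_c$profile) {
    nu <- ctlesion:::params_matrix(ctlesion:::damage_state(sch_c, step, p, ctm)$params, 10)
    if (!is.null(prev)) expect_true(all(abs(nu) <= abs(prev) + 1e-12))
    prev <- nu
  }
  # final white-matter state hits the 14% maximum exactly
  last <- ctlesion:::damage_state(sch, 1, p, ctm)
  masked <- maps$wm_mask & ctm$adjacency > 0
  expect_equal(unique(last$connectome$adjacency[masked] / ctm$adjacency[masked]), 0.86)
})

test_that("cell seeds are valid, deterministic and collision-free over a schedule", {
  seeds <- outer(1:20, 1:50, function(i, r) ctlesion:::cell_seed(123, i, r))
  expect_true(all(seeds == round(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(anyDuplicated(c(seeds)), 0)
  expect_identical(ctlesion:::cell_seed(5, 3, 4), ctlesion:::cell_seed(5, 3, 4))
})

test_that("run_experiment reproduces itself and aggregates coherently", {
  ctm <- tiny_connectome(8, 0.5, seed = 4)
  maps <- make_maps(ctm, seed = 5)
  sch <- damage_schedule("white_matter", maps, n_iterations = 2)
  p <- ct_params()
  t1 <- run_experiment(sch, p, ctm,
    n_realizations = 2, base_seed = 9,
    duration = 4, transient = 0.5
  )
  t2 <- run_experiment(sch, p, ctm,
    n_realizations = 2, base_seed = 9,
    duration = 4, transient = 0.5
  )
  expect_identical(t1$cells, t2$cells)
  expect_true(all(t1$cells$ok))
  expect_equal(nrow(t1$cells), 4)
  expect_equal(nrow(t1$aggregates), 2)
  agg1 <- t1$aggregates[1, ]
  base_cells <- t1$cells[t1$cells$iteration == 1, ]
  expect_equal(agg1$mean_plv_mean, mean(base_cells$mean_plv))
  expect_equal(agg1$mean_plv_sd, stats::sd(base_cells$mean_plv))
  expect_true(all(t1$aggregates[, grep("_sd$", names(t1$aggregates))] >= 0))

  prefix <- file.path(withr::local_tempdir(), "traj")
  write_trajectory(t1, prefix)
  cells <- utils::read.table(paste0(prefix, "_cells.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(cells), 4)
})

test_that("iteration 1 is the undamaged baseline, identical across experiment kinds", {
  ctm <- tiny_connectome(8, 0.5, seed = 4)
  maps <- make_maps(ctm, seed = 5)
  p <- ct_params()
  out <- lapply(c("white_matter", "cortical", "thalamic"), function(kind) {
    sch <- damage_schedule(kind, maps, n_iterations = 2)
    run_experiment(sch, p, ctm,
      n_realizations = 1, base_seed = 77,
      duration = 4, transient = 0.5
    )$cells
  })
  base <- lapply(out, function(cells) cells[cells$iteration == 1, -1])
  expect_identical(base[[1]], base[[2]])
  expect_identical(base[[1]], base[[3]])
})
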