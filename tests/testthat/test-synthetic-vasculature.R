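# Phantom generation, perturbation ensembles and analytic flow oracles.

test_that("phantom surfaces are watertight with closed-form volumes", {
  ph <- fix_tube40()
  v <- validate_surface(ph$surface, check_self_intersection = FALSE)
  expect_true(v$watertight)
  expect_true(v$consistently_oriented)
  expect_lt(abs(enclosed_volume(ph$surface) - pi * 4 * 40) / (pi * 4 * 40),
            0.01)
  sac <- fix_sac_phantom()
  expect_true(validate_surface(sac$surface,
                               check_self_intersection = FALSE)$watertight)
  # ground-truth record carries the constructed sac quantities
  expect_equal(sac$truth$ostium_area, pi * 1.2^2)
  R <- 3; hc <- sqrt(R^2 - 1.2^2); H <- R + hc
  expect_equal(sac$truth$sac_volume, pi * H^2 * (3 * R - H) / 3)
  expect_equal(sac$truth$sac_lateral_area, 2 * pi * R * H)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(sac = list(neck_radius = 3, sac_radius = 2)),
               class = "aneumorph_spec_error")
  expect_error(phantom_spec(radius = -1), class = "aneumorph_spec_error")
  expect_error(phantom_spec(branches = list(list(station = 5, radius = -1,
                                                 length = 3))),
               class = "aneumorph_spec_error")
})

test_that("zero-amplitude perturbation returns the input ensemble", {
  ph <- fix_tube30()
  gs <- perturb_ensemble(ph, perturbation_spec(radius_noise = 0,
                                               neck_bias = 0,
                                               branch_dropout = 0,
                                               n_groups = 3, seed = 5))
  for (g in gs)
    expect_identical(g$vertices, ph$surface$vertices)
})

test_that("perturbed ensembles are deterministic and watertight", {
  ph <- fix_tube30()
  ps <- perturbation_spec(radius_noise = 0.13, n_groups = 3, seed = 11)
  g1 <- perturb_ensemble(ph, ps)
  g2 <- perturb_ensemble(ph, ps)
  for (i in seq_along(g1)) {
    expect_identical(g1[[i]]$vertices, g2[[i]]$vertices)
    expect_true(validate_surface(g1[[i]],
                                 check_self_intersection = FALSE)$watertight)
  }
  # different groups genuinely differ
  expect_gt(max(abs(g1[[1]]$vertices - g1[[2]]$vertices)), 0.05)
  # pointwise offsets have the prescribed scale (sd over groups ~ 0.13)
  ps24 <- perturbation_spec(radius_noise = 0.13, n_groups = 24, seed = 11)
  g24 <- perturb_ensemble(ph, ps24)
  offs <- vapply(g24, function(g)
    sqrt(rowSums((g$vertices - ph$surface$vertices)^2)), numeric(nrow(ph$surface$vertices)))
  nrml <- aneumorph:::vertex_normals(ph$surface)
  signed <- vapply(g24, function(g)
    rowSums((g$vertices - ph$surface$vertices) * nrml), numeric(nrow(ph$surface$vertices)))
  ptw_sd <- apply(signed, 1, stats::sd)
  expect_lt(abs(mean(ptw_sd) - 0.13) / 0.13, 0.25)
})

test_that("branch dropout removes the side branch cleanly", {
  ph <- make_phantom(phantom_spec(length = 24, radius = 2,
                                  branches = list(list(station = 12,
                                                       radius = 1,
                                                       length = 6)),
                                  grid = 0.3, label = "branchy"))
  # the default branch direction points along -y
  expect_lt(min(ph$surface$vertices[, 2]), -5)
  gs <- perturb_ensemble(ph, perturbation_spec(radius_noise = 0,
                                               branch_dropout = 1,
                                               n_groups = 2, seed = 4))
  for (g in gs) {
    expect_gt(min(g$vertices[, 2]), -2.5)   # no branch material left
    expect_true(validate_surface(g,
                                 check_self_intersection = FALSE)$watertight)
  }
})

test_that("analytic flow matches its Poiseuille closed forms", {
  ph <- fix_tube30()
  wave <- two_harmonic_waveform(q_mean = 2, a1 = 0, a2 = 0, n = 5)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.3, n_times = 5)
  # wall shear 4 mu Q / (pi r^3) = 1.273 Pa on the trunk wall
  cen <- fl$wall$points
  trunk_wall <- abs(sqrt(cen[, 2]^2 + cen[, 3]^2) - 2) < 0.1 &
                cen[, 1] > 5 & cen[, 1] < 25
  a <- awss(fl$wall)
  expect_equal(mean(a[trunk_wall]), 1.27324, tolerance = 1e-3)
  # axis speed 2Q/(pi r^2) = 0.318 m/s
  P <- fl$volume$points
  axis_pts <- P[, 1] > 5 & P[, 1] < 25 & sqrt(P[, 2]^2 + P[, 3]^2) < 0.2
  mags <- sqrt(fl$volume$values[axis_pts, 3, 1]^2 +
               fl$volume$values[axis_pts, 3, 2]^2 +
               fl$volume$values[axis_pts, 3, 3]^2)
  expect_lt(abs(max(mags) - 0.3183) / 0.3183, 0.02)
})

test_that("pulsatile cycle-mean flux is exact on the analytic field", {
  # Q(t) = 2 + sin(2 pi t): trapezoid over the uniform full-cycle grid
  # integrates the sinusoid to zero exactly
  t <- seq(0, 1, length.out = 33)
  wave <- waveform(t, 2 + sin(2 * pi * t), d_ref = 4)
  ph <- fix_tube30()
  fl <- analytic_flow(ph, wave, sample_spacing = 0.3, n_times = 33)
  cl <- extract_centerline(ph$surface, c(3, 0, 0), c(27, 0, 0),
                           voxel = 0.3)
  vf <- vessel_flow_rate(fl$volume, ph$surface, cl, station = 15)
  expect_equal(cycle_average(vf$flux$q, vf$flux$times), 2,
               tolerance = 0.02 * 2)
  # the flux waveform tracks Q(t): amplitude of the oscillation survives
  expect_gt(max(vf$flux$q) - min(vf$flux$q), 1.5)
})

test_that("ensemble directories round trip through STL files", {
  ph <- fix_tube30()
  gs <- perturb_ensemble(ph, perturbation_spec(radius_noise = 0.1,
                                               n_groups = 2, seed = 9))
  dir <- withr::local_tempdir()
  write_ensemble(gs, dir)
  files <- list.files(dir)
  expect_identical(files, c("group_01.stl", "group_02.stl"))
  back <- read_ensemble(dir)
  expect_identical(length(back), 2L)
  expect_equal(surface_area(back[[1]]), surface_area(gs[[1]]),
               tolerance = 1e-5)
})
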