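# Ostium detection, sac isolation and the morphological parameters.

test_that("nsi evaluates its closed forms exactly", {
  # sphere: V = 4pi/3, S = 4pi reduces to 1 - 2^(-1/3)
  expect_equal(nsi(4 * pi / 3, 4 * pi), 1 - 2^(-1 / 3), tolerance = 1e-12)
  # unit cube
  expect_equal(nsi(1, 6), 1 - (18 * pi)^(1 / 3) / 6, tolerance = 1e-12)
  # degenerate volume
  expect_equal(nsi(0, 5), 1)
  expect_error(nsi(1, 0), class = "aneumorph_domain_error")
  expect_error(nsi(-1, 5), class = "aneumorph_domain_error")
})

test_that("nsi is scale-invariant and monotone in V at fixed S", {
  set.seed(5)
  for (i in 1:25) {
    V <- runif(1, 0.1, 100)
    S <- (36 * pi)^(1 / 3) * V^(2 / 3) * runif(1, 1, 3)  # physical S >= sphere S
    k <- runif(1, 0.1, 10)
    expect_equal(nsi(k^3 * V, k^2 * S), nsi(V, S), tolerance = 1e-12)
  }
  S <- 50
  Vs <- seq(1, 30, length.out = 10)
  expect_true(all(diff(vapply(Vs, nsi, numeric(1), S = S)) < 0))
})

test_that("elongating a sac at fixed mesh family increases nsi", {
  # prolate ellipsoids with axis ratio 1 -> 3 (meshed, volume-normalised)
  vals <- vapply(c(1, 1.5, 2, 3), function(ar) {
    e <- icosphere(1, 3)
    e$vertices[, 3] <- e$vertices[, 3] * ar
    e$vertices <- e$vertices / ar^(1 / 3)     # keep the volume fixed
    nsi(enclosed_volume(e), surface_area(e))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # the (discretised) sphere sits at the NSI minimum 1 - 2^(-1/3)
  expect_lt(abs(vals[1] - (1 - 2^(-1 / 3))), 0.01)
})

test_that("ostium detection recovers constructed neck areas", {
  ph <- fix_sac_phantom()      # sphere r=3 on tube r=2, neck a=1.2
  ost <- fix_sac_ostium()
  expect_s3_class(ost, "ostium_plane")
  expect_lt(abs(ost$area - pi * 1.2^2) / (pi * 1.2^2), 0.1)
  # normal points from the vessel toward the sac (+z here)
  expect_gt(ost$normal[3], 0.9)
  # neck curve is planar within tolerance
  sd <- abs((ost$neck_curve - matrix(ost$origin, nrow(ost$neck_curve), 3,
                                     byrow = TRUE)) %*% ost$normal)
  expect_lt(max(sd), 1e-6)

  # widened neck: area tracks pi a^2
  ph2 <- make_phantom(phantom_spec(length = 24, radius = 2,
                                   sac = list(neck_radius = 2,
                                              sac_radius = 3,
                                              station = 12),
                                   grid = 0.22, label = "wide"))
  cl2 <- extract_centerline(ph2$surface, c(3, 0, 0), c(21, 0, 0),
                            voxel = 0.3)
  ost2 <- detect_ostium(ph2$surface, ph2$truth$sac_center, cl2)
  expect_lt(abs(ost2$area - pi * 4) / (pi * 4), 0.1)
})

test_that("a plain vessel yields an isolation error", {
  ph <- fix_tube30()
  cl <- extract_centerline(ph$surface, c(3, 0, 0), c(27, 0, 0), voxel = 0.3)
  expect_error(detect_ostium(ph$surface, c(15, 0, 0.5), cl),
               class = "aneumorph_isolation_error")
})

test_that("ostium area is locally minimal against normal perturbations", {
  ph <- fix_sac_phantom()
  ost <- fix_sac_ostium()
  cl <- fix_sac_cl()
  ends <- rbind(cl$points[1, ], cl$points[nrow(cl$points), ])
  tb <- aneumorph:::.plane_basis(ost$normal)
  set.seed(9)
  for (i in 1:10) {
    ang <- 10 * pi / 180
    phi <- runif(1, 0, 2 * pi)
    n2 <- aneumorph:::.unit(cos(ang) * ost$normal +
                              sin(ang) * (cos(phi) * tb$u + sin(phi) * tb$v))
    sc <- aneumorph:::.ostium_score(ph$surface, ost$origin, n2,
                                    ph$truth$sac_center, ends, NULL)
    if (!is.null(sc))
      expect_gte(sc$area, ost$area * 0.999)
  }
})

test_that("sac isolation recovers spherical-cap volume and lateral area", {
  ph <- fix_sac_phantom()
  ost <- fix_sac_ostium()
  sac <- isolate_sac(ph$surface, ost)
  expect_true(validate_surface(sac$sac_surface,
                               check_self_intersection = FALSE)$watertight)
  expect_lt(abs(sac$volume - ph$truth$sac_volume) / ph$truth$sac_volume,
            0.05)
  expect_lt(abs(sac$lateral_area - ph$truth$sac_lateral_area) /
              ph$truth$sac_lateral_area, 0.05)
  expect_gt(sac$cap_area, 0)

  # ostium plane that misses the surface entirely
  bad <- ostium_plane(origin = c(12, 0, 50), normal = c(0, 0, 1),
                      neck_curve = ost$neck_curve, area = ost$area,
                      dome_seed = c(12, 0, 51))
  expect_error(isolate_sac(ph$surface, bad), class = "aneumorph_error")
})

test_that("hemisphere cut of a sphere matches closed forms", {
  # icosphere r=3 cut at the equator: V = 2 pi 27 / 3, lateral S = 2 pi 9
  ball <- icosphere(3, 4)
  ost <- ostium_plane(origin = c(0, 0, 0), normal = c(0, 0, 1),
                      neck_curve = cbind(3 * cos(seq(0, 2 * pi,
                                                     length.out = 65))[-65],
                                         3 * sin(seq(0, 2 * pi,
                                                     length.out = 65))[-65],
                                         0),
                      area = 9 * pi, dome_seed = c(0, 0, 1.5))
  hemi <- isolate_sac(ball, ost)
  expect_lt(abs(hemi$volume - 2 * pi * 27 / 3) / (2 * pi * 27 / 3), 0.02)
  expect_lt(abs(hemi$lateral_area - 2 * pi * 9) / (2 * pi * 9), 0.02)
})

test_that("cutting conserves volume between sac and remainder", {
  ph <- fix_sac_phantom()
  ost <- fix_sac_ostium()
  total <- enclosed_volume(ph$surface)
  up <- aneumorph:::clip_surface(ph$surface, ost$origin, ost$normal,
                                 cap = TRUE)
  dn <- aneumorph:::clip_surface(ph$surface, ost$origin, -ost$normal,
                                 cap = TRUE)
  v_up <- enclosed_volume(orient_outward(up$surface))
  v_dn <- enclosed_volume(orient_outward(dn$surface))
  expect_equal(v_up + v_dn, total, tolerance = 1e-6)
})

test_that("parent cross-sections are circular where the vessel is", {
  ph <- fix_sac_phantom()
  cl <- fix_sac_cl()
  a <- parent_cross_section(ph$surface, cl, station = 5)
  expect_lt(abs(a - 4 * pi) / (4 * pi), 0.01)
  expect_error(parent_cross_section(ph$surface, cl, station = 1e4),
               class = "aneumorph_section_error")
})

test_that("morphometrics composes the stages and isolates failures", {
  ph <- fix_sac_phantom()
  cl <- fix_sac_cl()
  mo <- morphometrics(ph$surface, ph$truth$sac_center, cl)
  expect_lt(abs(mo$ostium_area - ph$truth$ostium_area) /
              ph$truth$ostium_area, 0.1)
  expect_lt(abs(mo$volume - ph$truth$sac_volume) / ph$truth$sac_volume,
            0.05)
  expect_lt(abs(mo$parent_area - 4 * pi) / (4 * pi), 0.03)
  expect_true(mo$nsi >= 0 && mo$nsi <= 1)
  expect_gt(mo$nsi_with_cap, mo$nsi)   # extra cap area raises the index
  expect_lt(mo$proximal_station,
            cl$arclength[which.min(abs(cl$points[, 1] - 12))])

  # melted case: stage-labelled error from the ostium stage
  tube <- fix_tube30()
  cl_t <- extract_centerline(tube$surface, c(3, 0, 0), c(27, 0, 0),
                             voxel = 0.3)
  err <- tryCatch(morphometrics(tube$surface, c(15, 0, 1), cl_t),
                  error = function(e) e)
  expect_s3_class(err, "aneumorph_stage_error")
  expect_match(conditionMessage(err), "detect_ostium")
})

test_that("a perturbed ensemble yields records without crashing", {
  ph <- fix_sac_phantom()
  groups <- perturb_ensemble(ph, perturbation_spec(n_groups = 4, seed = 2,
                                                   radius_noise = 0.13))
  got <- 0
  for (g in groups) {
    cl <- extract_centerline(g, c(3, 0, 0), c(21, 0, 0), voxel = 0.3)
    mo <- tryCatch(morphometrics(g, ph$truth$sac_center, cl),
                   error = function(e) NULL)
    if (!is.null(mo)) {
      got <- got + 1
      expect_true(mo$volume > 0 && mo$ostium_area > 0)
    }
  }
  expect_gte(got, 3)
})
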