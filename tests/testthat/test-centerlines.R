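# Centerline extraction, inscribed-radius and velocity profiles.
# Seeds sit at least one vessel radius clear of the end caps so the medial
# axis is wall-limited (not cap-limited) at every evaluated station.

test_that("straight-tube centerline recovers the axis and the radius", {
  ph <- fix_tube40()
  cl <- fix_tube40_cl()
  off <- sqrt(cl$points[, 2]^2 + cl$points[, 3]^2)
  expect_lt(max(off), 0.2)
  interior <- cl$points[, 1] > 4 & cl$points[, 1] < 36
  expect_lt(max(abs(cl$radius[interior] - 2)) / 2, 0.02)
  expect_true(all(diff(cl$arclength) > 0))
  # path length at least the Euclidean seed separation
  expect_gte(max(cl$arclength),
             sqrt(sum((cl$points[nrow(cl$points), ] - cl$points[1, ])^2)))
})

test_that("bent-tube centerline follows the analytic arc", {
  spec <- phantom_spec(length = pi / 2 * 10, radius = 2, path = "arc",
                       bend_radius = 10, bend_angle = 90, grid = 0.25,
                       label = "bend")
  ph <- make_phantom(spec)
  s0 <- aneumorph:::.path_point(spec, 3)$p
  s1 <- aneumorph:::.path_point(spec, pi / 2 * 10 - 3)$p
  cl <- extract_centerline(ph$surface, s0, s1, voxel = 0.25)
  rho <- sqrt(cl$points[, 1]^2 + (cl$points[, 2] - 10)^2)
  arc_dev <- sqrt((rho - 10)^2 + cl$points[, 3]^2)
  expect_lt(max(arc_dev), 0.3)
  expect_lt(max(abs(cl$radius - 2)) / 2, 0.02)
})

test_that("tapering cone yields a linear inscribed-radius profile", {
  ph <- make_phantom(phantom_spec(length = 20, radius = c(3, 1),
                                  grid = 0.2, label = "cone"))
  cl <- extract_centerline(ph$surface, c(3.5, 0, 0), c(17.5, 0, 0),
                           voxel = 0.15)
  x <- cl$points[, 1]
  interior <- x > 4.5 & x < 16.5
  # slanted wall: inscribed radius is r(x) * cos(atan(|dr/dx|))
  r_true <- (3 - 0.1 * x) * cos(atan(0.1))
  expect_lt(max(abs(cl$radius[interior] - r_true[interior]) /
                  r_true[interior]), 0.02)
  fit <- stats::lm(cl$radius[interior] ~ x[interior])
  expect_lt(abs(unname(stats::coef(fit)[2]) + 0.1) / 0.1, 0.05)
})

test_that("seed handling: degenerate, outside-lumen and disconnected", {
  ph <- fix_tube40()
  expect_error(extract_centerline(ph$surface, c(5, 0, 0), c(5, 0, 0)),
               class = "aneumorph_seed_error")
  expect_error(extract_centerline(ph$surface, c(5, 10, 0), c(35, 0, 0),
                                  voxel = 0.3),
               class = "aneumorph_seed_error")
})

test_that("inscribed_radius matches exact wall distances and flags exits", {
  ph <- fix_tube40()
  cl <- centerline(cbind(seq(5, 35, by = 1), 0, 0))
  cl <- inscribed_radius(cl, ph$surface)
  expect_lt(max(abs(cl$radius - 2)) / 2, 0.01)
  # an off-axis interior point 0.5 mm from the wall
  cl2 <- inscribed_radius(centerline(rbind(c(20, 1.5, 0), c(21, 1.5, 0))),
                          ph$surface)
  expect_equal(cl2$radius[1], 0.5, tolerance = 0.02)
  outside <- centerline(rbind(c(20, 0, 0), c(20, 5, 0), c(21, 5, 0)))
  expect_error(inscribed_radius(outside, ph$surface),
               class = "aneumorph_negative_distance_error")
})

test_that("shorter tubes give shorter centerlines (monotone in length)", {
  lens <- c(20, 30)
  got <- vapply(lens, function(L) {
    ph <- make_phantom(phantom_spec(length = L, radius = 2, grid = 0.3))
    cl <- extract_centerline(ph$surface, c(3, 0, 0), c(L - 3, 0, 0),
                             voxel = 0.3)
    max(cl$arclength)
  }, numeric(1))
  expect_lt(got[1], got[2])
  expect_equal(got, lens - 6, tolerance = 0.05)
})

test_that("centerline velocity sampling matches plug and Poiseuille fields", {
  ph <- fix_tube30()
  cl <- extract_centerline(ph$surface, c(3, 0, 0), c(27, 0, 0), voxel = 0.25)
  # uniform plug 0.3 m/s
  vox <- voxelize_interior(ph$surface, 0.4)
  ins <- which(vox$mask)
  dims <- dim(vox$mask)
  P <- cbind(vox$gx[((ins - 1) %% dims[1]) + 1],
             vox$gy[((ins - 1) %/% dims[1]) %% dims[2] + 1],
             vox$gz[((ins - 1) %/% (dims[1] * dims[2])) + 1])
  plug <- steady_field(P, c(0.3, 0, 0), weights = rep(0.4^3, nrow(P)))
  v <- sample_velocity_magnitude(cl, plug)
  expect_equal(v, rep(0.3, nrow(cl$points)), tolerance = 1e-9)

  # Poiseuille, Q = 2 ml/s: axis speed 2Q/(pi r^2)
  wave <- two_harmonic_waveform(q_mean = 2, a1 = 0, a2 = 0, n = 5)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.3, n_times = 5)
  v2 <- sample_velocity_magnitude(cl, fl$volume)
  mid <- cl$points[, 1] > 6 & cl$points[, 1] < 24
  expect_lt(max(abs(v2[mid] - 2 * 2 / (pi * 4)) / (2 * 2 / (pi * 4))), 0.02)

  # steady single-snapshot field: cycle average equals the snapshot
  snap <- field_series(P, rep(1, nrow(P)),
                       array(0.25, c(nrow(P), 1, 3)), times = 0,
                       period = 1)
  v3 <- sample_velocity_magnitude(cl, snap)
  expect_equal(v3, rep(sqrt(3) * 0.25, nrow(cl$points)), tolerance = 1e-9)

  # coverage error when the field misses the centerline region
  far <- steady_field(P + 50, c(0.3, 0, 0))
  expect_error(sample_velocity_magnitude(cl, far),
               class = "aneumorph_coverage_error")
})

test_that("profile matching aligns groups on a common abscissa", {
  mk <- function(L, r) {
    pts <- cbind(seq(0, L, by = 0.5), 0, 0)
    centerline(pts, radius = rep(r, nrow(pts)))
  }
  expect_error(match_profiles(list(mk(30, 2))),
               class = "aneumorph_ensemble_error")

  # identical groups: zero band everywhere
  mp <- match_profiles(list(mk(30, 2), mk(30, 2), mk(30, 2)), step = 1)
  b <- profile_band(mp)
  expect_equal(max(b$std, na.rm = TRUE), 0)
  expect_equal(b$band_mean_std, 0)

  # unequal lengths: absent (not zero-filled) beyond a group's reach
  mp2 <- match_profiles(list(mk(30, 2), mk(40, 2)), step = 1)
  expect_identical(length(mp2$abscissa), 41L)
  expect_true(all(is.na(mp2$values[1, mp2$abscissa > 30 + 1e-9])))
  expect_true(all(!is.na(mp2$values[2, ])))
  b2 <- profile_band(mp2)
  expect_true(all(b2$n[mp2$abscissa > 30 + 1e-9] == 1))

  # hand-computed station statistics
  mp3 <- match_profiles(list(mk(10, 2.0), mk(10, 2.2), mk(10, 2.4)),
                        step = 1)
  b3 <- profile_band(mp3)
  expect_equal(unname(b3$mean[3]), 2.2, tolerance = 1e-12)
  expect_equal(unname(b3$std[3]), 0.2, tolerance = 1e-12)
  mp4 <- match_profiles(list(mk(10, 1), mk(10, 3)), step = 1)
  expect_equal(profile_band(mp4)$std[1], sqrt(2), tolerance = 1e-12)
})

test_that("profile band is shift-invariant and scales linearly", {
  set.seed(11)
  mk <- function(vals) centerline(cbind(seq_along(vals) - 1, 0, 0),
                                  radius = vals)
  base <- lapply(1:5, function(i) 2 + rnorm(21, sd = 0.1))
  cls <- lapply(base, mk)
  b0 <- profile_band(match_profiles(cls, step = 1))
  cls_shift <- lapply(base, function(v) mk(v + 3))
  b1 <- profile_band(match_profiles(cls_shift, step = 1))
  expect_equal(b1$std, b0$std, tolerance = 1e-12)
  cls_scale <- lapply(base, function(v) mk(2.5 * v))
  b2 <- profile_band(match_profiles(cls_scale, step = 1))
  expect_equal(b2$std, 2.5 * b0$std, tolerance = 1e-12)
})

test_that("centerline exporters write readable files", {
  cl <- centerline(cbind(0:10, 0, 0), radius = rep(2, 11))
  csvp <- withr::local_tempfile(fileext = ".csv")
  plyp <- withr::local_tempfile(fileext = ".ply")
  write_centerline_csv(cl, csvp)
  df <- utils::read.csv(csvp)
  expect_identical(names(df), c("x", "y", "z", "arclength", "radius"))
  expect_identical(nrow(df), 11L)
  write_centerline_ply(cl, plyp)
  expect_true(any(grepl("element edge 10", readLines(plyp))))
  mp <- match_profiles(list(cl, cl), step = 1)
  wp <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(mp, wp)
  expect_identical(ncol(utils::read.csv(wp)), 3L)
})
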