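# AWSS, OSI, flux integrals and sac means against closed forms.

test_that("cycle_average handles constants, sines and rectified sines", {
  expect_equal(cycle_average(2, times = 0.3), 2)
  t <- seq(0, 1, length.out = 513)
  expect_lt(abs(cycle_average(sin(2 * pi * t), t)), 1e-3)
  tau0 <- 1.7
  expect_equal(cycle_average(tau0 * abs(sin(2 * pi * t)), t),
               2 * tau0 / pi, tolerance = 1e-3)
  expect_error(cycle_average(numeric(0), numeric(0)),
               class = "aneumorph_domain_error")
})

test_that("awss reproduces constant, rectified-sine and Poiseuille shear", {
  t <- seq(0, 1, length.out = 513)
  k <- 3
  # constant vector (2, 0, 0) Pa
  vals <- array(0, c(k, length(t), 3))
  vals[, , 1] <- 2
  expect_equal(awss(wall_history(vals, t)), rep(2, k), tolerance = 1e-12)
  # tau0 * sin along x: AWSS = 2 tau0 / pi
  tau0 <- 0.8
  vals2 <- array(0, c(k, length(t), 3))
  vals2[, , 1] <- matrix(tau0 * sin(2 * pi * t), k, length(t), byrow = TRUE)
  expect_equal(awss(wall_history(vals2, t)), rep(2 * tau0 / pi, k),
               tolerance = 1e-3)
  # steady Poiseuille wall field at r = 2 mm, Q = 2 ml/s
  ph <- fix_tube30()
  wave <- two_harmonic_waveform(q_mean = 2, a1 = 0, a2 = 0, n = 5)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.4, n_times = 5)
  cen <- fl$wall$points
  on_wall <- abs(sqrt(cen[, 2]^2 + cen[, 3]^2) - 2) < 0.1 &
             cen[, 1] > 5 & cen[, 1] < 25
  tau_exact <- 4 * 0.004 * 2e-6 / (pi * (2e-3)^3)
  a <- awss(fl$wall)[on_wall]
  expect_lt(max(abs(a - tau_exact)) / tau_exact, 0.02)
})

test_that("osi hits its closed-form cases", {
  t <- seq(0, 1, length.out = 257)
  # constant direction, varying magnitude -> 0
  vals <- array(0, c(2, length(t), 3))
  vals[, , 1] <- matrix(1 + 0.5 * sin(2 * pi * t), 2, length(t),
                        byrow = TRUE)
  expect_equal(as.numeric(osi(wall_history(vals, t))), c(0, 0),
               tolerance = 1e-12)
  # symmetric reversal -> 0.5
  vals2 <- array(0, c(1, length(t), 3))
  vals2[, , 1] <- sin(2 * pi * t)
  expect_equal(as.numeric(osi(wall_history(vals2, t))), 0.5,
               tolerance = 1e-9)
  # half cycle +1, half cycle -0.5 -> exactly 1/3 (|net| T/4 over 3T/4)
  eps <- 1e-12
  t3 <- c(0, 0.5 - eps, 0.5 + eps, 1)
  vals3 <- array(0, c(1, 4, 3))
  vals3[1, , 1] <- c(1, 1, -0.5, -0.5)
  expect_equal(as.numeric(osi(wall_history(vals3, t3))), 1 / 3,
               tolerance = 1e-9)
  # zero shear everywhere -> 0 by convention, counted
  vals4 <- array(0, c(3, 4, 3))
  o <- osi(wall_history(vals4, t3))
  expect_equal(as.numeric(o), c(0, 0, 0))
  expect_identical(attr(o, "zero_shear_samples"), 3L)
})

test_that("osi stays in [0, 0.5] and satisfies the AWSS identity", {
  set.seed(21)
  n_hist <- 10000L
  nt <- 24L
  t <- seq(0, 1, length.out = nt)
  vals <- array(rnorm(n_hist * nt * 3), c(n_hist, nt, 3))
  wf <- wall_history(vals, t)
  o <- as.numeric(osi(wf))
  expect_true(all(o >= 0 & o <= 0.5))
  a <- awss(wf)
  tw <- aneumorph:::.trapz_weights(t)
  mean_vec <- cbind(vals[, , 1] %*% tw, vals[, , 2] %*% tw,
                    vals[, , 3] %*% tw) / (t[nt] - t[1])
  expect_equal((1 - 2 * o) * a, sqrt(rowSums(mean_vec^2)),
               tolerance = 1e-9)
})

test_that("plane_flux integrates plug and Poiseuille profiles", {
  # plug 0.5 m/s through a 4 mm^2 disc
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  r_disc <- sqrt(4 / pi)
  loop <- cbind(r_disc * cos(th), r_disc * sin(th), 0)
  set.seed(3)
  pts <- cbind(runif(600, -1.5, 1.5), runif(600, -1.5, 1.5),
               runif(600, -1, 1))
  plug <- steady_field(pts, c(0, 0, 0.5))
  fx <- plane_flux(plug, list(origin = c(0, 0, 0), normal = c(0, 0, 1)),
                   loop = loop)
  # quadrature area times plug speed; the 64-gon area is 0.16% under pi r^2
  expect_equal(fx$q, rep(0.5 * fx$area, length(fx$times)),
               tolerance = 1e-9)
  expect_lt(abs(fx$area - 4) / 4, 0.005)
  expect_equal(fx$q_in, fx$q, tolerance = 1e-12)
  # flipped normal: signed flux negates, positive part vanishes
  fx2 <- plane_flux(plug, list(origin = c(0, 0, 0), normal = c(0, 0, -1)),
                    loop = loop)
  expect_equal(fx2$q, -fx$q, tolerance = 1e-12)
  expect_equal(fx2$q_in, rep(0, length(fx2$times)), tolerance = 1e-12)

  # Poiseuille tube, Q = 3 ml/s, via the full section machinery
  ph <- fix_tube30()
  wave <- two_harmonic_waveform(q_mean = 3, a1 = 0, a2 = 0, n = 5)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.3, n_times = 5)
  cl <- extract_centerline(ph$surface, c(3, 0, 0), c(27, 0, 0),
                           voxel = 0.3)
  vf <- vessel_flow_rate(fl$volume, ph$surface, cl, station = 12)
  expect_lt(abs(vf$rate - 3) / 3, 0.02)
})

test_that("refining the section quadrature reduces the Poiseuille error", {
  ph <- fix_tube30()
  wave <- two_harmonic_waveform(q_mean = 3, a1 = 0, a2 = 0, n = 3)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.3, n_times = 3)
  loops <- aneumorph:::.section_loops(ph$surface, c(15, 0, 0), c(1, 0, 0))
  loop <- loops[[1]]
  errs <- vapply(c(1L, 2L, 4L), function(k) {
    fx <- plane_flux(fl$volume, list(origin = c(15, 0, 0),
                                     normal = c(1, 0, 0)),
                     loop = loop, refine = k)
    abs(mean(fx$q) - 3)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("flux is conserved between inlet and outlet sections", {
  ph <- fix_tube30()
  wave <- two_harmonic_waveform(q_mean = 2, n = 9)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.3, n_times = 9)
  cl <- extract_centerline(ph$surface, c(3, 0, 0), c(27, 0, 0),
                           voxel = 0.3)
  q_in <- vessel_flow_rate(fl$volume, ph$surface, cl, station = 4)$rate
  q_out <- vessel_flow_rate(fl$volume, ph$surface, cl, station = 20)$rate
  expect_lt(abs(q_in - q_out) / abs(q_in), 0.01)
})

test_that("neck inflow integrates only the sac-directed flux", {
  # half-in / half-out steady field over a 10 mm^2 disc: u.n = +-0.1 m/s
  r_disc <- sqrt(10 / pi)
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  loop <- cbind(r_disc * cos(th), r_disc * sin(th), 0)
  gx <- seq(-2.2, 2.2, by = 0.15)
  pts <- as.matrix(expand.grid(x = gx, y = gx, z = c(-0.2, 0, 0.2)))
  k <- nrow(pts)
  vals <- array(0, c(k, 2, 3))
  vals[, , 3] <- matrix(ifelse(pts[, 1] > 0, 0.1, -0.1), k, 2)
  f <- field_series(pts, rep(1, k), vals, c(0, 1), period = 1)
  ost <- ostium_plane(origin = c(0, 0, 0), normal = c(0, 0, 1),
                      neck_curve = loop, area = 10,
                      dome_seed = c(0, 0, 1))
  got <- neck_inflow_rate(f, ost)
  expect_equal(got, 0.5, tolerance = 0.03)   # 0.1 m/s over half of 10 mm^2
  # signed flux nets to ~0, so inflow must dominate it
  fx <- plane_flux(f, ost)
  expect_lt(abs(cycle_average(fx$q, fx$times)), 0.02)
  expect_gte(got, cycle_average(fx$q, fx$times))
  # zero field and full plug limits
  vals0 <- array(0, c(k, 2, 3))
  f0 <- field_series(pts, rep(1, k), vals0, c(0, 1), period = 1)
  expect_equal(neck_inflow_rate(f0, ost), 0)
  vals1 <- array(0, c(k, 2, 3))
  vals1[, , 3] <- 0.1
  f1 <- field_series(pts, rep(1, k), vals1, c(0, 1), period = 1)
  expect_equal(neck_inflow_rate(f1, ost), 1, tolerance = 0.01)
})

test_that("sac means are weighted means of the cycle-averaged fields", {
  # direct weighted-mean check: volumes {1, 3} mm^3, speeds {0.2, 0.1} m/s
  ph <- fix_sac_phantom()
  ost <- fix_sac_ostium()
  sac <- isolate_sac(ph$surface, ost)
  c0 <- ph$truth$sac_center
  pts <- rbind(c0 + c(0.3, 0, 0), c0 - c(0.3, 0, 0))
  vals <- array(0, c(2, 2, 3))
  vals[1, , 1] <- 0.2
  vals[2, , 1] <- 0.1
  f <- field_series(pts, c(1, 3), vals, c(0, 1), period = 1)
  # uniform wall shear 1.64 Pa on every wall sample
  wcen <- aneumorph:::.tri_centroids(sac$sac_surface)
  war <- aneumorph:::.tri_areas(sac$sac_surface)
  wvals <- array(0, c(nrow(wcen), 2, 3))
  wvals[, , 2] <- 1.64
  wf <- field_series(wcen, pmax(war, 1e-9), wvals, c(0, 1), period = 1,
                     kind = "wall")
  sm <- sac_means(f, wf, sac)
  expect_equal(sm$mean_velocity, (1 * 0.2 + 3 * 0.1) / 4,
               tolerance = 1e-9)
  expect_equal(sm$mean_wss, 1.64, tolerance = 1e-9)
  # plane masking agrees with the mesh test on this geometry
  sm2 <- sac_means(f, wf, sac, mask_method = "plane")
  expect_equal(sm2$mean_velocity, sm$mean_velocity, tolerance = 1e-9)
  # empty region
  far <- field_series(pts + 100, c(1, 3), vals, c(0, 1), period = 1)
  expect_error(sac_means(far, wf, sac), class = "aneumorph_coverage_error")
})

test_that("sac rotation field reproduces the prescribed mean speed", {
  ph <- fix_sac_phantom()
  wave <- two_harmonic_waveform(q_mean = 2, n = 9)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.25, n_times = 9,
                      sac_mean_speed = 0.1, sac_wall_wss = 2)
  sac <- isolate_sac(ph$surface, fix_sac_ostium())
  sm <- sac_means(fl$volume, fl$wall, sac)
  expect_equal(sm$mean_velocity, 0.1, tolerance = 0.01)
  expect_equal(sm$mean_wss, 2, tolerance = 0.02)
})

test_that("isovelocity fraction thresholds cycle-averaged speeds", {
  set.seed(4)
  pts <- matrix(runif(300), 100, 3)
  f_hi <- steady_field(pts, c(0.4, 0, 0))
  f_lo <- steady_field(pts, c(0.2, 0, 0))
  expect_equal(isovelocity_fraction(f_hi, 0.3), 1)
  expect_equal(isovelocity_fraction(f_lo, 0.3), 0)
  # Poiseuille: u >= u_max/2 inside r/sqrt(2), i.e. half the area
  ph <- make_phantom(phantom_spec(length = 14, radius = 2, grid = 0.3,
                                  label = "short"))
  wave <- two_harmonic_waveform(q_mean = 2, a1 = 0, a2 = 0, n = 3)
  fl <- analytic_flow(ph, wave, sample_spacing = 0.14, n_times = 3)
  P <- fl$volume$points
  trunk <- P[, 1] > 3 & P[, 1] < 11
  u_max <- 2 * 2 / (pi * 4)
  frac <- isovelocity_fraction(
    field_series(P[trunk, ], fl$volume$weights[trunk],
                 fl$volume$values[trunk, , , drop = FALSE],
                 fl$volume$times, fl$volume$period),
    threshold = u_max / 2)
  expect_equal(frac, 0.5, tolerance = 0.02)
})
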