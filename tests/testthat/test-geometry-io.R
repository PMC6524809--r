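# Surface ingestion, validation and basic measures.

test_that("STL round trips merge per-facet vertices back to a clean mesh", {
  cube <- unit_cube()
  tmp_a <- withr::local_tempfile(fileext = ".stl")
  tmp_b <- withr::local_tempfile(fileext = ".stl")
  tmp_p <- withr::local_tempfile(fileext = ".ply")

  write_surface(cube, tmp_a, "stl_ascii")
  got <- read_surface(tmp_a)
  # 12 facets x 3 vertex records collapse to the 8 cube corners
  expect_identical(nrow(got$vertices), 8L)
  expect_identical(nrow(got$triangles), 12L)
  expect_identical(unname(attr(got, "repairs")["merged_vertices"]), 28L)
  expect_equal(enclosed_volume(orient_outward(got)), 1)

  write_surface(cube, tmp_b, "stl")
  got_b <- read_surface(tmp_b)
  expect_identical(nrow(got_b$vertices), 8L)
  expect_equal(surface_area(got_b), 6)

  write_surface(cube, tmp_p, "ply")
  got_p <- read_surface(tmp_p)
  expect_identical(nrow(got_p$vertices), 8L)
  expect_identical(nrow(got_p$triangles), 12L)
})

test_that("OBJ reader handles v/vt/vn faces and polygon fans", {
  tmp <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1/1/1 2/2/1 3/3/1 4/4/1"), tmp)
  got <- read_surface(tmp)
  expect_identical(nrow(got$triangles), 2L)   # quad fan-triangulated
  expect_equal(surface_area(got), 1)
})

test_that("degenerate files raise format errors", {
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_surface(empty), class = "aneumorph_format_error")
  junk <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a mesh", junk)
  expect_error(read_surface(junk), class = "aneumorph_format_error")
  expect_error(read_surface(tempfile(fileext = ".stl")),
               class = "aneumorph_format_error")
})

test_that("validation reports watertightness, open edges and orientation", {
  ico <- icosphere(1, 2)
  v <- validate_surface(ico, check_self_intersection = FALSE)
  expect_true(v$watertight)
  expect_identical(v$open_edges, 0L)
  expect_true(v$consistently_oriented)
  expect_identical(v$signed_volume_sign, 1)

  # removing one square face (2 triangles) leaves the 4 boundary edges
  cube <- unit_cube()
  holed <- tri_surface(cube$vertices, cube$triangles[-c(1, 2), ],
                       clean = FALSE)
  vh <- validate_surface(holed, check_self_intersection = FALSE)
  expect_false(vh$watertight)
  expect_identical(vh$open_edges, 4L)
  expect_error(enclosed_volume(holed), class = "aneumorph_precondition_error")
})

test_that("self-intersection is flagged for interpenetrating spheres", {
  a <- icosphere(1, 2)
  # generic position: avoid the mirror symmetry that would put crossings
  # exactly on triangle edges
  b <- icosphere(1.07, 2, center = c(1.2, 0.13, 0.077))
  merged <- tri_surface(rbind(a$vertices, b$vertices),
                        rbind(a$triangles, b$triangles + nrow(a$vertices)),
                        clean = FALSE)
  expect_true(validate_surface(merged)$self_intersecting)
  # disjoint spheres do not intersect
  c_ <- icosphere(1, 2, center = c(3, 0, 0))
  merged2 <- tri_surface(rbind(a$vertices, c_$vertices),
                         rbind(a$triangles, c_$triangles + nrow(a$vertices)),
                         clean = FALSE)
  expect_false(validate_surface(merged2)$self_intersecting)
})

test_that("area and volume match closed forms and converge on spheres", {
  cube <- unit_cube()
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)
  tri <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)), clean = FALSE)
  expect_equal(surface_area(tri), 0.5)

  ico3 <- icosphere(1, 3)
  expect_lt(abs(surface_area(ico3) - 4 * pi) / (4 * pi), 0.01)
  expect_lt(abs(enclosed_volume(ico3) - 4 * pi / 3) / (4 * pi / 3), 0.01)
  # inscribed polyhedra: volume increases monotonically with subdivision
  vols <- vapply(1:3, function(s) enclosed_volume(icosphere(1, s)),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 * pi / 3))

  # inverted winding still yields the positive volume after orientation
  flipped <- cube
  flipped$triangles <- flipped$triangles[, c(1, 3, 2)]
  expect_identical(validate_surface(flipped,
                                    check_self_intersection = FALSE
                                    )$signed_volume_sign, -1)
  expect_equal(enclosed_volume(orient_outward(flipped)), 1)
})

test_that("area and volume are invariant under rigid motion", {
  ico <- icosphere(1.3, 2)
  a0 <- surface_area(ico)
  v0 <- enclosed_volume(ico)
  set.seed(42)
  for (rep in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    moved <- ico
    moved$vertices <- sweep(ico$vertices %*% (Rx %*% Rz), 2,
                            runif(3, -50, 50), "+")
    expect_equal(surface_area(moved), a0, tolerance = 1e-9)
    expect_equal(enclosed_volume(moved), v0, tolerance = 1e-9)
  }
})

test_that("watertight flag agrees with a brute-force edge-incidence oracle", {
  check_one <- function(surface) {
    Tm <- surface$triangles
    keys <- character(0)
    for (i in seq_len(nrow(Tm))) {     # deliberately naive oracle
      e <- rbind(sort(Tm[i, c(1, 2)]), sort(Tm[i, c(2, 3)]),
                 sort(Tm[i, c(1, 3)]))
      keys <- c(keys, paste(e[, 1], e[, 2]))
    }
    oracle <- all(table(keys) == 2)
    expect_identical(validate_surface(surface,
                                      check_self_intersection = FALSE
                                      )$watertight, oracle)
  }
  cube <- unit_cube()
  check_one(cube)
  check_one(icosphere(1, 2))
  check_one(tri_surface(cube$vertices, cube$triangles[-1, ], clean = FALSE))
})

test_that("field series CSV round trip preserves samples and rejects mismatch", {
  set.seed(1)
  pts <- matrix(runif(30), 10, 3)
  times <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- array(rnorm(10 * 5 * 3), c(10, 5, 3))
  fs <- field_series(pts, rep(0.5, 10), vals, times, period = 1)
  pp <- withr::local_tempfile(fileext = ".csv")
  vp <- withr::local_tempfile(fileext = ".csv")
  write_field_series(fs, pp, vp)
  back <- read_field_series(pp, vp, period = 1)
  expect_equal(back$points, fs$points, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$values, fs$values, tolerance = 1e-12)
  expect_equal(back$times, times)

  # row-count mismatch between the two tables is rejected
  pts9 <- utils::read.csv(pp)[1:9, ]
  pp9 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pts9, pp9, row.names = FALSE)
  expect_error(read_field_series(pp9, vp, period = 1),
               class = "aneumorph_format_error")

  # a single time sample is a valid steady field
  fs1 <- field_series(pts, rep(1, 10), array(1, c(10, 1, 3)), times = 0.5,
                      period = 1)
  expect_identical(length(fs1$times), 1L)
  # non-increasing times are rejected
  expect_error(field_series(pts, rep(1, 10), vals, c(0, 0.5, 0.5, 0.75, 1),
                            period = 1),
               class = "aneumorph_format_error")
})

test_that("simulation_config validates the protocol constants", {
  sc <- simulation_config()
  expect_equal(sc$density, 1055)
  expect_equal(sc$viscosity, 0.004)
  expect_equal(sc$time_step, 0.001)
  expect_error(simulation_config(cycles_analyzed = 5, cycles_total = 3),
               class = "aneumorph_domain_error")
  expect_error(simulation_config(density = -1),
               class = "aneumorph_domain_error")
})
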