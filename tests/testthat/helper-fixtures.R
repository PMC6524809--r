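# Shared fixtures, built once per test file and cached.

.fix_env <- new.env(parent = emptyenv())

.fixture <- function(name, builder) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- builder()
  .fix_env[[name]]
}

# 12-triangle unit cube with outward orientation.
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tr <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
              c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
              c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  orient_outward(tri_surface(v, tr, label = "cube"))
}

fix_tube40 <- function() .fixture("tube40", function()
  make_phantom(phantom_spec(length = 40, radius = 2, grid = 0.25,
                            label = "tube40")))

fix_tube30 <- function() .fixture("tube30", function()
  make_phantom(phantom_spec(length = 30, radius = 2, grid = 0.3,
                            label = "tube30")))

fix_sac_phantom <- function() .fixture("sacph", function()
  make_phantom(phantom_spec(length = 24, radius = 2,
                            sac = list(neck_radius = 1.2, sac_radius = 3,
                                       station = 12),
                            grid = 0.26, label = "sacph")))

fix_tube40_cl <- function() .fixture("tube40_cl", function()
  extract_centerline(fix_tube40()$surface, c(3, 0, 0), c(37, 0, 0),
                     voxel = 0.25))

fix_sac_cl <- function() .fixture("sac_cl", function()
  extract_centerline(fix_sac_phantom()$surface, c(3, 0, 0), c(21, 0, 0),
                     voxel = 0.3))

fix_sac_ostium <- function() .fixture("sac_ost", function()
  detect_ostium(fix_sac_phantom()$surface, fix_sac_phantom()$truth$sac_center,
                fix_sac_cl()))

# Steady uniform volumetric field on a grid of points.
steady_field <- function(points, u, weights = NULL, period = 1,
                         times = c(0, 0.5, 1)) {
  k <- nrow(points)
  if (is.null(weights)) weights <- rep(1, k)
  vals <- array(0, c(k, length(times), 3))
  for (j in seq_along(times)) vals[, j, ] <- matrix(u, k, 3, byrow = TRUE)
  field_series(points, weights, vals, times, period, kind = "volumetric")
}

# Wall-type field with a prescribed k x nt x 3 value array on dummy points.
wall_history <- function(values, times, period = max(times)) {
  k <- dim(values)[1]
  field_series(matrix(runif(3 * k), k, 3), rep(1, k), values, times,
               period, kind = "wall")
}
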