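# Time-resolved sampled fields: volumetric velocity (m/s) or wall shear
# stress vectors (Pa) over one cardiac cycle.  Geometry is in mm, field
# values in SI; unit conversion happens only inside flux/metric operations.

#' Time-resolved sampled vector field
#'
#' @param points k x 3 sample coordinates (mm).
#' @param weights length-k strictly positive quadrature weights: volume
#'   (mm^3) for volumetric sets, area (mm^2) for wall sets.
#' @param values numeric array k x nt x 3: vector samples (velocity m/s or
#'   WSS Pa) at each point and time.
#' @param times strictly increasing sample times (s), spanning at most one
#'   period.
#' @param period cardiac cycle length T (s).
#' @param kind `"volumetric"` or `"wall"`.
#' @return an object of class `field_series`.
#' @export
field_series <- function(points, weights, values, times, period,
                         kind = c("volumetric", "wall")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  .assert(ncol(points) == 3, "aneumorph_format_error",
          "points must be k x 3")
  k <- nrow(points)
  .assert(length(weights) == k && all(weights > 0),
          "aneumorph_format_error", "weights must be %d strictly positive values", k)
  .assert(is.array(values) && length(dim(values)) == 3 &&
            all(dim(values)[c(1, 3)] == c(k, 3)) &&
            dim(values)[2] == length(times),
          "aneumorph_format_error",
          "values must be a k x nt x 3 array matching points and times")
  .assert(length(times) >= 1 && all(diff(times) > 0),
          "aneumorph_format_error", "times must be strictly increasing")
  .assert(period > 0, "aneumorph_format_error", "period must be positive")
  .assert(times[length(times)] - times[1] <= period + 1e-12,
          "aneumorph_format_error",
          "time samples span more than one period")
  structure(list(points = points, weights = as.numeric(weights),
                 values = values, times = as.numeric(times),
                 period = as.numeric(period), kind = kind),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("field_series (%s): %d samples x %d times, T = %g s\n",
              x$kind, nrow(x$points), length(x$times), x$period))
  invisible(x)
}

# nt-vector of |v|(t) per sample -> k x nt matrix of magnitudes
.field_magnitudes <- function(field) {
  sqrt(field$values[, , 1]^2 + field$values[, , 2]^2 +
         field$values[, , 3]^2)
}

#' Read a field series from columnar text tables
#'
#' `points_path` is a CSV with columns `x,y,z,w` (mm and mm^3 or mm^2);
#' `values_path` is a CSV whose header row names the components as
#' `<comp>_<time>` triples, e.g. `ux_0.00,uy_0.00,uz_0.00,ux_0.01,...`,
#' one row per sample point.  Lines starting with `#` are treated as
#' metadata; a `# units:` line is recorded but not interpreted (values are
#' taken as declared SI).
#'
#' @param points_path,values_path file paths.
#' @param period cycle period (s).
#' @param kind `"volumetric"` or `"wall"`.
#' @return a [field_series].
#' @export
read_field_series <- function(points_path, values_path, period,
                              kind = c("volumetric", "wall")) {
  kind <- match.arg(kind)
  pts <- utils::read.csv(points_path, comment.char = "#")
  .assert(all(c("x", "y", "z", "w") %in% names(pts)),
          "aneumorph_format_error",
          "points table must have columns x,y,z,w")
  vals <- utils::read.csv(values_path, comment.char = "#",
                          check.names = FALSE)
  .assert(nrow(vals) == nrow(pts), "aneumorph_format_error",
          "row-count mismatch: %d points vs %d value rows",
          nrow(pts), nrow(vals))
  cn <- names(vals)
  comp <- sub("_.*$", "", cn)
  tstr <- sub("^[^_]*_", "", cn)
  .assert(all(comp %in% c("ux", "uy", "uz")), "aneumorph_format_error",
          "value columns must be named ux_<t>, uy_<t>, uz_<t>")
  times <- sort(unique(as.numeric(tstr)))
  .assert(!anyNA(times), "aneumorph_format_error",
          "cannot parse time stamps from value column names")
  nt <- length(times)
  k <- nrow(pts)
  arr <- array(NA_real_, c(k, nt, 3))
  for (j in seq_len(nt)) {
    for (ci in 1:3) {
      col <- which(comp == c("ux", "uy", "uz")[ci] &
                     as.numeric(tstr) == times[j])
      .assert(length(col) == 1, "aneumorph_format_error",
              "missing or duplicated column for component %d at t=%g",
              ci, times[j])
      arr[, j, ci] <- vals[[col]]
    }
  }
  field_series(as.matrix(pts[, c("x", "y", "z")]), pts$w, arr, times,
               period, kind)
}

#' Write a field series to the columnar text format read by
#' [read_field_series()]
#' @param field a [field_series].
#' @param points_path,values_path output paths.
#' @return invisibly, the two paths.
#' @export
write_field_series <- function(field, points_path, values_path) {
  pts <- data.frame(x = field$points[, 1], y = field$points[, 2],
                    z = field$points[, 3], w = field$weights)
  utils::write.csv(pts, points_path, row.names = FALSE)
  nt <- length(field$times)
  cols <- vector("list", 3 * nt)
  nms <- character(3 * nt)
  for (j in seq_len(nt)) {
    for (ci in 1:3) {
      idx <- (j - 1) * 3 + ci
      cols[[idx]] <- field$values[, j, ci]
      nms[idx] <- paste0(c("ux", "uy", "uz")[ci], "_",
                         format(field$times[j], digits = 12))
    }
  }
  df <- as.data.frame(cols)
  names(df) <- nms
  utils::write.csv(df, values_path, row.names = FALSE)
  invisible(c(points_path, values_path))
}

#' Simulation configuration record
#'
#' Records the hemodynamic modelling constants used by the study protocol:
#' incompressible Newtonian blood (density 1055 kg/m^3, dynamic viscosity
#' 0.004 Pa s), 1 ms time step, three simulated cardiac cycles with the
#' last cycle analysed.  The volumetric mesh base size is metadata only.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @param time_step s.
#' @param cycles_total,cycles_analyzed cycle counts.
#' @param mesh_base_size mm (recorded, not used).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(density = 1055, viscosity = 0.004,
                              time_step = 0.001, cycles_total = 3,
                              cycles_analyzed = 1,
                              mesh_base_size = c(0.07, 0.09)) {
  .assert(all(c(density, viscosity, time_step, cycles_total,
                cycles_analyzed, mesh_base_size) > 0),
          "aneumorph_domain_error",
          "all simulation constants must be strictly positive")
  .assert(cycles_analyzed <= cycles_total, "aneumorph_domain_error",
          "cycles_analyzed must not exceed cycles_total")
  structure(list(density = density, viscosity = viscosity,
                 time_step = time_step, cycles_total = cycles_total,
                 cycles_analyzed = cycles_analyzed,
                 mesh_base_size = mesh_base_size),
            class = "simulation_config")
}
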