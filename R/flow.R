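# Hemodynamic post-processing of time-resolved fields: cycle averages,
# time-averaged wall shear stress (AWSS), oscillatory shear index (OSI),
# planar flux integrals, neck inflow rate, sac spatial means and the
# iso-velocity volume fraction.
#
# Conventions: the vector/magnitude order follows the definitions —
# magnitude *inside* the time integral for AWSS, vector integral first in
# the OSI numerator.  Flow rates are reported in ml/s (geometry in mm,
# fields in SI, so ml/s = mm^2 * m/s without any constant).

#' Cycle average of a sampled time series
#'
#' Trapezoidal integral divided by the sampled span; a single sample
#' returns itself.
#' @param values numeric vector of samples.
#' @param times strictly increasing sample times (s).
#' @return scalar average.
#' @export
cycle_average <- function(values, times) {
  .assert(length(values) >= 1, "aneumorph_domain_error",
          "empty series has no cycle average")
  .assert(length(values) == length(times), "aneumorph_domain_error",
          "values and times differ in length")
  if (length(values) == 1L) return(values)
  .assert(all(diff(times) > 0), "aneumorph_domain_error",
          "times must be strictly increasing")
  .trapz(times, values) / (times[length(times)] - times[1])
}

#' Time-averaged wall shear stress per wall sample
#'
#' `AWSS = (1/T) integral |WSS(t)| dt`: magnitude of the instantaneous WSS
#' vector averaged over the cycle, per wall sample point.
#' @param wall a wall [field_series] (Pa).
#' @return numeric vector, one AWSS value (Pa) per wall sample.
#' @export
awss <- function(wall) {
  .assert(inherits(wall, "field_series"), "aneumorph_domain_error",
          "awss needs a field_series")
  mags <- rbind(.field_magnitudes(wall))
  if (length(wall$times) == 1L) return(as.numeric(mags))
  span <- wall$times[length(wall$times)] - wall$times[1]
  as.numeric(mags %*% .trapz_weights(wall$times)) / span
}

#' Oscillatory shear index per wall sample
#'
#' `OSI = 1/2 (1 - |integral WSS dt| / integral |WSS| dt)`: 0 for
#' unidirectional shear, 0.5 for fully reversing shear.  Samples with zero
#' shear over the whole cycle get OSI 0 by convention (no oscillation
#' where there is no shear); their count is reported as an attribute.
#' @param wall a wall [field_series] with at least two time samples.
#' @return numeric vector of OSI values in `[0, 0.5]`.
#' @export
osi <- function(wall) {
  .assert(inherits(wall, "field_series"), "aneumorph_domain_error",
          "osi needs a field_series")
  .assert(length(wall$times) >= 2, "aneumorph_domain_error",
          "osi needs at least two time samples")
  t <- wall$times
  tw <- .trapz_weights(t)
  ix <- as.numeric(rbind(wall$values[, , 1]) %*% tw)
  iy <- as.numeric(rbind(wall$values[, , 2]) %*% tw)
  iz <- as.numeric(rbind(wall$values[, , 3]) %*% tw)
  num <- sqrt(ix^2 + iy^2 + iz^2)
  den <- as.numeric(rbind(.field_magnitudes(wall)) %*% tw)
  out <- numeric(length(den))
  nz <- den > 0
  out[nz] <- 0.5 * (1 - num[nz] / den[nz])
  out <- pmin(pmax(out, 0), 0.5)
  attr(out, "zero_shear_samples") <- sum(!nz)
  out
}

# Quadrature nodes and weights over a closed planar polygon: fan
# triangulation about the centroid, each fan triangle split into
# refine^2 congruent sub-triangles, centroid rule.
.polygon_quadrature <- function(loop, refine = 3L, max_loop_vertices = 72L) {
  if (nrow(loop) > max_loop_vertices)
    loop <- loop[round(seq(1, nrow(loop),
                           length.out = max_loop_vertices + 1L))[-1], ,
                 drop = FALSE]
  cen <- colMeans(loop)
  n <- nrow(loop)
  pts <- list(); wts <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- cen; b <- loop[i, ]; c_ <- loop[j, ]
    A <- 0.5 * sqrt(sum(pracma_cross(b - a, c_ - a)^2))
    if (A <= 0) next
    k <- refine
    bc <- .subtri_centroids(k)
    P <- bc[, 1] %o% a + bc[, 2] %o% b + bc[, 3] %o% c_
    pts[[length(pts) + 1]] <- P
    wts[[length(wts) + 1]] <- rep(A / k^2, nrow(bc))
  }
  list(points = do.call(rbind, pts), weights = unlist(wts))
}

# Barycentric centroids of the k^2 congruent subtriangles of a triangle.
.subtri_centroids <- function(k) {
  out <- matrix(0, 0, 3)
  for (r in 0:(k - 1)) {
    for (cc in 0:(k - 1 - r)) {
      # upward subtriangle (r, cc)
      v <- rbind(c(cc, r), c(cc + 1, r), c(cc, r + 1)) / k
      out <- rbind(out, c(mean(v[, 1]), mean(v[, 2]),
                          1 - mean(v[, 1]) - mean(v[, 2])))
      # downward subtriangle
      if (cc < k - 1 - r) {
        v <- rbind(c(cc + 1, r), c(cc + 1, r + 1), c(cc, r + 1)) / k
        out <- rbind(out, c(mean(v[, 1]), mean(v[, 2]),
                            1 - mean(v[, 1]) - mean(v[, 2])))
      }
    }
  }
  out
}

#' Flux of a volumetric field through a planar lumen section
#'
#' Quadrature over a fan triangulation of the section polygon; the field
#' is interpolated at the quadrature nodes (inverse-distance weighting of
#' the 4 nearest volumetric samples).  Signed flux uses the plane normal
#' orientation; the positive part integrates `max(u . n, 0)` only.
#'
#' @param field volumetric [field_series] (velocity, m/s).
#' @param plane an [ostium_plane] or a list with `origin` and `normal`.
#' @param loop section polygon (k x 3, mm); defaults to the ostium
#'   `neck_curve` when `plane` is an [ostium_plane].
#' @param refine fan-triangle subdivision level (refine^2 subtriangles per
#'   fan triangle).
#' @return object of class `flux_series`: `times` (s), `q` signed flux
#'   (ml/s), `q_in` positive part (ml/s), `plane`, `area` (mm^2).
#' @export
plane_flux <- function(field, plane, loop = NULL, refine = 3L) {
  .assert(field$kind == "volumetric", "aneumorph_domain_error",
          "plane_flux needs a volumetric field")
  if (is.null(loop)) {
    .assert(inherits(plane, "ostium_plane"), "aneumorph_domain_error",
            "loop required unless plane is an ostium_plane")
    loop <- plane$neck_curve
  }
  normal <- .unit(plane$normal)
  quad <- .polygon_quadrature(loop, refine = refine)
  area <- sum(quad$weights)
  ip <- .idw_field(quad$points, field, k = 4L)
  sec_r <- sqrt(area / pi)
  .assert(max(ip$nearest) <= 2 * sec_r, "aneumorph_coverage_error",
          "field samples too sparse near the section (nearest %.2f mm, section radius %.2f mm)",
          max(ip$nearest), sec_r)
  un <- ip$values[, , 1] * normal[1] + ip$values[, , 2] * normal[2] +
        ip$values[, , 3] * normal[3]
  un <- rbind(un)
  q <- as.numeric(quad$weights %*% un)
  q_in <- as.numeric(quad$weights %*% pmax(un, 0))
  structure(list(times = field$times, q = q, q_in = q_in, plane = plane,
                 area = area),
            class = "flux_series")
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("flux_series: %d times, mean Q %.3f ml/s (section %.2f mm^2)\n",
              length(x$times), mean(x$q), x$area))
  invisible(x)
}

#' Cycle-averaged aneurysm neck inflow rate
#'
#' Average over the cardiac cycle of the positive (sac-directed) part of
#' the ostium flux; the ostium normal must point from the parent vessel
#' into the sac.
#' @param field volumetric [field_series].
#' @param ostium an [ostium_plane].
#' @param refine quadrature refinement, see [plane_flux()].
#' @return inflow rate in ml/s.
#' @export
neck_inflow_rate <- function(field, ostium, refine = 3L) {
  fx <- plane_flux(field, ostium, refine = refine)
  cycle_average(fx$q_in, fx$times)
}

#' Cycle-averaged flow rate through a vessel cross-section
#'
#' Convenience wrapper: section the lumen at a centerline station and
#' integrate the signed flux, oriented along the centerline tangent
#' (source-to-target positive).
#' @param field volumetric [field_series].
#' @param surface watertight [tri_surface].
#' @param centerline parent [centerline].
#' @param station arc length (mm).
#' @param refine quadrature refinement.
#' @return list with `rate` (ml/s, cycle-averaged signed flux), `area`
#'   (mm^2), `flux` (the [plane_flux()] series).
#' @export
vessel_flow_rate <- function(field, surface, centerline, station,
                             refine = 3L) {
  s <- centerline$arclength
  .assert(station >= s[1] && station <= s[length(s)],
          "aneumorph_section_error", "station outside centerline range")
  p <- c(stats::approx(s, centerline$points[, 1], xout = station)$y,
         stats::approx(s, centerline$points[, 2], xout = station)$y,
         stats::approx(s, centerline$points[, 3], xout = station)$y)
  i <- findInterval(station, s)
  i2 <- min(i + 1, length(s)); i1 <- max(i2 - 1, 1)
  tangent <- .unit(centerline$points[i2, ] - centerline$points[i1, ])
  loops <- .section_loops(surface, p, tangent)
  .assert(length(loops) > 0, "aneumorph_section_error",
          "section plane misses the lumen")
  tb <- .plane_basis(tangent)
  sel <- NULL
  for (lp in loops) {
    rel <- sweep(lp, 2, p)
    if (.point_in_poly2d(0, 0, rel %*% tb$u, rel %*% tb$v)) { sel <- lp; break }
  }
  .assert(!is.null(sel), "aneumorph_section_error",
          "no section loop encloses the centerline point")
  fx <- plane_flux(field, list(origin = p, normal = tangent), loop = sel,
                   refine = refine)
  list(rate = cycle_average(fx$q, fx$times), area = fx$area, flux = fx)
}

#' Spatial mean velocity and wall shear stress of the aneurysm sac
#'
#' Volume-weighted mean of the cycle-averaged velocity magnitude over
#' volumetric samples inside the sac, and area-weighted mean AWSS over
#' wall samples on the sac lateral surface.
#' @param field volumetric [field_series] (m/s).
#' @param wall wall [field_series] (Pa).
#' @param sac an [isolate_sac()] result.
#' @param wall_tol distance tolerance (mm) for attributing wall samples to
#'   the sac lateral surface; default twice the median wall-sample spacing.
#' @param mask_method `"mesh"` (point-in-mesh test against the capped sac
#'   surface; general) or `"plane"` (sac side of the ostium plane within
#'   the sac bounding box; exact for a single sac beyond its neck plane
#'   and much cheaper).
#' @return list with `mean_velocity` (m/s), `mean_wss` (Pa), and the two
#'   sample counts.
#' @export
sac_means <- function(field, wall, sac, wall_tol = NULL,
                      mask_method = c("mesh", "plane")) {
  mask_method <- match.arg(mask_method)
  ss <- sac$sac_surface
  bb_lo <- apply(ss$vertices, 2, min) - 1e-6
  bb_hi <- apply(ss$vertices, 2, max) + 1e-6
  near <- field$points[, 1] >= bb_lo[1] & field$points[, 1] <= bb_hi[1] &
          field$points[, 2] >= bb_lo[2] & field$points[, 2] <= bb_hi[2] &
          field$points[, 3] >= bb_lo[3] & field$points[, 3] <= bb_hi[3]
  idx <- which(near)
  inside <- logical(length(idx))
  if (length(idx)) {
    if (mask_method == "plane" && !is.null(sac$ostium)) {
      inside <- .plane_sd(field$points[idx, , drop = FALSE],
                          sac$ostium$origin, sac$ostium$normal) > 0
    } else {
      inside <- points_in_mesh(field$points[idx, , drop = FALSE], ss)
    }
  }
  vol_idx <- idx[inside]
  .assert(length(vol_idx) > 0, "aneumorph_coverage_error",
          "no volumetric samples inside the sac")
  mags <- sqrt(field$values[vol_idx, , 1, drop = FALSE]^2 +
               field$values[vol_idx, , 2, drop = FALSE]^2 +
               field$values[vol_idx, , 3, drop = FALSE]^2)
  dim(mags) <- c(length(vol_idx), length(field$times))
  cavg <- if (length(field$times) == 1L) as.numeric(mags)
          else as.numeric(mags %*% .trapz_weights(field$times)) /
               (field$times[length(field$times)] - field$times[1])
  w <- field$weights[vol_idx]
  mean_velocity <- sum(w * cavg) / sum(w)
  # wall: samples on the sac lateral surface (cap excluded)
  lat <- ss$triangles
  if (!is.null(sac$is_cap)) lat <- lat[!sac$is_cap, , drop = FALSE]
  lat_cen <- (ss$vertices[lat[, 1], , drop = FALSE] +
              ss$vertices[lat[, 2], , drop = FALSE] +
              ss$vertices[lat[, 3], , drop = FALSE]) / 3
  if (is.null(wall_tol)) {
    la <- tri_surface(ss$vertices, lat, clean = FALSE)
    wall_tol <- 2 * sqrt(stats::median(.tri_areas(la)))
  }
  wnear <- which(
    wall$points[, 1] >= bb_lo[1] - wall_tol &
    wall$points[, 1] <= bb_hi[1] + wall_tol &
    wall$points[, 2] >= bb_lo[2] - wall_tol &
    wall$points[, 2] <= bb_hi[2] + wall_tol &
    wall$points[, 3] >= bb_lo[3] - wall_tol &
    wall$points[, 3] <= bb_hi[3] + wall_tol)
  .assert(length(wnear) > 0, "aneumorph_coverage_error",
          "no wall samples near the sac")
  if (mask_method == "plane" && !is.null(sac$ostium)) {
    # wall samples strictly beyond the ostium plane lie on the sac
    # lateral surface (the cap is interior fluid, not wall)
    wsd <- .plane_sd(wall$points[wnear, , drop = FALSE],
                     sac$ostium$origin, sac$ostium$normal)
    wall_idx <- wnear[wsd > 0]
  } else {
    nnw <- .knn(wall$points[wnear, , drop = FALSE], lat_cen, 1L)
    wall_idx <- wnear[nnw$dist[, 1] <= wall_tol]
  }
  .assert(length(wall_idx) > 0, "aneumorph_coverage_error",
          "no wall samples on the sac lateral surface")
  wmag <- sqrt(wall$values[wall_idx, , 1, drop = FALSE]^2 +
               wall$values[wall_idx, , 2, drop = FALSE]^2 +
               wall$values[wall_idx, , 3, drop = FALSE]^2)
  dim(wmag) <- c(length(wall_idx), length(wall$times))
  aw <- if (length(wall$times) == 1L) as.numeric(wmag)
        else as.numeric(wmag %*% .trapz_weights(wall$times)) /
             (wall$times[length(wall$times)] - wall$times[1])
  ww <- wall$weights[wall_idx]
  list(mean_velocity = mean_velocity,
       mean_wss = sum(ww * aw) / sum(ww),
       n_volume_samples = length(vol_idx),
       n_wall_samples = length(wall_idx))
}

#' Iso-velocity volume fraction
#'
#' Weighted volume fraction of region samples whose cycle-averaged
#' velocity magnitude reaches the threshold (the iso-surface velocity
#' criterion, default threshold 0.3 m/s in the study protocol).
#' @param field volumetric [field_series].
#' @param threshold m/s.
#' @param region logical mask over field samples, an [aneurysm_sac]
#'   (samples inside the sac), or `NULL` for all samples.
#' @return fraction in `[0, 1]`.
#' @export
isovelocity_fraction <- function(field, threshold = 0.3, region = NULL) {
  mask <- rep(TRUE, nrow(field$points))
  if (inherits(region, "aneurysm_sac"))
    mask <- points_in_mesh(field$points, region$sac_surface)
  else if (is.logical(region)) mask <- region
  .assert(any(mask), "aneumorph_coverage_error", "empty region")
  mags <- rbind(.field_magnitudes(field))[mask, , drop = FALSE]
  cavg <- if (length(field$times) == 1L) as.numeric(mags)
          else as.numeric(mags %*% .trapz_weights(field$times)) /
               (field$times[length(field$times)] - field$times[1])
  w <- field$weights[mask]
  sum(w[cavg >= threshold]) / sum(w)
}
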