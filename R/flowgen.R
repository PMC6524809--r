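# Analytic flow fields on phantom geometry.
#
# Quasi-steady Poiseuille flow in the tubular vessel at every instant:
#   u(rho, t) = 2 Q(t) / (pi r^2) (1 - rho^2 / r^2)   along the local axis
#   WSS(t)    = 4 mu Q(t) / (pi r^3)                  along the local axis
# with Q in ml/s, r in mm, u in m/s and WSS in Pa (the mixed mm/SI unit
# system cancels: 2Q/(pi r^2) [ml/s/mm^2] = m/s, 4 mu Q/(pi r^3) with mu
# in Pa s, Q in m^3/s, r in m).  Downstream of a side branch a fixed flow
# fraction leaves the trunk.  The sac interior carries a solid-rotation
# field calibrated to a prescribed spatial-mean speed, modulated by
# Q(t)/Q_mean; the sac wall carries a prescribed shear magnitude with the
# same modulation.  Every flux and shear value is therefore analytically
# known at every instant, which makes the generated fields an oracle for
# the post-processing operators.

#' Analytic quasi-steady flow field for a phantom
#'
#' @param phantom a [make_phantom()] result.
#' @param wave inflow [waveform] (ml/s).
#' @param sample_spacing volumetric sample grid spacing (mm).
#' @param n_times number of time samples over one period.
#' @param viscosity dynamic viscosity (Pa s).
#' @param branch_fraction fraction of the trunk flow leaving through each
#'   side branch present in the phantom.
#' @param sac_mean_speed prescribed spatial-mean sac speed at cycle-mean
#'   flow (m/s).
#' @param sac_wall_wss prescribed sac wall shear magnitude at cycle-mean
#'   flow (Pa).
#' @param geometry optional override for per-group fields on a perturbed
#'   segmentation: a list with `surface` (the group's [tri_surface]),
#'   `centerline` (the group's [centerline] with radius filled) and
#'   optionally `s_offset`, the arc length of the centerline source on the
#'   truth axis (so branch stations still line up).  When given, the
#'   Poiseuille field follows the group's own axis and radius profile.
#' @return list with `volume` and `wall` [field_series], plus the exact
#'   `truth`: per-time trunk flux proximal/distal, wall shear magnitude
#'   proximal/distal, axis peak velocity, and the prescribed sac values.
#' @export
analytic_flow <- function(phantom, wave, sample_spacing = 0.35,
                          n_times = 21L, viscosity = 0.004,
                          branch_fraction = 0.3,
                          sac_mean_speed = 0.1, sac_wall_wss = 2,
                          geometry = NULL) {
  spec <- phantom$spec
  truth <- phantom$truth
  surface <- phantom$surface
  axis_pts <- truth$axis
  axis_s <- truth$s
  axis_r <- truth$r
  axis_tg <- .axis_tangents(spec, truth)
  s_offset <- 0
  if (!is.null(geometry)) {
    surface <- geometry$surface
    cl <- geometry$centerline
    axis_pts <- cl$points
    axis_s <- cl$arclength
    axis_r <- cl$radius
    n <- nrow(axis_pts)
    axis_tg <- .normalize_rows(rbind(
      axis_pts[2, ] - axis_pts[1, ],
      axis_pts[3:n, , drop = FALSE] - axis_pts[1:(n - 2), , drop = FALSE],
      axis_pts[n, ] - axis_pts[n - 1, ]))
    if (!is.null(geometry$s_offset)) s_offset <- geometry$s_offset
  }
  times <- seq(0, wave$period, length.out = n_times)
  qt <- stats::approx(wave$times, wave$q, xout = times, rule = 2)$y
  # true cycle mean (trapezoid), so Q(t)/q_mean averages to 1 over the cycle
  q_mean <- .trapz(wave$times, wave$q) /
            (wave$times[length(wave$times)] - wave$times[1])
  has_sac <- !is.null(spec$sac)
  nb <- length(spec$branches)
  b_station <- if (nb) vapply(spec$branches, `[[`, numeric(1), "station")
               else numeric(0)
  # --- volumetric samples: interior voxel centres --------------------------
  vox <- voxelize_interior(surface, sample_spacing)
  ins <- which(vox$mask)
  dims <- dim(vox$mask)
  ii <- ((ins - 1L) %% dims[1]) + 1L
  jj <- ((ins - 1L) %/% dims[1]) %% dims[2] + 1L
  kk <- ((ins - 1L) %/% (dims[1] * dims[2])) + 1L
  P <- cbind(vox$gx[ii], vox$gy[jj], vox$gz[kk])
  wvol <- rep(sample_spacing^3, nrow(P))
  # nearest axis station for each sample
  nn <- .knn(P, axis_pts, 1L)
  s_loc <- axis_s[nn$index[, 1]] + s_offset
  r_loc <- axis_r[nn$index[, 1]]
  ax <- axis_pts[nn$index[, 1], , drop = FALSE]
  tg <- axis_tg[nn$index[, 1], , drop = FALSE]
  rel <- P - ax
  along <- rowSums(rel * tg)
  perp <- rel - along * tg
  rho <- .rownorm(perp)
  frac_remaining <- rep(1, nrow(P))
  for (bs in b_station)
    frac_remaining <- frac_remaining * ifelse(s_loc > bs,
                                              1 - branch_fraction, 1)
  shape <- pmax(1 - rho^2 / r_loc^2, 0)      # Poiseuille profile
  upeak_unit <- 2 / (pi * r_loc^2)           # (m/s) per (ml/s)
  in_sac <- rep(FALSE, nrow(P))
  if (has_sac) {
    geo <- .sac_geometry(spec)
    cs <- truth$sac_center
    dsac <- sqrt((P[, 1] - cs[1])^2 + (P[, 2] - cs[2])^2 +
                 (P[, 3] - cs[3])^2)
    # sac region: the sphere plus the exposed neck stalk beyond the
    # vessel-wall plane (what an ostium cut at the wall isolates)
    wrel <- sweep(P, 2, geo$wall_exit)
    beyond_wall <- (wrel %*% geo$dir)[, 1] > 0
    srel <- sweep(P, 2, geo$attach)
    salong <- (srel %*% geo$dir)[, 1]
    sradial2 <- rowSums(srel * srel) - salong^2
    in_stalk <- beyond_wall & sradial2 <= spec$sac$neck_radius^2 &
                salong <= geo$stalk_top
    in_sac <- dsac <= spec$sac$sac_radius + 1e-9 | in_stalk
    # solid rotation u = omega x r'; omega in (m/s)/mm so u is in m/s.
    # The rate is calibrated on the generator's own sac samples so the
    # region-mean speed at cycle-mean flow equals sac_mean_speed exactly.
    rot_axis <- .unit(pracma_cross(geo$dir, c(1, 0, 0)) + c(1e-9, 0, 0))
    rvec <- sweep(P, 2, cs)
    urot <- cbind(rot_axis[2] * rvec[, 3] - rot_axis[3] * rvec[, 2],
                  rot_axis[3] * rvec[, 1] - rot_axis[1] * rvec[, 3],
                  rot_axis[1] * rvec[, 2] - rot_axis[2] * rvec[, 1])
    m0 <- mean(.rownorm(urot[in_sac, , drop = FALSE]))
    if (is.finite(m0) && m0 > 0) urot <- urot * (sac_mean_speed / m0)
  }
  # branch interiors: keep the trunk formula switched off, give the branch
  # its own Poiseuille field along the branch direction
  vol_vals <- array(0, c(nrow(P), n_times, 3))
  for (j in seq_len(n_times)) {
    qj <- qt[j]
    u_ax <- upeak_unit * shape * qj * frac_remaining
    vj <- u_ax * tg
    if (has_sac) {
      mod <- qj / q_mean
      vj[in_sac, ] <- urot[in_sac, , drop = FALSE] * mod
    }
    vol_vals[, j, ] <- vj
  }
  if (nb) {
    for (b in spec$branches) {
      pp <- .path_point(spec, b$station)
      bdir <- if (!is.null(b$direction)) .unit(b$direction)
              else .unit(pracma_cross(pp$t, pp$up))
      w <- sweep(P, 2, pp$p)
      balong <- w %*% bdir
      bperp2 <- pmax(rowSums(w * w) - balong[, 1]^2, 0)
      r_b <- b$radius
      inb <- balong[, 1] > .vessel_radius_at(spec, b$station) * 0.5 &
             balong[, 1] <= b$length + r_b & bperp2 <= r_b^2
      if (!any(inb)) next
      bshape <- pmax(1 - bperp2[inb] / r_b^2, 0)
      for (j in seq_len(n_times)) {
        qb <- qt[j] * branch_fraction
        vb <- (2 / (pi * r_b^2)) * bshape * qb
        vol_vals[inb, j, ] <- cbind(vb * bdir[1], vb * bdir[2],
                                    vb * bdir[3])
      }
    }
  }
  volume <- field_series(P, wvol, vol_vals, times, wave$period,
                         kind = "volumetric")
  # --- wall samples: triangle centroids ------------------------------------
  cen <- .tri_centroids(surface)
  war <- .tri_areas(surface)
  nnw <- .knn(cen, axis_pts, 1L)
  s_w <- axis_s[nnw$index[, 1]] + s_offset
  r_w <- axis_r[nnw$index[, 1]]
  axw <- axis_pts[nnw$index[, 1], , drop = FALSE]
  tgw <- axis_tg[nnw$index[, 1], , drop = FALSE]
  relw <- cen - axw
  rhow <- .rownorm(relw - rowSums(relw * tgw) * tgw)
  frac_w <- rep(1, nrow(cen))
  for (bs in b_station)
    frac_w <- frac_w * ifelse(s_w > bs, 1 - branch_fraction, 1)
  on_tube <- abs(rhow - r_w) < 0.35
  wall_kind <- ifelse(on_tube, "tube", "cap")
  if (has_sac) {
    cs <- truth$sac_center
    dw <- sqrt((cen[, 1] - cs[1])^2 + (cen[, 2] - cs[2])^2 +
               (cen[, 3] - cs[3])^2)
    wall_kind[dw <= spec$sac$sac_radius + 0.3] <- "sac"
  }
  if (nb) {
    for (b in spec$branches) {
      pp <- .path_point(spec, b$station)
      bdir <- if (!is.null(b$direction)) .unit(b$direction)
              else .unit(pracma_cross(pp$t, pp$up))
      w <- sweep(cen, 2, pp$p)
      balong <- (w %*% bdir)[, 1]
      bperp <- sqrt(pmax(rowSums(w * w) - balong^2, 0))
      onb <- balong > .vessel_radius_at(spec, b$station) * 0.8 &
             abs(bperp - b$radius) < 0.3
      wall_kind[onb] <- "branch"
    }
  }
  # unit shear (Pa per ml/s): 4 mu Q / (pi r^3), r mm -> m, Q ml/s -> m3/s
  tau_unit <- 4 * viscosity / (pi * (r_w * 1e-3)^3) * 1e-6
  wall_vals <- array(0, c(nrow(cen), n_times, 3))
  if (has_sac) {
    # tangential direction on the sac sphere
    cs <- truth$sac_center
    nrm <- .normalize_rows(sweep(cen, 2, cs))
    rot_axis <- .unit(pracma_cross(.sac_geometry(spec)$dir, c(1, 0, 0)) +
                        c(1e-9, 0, 0))
    tdir <- .normalize_rows(.cross(matrix(rot_axis, nrow(cen), 3,
                                          byrow = TRUE), nrm))
  }
  for (j in seq_len(n_times)) {
    qj <- qt[j]
    tau <- tau_unit * qj * frac_w
    wj <- tau * tgw
    wj[wall_kind == "cap", ] <- 0
    if (has_sac) {
      sel <- wall_kind == "sac"
      wj[sel, ] <- tdir[sel, , drop = FALSE] * (sac_wall_wss * qj / q_mean)
    }
    if (nb) {
      for (b in spec$branches) {
        pp <- .path_point(spec, b$station)
        bdir <- if (!is.null(b$direction)) .unit(b$direction)
                else .unit(pracma_cross(pp$t, pp$up))
        sel <- wall_kind == "branch"
        if (any(sel)) {
          tau_b <- 4 * viscosity / (pi * (b$radius * 1e-3)^3) * 1e-6 *
                   qt[j] * branch_fraction
          wj[sel, ] <- matrix(bdir, sum(sel), 3, byrow = TRUE) * tau_b
        }
      }
    }
    wall_vals[, j, ] <- wj
  }
  wall <- field_series(cen, war, wall_vals, times, wave$period,
                       kind = "wall")
  r_ref <- .vessel_radius_at(spec, 0)
  list(volume = volume, wall = wall,
       truth = list(times = times, q = qt, q_mean = q_mean,
                    wall_shear_unit = 4 * viscosity /
                      (pi * (r_ref * 1e-3)^3) * 1e-6,
                    axis_peak_unit = 2 / (pi * r_ref^2),
                    branch_fraction = if (nb) branch_fraction else 0,
                    sac_mean_speed = if (has_sac) sac_mean_speed else NA,
                    sac_wall_wss = if (has_sac) sac_wall_wss else NA))
}

# Tangent vectors along the recorded truth axis.
.axis_tangents <- function(spec, truth) {
  t(vapply(truth$s, function(s) .path_point(spec, s)$t, numeric(3)))
}
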