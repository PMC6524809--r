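# Synthetic vascular phantoms with analytically known geometry.
#
# A phantom is a constructive solid: a tubular parent vessel (straight or
# planar arc, constant or linearly tapering radius), an optional saccular
# aneurysm modelled as a sphere connected through a cylindrical neck stalk
# of known radius, and optional cylindrical side branches.  The surface is
# extracted from the signed implicit field with marching tetrahedra on a
# uniform grid, which yields a watertight triangulation by construction.
# Every quantity the analysis pipeline measures (axis, radius profile,
# neck circle and area, sac volume and lateral surface, cross-section
# areas) has a closed form recorded in the ground-truth slot.

#' Specification of a synthetic vascular phantom
#'
#' @param length parent vessel length along its path (mm).
#' @param radius parent vessel radius (mm); scalar, or length-2 for a
#'   linear taper from the source to the target end.
#' @param path `"straight"` (along +x) or `"arc"` (planar circular bend in
#'   the xy-plane).
#' @param bend_radius arc path radius (mm), for `path = "arc"`.
#' @param bend_angle arc sweep in degrees, for `path = "arc"`.
#' @param sac `NULL` or a list with `neck_radius`, `sac_radius` (mm),
#'   `station` (arc length of the attachment point, mm; default mid-vessel)
#'   and `stalk_offset` (exposed neck-stalk length between the vessel wall
#'   and the sac sphere, mm; default 0.4).
#' @param branches list of side branches, each a list with `station`,
#'   `radius`, `length` (mm) and optionally `direction` (length-3).
#' @param grid grid resolution h for surface extraction (mm); default
#'   adapts to the smallest feature.
#' @param label provenance label.
#' @return a `phantom_spec` list (validated).
#' @export
phantom_spec <- function(length = 40, radius = 2, path = c("straight", "arc"),
                         bend_radius = 10, bend_angle = 90, sac = NULL,
                         branches = list(), grid = NULL, label = "phantom") {
  path <- match.arg(path)
  radius <- rep(as.numeric(radius), length.out = 2)
  .assert(all(radius > 0) && length > 0, "aneumorph_spec_error",
          "vessel radius and length must be positive")
  if (!is.null(sac)) {
    .assert(all(c("neck_radius", "sac_radius") %in% names(sac)),
            "aneumorph_spec_error", "sac needs neck_radius and sac_radius")
    .assert(sac$neck_radius > 0 && sac$sac_radius > 0,
            "aneumorph_spec_error", "sac radii must be positive")
    .assert(sac$neck_radius < sac$sac_radius, "aneumorph_spec_error",
            "neck radius must be smaller than the sac radius")
    if (is.null(sac$station)) sac$station <- length / 2
    if (is.null(sac$stalk_offset)) sac$stalk_offset <- 0.4
    .assert(sac$stalk_offset >= 0, "aneumorph_spec_error",
            "stalk_offset must be non-negative")
  }
  for (b in branches)
    .assert(all(c("station", "radius", "length") %in% names(b)) &&
              b$radius > 0 && b$length > 0, "aneumorph_spec_error",
            "each branch needs positive station/radius/length")
  if (is.null(grid)) {
    feat <- min(radius, if (!is.null(sac)) sac$neck_radius else Inf,
                if (length(branches))
                  min(vapply(branches, `[[`, numeric(1), "radius")) else Inf)
    grid <- max(min(0.25, feat / 5), 0.08)
  }
  structure(list(length = length, radius = radius, path = path,
                 bend_radius = bend_radius, bend_angle = bend_angle,
                 sac = sac, branches = branches, grid = grid, label = label),
            class = "phantom_spec")
}

# --- path parameterisation -------------------------------------------------

# Point, tangent and outward sac direction at arc length s along the path.
.path_point <- function(spec, s) {
  if (spec$path == "straight") {
    list(p = c(s, 0, 0), t = c(1, 0, 0), up = c(0, 0, 1))
  } else {
    R <- spec$bend_radius
    th <- s / R
    # arc centred at (0, R, 0), starting at the origin heading +x
    list(p = c(R * sin(th), R * (1 - cos(th)), 0),
         t = c(cos(th), sin(th), 0),
         up = c(0, 0, 1))
  }
}

.path_length <- function(spec) spec$length

.vessel_radius_at <- function(spec, s) {
  f <- pmin(pmax(s / spec$length, 0), 1)
  spec$radius[1] + f * (spec$radius[2] - spec$radius[1])
}

# --- implicit field --------------------------------------------------------

# Signed field (negative inside) of the phantom solid at points (n x 3).
.phantom_field <- function(spec, pts) {
  n <- nrow(pts)
  if (spec$path == "straight") {
    x <- pts[, 1]
    r_at <- .vessel_radius_at(spec, x)
    radial <- sqrt(pts[, 2]^2 + pts[, 3]^2) - r_at
    axial <- pmax(-x, x - spec$length)
    d <- pmax(radial, axial)
  } else {
    R <- spec$bend_radius
    thmax <- spec$bend_angle * pi / 180
    cx <- 0; cy <- R
    dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
    th <- atan2(dx, -dy)          # 0 at origin, increasing along the arc
    rho <- sqrt(dx * dx + dy * dy)
    s_arc <- pmin(pmax(th, 0), thmax) * R
    r_at <- .vessel_radius_at(spec, s_arc)
    tube <- sqrt((rho - R)^2 + pts[, 3]^2) - r_at
    cap0 <- -(pts[, 1] * 1)                     # plane x = 0, outward -x
    e1 <- c(R * sin(thmax), R * (1 - cos(thmax)), 0)
    t1 <- c(cos(thmax), sin(thmax), 0)
    cap1 <- (pts[, 1] - e1[1]) * t1[1] + (pts[, 2] - e1[2]) * t1[2]
    d <- pmax(tube, cap0, cap1)
  }
  if (!is.null(spec$sac)) {
    geo <- .sac_geometry(spec)
    dsph <- sqrt((pts[, 1] - geo$center[1])^2 + (pts[, 2] - geo$center[2])^2 +
                 (pts[, 3] - geo$center[3])^2) - spec$sac$sac_radius
    # neck stalk: capped cylinder from the vessel axis point to the sphere
    ap <- geo$attach
    axis <- geo$dir
    w <- cbind(pts[, 1] - ap[1], pts[, 2] - ap[2], pts[, 3] - ap[3])
    along <- w %*% axis
    radial <- sqrt(pmax(rowSums(w * w) - along^2, 0)) - spec$sac$neck_radius
    stalk <- pmax(radial, pmax(-along, along - geo$stalk_top))
    d <- pmin(d, dsph, stalk)
  }
  for (b in spec$branches) {
    pp <- .path_point(spec, b$station)
    dir <- if (!is.null(b$direction)) .unit(b$direction)
           else .unit(pracma_cross(pp$t, pp$up))
    w <- cbind(pts[, 1] - pp$p[1], pts[, 2] - pp$p[2], pts[, 3] - pp$p[3])
    along <- w %*% dir
    radial2 <- pmax(rowSums(w * w) - along^2, 0)
    # capsule: rounded far end
    clamped <- pmin(pmax(along, 0), b$length)
    dd <- w - cbind(clamped * dir[1], clamped * dir[2], clamped * dir[3])
    d <- pmin(d, sqrt(rowSums(dd * dd)) - b$radius)
  }
  as.numeric(d)
}

# Sac attachment geometry: attachment axis point, outward direction, sphere
# center, neck-circle plane.
.sac_geometry <- function(spec) {
  sac <- spec$sac
  pp <- .path_point(spec, sac$station)
  dir <- pp$up        # sac extrudes out of the bend plane / straight axis
  r_vessel <- .vessel_radius_at(spec, sac$station)
  h_c <- sqrt(sac$sac_radius^2 - sac$neck_radius^2)
  center <- pp$p + (r_vessel + sac$stalk_offset + h_c) * dir
  neck_origin <- pp$p + (r_vessel + sac$stalk_offset) * dir
  list(attach = pp$p, dir = dir, center = center,
       stalk_top = r_vessel + sac$stalk_offset + h_c,
       neck_origin = neck_origin, neck_normal = dir,
       wall_exit = pp$p + r_vessel * dir, h_c = h_c)
}

# --- marching tetrahedra ---------------------------------------------------

# Extract the zero level set of values sampled on a uniform grid.
# Each cube is split into 6 tetrahedra sharing the main diagonal, which
# guarantees conforming faces and a watertight result.  Triangles are
# oriented so normals point towards positive field values (outside).
.marching_tets <- function(gx, gy, gz, vals) {
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  dim(vals) <- c(nx, ny, nz)
  cube_i <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  cube_j <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  cube_k <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  lin <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i
  c000 <- lin(cube_i,     cube_j,     cube_k)
  c100 <- lin(cube_i + 1L, cube_j,     cube_k)
  c010 <- lin(cube_i,     cube_j + 1L, cube_k)
  c110 <- lin(cube_i + 1L, cube_j + 1L, cube_k)
  c001 <- lin(cube_i,     cube_j,     cube_k + 1L)
  c101 <- lin(cube_i + 1L, cube_j,     cube_k + 1L)
  c011 <- lin(cube_i,     cube_j + 1L, cube_k + 1L)
  c111 <- lin(cube_i + 1L, cube_j + 1L, cube_k + 1L)
  # 6 tets around the main diagonal c000-c111
  tets <- list(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
               c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  corner <- cbind(c000, c100, c010, c110, c001, c101, c011, c111)
  # prune cubes whose 8 corners have uniform sign
  vmin <- vals[corner[, 1]]
  vmax <- vmin
  for (cc in 2:8) {
    vcc <- vals[corner[, cc]]
    vmin <- pmin(vmin, vcc)
    vmax <- pmax(vmax, vcc)
  }
  active <- which(vmin < 0 & vmax >= 0)
  if (!length(active))
    .err("aneumorph_spec_error", "implicit field has no zero crossing")
  corner <- corner[active, , drop = FALSE]
  tri_a <- integer(0); tri_b <- integer(0); tri_c <- integer(0)
  ekeys <- character(0)
  seg_a1 <- integer(0); seg_a2 <- integer(0)
  emit <- list()
  for (tt in tets) {
    g1 <- corner[, tt[1]]; g2 <- corner[, tt[2]]
    g3 <- corner[, tt[3]]; g4 <- corner[, tt[4]]
    f1 <- vals[g1]; f2 <- vals[g2]; f3 <- vals[g3]; f4 <- vals[g4]
    neg <- cbind(f1 < 0, f2 < 0, f3 < 0, f4 < 0)
    cnt <- rowSums(neg)
    gm <- cbind(g1, g2, g3, g4)
    # one corner inside: triangle between the three cut edges
    for (vi in 1:4) {
      sel <- which(cnt == 1L & neg[, vi])
      if (length(sel)) {
        others <- setdiff(1:4, vi)
        emit[[length(emit) + 1]] <- list(
          e1 = cbind(gm[sel, vi], gm[sel, others[1]]),
          e2 = cbind(gm[sel, vi], gm[sel, others[2]]),
          e3 = cbind(gm[sel, vi], gm[sel, others[3]]))
      }
      sel3 <- which(cnt == 3L & !neg[, vi])
      if (length(sel3)) {
        others <- setdiff(1:4, vi)
        emit[[length(emit) + 1]] <- list(
          e1 = cbind(gm[sel3, others[1]], gm[sel3, vi]),
          e2 = cbind(gm[sel3, others[2]], gm[sel3, vi]),
          e3 = cbind(gm[sel3, others[3]], gm[sel3, vi]))
      }
    }
    # two corners inside: quad between the four cut edges
    pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pr in pairs) {
      sel <- which(cnt == 2L & neg[, pr[1]] & neg[, pr[2]])
      if (length(sel)) {
        out2 <- setdiff(1:4, pr)
        # edges (in1,out1) (in1,out2) (in2,out1) (in2,out2)
        emit[[length(emit) + 1]] <- list(
          e1 = cbind(gm[sel, pr[1]], gm[sel, out2[1]]),
          e2 = cbind(gm[sel, pr[1]], gm[sel, out2[2]]),
          e3 = cbind(gm[sel, pr[2]], gm[sel, out2[1]]),
          e4 = cbind(gm[sel, pr[2]], gm[sel, out2[2]]))
      }
    }
  }
  # collect all edge cut points, dedupe by grid-edge key
  all_edges <- do.call(rbind, unlist(lapply(emit, function(e)
    unname(e)), recursive = FALSE))
  key <- paste(pmin(all_edges[, 1], all_edges[, 2]),
               pmax(all_edges[, 1], all_edges[, 2]))
  uk <- !duplicated(key)
  ue <- all_edges[uk, , drop = FALSE]
  fa <- vals[ue[, 1]]; fb <- vals[ue[, 2]]
  t <- fa / (fa - fb)
  coord_of <- function(g) {
    i <- ((g - 1L) %% nx) + 1L
    j <- ((g - 1L) %/% nx) %% ny + 1L
    k <- ((g - 1L) %/% (nx * ny)) + 1L
    cbind(gx[i], gy[j], gz[k])
  }
  pa <- coord_of(ue[, 1]); pb <- coord_of(ue[, 2])
  cut_pts <- pa + t * (pb - pa)
  vid_of <- function(edges2) {
    k2 <- paste(pmin(edges2[, 1], edges2[, 2]),
                pmax(edges2[, 1], edges2[, 2]))
    match(k2, key[uk])
  }
  tris <- list()
  for (e in emit) {
    v1 <- vid_of(e$e1); v2 <- vid_of(e$e2); v3 <- vid_of(e$e3)
    if (is.null(e$e4)) {
      tris[[length(tris) + 1]] <- cbind(v1, v2, v3)
    } else {
      v4 <- vid_of(e$e4)
      tris[[length(tris) + 1]] <- cbind(v1, v2, v3)
      tris[[length(tris) + 1]] <- cbind(v3, v2, v4)
    }
  }
  Tm <- do.call(rbind, tris)
  # orient: normal should point towards increasing field (outward); use the
  # field gradient approximated by the cut-edge directions
  p1 <- cut_pts[Tm[, 1], , drop = FALSE]
  p2 <- cut_pts[Tm[, 2], , drop = FALSE]
  p3 <- cut_pts[Tm[, 3], , drop = FALSE]
  fn <- .cross(p2 - p1, p3 - p1)
  # outward reference: average of (outside corner - inside corner) over the
  # generating edges of vertex 1
  ref <- pb - pa   # a is first endpoint; orient so edge goes inside->outside
  flipped <- vals[ue[, 1]] > 0
  ref[flipped, ] <- -ref[flipped, , drop = FALSE]
  ref_tri <- ref[Tm[, 1], , drop = FALSE] + ref[Tm[, 2], , drop = FALSE] +
             ref[Tm[, 3], , drop = FALSE]
  flip <- rowSums(fn * ref_tri) < 0
  Tm[flip, ] <- Tm[flip, c(1, 3, 2), drop = FALSE]
  list(vertices = cut_pts, triangles = Tm)
}

#' Generate a synthetic vascular phantom surface with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: `surface` (watertight outward-oriented
#'   [tri_surface]), `spec`, and `truth` — a list with the axis polyline
#'   (`axis`, with arc length `s` and radius `r`), and when a sac is
#'   present: `neck_origin`, `neck_normal`, `neck_radius`, `ostium_area`,
#'   `sac_volume`, `sac_lateral_area`, `sac_center`, plus closed-form
#'   `section_area(s)` values for the parent vessel.
#' @export
make_phantom <- function(spec) {
  .assert(inherits(spec, "phantom_spec"), "aneumorph_spec_error",
          "spec must be a phantom_spec")
  h <- spec$grid
  # grid bounds: vessel bbox + sac + branches + margin
  probe_s <- seq(0, spec$length, length.out = 200)
  axis_pts <- t(vapply(probe_s, function(s) .path_point(spec, s)$p,
                       numeric(3)))
  rmax <- max(spec$radius)
  lo <- apply(axis_pts, 2, min) - rmax
  hi <- apply(axis_pts, 2, max) + rmax
  if (!is.null(spec$sac)) {
    geo <- .sac_geometry(spec)
    lo <- pmin(lo, geo$center - spec$sac$sac_radius)
    hi <- pmax(hi, geo$center + spec$sac$sac_radius)
  }
  for (b in spec$branches) {
    pp <- .path_point(spec, b$station)
    dir <- if (!is.null(b$direction)) .unit(b$direction)
           else .unit(pracma_cross(pp$t, pp$up))
    tip <- pp$p + (b$length + b$radius) * dir
    lo <- pmin(lo, pmin(pp$p, tip) - b$radius)
    hi <- pmax(hi, pmax(pp$p, tip) + b$radius)
  }
  lo <- lo - 3 * h
  hi <- hi + 3 * h
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  pts <- cbind(rep(gx, times = length(gy) * length(gz)),
               rep(rep(gy, each = length(gx)), times = length(gz)),
               rep(gz, each = length(gx) * length(gy)))
  vals <- .phantom_field(spec, pts)
  .assert(min(vals) < 0, "aneumorph_spec_error",
          "phantom spec produces an empty solid")
  mesh <- .marching_tets(gx, gy, gz, vals)
  surface <- orient_outward(tri_surface(mesh$vertices, mesh$triangles,
                                        label = spec$label))
  truth <- list(axis = axis_pts, s = probe_s,
                r = .vessel_radius_at(spec, probe_s),
                section_area = pi * .vessel_radius_at(spec, probe_s)^2)
  if (!is.null(spec$sac)) {
    geo <- .sac_geometry(spec)
    R <- spec$sac$sac_radius
    H <- R + geo$h_c                      # spherical cap height above neck
    truth$neck_origin <- geo$neck_origin
    truth$neck_normal <- geo$neck_normal
    truth$neck_radius <- spec$sac$neck_radius
    truth$ostium_area <- pi * spec$sac$neck_radius^2
    truth$sac_volume <- pi * H^2 * (3 * R - H) / 3
    truth$sac_lateral_area <- 2 * pi * R * H
    truth$sac_center <- geo$center
    truth$wall_exit <- geo$wall_exit
  }
  structure(list(surface = surface, spec = spec, truth = truth),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom '%s': %s vessel r=%.2f mm L=%.1f mm%s%s\n",
              x$spec$label, x$spec$path, x$spec$radius[1], x$spec$length,
              if (!is.null(x$spec$sac))
                sprintf(", sac R=%.2f neck a=%.2f", x$spec$sac$sac_radius,
                        x$spec$sac$neck_radius) else "",
              if (length(x$spec$branches))
                sprintf(", %d side branch(es)", length(x$spec$branches))
              else ""))
  print(x$surface)
  invisible(x)
}
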