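# Ostium detection, sac isolation and the four morphological parameters:
# ostium area, parent-vessel cross-sectional area proximal to the ostium,
# sac volume, and the non-sphericity index.
#
# The ostium is operationalised as the *smallest separating planar
# section*: among candidate planes (origins sampled on the segment from
# the dome seed to its nearest parent-centerline point, normals on a
# 10-degree hemisphere grid, then local refinement), the plane whose
# lumen cross-section separates the dome seed from both ends of the
# parent centerline with minimal section area.  Cuts are exact on the
# triangulation (edges split at the plane).

#' Ostium plane of an aneurysm
#'
#' @param origin point on the plane (mm) — the neck-curve centroid.
#' @param normal unit normal, oriented from the parent vessel toward the sac.
#' @param neck_curve closed polygon (k x 3) on the surface, on the plane.
#' @param area enclosed area of the neck curve (mm^2).
#' @param dome_seed the seed the detection used (kept for downstream cuts).
#' @return object of class `ostium_plane`.
#' @export
ostium_plane <- function(origin, normal, neck_curve, area, dome_seed = NULL) {
  .assert(area > 0, "aneumorph_domain_error", "ostium area must be positive")
  structure(list(origin = origin, normal = .unit(normal),
                 neck_curve = neck_curve, area = area,
                 dome_seed = dome_seed),
            class = "ostium_plane")
}

#' @export
print.ostium_plane <- function(x, ...) {
  cat(sprintf("ostium_plane: area %.3f mm^2, normal (%.2f, %.2f, %.2f)\n",
              x$area, x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# Score one candidate plane: quick side checks, then the area of the
# cross-section loop enclosing the dome-seed projection.  Returns NA when
# the candidate cannot separate.
.ostium_score <- function(surface, origin, normal, dome_seed, ends, sd_cache,
                          cl_points = NULL) {
  s_dome <- sum((dome_seed - origin) * normal)
  if (s_dome <= 0) return(NULL)
  if (sum((ends[1, ] - origin) * normal) >= 0) return(NULL)
  if (sum((ends[2, ] - origin) * normal) >= 0) return(NULL)
  if (!is.null(cl_points)) {
    # a neck plane sits at or above the vessel wall, so the whole parent
    # centerline must stay on the vessel side
    sd_cl <- (cl_points[, 1] - origin[1]) * normal[1] +
             (cl_points[, 2] - origin[2]) * normal[2] +
             (cl_points[, 3] - origin[3]) * normal[3]
    if (max(sd_cl) >= 0) return(NULL)
  }
  loops <- .section_loops(surface, origin, normal, sd = sd_cache)
  if (!length(loops)) return(NULL)
  tb <- .plane_basis(normal)
  dp <- dome_seed - origin
  px <- sum(dp * tb$u); py <- sum(dp * tb$v)
  e1 <- ends[1, ] - origin; e2 <- ends[2, ] - origin
  ex <- c(sum(e1 * tb$u), sum(e2 * tb$u))
  ey <- c(sum(e1 * tb$v), sum(e2 * tb$v))
  for (lp in loops) {
    rel <- sweep(lp, 2, origin)
    xs <- rel %*% tb$u
    ys <- rel %*% tb$v
    if (!.point_in_poly2d(px, py, xs, ys)) next
    # a neck loop encloses the dome but not the projection of either
    # parent-centerline end (otherwise the cut runs along the vessel)
    if (.point_in_poly2d(ex[1], ey[1], xs, ys) ||
        .point_in_poly2d(ex[2], ey[2], xs, ys)) next
    return(list(area = .polygon_area(lp, normal), loop = lp))
  }
  NULL
}

# Exact separation check for a winning candidate: clip the surface on the
# dome side; the component containing the dome seed must not contain the
# surface vertices nearest to either centerline end, must have exactly one
# boundary loop (the neck curve), and the cut must be clean: any other
# sac-side fragments (noise bumps of the vessel wall grazed by the plane)
# must stay below a sliver fraction of the sac area.
.ostium_separates <- function(surface, origin, normal, dome_seed, ends,
                              end_radii = NULL, sliver_tol = 0.01) {
  cp <- tryCatch(clip_surface(surface, origin, normal, cap = FALSE,
                              component_point = dome_seed),
                 error = function(e) NULL)
  if (is.null(cp)) return(FALSE)
  if (cp$n_boundary_loops != 1) return(FALSE)
  ca <- cp$component_areas
  if (!is.null(ca) && length(ca) > 1) {
    kept <- attr(ca, "kept")
    if (sum(ca[-kept]) > sliver_tol * ca[kept]) return(FALSE)
  }
  V <- surface$vertices
  pv <- cp$surface$vertices
  for (k in 1:2) {
    d2 <- (V[, 1] - ends[k, 1])^2 + (V[, 2] - ends[k, 2])^2 +
          (V[, 3] - ends[k, 3])^2
    nv <- V[which.min(d2), ]
    dcomp2 <- min((pv[, 1] - nv[1])^2 + (pv[, 2] - nv[2])^2 +
                  (pv[, 3] - nv[3])^2)
    if (dcomp2 < 1e-12) return(FALSE)
    # the sac piece must also keep clear of the vessel lumen at the ends
    if (!is.null(end_radii)) {
      dend2 <- min((pv[, 1] - ends[k, 1])^2 + (pv[, 2] - ends[k, 2])^2 +
                   (pv[, 3] - ends[k, 3])^2)
      if (dend2 < (0.95 * end_radii[k])^2) return(FALSE)
    }
  }
  TRUE
}

#' Detect the aneurysm ostium as the smallest separating planar section
#'
#' @param surface watertight [tri_surface] containing parent vessel and sac.
#' @param dome_seed point inside the sac (mm).
#' @param parent_centerline [centerline] of the parent vessel passing the
#'   sac region.
#' @param angle_res hemisphere sampling resolution in degrees.
#' @param n_origins number of candidate origins on the seed-to-centerline
#'   segment.
#' @param refine logical: locally refine (origin offset and normal angles)
#'   around the best grid candidate.
#' @return an [ostium_plane], with the normal oriented from the parent
#'   vessel toward the sac.
#' @export
detect_ostium <- function(surface, dome_seed, parent_centerline,
                          angle_res = 10, n_origins = 9, refine = TRUE) {
  cl <- parent_centerline
  d2 <- (cl$points[, 1] - dome_seed[1])^2 + (cl$points[, 2] - dome_seed[2])^2 +
        (cl$points[, 3] - dome_seed[3])^2
  foot <- cl$points[which.min(d2), ]
  ends <- rbind(cl$points[1, ], cl$points[nrow(cl$points), ])
  axis_dir <- dome_seed - foot
  .assert(sqrt(sum(axis_dir^2)) > 1e-9, "aneumorph_isolation_error",
          "dome seed lies on the parent centerline; nothing to isolate")
  axis_dir <- .unit(axis_dir)
  tb <- .plane_basis(axis_dir)
  th <- seq(0, 80, by = angle_res) * pi / 180
  phi <- seq(0, 360 - angle_res, by = angle_res) * pi / 180
  dirs <- rbind(axis_dir,
                do.call(rbind, lapply(th[th > 0], function(t_)
                  t(vapply(phi, function(p_)
                    cos(t_) * axis_dir + sin(t_) * cos(p_) * tb$u +
                      sin(t_) * sin(p_) * tb$v, numeric(3))))))
  fr <- seq(0.1, 0.9, length.out = n_origins)
  origins <- t(vapply(fr, function(f) foot + f * (dome_seed - foot),
                      numeric(3)))
  end_radii <- if (!is.null(cl$radius))
    cl$radius[c(1, nrow(cl$points))] else NULL
  cands <- list()
  for (oi in seq_len(nrow(origins))) {
    o <- origins[oi, ]
    for (ni in seq_len(nrow(dirs))) {
      sc <- .ostium_score(surface, o, dirs[ni, ], dome_seed, ends,
                          sd_cache = NULL, cl_points = cl$points)
      if (!is.null(sc))
        cands[[length(cands) + 1]] <- c(sc, list(origin = o,
                                                 normal = dirs[ni, ]))
    }
  }
  .assert(length(cands) > 0, "aneumorph_isolation_error",
          "no separating plane found (sac melted into the parent vessel?)")
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "area"))]
  best <- NULL
  for (cand in cands[seq_len(min(length(cands), 60L))]) {
    if (.ostium_separates(surface, cand$origin, cand$normal, dome_seed,
                          ends, end_radii)) { best <- cand; break }
  }
  .assert(!is.null(best), "aneumorph_isolation_error",
          "no candidate plane isolates the sac (segmentation artifact?)")
  if (refine) {
    seg <- dome_seed - foot
    base_n <- best$normal
    pen <- function(par) {
      # par: offset fraction along segment, tilt components about u/v
      o <- foot + pmin(pmax(par[1], 0.02), 0.98) * seg
      n <- .unit(base_n + par[2] * tb$u + par[3] * tb$v)
      sc <- .ostium_score(surface, o, n, dome_seed, ends, sd_cache = NULL,
                          cl_points = cl$points)
      if (is.null(sc)) 1e6 else sc$area
    }
    f0 <- sum((best$origin - foot) * seg) / sum(seg * seg)
    opt <- stats::optim(c(f0, 0, 0), pen, method = "Nelder-Mead",
                        control = list(maxit = 120, reltol = 1e-6))
    if (opt$value < best$area) {
      o <- foot + pmin(pmax(opt$par[1], 0.02), 0.98) * seg
      n <- .unit(base_n + opt$par[2] * tb$u + opt$par[3] * tb$v)
      sc <- .ostium_score(surface, o, n, dome_seed, ends, sd_cache = NULL,
                          cl_points = cl$points)
      refine_ok <- !is.null(sc) &&
        .ostium_separates(surface, o, n, dome_seed, ends, end_radii)
      if (refine_ok)
        best <- c(sc, list(origin = o, normal = n))
    } else refine_ok <- TRUE
    # constrained descent towards the vessel, used when the unconstrained
    # refinement was rejected: its optimum can sit below the lowest
    # *clean* cut, so walk the accepted plane down its own normal while
    # the smaller section still separates
    step <- if (refine_ok) 0 else 0.12
    tries <- 0L
    while (step >= 0.02 && tries < 12L) {
      tries <- tries + 1L
      o2 <- best$origin - step * best$normal
      sc2 <- .ostium_score(surface, o2, best$normal, dome_seed, ends,
                           sd_cache = NULL, cl_points = cl$points)
      if (!is.null(sc2) && sc2$area < best$area - 1e-9 &&
          .ostium_separates(surface, o2, best$normal, dome_seed, ends,
                            end_radii)) {
        best <- c(sc2, list(origin = o2, normal = best$normal))
      } else {
        step <- step / 2
      }
    }
  }
  ostium_plane(origin = colMeans(best$loop), normal = best$normal,
               neck_curve = best$loop, area = best$area,
               dome_seed = dome_seed)
}

#' Aneurysm sac isolated at the ostium plane
#'
#' Cuts the surface along the ostium plane, keeps the sac-side component
#' containing the dome seed, and caps it with a fan triangulation of the
#' neck polygon.  `volume` is the enclosed volume of the capped sac;
#' `lateral_area` excludes the cap (reported separately) so the
#' non-sphericity index can be computed with either convention.
#'
#' @param surface watertight [tri_surface].
#' @param ostium an [ostium_plane] for this surface.
#' @param sliver_tol fraction of sac area below which stray sac-side
#'   components (cut slivers) are discarded rather than raised as errors.
#' @return object of class `aneurysm_sac`: `sac_surface`, `volume`,
#'   `lateral_area`, `cap_area`.
#' @export
isolate_sac <- function(surface, ostium, sliver_tol = 0.01) {
  seed <- ostium$dome_seed
  if (is.null(seed))
    seed <- ostium$origin + 1e-3 * ostium$normal
  cp <- clip_surface(surface, ostium$origin, ostium$normal, cap = TRUE,
                     component_point = seed)
  ca <- cp$component_areas
  if (!is.null(ca) && length(ca) > 1) {
    kept <- attr(ca, "kept")
    .assert(sum(ca[-kept]) <= sliver_tol * ca[kept],
            "aneumorph_topology_error",
            "cut produced %d substantial sac-side components", length(ca))
  }
  .assert(cp$n_boundary_loops == 1, "aneumorph_topology_error",
          "sac piece has %d boundary loops (expected a single neck curve)",
          cp$n_boundary_loops)
  sac_surface <- orient_outward(cp$surface)
  vol <- enclosed_volume(sac_surface)
  total_area <- surface_area(sac_surface)
  # cap triangles: all three vertices on the ostium plane
  vsd <- abs(.plane_sd(sac_surface$vertices, ostium$origin, ostium$normal))
  on_plane <- vsd < 1e-7
  is_cap <- on_plane[sac_surface$triangles[, 1]] &
            on_plane[sac_surface$triangles[, 2]] &
            on_plane[sac_surface$triangles[, 3]]
  structure(list(sac_surface = sac_surface, volume = vol,
                 lateral_area = total_area - cp$cap_area,
                 cap_area = cp$cap_area, is_cap = is_cap,
                 ostium = ostium),
            class = "aneurysm_sac")
}

#' @export
print.aneurysm_sac <- function(x, ...) {
  cat(sprintf("aneurysm_sac: V = %.2f mm^3, lateral S = %.2f mm^2 (cap %.2f mm^2)\n",
              x$volume, x$lateral_area, x$cap_area))
  invisible(x)
}

#' Non-sphericity index
#'
#' `NSI = 1 - (18 pi)^(1/3) V^(2/3) / S`, a dimensionless shape deviation:
#' 0 for a perfect sphere (when S is the full bounding surface), growing as
#' the sac elongates or flattens.
#' @param V volume (mm^3), non-negative.
#' @param S surface area (mm^2), positive.
#' @return NSI in `[0, 1]` for physical V/S pairs.
#' @export
nsi <- function(V, S) {
  .assert(S > 0, "aneumorph_domain_error", "surface area must be positive")
  .assert(V >= 0, "aneumorph_domain_error", "volume must be non-negative")
  1 - (18 * pi)^(1 / 3) * V^(2 / 3) / S
}

#' Parent-vessel cross-sectional area at a centerline station
#'
#' Cuts the lumen with the plane through the centerline point at arc
#' length `station`, normal to the local tangent; only the section loop
#' containing the centerline point counts.
#' @param surface watertight [tri_surface].
#' @param centerline parent [centerline].
#' @param station arc length (mm) within the centerline range.
#' @return area in mm^2.
#' @export
parent_cross_section <- function(surface, centerline, station) {
  s <- centerline$arclength
  .assert(station >= s[1] && station <= s[length(s)],
          "aneumorph_section_error",
          "station %.2f mm outside centerline range [%.2f, %.2f]",
          station, s[1], s[length(s)])
  p <- c(stats::approx(s, centerline$points[, 1], xout = station)$y,
         stats::approx(s, centerline$points[, 2], xout = station)$y,
         stats::approx(s, centerline$points[, 3], xout = station)$y)
  i <- findInterval(station, s)
  i2 <- min(i + 1, length(s))
  i1 <- max(i2 - 1, 1)
  tangent <- .unit(centerline$points[i2, ] - centerline$points[i1, ])
  loops <- .section_loops(surface, p, tangent)
  .assert(length(loops) > 0, "aneumorph_section_error",
          "section plane misses the lumen")
  tb <- .plane_basis(tangent)
  for (lp in loops) {
    rel <- sweep(lp, 2, p)
    if (.point_in_poly2d(0, 0, rel %*% tb$u, rel %*% tb$v))
      return(.polygon_area(lp, tangent))
  }
  .err("aneumorph_section_error",
       "no closed section loop encloses the centerline point")
}

#' Full morphometric record for one aneurysm
#'
#' Composition of [detect_ostium()], [isolate_sac()], [nsi()] and
#' [parent_cross_section()] at the station `proximal_offset` millimetres
#' proximal to the ostium's centerline foot.
#'
#' @param surface watertight [tri_surface].
#' @param dome_seed point inside the sac (mm).
#' @param centerline parent [centerline] (source = proximal/inlet end).
#' @param proximal_offset distance proximal to the ostium foot (mm);
#'   default two local vessel diameters.
#' @return object of class `morpho_record` with `ostium_area`,
#'   `parent_area`, `volume`, `nsi` (cap excluded from S), `nsi_with_cap`,
#'   `lateral_area`, `cap_area`, the `ostium` and `sac` objects, and
#'   `proximal_station`.  On failure, a record whose `failure` field names
#'   the stage and reason.
#' @export
morphometrics <- function(surface, dome_seed, centerline,
                          proximal_offset = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .err("aneumorph_stage_error", "[%s] %s", name, conditionMessage(e))
    })
  }
  ost <- stage("detect_ostium",
               detect_ostium(surface, dome_seed, centerline))
  sac <- stage("isolate_sac", isolate_sac(surface, ostium = ost))
  d2 <- (centerline$points[, 1] - ost$origin[1])^2 +
        (centerline$points[, 2] - ost$origin[2])^2 +
        (centerline$points[, 3] - ost$origin[3])^2
  foot_i <- which.min(d2)
  foot_s <- centerline$arclength[foot_i]
  r_foot <- if (!is.null(centerline$radius)) centerline$radius[foot_i]
            else sqrt(min(d2)) / 2
  if (is.null(proximal_offset)) proximal_offset <- 4 * r_foot
  station <- max(foot_s - proximal_offset, centerline$arclength[1])
  parent_area <- stage("parent_cross_section",
                       parent_cross_section(surface, centerline, station))
  structure(list(
    ostium_area = ost$area,
    parent_area = parent_area,
    volume = sac$volume,
    nsi = nsi(sac$volume, sac$lateral_area),
    nsi_with_cap = nsi(sac$volume, sac$lateral_area + sac$cap_area),
    lateral_area = sac$lateral_area,
    cap_area = sac$cap_area,
    ostium = ost, sac = sac,
    proximal_station = station,
    failure = NULL
  ), class = "morpho_record")
}

#' @export
print.morpho_record <- function(x, ...) {
  if (!is.null(x$failure)) {
    cat("morpho_record: FAILED -", x$failure, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("morpho_record: ostium %.2f mm^2, parent %.2f mm^2, ",
                     "V %.2f mm^3, NSI %.3f\n"),
              x$ostium_area, x$parent_area, x$volume, x$nsi))
  invisible(x)
}
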