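# Centerline extraction and profile analysis.
#
# Algorithm: voxelise the lumen interior, build a Euclidean distance
# transform to the wall, run a least-cost path between the two seed points
# with per-step cost 1/d^2 (so the path hugs the medial axis), smooth,
# resample, and project every node to the local medial position by
# maximising the exact point-to-surface distance in the plane orthogonal
# to the local tangent.  The inscribed-sphere radius at a medial point is
# its exact distance to the surface.

#' Voxelise the interior of a watertight surface
#'
#' Cell-centred uniform grid; interior flags by ray-casting parity along
#' grid columns.
#' @param surface watertight [tri_surface].
#' @param voxel cell edge length (mm).
#' @param margin extra empty space around the bounding box (mm).
#' @return list with `mask` (3D logical array), axis coordinate vectors
#'   `gx`, `gy`, `gz`, and `voxel`.
#' @export
voxelize_interior <- function(surface, voxel, margin = NULL) {
  if (is.null(margin)) margin <- 2 * voxel
  V <- surface$vertices
  lo <- apply(V, 2, min) - margin
  hi <- apply(V, 2, max) + margin
  nx <- max(2L, ceiling((hi[1] - lo[1]) / voxel))
  ny <- max(2L, ceiling((hi[2] - lo[2]) / voxel))
  nz <- max(2L, ceiling((hi[3] - lo[3]) / voxel))
  gx <- lo[1] + (seq_len(nx) - 0.5) * voxel
  gy <- lo[2] + (seq_len(ny) - 0.5) * voxel + 1.7e-7   # break edge-degeneracy
  gz <- lo[3] + (seq_len(nz) - 0.5) * voxel + 2.9e-7
  cr <- .tri_corners(surface)
  p1 <- cr$p1; p2 <- cr$p2; p3 <- cr$p3
  den <- (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
         (p3[, 2] - p1[, 2]) * (p2[, 3] - p1[, 3])
  live <- which(abs(den) > 1e-14)
  # candidate (triangle, grid column) pairs, built without a per-triangle
  # loop: each triangle covers only the columns inside its (y, z) bbox
  ylo <- pmin(p1[live, 2], p2[live, 2], p3[live, 2])
  yhi <- pmax(p1[live, 2], p2[live, 2], p3[live, 2])
  zlo <- pmin(p1[live, 3], p2[live, 3], p3[live, 3])
  zhi <- pmax(p1[live, 3], p2[live, 3], p3[live, 3])
  iy0 <- pmax(findInterval(ylo, gy) + 1L, 1L)
  iy1 <- findInterval(yhi, gy)
  iz0 <- pmax(findInterval(zlo, gz) + 1L, 1L)
  iz1 <- findInterval(zhi, gz)
  nyc <- pmax(iy1 - iy0 + 1L, 0L)
  nzc <- pmax(iz1 - iz0 + 1L, 0L)
  npair <- nyc * nzc
  keep <- npair > 0L
  trid <- rep(live[keep], npair[keep])
  # per-pair local (row, col) offsets within each triangle's bbox window
  off <- sequence(npair[keep]) - 1L
  nyr <- rep(nyc[keep], npair[keep])
  iyp <- rep(iy0[keep], npair[keep]) + off %% nyr
  izp <- rep(iz0[keep], npair[keep]) + off %/% nyr
  py <- gy[iyp]
  pz <- gz[izp]
  w1 <- ((p2[trid, 2] - py) * (p3[trid, 3] - pz) -
         (p3[trid, 2] - py) * (p2[trid, 3] - pz)) / den[trid]
  w2 <- ((p3[trid, 2] - py) * (p1[trid, 3] - pz) -
         (p1[trid, 2] - py) * (p3[trid, 3] - pz)) / den[trid]
  w3 <- 1 - w1 - w2
  ok <- w1 > 0 & w2 > 0 & w3 > 0
  cid <- (izp[ok] - 1L) * length(gy) + iyp[ok]
  xc <- w1[ok] * p1[trid[ok], 1] + w2[ok] * p2[trid[ok], 1] +
        w3[ok] * p3[trid[ok], 1]
  mask <- array(FALSE, c(nx, ny, nz))
  if (length(cid)) {
    o <- order(cid, xc)
    cid <- cid[o]; xc <- xc[o]
    runs <- rle(cid)
    runlen <- rep(runs$lengths, runs$lengths)
    pos <- sequence(runs$lengths)
    good <- runlen %% 2L == 0L
    odd_cols <- sum(runs$lengths %% 2L == 1L)
    pair_start <- which(good & pos %% 2L == 1L)
    if (length(pair_start)) {
      x1 <- xc[pair_start]
      x2 <- xc[pair_start + 1L]
      col <- cid[pair_start]
      iy <- (col - 1L) %% length(gy) + 1L
      iz <- (col - 1L) %/% length(gy) + 1L
      ix0 <- findInterval(x1, gx) + 1L
      ix1 <- findInterval(x2, gx)
      counts <- pmax(ix1 - ix0 + 1L, 0L)
      keepp <- counts > 0L
      starts <- ix0[keepp] + (iy[keepp] - 1L) * nx +
                (iz[keepp] - 1L) * nx * ny
      lin <- rep(starts, counts[keepp]) + (sequence(counts[keepp]) - 1L)
      mask[lin] <- TRUE
    }
    if (odd_cols > 0)
      warning(sprintf("voxelize_interior: %d columns with odd crossing parity skipped",
                      odd_cols))
  }
  list(mask = mask, gx = gx, gy = gy, gz = gz, voxel = voxel)
}

# Shift a 3D array along one dimension, padding with `fill`.
.shift_arr <- function(a, k, dim, fill = Inf) {
  d <- base::dim(a)
  out <- array(fill, d)
  if (k == 0) return(a)
  n <- d[dim]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  ix <- function(sel, which_dim) {
    l <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    l[[which_dim]] <- sel
    l
  }
  out[ix(dst, dim)[[1]], ix(dst, dim)[[2]], ix(dst, dim)[[3]]] <-
    a[ix(src, dim)[[1]], ix(src, dim)[[2]], ix(src, dim)[[3]]]
  out
}

# Separable squared Euclidean distance transform (voxel units) with a
# bounded scan window; the window is doubled until it covers the largest
# interior distance, so the result is exact.
.edt_sq <- function(mask) {
  D <- array(0, dim(mask))
  D[mask] <- Inf
  K <- 8L
  repeat {
    A <- D
    for (dm in 1:3) {
      B <- A
      for (k in c(-(K:1), 1:K)) {
        B <- pmin(B, .shift_arr(A, k, dm) + k * k)
      }
      A <- B
    }
    if (all(is.finite(A[mask])) && max(A[mask]) <= (K - 1)^2) return(A)
    if (all(is.finite(A[mask])) && K >= max(dim(mask))) return(A)
    K <- K * 2L
    if (K > 4 * max(dim(mask))) return(A)
  }
}

#' Ordered lumen centerline
#'
#' @param points k x 3 matrix of ordered medial points (mm).
#' @param radius inscribed-sphere radius per point (mm), or `NULL`.
#' @param source_landmark,target_landmark seed labels.
#' @return object of class `centerline` with fields `points`, `arclength`
#'   (cumulative, from the source), `radius`, and the landmark labels.
#' @export
centerline <- function(points, radius = NULL, source_landmark = "source",
                       target_landmark = "target") {
  points <- as.matrix(points)
  steps <- .rownorm(diff(points))
  keep <- c(TRUE, steps > 1e-12)
  points <- points[keep, , drop = FALSE]
  if (!is.null(radius)) radius <- radius[keep]
  arclength <- c(0, cumsum(.rownorm(diff(points))))
  structure(list(points = points, arclength = arclength, radius = radius,
                 source_landmark = source_landmark,
                 target_landmark = target_landmark),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.2f mm (%s -> %s)\n",
              nrow(x$points), max(x$arclength), x$source_landmark,
              x$target_landmark))
  if (!is.null(x$radius))
    cat(sprintf("  inscribed radius: %.3f - %.3f mm\n",
                min(x$radius), max(x$radius)))
  invisible(x)
}

#' Extract a centerline between two interior seed points
#'
#' @param surface watertight [tri_surface].
#' @param source,target length-3 seed coordinates (mm), strictly inside the
#'   lumen.
#' @param voxel grid resolution (mm); default `min(0.1, d_seed/8)` where
#'   `d_seed` is the smaller seed-to-wall distance, keeping the grid below
#'   an eighth of the local vessel radius.
#' @param spacing resampling step of the output polyline (mm); defaults to
#'   `voxel`.
#' @param refine logical: project nodes to the medial axis by maximising
#'   exact wall distance in the plane orthogonal to the local tangent.
#' @param source_landmark,target_landmark labels carried on the result.
#' @return a [centerline] with the radius filled in.
#' @export
extract_centerline <- function(surface, source, target, voxel = NULL,
                               spacing = NULL, refine = TRUE,
                               source_landmark = "source",
                               target_landmark = "target") {
  .assert(sqrt(sum((source - target)^2)) > 1e-9,
          "aneumorph_seed_error", "source and target seeds coincide")
  cache <- .tri_dist_cache(surface)
  inside <- points_in_mesh(rbind(source, target), surface)
  .assert(inside[1], "aneumorph_seed_error", "source seed outside the lumen")
  .assert(inside[2], "aneumorph_seed_error", "target seed outside the lumen")
  if (is.null(voxel)) {
    dseed <- .points_surface_dist(rbind(source, target), cache)
    voxel <- min(0.1, min(dseed) / 8)
  }
  if (is.null(spacing)) spacing <- voxel
  vox <- voxelize_interior(surface, voxel)
  mask <- vox$mask
  dims <- dim(mask)
  d2 <- .edt_sq(mask)
  dist_mm <- pmax((sqrt(d2) - 0.5) * voxel, voxel / 4)
  lin_of <- function(p) {
    i <- pmin(pmax(round((p[1] - vox$gx[1]) / voxel) + 1, 1), dims[1])
    j <- pmin(pmax(round((p[2] - vox$gy[1]) / voxel) + 1, 1), dims[2])
    k <- pmin(pmax(round((p[3] - vox$gz[1]) / voxel) + 1, 1), dims[3])
    c(i, j, k)
  }
  snap <- function(p, label) {
    ijk <- lin_of(p)
    # search a small neighbourhood for the nearest interior voxel
    for (r in 0:3) {
      ii <- max(1, ijk[1] - r):min(dims[1], ijk[1] + r)
      jj <- max(1, ijk[2] - r):min(dims[2], ijk[2] + r)
      kk <- max(1, ijk[3] - r):min(dims[3], ijk[3] + r)
      sub <- which(mask[ii, jj, kk, drop = FALSE], arr.ind = TRUE)
      if (nrow(sub)) {
        cand <- cbind(ii[sub[, 1]], jj[sub[, 2]], kk[sub[, 3]])
        dd <- (vox$gx[cand[, 1]] - p[1])^2 + (vox$gy[cand[, 2]] - p[2])^2 +
              (vox$gz[cand[, 3]] - p[3])^2
        return(cand[which.min(dd), ])
      }
    }
    .err("aneumorph_seed_error", "%s seed not inside the voxelised lumen",
         label)
  }
  s_ijk <- snap(source, "source")
  t_ijk <- snap(target, "target")
  interior <- which(mask)
  node_id <- array(NA_integer_, dims)
  node_id[interior] <- seq_along(interior)
  ii <- ((interior - 1L) %% dims[1]) + 1L
  jj <- ((interior - 1L) %/% dims[1]) %% dims[2] + 1L
  kk <- ((interior - 1L) %/% (dims[1] * dims[2])) + 1L
  inv_d2 <- 1 / (dist_mm[interior]^2)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    ni <- ii + offs[o, 1]; nj <- jj + offs[o, 2]; nk <- kk + offs[o, 3]
    okn <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
           nk >= 1 & nk <= dims[3]
    lin2 <- (nk[okn] - 1L) * dims[1] * dims[2] + (nj[okn] - 1L) * dims[1] +
            ni[okn]
    tid <- node_id[lin2]
    okx <- !is.na(tid)
    f <- which(okn)[okx]
    t_ <- tid[okx]
    step <- voxel * sqrt(sum(offs[o, ]^2))
    w <- step * 0.5 * (inv_d2[f] + inv_d2[t_])
    efrom <- c(efrom, f); eto <- c(eto, t_); ew <- c(ew, w)
  }
  g <- igraph::make_graph(as.vector(rbind(efrom, eto)),
                          n = length(interior), directed = FALSE)
  from_id <- node_id[s_ijk[1], s_ijk[2], s_ijk[3]]
  to_id <- node_id[t_ijk[1], t_ijk[2], t_ijk[3]]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from_id, to = to_id, weights = ew,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  .assert(length(vp) >= 2, "aneumorph_disconnection_error",
          "no interior connectivity between the seed points")
  path <- cbind(vox$gx[ii[vp]], vox$gy[jj[vp]], vox$gz[kk[vp]])
  # smoothing: two passes of a centred moving average, endpoints pinned
  smooth_path <- function(p, w = 5L, passes = 2L) {
    for (pass in seq_len(passes)) {
      n <- nrow(p)
      if (n <= w) break
      q <- p
      h <- w %/% 2
      for (i in (h + 1):(n - h))
        q[i, ] <- colMeans(p[(i - h):(i + h), , drop = FALSE])
      p <- q
    }
    p
  }
  path <- smooth_path(path)
  path <- .resample_polyline(path, spacing)
  if (refine) path <- .medial_project(path, cache, max_shift = 3 * voxel)
  radius <- .points_surface_dist(path, cache, prefilter_margin = 1)
  centerline(path, radius = radius, source_landmark = source_landmark,
             target_landmark = target_landmark)
}

# Resample an ordered polyline at (approximately) fixed arc-length steps.
.resample_polyline <- function(p, spacing) {
  s <- c(0, cumsum(.rownorm(diff(p))))
  L <- s[length(s)]
  if (L <= spacing) return(p[c(1, nrow(p)), , drop = FALSE])
  grid <- seq(0, L, by = spacing)
  if (grid[length(grid)] < L - 1e-9) grid <- c(grid, L)
  cbind(stats::approx(s, p[, 1], xout = grid)$y,
        stats::approx(s, p[, 2], xout = grid)$y,
        stats::approx(s, p[, 3], xout = grid)$y)
}

# Project each node towards the medial axis: maximise wall distance within
# the plane orthogonal to the local tangent.  Pattern search (3 x 3
# stencil, step halved each round) on the two in-plane offsets.  During the
# search the wall distance is evaluated against the surface vertex cloud —
# for meshes whose vertices lie on the true surface this overestimates the
# exact distance by at most (edge/2)^2 / (2 d), well below a percent at the
# resolutions used — so the exact point-to-triangle distance is only needed
# once, for the final radius.  The shift is clamped to `max_shift` to
# preserve the path ordering.
.medial_project <- function(path, cache, max_shift, rounds = 6L) {
  n <- nrow(path)
  if (n < 3) return(path)
  tangents <- rbind(path[2, ] - path[1, ],
                    path[3:n, , drop = FALSE] - path[1:(n - 2), , drop = FALSE],
                    path[n, ] - path[n - 1, ])
  tangents <- .normalize_rows(tangents)
  vw <- cache$verts
  out <- path
  sten <- as.matrix(expand.grid(a = -1:1, b = -1:1))
  for (i in seq_len(n)) {
    p0 <- path[i, ]
    tb <- .plane_basis(tangents[i, ])
    dv2 <- (vw[, 1] - p0[1])^2 + (vw[, 2] - p0[2])^2 + (vw[, 3] - p0[3])^2
    dmin <- sqrt(min(dv2))
    sel <- dv2 <= (dmin + 2 * max_shift + 0.3)^2
    vs <- vw[sel, , drop = FALSE]
    ab <- c(0, 0)
    dcur <- dmin         # vertex-cloud wall distance at the unshifted node
    step <- max_shift / 2
    for (r in seq_len(rounds)) {
      cand <- sweep(sten * step, 2, ab, "+")
      cand <- cand[pmax(abs(cand[, 1]), abs(cand[, 2])) <= max_shift, ,
                   drop = FALSE]
      Pc <- matrix(p0, nrow(cand), 3, byrow = TRUE) +
        cand[, 1] %o% tb$u + cand[, 2] %o% tb$v
      d2m <- outer(rowSums(Pc * Pc), rowSums(vs * vs), "+") -
        2 * Pc %*% t(vs)
      dd <- sqrt(pmax(apply(d2m, 1, min), 0))
      best <- which.max(dd)
      # move only on strict improvement: on plateaus (e.g. end-cap limited
      # regions) the node must stay put rather than drift with the stencil
      if (dd[best] > dcur + 1e-9) {
        ab <- cand[best, ]
        dcur <- dd[best]
      }
      step <- step / 2
    }
    out[i, ] <- p0 + ab[1] * tb$u + ab[2] * tb$v
  }
  out
}

#' Fill the maximum-inscribed-sphere radius along a centerline
#'
#' For a medial point the exact distance to the surface is the radius of
#' the largest inscribed sphere centred there.
#' @param centerline a [centerline].
#' @param surface the [tri_surface] the centerline runs through.
#' @return the centerline with `radius` replaced by exact point-to-surface
#'   distances.
#' @export
inscribed_radius <- function(centerline, surface) {
  inside <- points_in_mesh(centerline$points, surface)
  .assert(all(inside), "aneumorph_negative_distance_error",
          "%d centerline points lie outside the surface", sum(!inside))
  cache <- .tri_dist_cache(surface)
  centerline$radius <- .points_surface_dist(centerline$points, cache)
  centerline
}

#' Cycle-averaged velocity magnitude along a centerline
#'
#' Inverse-distance-weighted interpolation (4 nearest volumetric samples)
#' of the velocity vector, magnitude taken after interpolation, then
#' cycle-averaged with the trapezoidal rule.
#' @param centerline a [centerline] with radius filled.
#' @param field volumetric [field_series] covering the centerline.
#' @return numeric vector of per-point cycle-averaged speeds (m/s).
#' @export
sample_velocity_magnitude <- function(centerline, field) {
  .assert(field$kind == "volumetric", "aneumorph_domain_error",
          "velocity sampling needs a volumetric field")
  ip <- .idw_field(centerline$points, field, k = 4L)
  if (!is.null(centerline$radius)) {
    bad <- ip$nearest > 2 * pmax(centerline$radius, 1e-9)
    .assert(!any(bad), "aneumorph_coverage_error",
            "%d centerline points farther than 2 local radii from any field sample",
            sum(bad))
  }
  mag <- sqrt(ip$values[, , 1]^2 + ip$values[, , 2]^2 + ip$values[, , 3]^2)
  mag <- rbind(mag)
  if (length(field$times) == 1L) return(as.numeric(mag))
  span <- field$times[length(field$times)] - field$times[1]
  as.numeric(mag %*% .trapz_weights(field$times)) / span
}

#' Align per-group profiles on a common arc-length grid
#'
#' Each group's profile is linearly resampled on the grid `0, step,
#' 2*step, ...` anchored at the shared source landmark; a group contributes
#' up to its own terminal arc length and is marked absent (`NA`) beyond it.
#'
#' @param centerlines list of [centerline]s with identical landmark labels.
#' @param step grid step (mm).
#' @param values `"radius"` (default) or a list of per-group numeric
#'   vectors (e.g. centerline velocities), one value per centerline point.
#' @param group_labels optional labels; default `group_01`, ...
#' @return object of class `matched_profiles`: `abscissa`, `values`
#'   (groups x stations matrix with NA where absent), `group_labels`.
#' @export
match_profiles <- function(centerlines, step = 0.5, values = "radius",
                           group_labels = NULL) {
  .assert(length(centerlines) >= 2, "aneumorph_ensemble_error",
          "need at least 2 centerlines to match profiles")
  src <- unique(vapply(centerlines, `[[`, character(1), "source_landmark"))
  tgt <- unique(vapply(centerlines, `[[`, character(1), "target_landmark"))
  .assert(length(src) == 1 && length(tgt) == 1, "aneumorph_ensemble_error",
          "centerlines do not share source/target landmarks")
  if (identical(values, "radius"))
    values <- lapply(centerlines, `[[`, "radius")
  .assert(length(values) == length(centerlines), "aneumorph_ensemble_error",
          "one value vector per centerline required")
  lmax <- max(vapply(centerlines, function(cl) max(cl$arclength), numeric(1)))
  grid <- seq(0, lmax, by = step)
  mat <- matrix(NA_real_, length(centerlines), length(grid))
  for (gi in seq_along(centerlines)) {
    cl <- centerlines[[gi]]
    v <- values[[gi]]
    .assert(length(v) == nrow(cl$points), "aneumorph_ensemble_error",
            "value vector length mismatch for group %d", gi)
    ok <- grid <= max(cl$arclength) + 1e-9
    mat[gi, ok] <- stats::approx(cl$arclength, v, xout = pmin(grid[ok],
                                 max(cl$arclength)))$y
  }
  if (is.null(group_labels))
    group_labels <- sprintf("group_%02d", seq_along(centerlines))
  structure(list(abscissa = grid, values = mat, group_labels = group_labels),
            class = "matched_profiles")
}

#' @export
print.matched_profiles <- function(x, ...) {
  cat(sprintf("matched_profiles: %d groups x %d stations (step %.3g mm)\n",
              nrow(x$values), length(x$abscissa),
              if (length(x$abscissa) > 1) diff(x$abscissa[1:2]) else NA))
  invisible(x)
}

#' Per-station variability band of matched profiles
#'
#' Sample (n-1) standard deviation per station over the groups present
#' there; stations with fewer than two groups do not contribute.  The
#' profile-averaged standard deviation (`band_mean_std`) is the unweighted
#' mean over contributing stations — the scalar variability summary of an
#' ensemble of segmentations.
#' @param profiles a [match_profiles()] result.
#' @return list with `abscissa`, `mean`, `std`, `n`, `band_mean_std`.
#' @export
profile_band <- function(profiles) {
  v <- profiles$values
  n <- colSums(!is.na(v))
  mu <- colMeans(v, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(v, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2) stats::sd(col) else NA_real_
  })
  list(abscissa = profiles$abscissa, mean = mu, std = sdv, n = n,
       band_mean_std = mean(sdv[n >= 2]))
}

#' Export a centerline as columnar CSV (x, y, z, arclength, radius)
#' @param cl a [centerline].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  utils::write.csv(data.frame(
    x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
    arclength = cl$arclength,
    radius = if (is.null(cl$radius)) NA_real_ else cl$radius),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a centerline as an ASCII PLY polyline
#' @param cl a [centerline].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centerline_ply <- function(cl, path) {
  n <- nrow(cl$points)
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    sprintf("element edge %d", n - 1L),
    "property int vertex1", "property int vertex2", "end_header",
    sprintf("%.9g %.9g %.9g", cl$points[, 1], cl$points[, 2],
            cl$points[, 3]),
    sprintf("%d %d", seq_len(n - 1L) - 1L, seq_len(n - 1L))), path)
  invisible(path)
}

#' Export matched profiles as a wide CSV (station rows, group columns)
#' @param profiles a [match_profiles()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(arclength = profiles$abscissa)
  m <- t(profiles$values)
  colnames(m) <- profiles$group_labels
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}
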