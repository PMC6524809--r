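#' Triangulated vascular surface
#'
#' Container for a triangulated surface in millimetres, the unit of
#' segmentation comparison.  Construction cleans the raw triangle soup:
#' vertices closer than `merge_tol` are merged and triangles that collapse
#' onto fewer than three distinct vertices are dropped.  Repair counts are
#' kept in the `repairs` attribute.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param label free-text provenance label (group / dataset id).
#' @param merge_tol vertex merge tolerance in mm.  The default 1e-6 mm is
#'   far below angiographic voxel size, so only numerically duplicated
#'   vertices (e.g. the per-facet records of an STL file) are merged.
#' @param clean logical; set `FALSE` to keep the soup as-is.
#' @return an object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles, label = "", merge_tol = 1e-6,
                        clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  .assert(ncol(vertices) == 3, "aneumorph_format_error",
          "vertices must be an n x 3 matrix")
  .assert(ncol(triangles) == 3, "aneumorph_format_error",
          "triangles must be an m x 3 matrix")
  .assert(nrow(triangles) == 0 || (min(triangles) >= 1L &&
            max(triangles) <= nrow(vertices)),
          "aneumorph_format_error", "triangle indices out of range")
  repairs <- c(merged_vertices = 0L, dropped_triangles = 0L)
  if (clean && nrow(vertices) > 0) {
    key <- paste(round(vertices[, 1] / merge_tol),
                 round(vertices[, 2] / merge_tol),
                 round(vertices[, 3] / merge_tol))
    first <- !duplicated(key)
    map <- match(key, key[first])
    repairs["merged_vertices"] <- as.integer(sum(!first))
    vertices <- vertices[first, , drop = FALSE]
    triangles <- matrix(map[triangles], ncol = 3)
    degen <- triangles[, 1] == triangles[, 2] |
             triangles[, 2] == triangles[, 3] |
             triangles[, 1] == triangles[, 3]
    repairs["dropped_triangles"] <- as.integer(sum(degen))
    triangles <- triangles[!degen, , drop = FALSE]
    used <- sort(unique(as.vector(triangles)))
    vertices <- vertices[used, , drop = FALSE]
    triangles <- matrix(match(triangles, used), ncol = 3)
    storage.mode(triangles) <- "integer"
  }
  .assert(nrow(triangles) > 0, "aneumorph_empty_geometry_error",
          "surface is empty after cleaning")
  structure(
    list(vertices = vertices, triangles = triangles,
         provenance_label = label),
    repairs = repairs, class = "tri_surface"
  )
}

#' @export
print.tri_surface <- function(x, ...) {
  rep <- attr(x, "repairs")
  cat(sprintf("tri_surface: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (nzchar(x$provenance_label))
                paste0(" [", x$provenance_label, "]") else ""))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  if (!is.null(rep) && any(rep > 0))
    cat(sprintf("  repairs: %d vertices merged, %d degenerate triangles dropped\n",
                rep["merged_vertices"], rep["dropped_triangles"]))
  invisible(x)
}

# Triangle corner coordinate matrices.
.tri_corners <- function(surface) {
  V <- surface$vertices
  Tm <- surface$triangles
  list(p1 = V[Tm[, 1], , drop = FALSE],
       p2 = V[Tm[, 2], , drop = FALSE],
       p3 = V[Tm[, 3], , drop = FALSE])
}

.tri_areas <- function(surface) {
  cr <- .tri_corners(surface)
  0.5 * .rownorm(.cross(cr$p2 - cr$p1, cr$p3 - cr$p1))
}

.tri_centroids <- function(surface) {
  cr <- .tri_corners(surface)
  (cr$p1 + cr$p2 + cr$p3) / 3
}

.tri_normals <- function(surface, normalize = TRUE) {
  cr <- .tri_corners(surface)
  n <- .cross(cr$p2 - cr$p1, cr$p3 - cr$p1)
  if (normalize) .normalize_rows(n) else n
}

#' Total surface area
#'
#' Sum of triangle areas, in mm^2; invariant under rigid motion.
#' @param surface a [tri_surface].
#' @return area in mm^2.
#' @export
surface_area <- function(surface) {
  sum(.tri_areas(surface))
}

.signed_volume <- function(surface) {
  cr <- .tri_corners(surface)
  sum(rowSums(cr$p1 * .cross(cr$p2, cr$p3))) / 6
}

# Undirected edge table with incidence counts.
.edge_incidence <- function(surface) {
  Tm <- surface$triangles
  e <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  list(edges = e, key = key, counts = tab)
}

.is_watertight <- function(surface) {
  all(.edge_incidence(surface)$counts == 2L)
}

#' Flip triangle winding so the signed volume is positive
#'
#' Enforces the outward-normal convention used throughout: wall vectors and
#' flux signs need a fixed orientation.
#' @param surface a watertight [tri_surface].
#' @return the surface, consistently oriented outward.
#' @export
orient_outward <- function(surface) {
  if (.signed_volume(surface) < 0)
    surface$triangles <- surface$triangles[, c(1, 3, 2), drop = FALSE]
  surface
}

#' Enclosed volume of a watertight surface
#'
#' Divergence-theorem signed volume, returned positive after outward
#' orientation.  Errors on non-watertight input, naming the open-edge count.
#' @param surface a watertight [tri_surface].
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(surface) {
  inc <- .edge_incidence(surface)$counts
  n_open <- sum(inc == 1L)
  .assert(all(inc == 2L), "aneumorph_precondition_error",
          "surface is not watertight (%d open edges, %d non-manifold edges)",
          n_open, sum(inc > 2L))
  abs(.signed_volume(surface))
}

#' Validate a triangulated surface
#'
#' Reports (never raises) on geometric quality: watertightness by edge
#' incidence, open-edge count, self-intersection and the sign of the signed
#' volume.  Self-intersection testing is exact (all bounding-box overlapping
#' triangle pairs) up to `exact_limit` triangles and falls back to a random
#' subsample above it to stay desk-scale.
#'
#' @param surface a [tri_surface].
#' @param check_self_intersection logical; the pairwise test is the costly part.
#' @param exact_limit triangle count above which the test subsamples.
#' @return list with `watertight`, `open_edges`, `non_manifold_edges`,
#'   `consistently_oriented`, `self_intersecting`, `signed_volume_sign`.
#' @export
validate_surface <- function(surface, check_self_intersection = TRUE,
                             exact_limit = 1e5) {
  inc <- .edge_incidence(surface)
  counts <- inc$counts
  watertight <- all(counts == 2L)
  # consistent orientation: each undirected edge is traversed once per
  # direction, i.e. no directed edge repeats
  dir_key <- paste(inc$edges[, 1], inc$edges[, 2])
  consistent <- !anyDuplicated(dir_key)
  selfx <- if (check_self_intersection)
    .self_intersects(surface, exact_limit) else NA
  list(
    watertight = watertight,
    open_edges = as.integer(sum(counts == 1L)),
    non_manifold_edges = as.integer(sum(counts > 2L)),
    consistently_oriented = consistent,
    self_intersecting = selfx,
    signed_volume_sign = sign(.signed_volume(surface))
  )
}

# Segment-triangle intersection (Moller-Trumbore), vectorised over segments.
# o: k x 3 origins, d: k x 3 directions; p1/p2/p3: single triangle corners.
.seg_tri_hit <- function(o, d, p1, p2, p3) {
  e1 <- p2 - p1
  e2 <- p3 - p1
  pv <- .cross(d, matrix(e2, nrow(d), 3, byrow = TRUE))
  det <- rowSums(pv * matrix(e1, nrow(d), 3, byrow = TRUE))
  ok <- abs(det) > 1e-14
  tv <- o - matrix(p1, nrow(o), 3, byrow = TRUE)
  u <- rowSums(tv * pv) / det
  qv <- .cross(tv, matrix(e1, nrow(d), 3, byrow = TRUE))
  v <- rowSums(d * qv) / det
  t <- rowSums(matrix(e2, nrow(d), 3, byrow = TRUE) * qv) / det
  eps <- 1e-10
  ok & u > eps & v > eps & (u + v) < 1 - eps & t > eps & t < 1 - eps
}

# Exact-ish self-intersection test: candidate pairs from a uniform grid
# hash of triangle bounding boxes, then edge-vs-triangle crossing tests.
# Pairs sharing a vertex are skipped (mesh adjacency is contact, not
# intersection).
.self_intersects <- function(surface, exact_limit = 1e5) {
  Tm <- surface$triangles
  m <- nrow(Tm)
  idx <- seq_len(m)
  if (m > exact_limit) {
    set.seed(1L)  # sampling mode only; keeps the report deterministic
    idx <- sort(sample.int(m, exact_limit))
  }
  V <- surface$vertices
  sub <- Tm[idx, , drop = FALSE]
  p1 <- V[sub[, 1], , drop = FALSE]
  p2 <- V[sub[, 2], , drop = FALSE]
  p3 <- V[sub[, 3], , drop = FALSE]
  lo <- pmin(p1, pmin(p2, p3))
  hi <- pmax(p1, pmax(p2, p3))
  cell <- max(stats::median(hi[, 1] - lo[, 1]),
              stats::median(hi[, 2] - lo[, 2]),
              stats::median(hi[, 3] - lo[, 3]), 1e-9) * 2
  key_of <- function(pt) floor(pt / cell)
  # register each triangle in all cells its bbox touches
  regs <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    kx <- key_of(lo[i, 1]):key_of(hi[i, 1])
    ky <- key_of(lo[i, 2]):key_of(hi[i, 2])
    kz <- key_of(lo[i, 3]):key_of(hi[i, 3])
    g <- expand.grid(kx, ky, kz)
    regs[[i]] <- paste(g[, 1], g[, 2], g[, 3])
  }
  cellmap <- split(rep(seq_along(idx), lengths(regs)), unlist(regs))
  seen <- new.env(hash = TRUE)
  for (ids in cellmap) {
    if (length(ids) < 2) next
    for (a in seq_len(length(ids) - 1)) {
      i <- ids[a]
      for (b in (a + 1):length(ids)) {
        j <- ids[b]
        pk <- paste(i, j)
        if (!is.null(seen[[pk]])) next
        seen[[pk]] <- TRUE
        # bbox overlap
        if (any(lo[i, ] > hi[j, ]) || any(lo[j, ] > hi[i, ])) next
        # shared vertices -> adjacency, skip
        if (length(intersect(sub[i, ], sub[j, ])) > 0) next
        if (.tri_pair_cross(p1[i, ], p2[i, ], p3[i, ],
                            p1[j, ], p2[j, ], p3[j, ])) return(TRUE)
      }
    }
  }
  FALSE
}

.tri_pair_cross <- function(a1, a2, a3, b1, b2, b3) {
  segs_o <- rbind(a1, a2, a3, b1, b2, b3)
  segs_d <- rbind(a2 - a1, a3 - a2, a1 - a3, b2 - b1, b3 - b2, b1 - b3)
  hits_a <- .seg_tri_hit(segs_o[1:3, , drop = FALSE], segs_d[1:3, , drop = FALSE],
                         b1, b2, b3)
  if (any(hits_a)) return(TRUE)
  hits_b <- .seg_tri_hit(segs_o[4:6, , drop = FALSE], segs_d[4:6, , drop = FALSE],
                         a1, a2, a3)
  any(hits_b)
}

#' Area-weighted outward vertex normals
#' @param surface an outward-oriented [tri_surface].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(surface) {
  fn <- .tri_normals(surface, normalize = FALSE)  # area-weighted
  n <- rowsum(rbind(fn, fn, fn),
              group = c(surface$triangles[, 1], surface$triangles[, 2],
                        surface$triangles[, 3]),
              reorder = TRUE)
  full <- matrix(0, nrow(surface$vertices), 3)
  full[as.integer(rownames(n)), ] <- n
  .normalize_rows(full)
}

#' Point-in-mesh test by ray parity
#'
#' Casts a ray along +x from each query point and counts triangle
#' crossings; odd parity means inside.  Intended for moderate numbers of
#' query points against watertight surfaces.
#' @param points k x 3 matrix of query points (mm).
#' @param surface a watertight [tri_surface].
#' @return logical vector of length k.
#' @export
points_in_mesh <- function(points, surface) {
  points <- rbind(points)
  cr <- .tri_corners(surface)
  p1 <- cr$p1; p2 <- cr$p2; p3 <- cr$p3
  # 2D projection to (y, z); precompute barycentric denominators
  d <- (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
       (p3[, 2] - p1[, 2]) * (p2[, 3] - p1[, 3])
  ok <- abs(d) > 1e-14
  ylo <- pmin(p1[, 2], pmin(p2[, 2], p3[, 2]))
  yhi <- pmax(p1[, 2], pmax(p2[, 2], p3[, 2]))
  zlo <- pmin(p1[, 3], pmin(p2[, 3], p3[, 3]))
  zhi <- pmax(p1[, 3], pmax(p2[, 3], p3[, 3]))
  out <- logical(nrow(points))
  # tiny deterministic jitter avoids rays through edges/vertices
  jy <- 1e-9; jz <- 2.3e-9
  for (i in seq_len(nrow(points))) {
    py <- points[i, 2] + jy; pz <- points[i, 3] + jz
    cand <- which(ok & ylo <= py & yhi >= py & zlo <= pz & zhi >= pz)
    if (!length(cand)) next
    w1 <- ((p2[cand, 2] - py) * (p3[cand, 3] - pz) -
           (p3[cand, 2] - py) * (p2[cand, 3] - pz)) / d[cand]
    w2 <- ((p3[cand, 2] - py) * (p1[cand, 3] - pz) -
           (p1[cand, 2] - py) * (p3[cand, 3] - pz)) / d[cand]
    w3 <- 1 - w1 - w2
    inside2d <- w1 > 0 & w2 > 0 & w3 > 0
    if (!any(inside2d)) next
    c2 <- cand[inside2d]
    xs <- w1[inside2d] * p1[c2, 1] + w2[inside2d] * p2[c2, 1] +
          w3[inside2d] * p3[c2, 1]
    out[i] <- (sum(xs > points[i, 1]) %% 2L) == 1L
  }
  out
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected to the sphere; a standard watertight
#' test body whose area and volume converge to the closed forms.
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions.
#' @param center length-3 center (mm).
#' @return a [tri_surface], outward oriented.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- .normalize_rows(v)
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    # midpoint cache keyed on sorted vertex pair
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- ekey(e[, 1], e[, 2])
    uk <- !duplicated(keys)
    mids <- .normalize_rows((v[e[uk, 1], , drop = FALSE] +
                             v[e[uk, 2], , drop = FALSE]) / 2)
    mid_idx <- nrow(v) + match(keys, keys[uk])
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m31 <- mid_idx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  orient_outward(tri_surface(v, f, label = "icosphere"))
}
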