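# Low-level geometric kernel: exact point-to-triangle distances,
# brute-force k-nearest-neighbour queries and inverse-distance-weighted
# field interpolation.  Everything is vectorised over triangles/samples;
# loops run over query points only.

# Precompute per-triangle quantities for repeated distance queries.
.tri_dist_cache <- function(surface) {
  cr <- .tri_corners(surface)
  a <- cr$p1
  e1 <- cr$p2 - cr$p1
  e2 <- cr$p3 - cr$p1
  d11 <- rowSums(e1 * e1)
  d12 <- rowSums(e1 * e2)
  d22 <- rowSums(e2 * e2)
  det <- pmax(d11 * d22 - d12 * d12, 1e-300)
  e3 <- cr$p3 - cr$p2                      # edge b->c
  list(a = a, b = cr$p2, c = cr$p3, e1 = e1, e2 = e2, e3 = e3,
       d11 = d11, d12 = d12, d22 = d22, det = det,
       l1 = pmax(d11, 1e-300), l2 = pmax(d22, 1e-300),
       l3 = pmax(rowSums(e3 * e3), 1e-300),
       centroids = (cr$p1 + cr$p2 + cr$p3) / 3,
       verts = surface$vertices)
}

# Exact unsigned distance from point p (length 3) to every triangle in the
# cache (optionally a subset); returns the minimum.
.point_surface_dist <- function(p, cache, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(cache$a))
  a <- cache$a[subset, , drop = FALSE]
  e1 <- cache$e1[subset, , drop = FALSE]
  e2 <- cache$e2[subset, , drop = FALSE]
  pp <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  d1p <- rowSums(e1 * pp)
  d2p <- rowSums(e2 * pp)
  u <- (cache$d22[subset] * d1p - cache$d12[subset] * d2p) / cache$det[subset]
  v <- (cache$d11[subset] * d2p - cache$d12[subset] * d1p) / cache$det[subset]
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  # distance via closest point on face for interior projections
  q <- a + u * e1 + v * e2
  dq <- pp + a - q          # p - q
  d_face <- rowSums(dq * dq)
  # segment distances for the rest
  seg_d2 <- function(orig, edge, len2) {
    w <- matrix(p, nrow(orig), 3, byrow = TRUE) - orig
    t <- pmin(pmax(rowSums(w * edge) / len2, 0), 1)
    diffv <- w - t * edge
    rowSums(diffv * diffv)
  }
  d_edge <- pmin(seg_d2(a, e1, cache$l1[subset]),
                 seg_d2(a, e2, cache$l2[subset]),
                 seg_d2(cache$b[subset, , drop = FALSE],
                        cache$e3[subset, , drop = FALSE],
                        cache$l3[subset]))
  d2 <- ifelse(inside, pmin(d_face, d_edge), d_edge)
  sqrt(min(d2))
}

# Exact distances from a small block of points to the same triangle
# subset, vectorised over (triangle, point) pairs.
.point_block_dist <- function(P, cache, subset) {
  P <- rbind(P)
  m <- nrow(P)
  nt <- length(subset)
  ti <- rep(subset, times = m)
  pi_ <- rep(seq_len(m), each = nt)
  a <- cache$a[ti, , drop = FALSE]
  e1 <- cache$e1[ti, , drop = FALSE]
  e2 <- cache$e2[ti, , drop = FALSE]
  pp <- P[pi_, , drop = FALSE] - a
  d1p <- rowSums(e1 * pp)
  d2p <- rowSums(e2 * pp)
  d11 <- cache$d11[ti]; d12 <- cache$d12[ti]; d22 <- cache$d22[ti]
  det <- cache$det[ti]
  u <- (d22 * d1p - d12 * d2p) / det
  v <- (d11 * d2p - d12 * d1p) / det
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  dq <- pp - u * e1 - v * e2
  d_face <- rowSums(dq * dq)
  seg_d2 <- function(orig, edge, len2) {
    w <- P[pi_, , drop = FALSE] - orig
    t <- pmin(pmax(rowSums(w * edge) / len2, 0), 1)
    diffv <- w - t * edge
    rowSums(diffv * diffv)
  }
  d_edge <- pmin(seg_d2(a, e1, cache$l1[ti]),
                 seg_d2(a, e2, cache$l2[ti]),
                 seg_d2(cache$b[ti, , drop = FALSE],
                        cache$e3[ti, , drop = FALSE], cache$l3[ti]))
  d2 <- ifelse(inside, pmin(d_face, d_edge), d_edge)
  sqrt(apply(matrix(d2, nt, m), 2, min))
}

# Distances from multiple points; prefilter triangles by centroid distance
# so long surfaces do not pay the full triangle count per query.
.points_surface_dist <- function(points, cache, prefilter_margin = 3) {
  points <- rbind(points)
  n <- nrow(points)
  out <- numeric(n)
  cen <- cache$centroids
  for (i in seq_len(n)) {
    p <- points[i, ]
    dc <- sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 +
               (cen[, 3] - p[3])^2)
    dmin <- min(dc)
    sel <- which(dc <= dmin + prefilter_margin)
    out[i] <- .point_surface_dist(p, cache, sel)
  }
  out
}

# k-nearest neighbours by brute force (chunked over queries).
.knn <- function(query, ref, k = 4L) {
  query <- rbind(query)
  nq <- nrow(query)
  nr <- nrow(ref)
  k <- min(k, nr)
  idx <- matrix(0L, nq, k)
  d <- matrix(0, nq, k)
  rs <- rowSums(ref * ref)
  chunk <- max(1L, floor(2e7 / nr))
  for (s in seq(1, nq, by = chunk)) {
    e <- min(s + chunk - 1, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q * q), rs, "+") - 2 * q %*% t(ref)
    # k passes of row-wise argmin (vectorised) beat per-row sorting for
    # the small k used here
    rows <- seq_len(nrow(q))
    for (j in seq_len(k)) {
      o <- max.col(-d2, ties.method = "first")
      idx[s:e, j] <- o
      d[s:e, j] <- sqrt(pmax(d2[cbind(rows, o)], 0))
      if (j < k) d2[cbind(rows, o)] <- Inf
    }
  }
  list(index = idx, dist = d)
}

# Inverse-distance-weighted (power 2) interpolation of a field_series at
# query points, using the k nearest samples.  Returns list with the
# interpolated k x nt x 3 array and the nearest-sample distance per query.
.idw_field <- function(query, field, k = 4L) {
  query <- rbind(query)
  nn <- .knn(query, field$points, k)
  w <- 1 / pmax(nn$dist, 1e-9)^2
  w <- w / rowSums(w)
  nt <- length(field$times)
  nq <- nrow(query)
  out <- array(0, c(nq, nt, 3))
  for (j in seq_len(ncol(nn$index))) {
    vj <- field$values[nn$index[, j], , , drop = FALSE]
    out <- out + array(rep(w[, j], nt * 3), c(nq, nt, 3)) * vj
  }
  list(values = out, nearest = nn$dist[, 1])
}

# Area of a closed planar polygon embedded in 3D with plane normal n.
.polygon_area <- function(points, normal) {
  n <- nrow(points)
  if (n < 3) return(0)
  nxt <- c(2:n, 1L)
  s <- colSums(.cross(points, points[nxt, , drop = FALSE]))
  abs(sum(s * normal)) / 2
}

.polygon_centroid <- function(points) colMeans(points)

# Even-odd point-in-polygon in 2D (vectorised over polygon edges).
.point_in_poly2d <- function(px, py, xs, ys) {
  n <- length(xs)
  xj <- xs[c(n, seq_len(n - 1))]
  yj <- ys[c(n, seq_len(n - 1))]
  straddle <- (ys > py) != (yj > py)
  if (!any(straddle)) return(FALSE)
  xi <- xs[straddle]; yi <- ys[straddle]
  xjj <- xj[straddle]; yjj <- yj[straddle]
  crosses <- px < (xjj - xi) * (py - yi) / (yjj - yi) + xi
  (sum(crosses) %% 2L) == 1L
}
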