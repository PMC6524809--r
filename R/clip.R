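# Exact planar sectioning of triangle meshes.  Triangles crossing the
# plane are split at the edge/plane intersections, so cross-section areas
# and cut volumes are exact on the triangulation (no voxelisation).

# Signed distances of vertices to plane; exact zeros are nudged off the
# plane deterministically so every triangle classifies cleanly.
.plane_sd <- function(vertices, origin, normal) {
  sd <- (vertices[, 1] - origin[1]) * normal[1] +
        (vertices[, 2] - origin[2]) * normal[2] +
        (vertices[, 3] - origin[3]) * normal[3]
  sd[sd == 0] <- 1e-12
  sd
}

# Cross-section loops of a closed surface with a plane: ordered closed
# polygons (3D points on the plane).  Fast path used by the ostium search;
# does not build the clipped mesh.
.section_loops <- function(surface, origin, normal, sd = NULL) {
  V <- surface$vertices
  Tm <- surface$triangles
  if (is.null(sd)) sd <- .plane_sd(V, origin, normal)
  pos <- sd > 0
  np <- pos[Tm[, 1]] + pos[Tm[, 2]] + pos[Tm[, 3]]
  cross_idx <- which(np == 1L | np == 2L)
  if (!length(cross_idx)) return(list())
  tri <- Tm[cross_idx, , drop = FALSE]
  tp <- cbind(pos[tri[, 1]], pos[tri[, 2]], pos[tri[, 3]])
  # rotate so the odd vertex (the isolated one) sits first
  odd_is_pos <- np[cross_idx] == 1L
  oddpos <- ifelse(odd_is_pos, max.col(tp, "first"), max.col(!tp, "first"))
  r1 <- tri[cbind(seq_len(nrow(tri)), oddpos)]
  r2 <- tri[cbind(seq_len(nrow(tri)), oddpos %% 3 + 1)]
  r3 <- tri[cbind(seq_len(nrow(tri)), (oddpos + 1) %% 3 + 1)]
  # crossing edges are (r1,r2) and (r1,r3); numeric edge keys
  K <- nrow(V) + 1
  e1k <- pmin(r1, r2) * K + pmax(r1, r2)
  e2k <- pmin(r1, r3) * K + pmax(r1, r3)
  cut_point <- function(a, b) {
    t <- sd[a] / (sd[a] - sd[b])
    V[a, , drop = FALSE] + t * (V[b, , drop = FALSE] - V[a, , drop = FALSE])
  }
  p1 <- cut_point(r1, r2)
  p2 <- cut_point(r1, r3)
  # chain segments: on a closed manifold each cut mesh edge belongs to
  # exactly two section segments
  uk <- unique(c(e1k, e2k))
  k1 <- match(e1k, uk)
  k2 <- match(e2k, uk)
  pts <- matrix(NA_real_, length(uk), 3)
  pts[k1, ] <- p1
  pts[k2, ] <- p2
  nseg <- length(k1)
  npt <- length(uk)
  cnt <- tabulate(c(k1, k2), npt)
  if (any(cnt != 2L)) {
    # non-manifold or open geometry near the plane: drop incomplete
    # segments and keep only cleanly paired ones
    okseg <- cnt[k1] == 2L & cnt[k2] == 2L
    k1 <- k1[okseg]; k2 <- k2[okseg]
    nseg <- length(k1)
    if (!nseg) return(list())
    cnt <- tabulate(c(k1, k2), npt)
    if (any(cnt[c(k1, k2)] != 2L)) return(list())
  }
  ordp <- order(c(k1, k2))
  seg_of <- rep(seq_len(nseg), 2)[ordp]
  adj <- matrix(0L, 2, npt)
  adj[, sort(unique(c(k1, k2)))] <- matrix(seg_of, nrow = 2)
  used <- logical(nseg)
  loops <- list()
  buf <- integer(nseg + 1)
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    n_in <- 0L
    used[s0] <- TRUE
    cur_seg <- s0
    cur_pt <- k1[s0]
    n_in <- n_in + 1L; buf[n_in] <- cur_pt
    nxt_pt <- k2[s0]
    repeat {
      n_in <- n_in + 1L; buf[n_in] <- nxt_pt
      two <- adj[, nxt_pt]
      nxt <- if (two[1] == cur_seg) two[2] else two[1]
      if (nxt == 0L || used[nxt]) break
      used[nxt] <- TRUE
      cur_seg <- nxt
      nxt_pt <- if (k1[nxt] == nxt_pt) k2[nxt] else k1[nxt]
    }
    if (n_in >= 4)   # closed loop: first point repeats at the end
      loops[[length(loops) + 1]] <- pts[buf[seq_len(n_in - 1)], ,
                                        drop = FALSE]
  }
  loops
}

# Clip a closed surface, keeping the positive side of the plane.  Returns
# the kept piece (optionally capped along each boundary loop) plus the
# boundary loops themselves.  `component_point`: if given, keep only the
# connected component whose surface is nearest that point.
clip_surface <- function(surface, origin, normal, cap = FALSE,
                         component_point = NULL) {
  V <- surface$vertices
  Tm <- surface$triangles
  sd <- .plane_sd(V, origin, normal)
  pos <- sd > 0
  np <- pos[Tm[, 1]] + pos[Tm[, 2]] + pos[Tm[, 3]]
  keep <- Tm[np == 3L, , drop = FALSE]
  cross1 <- which(np == 1L)
  cross2 <- which(np == 2L)
  .assert(length(cross1) + length(cross2) > 0 || nrow(keep) > 0,
          "aneumorph_topology_error", "plane misses the surface")
  new_env <- new.env()
  new_env$pts <- list()
  new_env$keys <- character(0)
  get_cut <- function(a, b) {
    key <- paste(pmin(a, b), pmax(a, b))
    m <- match(key, new_env$keys)
    needs <- is.na(m)
    if (any(needs)) {
      an <- a[needs]; bn <- b[needs]
      t <- sd[an] / (sd[an] - sd[bn])
      p <- V[an, , drop = FALSE] + t * (V[bn, , drop = FALSE] -
                                          V[an, , drop = FALSE])
      new_env$keys <- c(new_env$keys, key[needs])
      new_env$pts <- c(new_env$pts, list(p))
      m <- match(key, new_env$keys)
    }
    nrow(V) + m
  }
  tris <- list(keep)
  bnd <- NULL
  if (length(cross1)) {
    tri <- Tm[cross1, , drop = FALSE]
    tp <- cbind(pos[tri[, 1]], pos[tri[, 2]], pos[tri[, 3]])
    i1 <- max.col(tp, "first")
    a <- tri[cbind(seq_along(cross1), i1)]
    b <- tri[cbind(seq_along(cross1), i1 %% 3 + 1)]
    c_ <- tri[cbind(seq_along(cross1), (i1 + 1) %% 3 + 1)]
    mab <- get_cut(a, b)
    mca <- get_cut(c_, a)
    tris <- c(tris, list(cbind(a, mab, mca)))
    bnd <- rbind(bnd, cbind(mab, mca))
  }
  if (length(cross2)) {
    tri <- Tm[cross2, , drop = FALSE]
    tp <- cbind(pos[tri[, 1]], pos[tri[, 2]], pos[tri[, 3]])
    i3 <- max.col(!tp, "first")  # the single negative vertex
    c_ <- tri[cbind(seq_along(cross2), i3)]
    a <- tri[cbind(seq_along(cross2), i3 %% 3 + 1)]
    b <- tri[cbind(seq_along(cross2), (i3 + 1) %% 3 + 1)]
    mbc <- get_cut(b, c_)
    mca <- get_cut(c_, a)
    tris <- c(tris, list(cbind(a, b, mbc), cbind(a, mbc, mca)))
    bnd <- rbind(bnd, cbind(mbc, mca))
  }
  allV <- rbind(V, do.call(rbind, new_env$pts))
  allT <- do.call(rbind, tris)
  .assert(nrow(allT) > 0, "aneumorph_topology_error",
          "nothing on the positive side of the plane")
  # boundary loops: chain the cut edges
  loops <- .chain_loops(bnd)
  component_areas <- NULL
  if (!is.null(component_point)) {
    compo <- .triangle_components(allT)
    # component whose vertices come nearest the probe point
    dmin <- vapply(seq_len(max(compo)), function(ci) {
      vs <- unique(as.vector(allT[compo == ci, , drop = FALSE]))
      min(sqrt((allV[vs, 1] - component_point[1])^2 +
               (allV[vs, 2] - component_point[2])^2 +
               (allV[vs, 3] - component_point[3])^2))
    }, numeric(1))
    p1c <- allV[allT[, 1], , drop = FALSE]
    p2c <- allV[allT[, 2], , drop = FALSE]
    p3c <- allV[allT[, 3], , drop = FALSE]
    tarea <- 0.5 * .rownorm(.cross(p2c - p1c, p3c - p1c))
    component_areas <- as.numeric(rowsum(tarea, compo))
    sel <- which.min(dmin)
    keep_tris <- compo == sel
    kept_vs <- unique(as.vector(allT[keep_tris, , drop = FALSE]))
    loops <- Filter(function(l) all(l %in% kept_vs), loops)
    allT <- allT[keep_tris, , drop = FALSE]
    attr(component_areas, "kept") <- sel
  }
  cap_area <- 0
  if (cap) {
    for (loop in loops) {
      lp <- allV[loop, , drop = FALSE]
      cen <- colMeans(lp)
      cap_area <- cap_area + .polygon_area(lp, .unit(normal))
      ci <- nrow(allV) + 1L
      allV <- rbind(allV, cen)
      nl <- length(loop)
      fan <- cbind(ci, loop, loop[c(2:nl, 1)])
      # orient cap normals against the clip normal (outward for the kept
      # positive-side piece)
      fn <- .cross(allV[fan[, 2], , drop = FALSE] - allV[fan[, 1], , drop = FALSE],
                   allV[fan[, 3], , drop = FALSE] - allV[fan[, 1], , drop = FALSE])
      flip <- (fn %*% normal)[, 1] > 0
      fan[flip, ] <- fan[flip, c(1, 3, 2)]
      allT <- rbind(allT, fan)
    }
  }
  piece <- tri_surface(allV, allT, label = surface$provenance_label,
                       clean = TRUE)
  list(surface = piece,
       loops = lapply(loops, function(l) allV[l, , drop = FALSE]),
       cap_area = cap_area,
       n_boundary_loops = length(loops),
       component_areas = component_areas)
}

# Chain boundary edges (two-column vertex-id matrix) into ordered closed
# vertex loops.
.chain_loops <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  verts <- unique(as.vector(edges))
  adj <- new.env(hash = TRUE)
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    adj[[a]] <- c(adj[[a]], edges[i, 2])
    adj[[b]] <- c(adj[[b]], edges[i, 1])
  }
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (v0 in verts) {
    if (!is.null(visited[[as.character(v0)]])) next
    loop <- v0
    visited[[as.character(v0)]] <- TRUE
    prev <- NA_integer_
    cur <- v0
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nbrs <- nbrs[is.na(prev) | nbrs != prev]
      nxt <- NA_integer_
      for (cand in nbrs) {
        if (is.null(visited[[as.character(cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      loop <- c(loop, nxt)
      visited[[as.character(nxt)]] <- TRUE
      prev <- cur
      cur <- nxt
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# Connected components of a triangle set via shared vertices.
.triangle_components <- function(Tm) {
  verts <- sort(unique(as.vector(Tm)))
  vid <- match(Tm, verts)
  dim(vid) <- dim(Tm)
  g <- igraph::graph_from_edgelist(
    rbind(vid[, 1:2, drop = FALSE], vid[, 2:3, drop = FALSE]),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  tri_comp <- memb[vid[, 1]]
  # re-label 1..k
  match(tri_comp, unique(tri_comp))
}
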