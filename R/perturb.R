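# Segmentation-variability emulation: an ensemble of smooth normal-offset
# perturbations of one ground-truth phantom.
#
# The offset field is a fixed spatial basis of Gaussian bumps with random
# coefficients per group, normalised so the pointwise (across-group)
# standard deviation equals the prescribed radius noise at every vertex.
# Smooth, spatially correlated noise mimics how segmentations differ —
# coherent over/under-estimation of the wall — whereas i.i.d. vertex
# jitter would destroy watertightness statistics and inflate curvature.
# Optional features: a random neck dilation/erosion per group (neck over-
# or under-segmentation) and random dropping of side branches.

#' Specification of a segmentation-perturbation ensemble
#'
#' @param radius_noise pointwise standard deviation of the wall offset
#'   (mm); the study-scale default is 0.13 mm.
#' @param correlation_length length scale of the offset field (mm).
#' @param neck_bias maximum neck over/under-segmentation offset (mm); each
#'   group draws a bias uniformly in `[-neck_bias, +neck_bias]`.
#' @param branch_dropout probability that a group misses each side branch.
#' @param n_groups ensemble size (the study analysed 24-26 groups).
#' @param seed integer RNG seed; the ensemble is reproducible per
#'   (seed, group index).
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(radius_noise = 0.13, correlation_length = 8,
                              neck_bias = 0, branch_dropout = 0,
                              n_groups = 24L, seed = 1L) {
  .assert(radius_noise >= 0, "aneumorph_spec_error",
          "radius_noise must be non-negative")
  .assert(branch_dropout >= 0 && branch_dropout <= 1,
          "aneumorph_spec_error", "branch_dropout must be in [0, 1]")
  .assert(n_groups >= 2, "aneumorph_spec_error", "need at least 2 groups")
  .assert(correlation_length > 0, "aneumorph_spec_error",
          "correlation_length must be positive")
  structure(list(radius_noise = radius_noise,
                 correlation_length = correlation_length,
                 neck_bias = neck_bias, branch_dropout = branch_dropout,
                 n_groups = as.integer(n_groups), seed = as.integer(seed)),
            class = "perturbation_spec")
}

# Basis matrix of Gaussian bumps at fixed centers, row-normalised so that
# rowSums(B^2) == 1 (pointwise unit variance under iid N(0,1) coefficients).
.noise_basis <- function(vertices, centers, ell) {
  B <- matrix(0, nrow(vertices), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d2 <- (vertices[, 1] - centers[j, 1])^2 +
          (vertices[, 2] - centers[j, 2])^2 +
          (vertices[, 3] - centers[j, 3])^2
    B[, j] <- exp(-d2 / (2 * ell^2))
  }
  nrm <- sqrt(rowSums(B * B))
  nrm[nrm < 1e-12] <- 1
  B / nrm
}

#' Generate an ensemble of perturbed segmentations of a phantom
#'
#' @param phantom a [make_phantom()] result (the ground truth).
#' @param pspec a [perturbation_spec()].
#' @return list of [tri_surface]s, one per group, labelled
#'   `group_01 ...`; groups that dropped branches are rebuilt from the
#'   branch-free spec so the stump is capped smoothly.  Deterministic for
#'   fixed (seed, group index).
#' @export
perturb_ensemble <- function(phantom, pspec) {
  .assert(inherits(phantom, "phantom"), "aneumorph_spec_error",
          "phantom must be a make_phantom() result")
  .assert(inherits(pspec, "perturbation_spec"), "aneumorph_spec_error",
          "pspec must be a perturbation_spec")
  base <- phantom$surface
  nb <- length(phantom$spec$branches)
  nobranch <- NULL
  # fixed bump centers: low-discrepancy subsample of the truth vertices
  set.seed(pspec$seed)
  ncen <- 80L
  cen_idx <- round(seq(1, nrow(base$vertices), length.out = ncen))
  centers <- base$vertices[cen_idx, , drop = FALSE]
  basis_cache <- new.env()
  get_basis <- function(surf, key) {
    if (is.null(basis_cache[[key]]))
      basis_cache[[key]] <- .noise_basis(surf$vertices, centers,
                                         pspec$correlation_length)
    basis_cache[[key]]
  }
  neck <- phantom$truth$neck_origin
  out <- vector("list", pspec$n_groups)
  for (g in seq_len(pspec$n_groups)) {
    set.seed(.substream_seed(pspec$seed, g))
    z <- stats::rnorm(ncen)
    bias <- if (pspec$neck_bias > 0)
      stats::runif(1, -pspec$neck_bias, pspec$neck_bias) else 0
    drop_branches <- nb > 0 &&
      any(stats::runif(nb) < pspec$branch_dropout)
    surf <- base
    key <- "base"
    if (drop_branches) {
      if (is.null(nobranch)) {
        sp2 <- phantom$spec
        sp2$branches <- list()
        nobranch <- make_phantom(sp2)$surface
      }
      surf <- nobranch
      key <- "nobranch"
    }
    offs <- rep(0, nrow(surf$vertices))
    if (pspec$radius_noise > 0) {
      B <- get_basis(surf, key)
      offs <- pspec$radius_noise * as.numeric(B %*% z)
    }
    if (bias != 0 && !is.null(neck)) {
      w_neck <- 1.5 * phantom$truth$neck_radius
      d2 <- (surf$vertices[, 1] - neck[1])^2 +
            (surf$vertices[, 2] - neck[2])^2 +
            (surf$vertices[, 3] - neck[3])^2
      offs <- offs + bias * exp(-d2 / (2 * w_neck^2))
    }
    if (all(offs == 0)) {
      g_surf <- surf
    } else {
      nrml <- vertex_normals(surf)
      amp <- 1
      old_fn <- .tri_normals(surf)
      # fold-over check: isolated skinny iso-surfacing triangles reorient
      # under any offset, so only a contiguous folded fraction of the wall
      # indicates a genuine self-fold worth damping
      areas <- .tri_areas(surf)
      chk <- areas > 0.5 * stats::median(areas)
      folded <- function(g_surf) {
        new_fn <- .tri_normals(g_surf)
        dots <- rowSums(old_fn[chk, , drop = FALSE] *
                          new_fn[chk, , drop = FALSE])
        mean(dots < -0.5) > 0.01
      }
      for (try in 1:3) {
        vv <- surf$vertices + amp * offs * nrml
        g_surf <- tri_surface(vv, surf$triangles, clean = FALSE)
        if (!folded(g_surf)) break
        amp <- amp / 2          # damp amplitude if the wall folds over
      }
      if (folded(g_surf))
        attr(g_surf, "perturbation_flag") <- "damped_self_folding"
    }
    g_surf$provenance_label <- sprintf("group_%02d", g)
    out[[g]] <- g_surf
  }
  out
}

#' Write / read an ensemble directory of surface files
#'
#' Mirrors the challenge-dataset layout: one file per group,
#' `group_01.stl`, `group_02.stl`, ...
#' @param surfaces list of [tri_surface]s.
#' @param dir directory (created if needed).
#' @param format passed to [write_surface()].
#' @return the directory, invisibly.
#' @export
write_ensemble <- function(surfaces, dir, format = "stl") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "ply") "ply" else "stl"
  for (i in seq_along(surfaces))
    write_surface(surfaces[[i]],
                  file.path(dir, sprintf("group_%02d.%s", i, ext)),
                  format = format)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(stl|ply|obj)$",
                           full.names = TRUE))
  .assert(length(files) > 0, "aneumorph_format_error",
          "no surface files found in %s", dir)
  lapply(files, read_surface)
}
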