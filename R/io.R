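# Surface and field-table readers/writers.
#
# Formats covered: STL (ASCII and binary) read/write, PLY (ASCII) read/write,
# OBJ read-only — the common trio for exchanged vascular segmentations.
# No mesh repair beyond vertex dedupe and degenerate-triangle dropping.

#' Read a triangulated surface file
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; default guesses from the
#'   file extension.
#' @param label provenance label stored on the surface; defaults to the
#'   file name.
#' @return a cleaned [tri_surface]; repair counts are in `attr(, "repairs")`.
#' @export
read_surface <- function(path, format = NULL, label = basename(path)) {
  .assert(file.exists(path), "aneumorph_format_error",
          "file does not exist: %s", path)
  .assert(file.size(path) > 0, "aneumorph_format_error",
          "empty file: %s", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply", "obj"))
  raw <- switch(format,
    stl = .read_stl(path),
    ply = .read_ply(path),
    obj = .read_obj(path))
  tri_surface(raw$vertices, raw$triangles, label = label)
}

.read_stl <- function(path) {
  head <- readBin(path, "raw", n = 512)
  is_ascii <- length(grepRaw("solid", head, fixed = TRUE)) > 0 &&
              length(grepRaw("facet", head, fixed = TRUE)) > 0
  if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  .assert(length(vl) >= 3 && length(vl) %% 3 == 0, "aneumorph_format_error",
          "malformed ASCII STL: %d vertex records", length(vl))
  nums <- suppressWarnings(
    matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                      "\\s+"))), ncol = 3, byrow = TRUE))
  .assert(!anyNA(nums), "aneumorph_format_error",
          "non-numeric vertex coordinates in ASCII STL")
  list(vertices = nums,
       triangles = matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE))
}

.read_stl_binary <- function(path) {
  sz <- file.size(path)
  .assert(sz >= 84, "aneumorph_format_error", "binary STL too short")
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nfac <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  .assert(nfac > 0 && sz >= 84 + 50 * nfac, "aneumorph_format_error",
          "binary STL truncated (%d facets declared)", nfac)
  body <- readBin(con, "raw", n = 50 * nfac)
  rec <- matrix(body, nrow = 50)
  float_bytes <- as.vector(rec[1:48, ])
  vals <- readBin(float_bytes, "numeric", n = 12 * nfac, size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 12, byrow = TRUE)  # normal xyz + 3 vertices
  verts <- matrix(0, 3 * nfac, 3)
  verts[seq(1, 3 * nfac, 3), ] <- m[, 4:6, drop = FALSE]
  verts[seq(2, 3 * nfac, 3), ] <- m[, 7:9, drop = FALSE]
  verts[seq(3, 3 * nfac, 3), ] <- m[, 10:12, drop = FALSE]
  list(vertices = verts,
       triangles = matrix(seq_len(3 * nfac), ncol = 3, byrow = TRUE))
}

.read_ply <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character()
  repeat {
    l <- readLines(con, 1)
    .assert(length(l) == 1, "aneumorph_format_error", "PLY header truncated")
    hdr <- c(hdr, l)
    if (grepl("^end_header", l)) break
    .assert(length(hdr) < 200, "aneumorph_format_error", "PLY header too long")
  }
  .assert(grepl("^ply", hdr[1]), "aneumorph_format_error", "not a PLY file")
  .assert(any(grepl("format ascii", hdr)), "aneumorph_format_error",
          "only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  .assert(!is.na(nv) && !is.na(nf), "aneumorph_format_error",
          "PLY header lacks vertex/face counts")
  vl <- readLines(con, nv)
  fl <- readLines(con, nf)
  vm <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                        `[`, 1:3))), ncol = 3, byrow = TRUE)
  .assert(!anyNA(vm), "aneumorph_format_error", "bad PLY vertex records")
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    n <- as.integer(p[1])
    idx <- as.integer(p[2:(1 + n)]) + 1L
    if (n == 3) rbind(idx)
    else t(vapply(2:(n - 1), function(k) idx[c(1, k, k + 1)], integer(3)))
  })
  list(vertices = vm, triangles = do.call(rbind, faces))
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  .assert(length(vl) >= 3 && length(fl) >= 1, "aneumorph_format_error",
          "OBJ file lacks vertices or faces")
  vm <- matrix(as.numeric(unlist(lapply(
    strsplit(trimws(sub("^v\\s+", "", vl)), "\\s+"), `[`, 1:3))),
    ncol = 3, byrow = TRUE)
  .assert(!anyNA(vm), "aneumorph_format_error", "bad OBJ vertex records")
  faces <- lapply(strsplit(trimws(sub("^f\\s+", "", fl)), "\\s+"),
                  function(p) {
    idx <- as.integer(vapply(strsplit(p, "/"), `[`, character(1), 1))
    idx[idx < 0] <- nrow(vm) + 1L + idx[idx < 0]
    if (length(idx) == 3) rbind(idx)
    else t(vapply(2:(length(idx) - 1),
                  function(k) idx[c(1, k, k + 1)], integer(3)))
  })
  list(vertices = vm, triangles = do.call(rbind, faces))
}

#' Write a surface to STL or PLY
#'
#' @param surface a [tri_surface].
#' @param path output path.
#' @param format `"stl"` (binary), `"stl_ascii"` or `"ply"` (ASCII).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path,
                          format = c("stl", "stl_ascii", "ply")) {
  format <- match.arg(format)
  V <- surface$vertices
  Tm <- surface$triangles
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(Tm)), con, size = 4, endian = "little")
    n <- .tri_normals(surface)
    rec <- cbind(n, V[Tm[, 1], ], V[Tm[, 2], ], V[Tm[, 3], ])
    fr <- writeBin(as.numeric(t(rec)), raw(), size = 4, endian = "little")
    body <- matrix(as.raw(0), 50, nrow(Tm))
    body[1:48, ] <- matrix(fr, 48)
    writeBin(as.vector(body), con)
  } else if (format == "stl_ascii") {
    n <- .tri_normals(surface)
    out <- c("solid aneumorph",
             unlist(lapply(seq_len(nrow(Tm)), function(i) {
               c(sprintf("  facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         V[Tm[i, ], 1], V[Tm[i, ], 2], V[Tm[i, ], 3]),
                 "    endloop", "  endfacet")
             })),
             "endsolid aneumorph")
    writeLines(out, path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(V)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(Tm)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr,
                 sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("3 %d %d %d", Tm[, 1] - 1L, Tm[, 2] - 1L,
                         Tm[, 3] - 1L)),
               path)
  }
  invisible(path)
}
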