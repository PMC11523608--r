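#' Triangulated surface mesh
#'
#' Light-weight carrier for triangulated anatomy (left atrium, right atrium,
#' fossa ovalis) in millimetres.  Vertices are an `n x 3` numeric matrix,
#' faces an `m x 3` integer matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix, `n x 3`, coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param name label for printing.
#' @return An object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `name`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
#'               name = "tetra")
#' mesh_volume(m)
#' @export
tri_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    fg_validation_error("vertices and faces must have 3 columns")
  if (nrow(vertices) < 3L || nrow(faces) < 1L)
    fg_validation_error("mesh needs at least 3 vertices and 1 face")
  if (!all(is.finite(vertices)))
    fg_validation_error("mesh vertices contain non-finite coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    fg_validation_error("face indices out of range")
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  watertight: %s\n", is_watertight(x)))
  invisible(x)
}

#' Read a surface mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected).  Coordinates are returned in
#' millimetres; meshes exported in metres are converted with `units = "m"`.
#' Coincident facet corners are welded into shared vertices.
#'
#' @param path path to an `.stl` file.
#' @param units unit of the file's coordinates, `"mm"` (default) or `"m"`.
#' @param name mesh label; defaults to the file name.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, units = c("mm", "m"), name = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    fg_resolution_error(sprintf("mesh file not found: '%s'", path))
  head_raw <- readBin(path, "raw", n = 512L)
  if (length(head_raw) == 0L) fg_format_error(sprintf("empty file: '%s'", path))
  tri <- if (is_ascii_stl(head_raw, path)) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) fg_validation_error(sprintf("no facets in '%s'", path))
  if (units == "m") tri <- tri * 1000
  weld_facets(tri, name = name %||% basename(path))
}

# ASCII STL starts with "solid" AND contains "facet"; some binary exporters
# also start with "solid", so check for the keyword in the header region.
is_ascii_stl <- function(head_raw, path) {
  txt <- tryCatch(rawToChar(head_raw[head_raw != as.raw(0L)]), error = function(e) "")
  grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, fixed = TRUE, useBytes = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    fg_format_error(sprintf("malformed ASCII STL: '%s'", path))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) as.numeric(tok[2:4]))
  tri <- do.call(rbind, nums)
  if (!all(is.finite(tri))) fg_format_error(sprintf("non-numeric vertex in '%s'", path))
  tri
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!is.finite(n) || n < 0L || sz < 84 + 50 * n)
    fg_format_error(sprintf("corrupt binary STL: '%s'", path))
  tri <- matrix(0, nrow = 3L * n, ncol = 3L)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  tri
}

# Merge duplicated facet-corner coordinates into a shared vertex table.
weld_facets <- function(tri, name) {
  key <- paste(format(tri[, 1], digits = 17), format(tri[, 2], digits = 17),
               format(tri[, 3], digits = 17))
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces, name = name)
}

#' Write a mesh to an STL file
#'
#' @param mesh a [tri_mesh()].
#' @param path destination path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3)
        writeLines(sprintf("      vertex %.9e %.9e %.9e",
                           v[f[i, j], 1], v[f[i, j], 2], v[f[i, j], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", substr(paste("fossagii", mesh$name), 1, 80)))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(n[i, ], t(v[f[i, ], , drop = FALSE]))[1:12], con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

#' Export a per-vertex scalar heatmap as ASCII PLY
#'
#' Writes the mesh with a `quality` property and a red-to-blue colour ramp,
#' viewable in MeshLab/ParaView; used for GII heatmaps and reachability maps.
#'
#' @param mesh a [tri_mesh()].
#' @param scalar numeric vector, one value per vertex.
#' @param path destination `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply_scalar <- function(mesh, scalar, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  if (length(scalar) != nrow(v))
    fg_validation_error("scalar length must equal vertex count")
  rng <- range(scalar, finite = TRUE)
  t <- if (diff(rng) > 0) (scalar - rng[1]) / diff(rng) else rep(0, length(scalar))
  col <- grDevices::col2rgb(grDevices::hcl.colors(256, "RdYlBu", rev = TRUE))
  ci <- pmin(pmax(1L, as.integer(t * 255) + 1L), 256L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               "property float quality",
               "property uchar red", "property uchar green", "property uchar blue",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %.6f %d %d %d",
                     v[, 1], v[, 2], v[, 3], scalar,
                     col[1, ci], col[2, ci], col[3, ci]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Per-face unit normals
#' @param mesh a [tri_mesh()].
#' @return `m x 3` matrix of unit normals (right-hand rule on vertex order).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

#' Area-weighted per-vertex unit normals
#' @param mesh a [tri_mesh()].
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted (unnormalized)
  vn <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate_sum(f[, j], n[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulate_sum(f[, j], n[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulate_sum(f[, j], n[, 3], nrow(v))
  }
  len <- sqrt(rowSums(vn * vn))
  len[len == 0] <- 1
  vn / len
}

tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Is every mesh edge shared by exactly two opposite-oriented faces?
#' @param mesh a [tri_mesh()].
#' @return logical flag.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  directed <- paste(a, b)
  if (anyDuplicated(directed) > 0L) return(FALSE)  # non-manifold / repeated edge
  all(directed %in% paste(b, a))                   # every half-edge has its twin
}

#' Signed enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a [tri_mesh()].
#' @return volume in mm^3; positive when faces are oriented outward.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}
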