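#' Write a surface mesh (ASCII PLY or legacy-VTK polydata)
#'
#' The dialect is chosen from the file extension: `.ply` or `.vtk`.
#' Vertex coordinates are written in full double precision; optional
#' per-vertex scalars are stored as a `quality` property (PLY) or a
#' named `SCALARS` array (VTK).
#'
#' @param mesh a [surface_mesh].
#' @param path output file ending in `.ply` or `.vtk`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") write_mesh_ply(mesh, path)
  else if (ext == "vtk") write_mesh_vtk(mesh, path)
  else stop("write_mesh: unknown extension '.", ext,
            "'; supported dialects: .ply (ascii), .vtk (legacy ascii)")
  invisible(path)
}

#' Read a surface mesh written in ASCII PLY or legacy-VTK format
#'
#' @param path input file ending in `.ply` or `.vtk`.
#' @return A [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_mesh_ply(path)
  else if (ext == "vtk") read_mesh_vtk(path)
  else stop("read_mesh: unknown extension '.", ext,
            "'; supported dialects: .ply (ascii), .vtk (legacy ascii)")
}

fmt_num <- function(x) sprintf("%.17g", x)

write_mesh_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_s <- !is.null(mesh$scalars)
  header <- c(
    "ply", "format ascii 1.0", "comment limbkit surface mesh",
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    if (has_s) "property double quality",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  vmat <- mesh$vertices
  vlines <- if (has_s)
    paste(fmt_num(vmat[, 1]), fmt_num(vmat[, 2]), fmt_num(vmat[, 3]),
          fmt_num(mesh$scalars))
  else paste(fmt_num(vmat[, 1]), fmt_num(vmat[, 2]), fmt_num(vmat[, 3]))
  flines <- if (nf > 0)
    paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  else character()
  writeLines(c(header, vlines, flines), path)
}

read_mesh_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("read_mesh: not a PLY file: ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("read_mesh: PLY header not terminated in ", path)
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  vprops <- grep("^property (double|float) ", header, value = TRUE)
  has_s <- any(grepl("quality$", vprops))
  vlines <- lines[endh + seq_len(nv)]
  vdat <- matrix(scan(text = vlines, quiet = TRUE), nrow = nv, byrow = TRUE)
  flines <- if (nf > 0) lines[endh + nv + seq_len(nf)] else character()
  faces <- if (nf > 0) {
    fdat <- matrix(scan(text = flines, quiet = TRUE), nrow = nf, byrow = TRUE)
    if (any(fdat[, 1] != 3)) stop("read_mesh: non-triangular PLY face in ", path)
    fdat[, 2:4, drop = FALSE] + 1L
  } else matrix(integer(), ncol = 3)
  surface_mesh(vdat[, 1:3, drop = FALSE], faces,
               if (has_s) vdat[, 4] else NULL)
}

write_mesh_vtk <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  lines <- c(
    "# vtk DataFile Version 3.0", "limbkit surface mesh", "ASCII",
    "DATASET POLYDATA",
    paste("POINTS", nv, "double"),
    paste(fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
          fmt_num(mesh$vertices[, 3])),
    paste("POLYGONS", nf, 4L * nf))
  if (nf > 0)
    lines <- c(lines, paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                            mesh$faces[, 3] - 1L))
  if (!is.null(mesh$scalars))
    lines <- c(lines,
               paste("POINT_DATA", nv),
               "SCALARS quality double 1",
               "LOOKUP_TABLE default",
               fmt_num(mesh$scalars))
  writeLines(lines, path)
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("read_mesh: not a legacy VTK file: ", path)
  if (!any(lines == "DATASET POLYDATA"))
    stop("read_mesh: not a POLYDATA VTK file: ", path)
  pts_i <- grep("^POINTS ", lines)[1]
  nv <- as.integer(strsplit(lines[pts_i], " +")[[1]][2])
  verts <- matrix(scan(text = lines[pts_i + seq_len(nv)], quiet = TRUE),
                  nrow = nv, byrow = TRUE)
  poly_i <- grep("^POLYGONS ", lines)[1]
  nf <- as.integer(strsplit(lines[poly_i], " +")[[1]][2])
  faces <- if (nf > 0) {
    fdat <- matrix(scan(text = lines[poly_i + seq_len(nf)], quiet = TRUE),
                   nrow = nf, byrow = TRUE)
    if (any(fdat[, 1] != 3)) stop("read_mesh: non-triangular VTK face in ", path)
    fdat[, 2:4, drop = FALSE] + 1L
  } else matrix(integer(), ncol = 3)
  scalars <- NULL
  sc_i <- grep("^SCALARS ", lines)
  if (length(sc_i) > 0) {
    skip <- if (grepl("^LOOKUP_TABLE", lines[sc_i[1] + 1L])) 2L else 1L
    scalars <- scan(text = lines[(sc_i[1] + skip):length(lines)], n = nv,
                    quiet = TRUE)
  }
  surface_mesh(verts, faces, scalars)
}
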