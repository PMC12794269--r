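#' Voxel grid: a 3D scalar field with physical calibration
#'
#' The unit of all volume operations. Intensities are stored as a numeric
#' 3D array indexed `[x, y, z]`; the physical coordinate (in micrometres)
#' of voxel index `(i, j, k)` (1-based) is
#' `origin + (i-1, j-1, k-1) * spacing` — i.e. voxel *centres* sit on the
#' lattice, not voxel corners.
#'
#' @param data numeric 3D array of intensities (arbitrary units).
#' @param spacing length-3 positive numeric, physical size of one voxel
#'   along each axis (micrometres).
#' @param origin length-3 numeric, physical coordinate of voxel (1,1,1)
#'   (micrometres).
#' @param channel_name optional text label (e.g. `"DAPI"`, `"Hoxa11"`).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       channel_name = "") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("voxel_grid: 'data' must have 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_grid: 'spacing' must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("voxel_grid: 'origin' must be 3 finite numbers")
  structure(
    list(data = data, spacing = spacing, origin = origin,
         channel_name = as.character(channel_name)[1]),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid%s %dx%dx%d, spacing (%g, %g, %g) um, origin (%g, %g, %g)>\n",
              if (nzchar(x$channel_name)) paste0(" '", x$channel_name, "'") else "",
              d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Physical coordinates of voxel centres
#'
#' @param grid a [voxel_grid].
#' @param axis axis 1, 2 or 3.
#' @return numeric vector of voxel-centre coordinates along `axis` (um).
#' @export
grid_axis_coords <- function(grid, axis) {
  n <- dim(grid$data)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Triangulated surface mesh
#'
#' The unit of staging and registration. Vertices carry physical
#' micrometre coordinates; faces are 1-based vertex-index triples.
#'
#' @param vertices numeric matrix, n x 3 (um).
#' @param faces integer matrix, m x 3, 1-based indices into `vertices`.
#' @param scalars optional numeric vector of per-vertex values.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalars = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("surface_mesh: face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("surface_mesh: face with repeated vertices")
  }
  if (!is.null(scalars)) {
    scalars <- as.numeric(scalars)
    if (length(scalars) != nrow(vertices))
      stop("surface_mesh: 'scalars' must have one value per vertex")
  }
  structure(list(vertices = vertices, faces = faces, scalars = scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$scalars)) ", with scalars" else ""))
  invisible(x)
}

#' Limb sample metadata
#'
#' @param side `"left"` or `"right"`.
#' @param limb_type `"forelimb"` or `"hindlimb"`.
#' @param voxel_spacing length-3 positive numeric (um). The default
#'   matches a common light-sheet acquisition setting.
#' @return An object of class `limb_metadata`.
#' @export
limb_metadata <- function(side, limb_type, voxel_spacing = c(0.65, 0.65, 2.0)) {
  side <- match.arg(side, c("left", "right"))
  limb_type <- match.arg(limb_type, c("forelimb", "hindlimb"))
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("limb_metadata: 'voxel_spacing' must be 3 positive numbers")
  structure(list(side = side, limb_type = limb_type,
                 voxel_spacing = voxel_spacing),
            class = "limb_metadata")
}

#' Landmark set
#'
#' An ordered list of 3D physical points (um), optionally labelled.
#'
#' @param points numeric matrix n x 3 (um).
#' @param labels optional character vector of length n.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1L) stop("landmark_set: need at least one point")
  if (any(!is.finite(points))) stop("landmark_set: non-finite coordinates")
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("landmark_set: one label per point required")
  structure(list(points = points, labels = labels), class = "landmark_set")
}

as_points <- function(x) {
  if (inherits(x, "landmark_set")) x$points else matrix(as.numeric(x), ncol = 3)
}

#' Morphological stage result
#'
#' @param stage finite numeric morphological stage (staging-system units,
#'   roughly developmental hours).
#' @param uncertainty non-negative numeric (hours).
#' @param summary opaque text returned by the staging service.
#' @return An object of class `stage_result`.
#' @export
stage_result <- function(stage, uncertainty = 0, summary = "") {
  stage <- as.numeric(stage)[1]
  uncertainty <- as.numeric(uncertainty)[1]
  if (!is.finite(stage)) stop("stage_result: 'stage' must be finite")
  if (!is.finite(uncertainty) || uncertainty < 0)
    stop("stage_result: 'uncertainty' must be >= 0")
  structure(list(stage = stage, uncertainty = uncertainty,
                 summary = as.character(summary)[1]),
            class = "stage_result")
}
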