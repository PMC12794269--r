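#' Automatic isovalue selection
#'
#' Histogram-based selection for the outer tissue surface: the
#' arithmetic mean of the strictly positive voxel intensities serves as
#' the isovalue. Cleaned volumes set sub-threshold voxels to 0, so
#' excluding zeros targets the tissue intensity distribution;
#' `include_zeros = TRUE` averages over all voxels instead.
#'
#' @param grid a [voxel_grid].
#' @param include_zeros include zero-intensity (background) voxels.
#' @param ledger optional ledger; records `isovalue`.
#' @return The isovalue (intensity units).
#' @export
auto_isovalue <- function(grid, include_zeros = FALSE, ledger = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  vals <- if (include_zeros) as.numeric(grid$data)
          else grid$data[grid$data > 0]
  if (length(vals) == 0)
    stop("auto_isovalue: degenerate input (no positive voxels)")
  iso <- mean(vals)
  if (!is.null(ledger)) ledger_record(ledger, "isovalue", iso)
  iso
}

#' Marching-cubes isosurface extraction
#'
#' Extracts the triangulated surface of constant intensity `isovalue`.
#' Edge-crossing vertices are placed by linear interpolation along cell
#' edges; output vertices are in physical micrometre coordinates
#' (spacing and origin applied) and triangles are consistently wound so
#' closed surfaces around high-intensity regions have positive enclosed
#' volume. Surfaces of features fully interior to the grid are
#' watertight.
#'
#' @param grid a [voxel_grid].
#' @param isovalue finite intensity threshold.
#' @param ledger optional ledger; records `isovalue`.
#' @return A [surface_mesh].
#' @export
extract_isosurface <- function(grid, isovalue, ledger = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(isovalue)) stop("extract_isosurface: isovalue must be finite")
  rng <- range(grid$data)
  if (isovalue < rng[1] || isovalue >= rng[2])
    stop("extract_isosurface: isovalue ", isovalue,
         " is outside the data range [", rng[1], ", ", rng[2],
         "); the isosurface would be empty")
  res <- .mc_triangulate(as.numeric(grid$data), dim(grid$data),
                         grid$spacing, grid$origin, isovalue,
                         mc_case_table(), mc_edges())
  if (nrow(res$faces) == 0)
    stop("extract_isosurface: empty mesh at isovalue ", isovalue)
  if (!is.null(ledger)) ledger_record(ledger, "isovalue", isovalue)
  surface_mesh(res$vertices, res$faces)
}

#' Keep the largest connected component of a mesh
#'
#' Removes residual tissue fragments and imaging artifacts: connected
#' components are ranked by triangle count, ties broken by total
#' surface area, and only the winner is kept.
#'
#' @param mesh a [surface_mesh].
#' @return The largest-component [surface_mesh].
#' @export
largest_component <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) stop("largest_component: empty mesh")
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  fcomp <- comp[mesh$faces[, 1]]
  tab <- table(fcomp)
  best <- as.integer(names(tab)[tab == max(tab)])
  if (length(best) > 1L) {
    areas <- vapply(best, function(cc)
      sum(triangle_areas(mesh)[fcomp == cc]), 0.0)
    best <- best[which.max(areas)]
  }
  keep_faces <- mesh$faces[fcomp == best, , drop = FALSE]
  keep_verts <- sort(unique(as.integer(keep_faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep_verts] <- seq_along(keep_verts)
  surface_mesh(mesh$vertices[keep_verts, , drop = FALSE],
               matrix(remap[keep_faces], ncol = 3),
               if (!is.null(mesh$scalars)) mesh$scalars[keep_verts] else NULL)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Decimation configuration
#'
#' @param target_reduction fraction of triangles to *remove* (default
#'   0.995, i.e. 0.5% of the original triangles are retained).
#' @param preserve_volume constrain each collapse to zero local volume
#'   change and penalise deviations in triangle normals, so the
#'   simplified mesh stays volumetrically faithful.
#' @param alpha weight of the residual local-volume-change penalty
#'   (per um^3) added to the quadric collapse cost.
#' @param beta weight of the triangle-normal-deviation penalty.
#' @return An object of class `decimation_config`.
#' @export
decimation_config <- function(target_reduction = 0.995,
                              preserve_volume = TRUE,
                              alpha = 1.0, beta = 1.0) {
  if (!(target_reduction >= 0 && target_reduction < 1))
    stop("decimation_config: target_reduction must be in [0, 1)")
  structure(list(target_reduction = target_reduction,
                 preserve_volume = isTRUE(preserve_volume),
                 alpha = alpha, beta = beta),
            class = "decimation_config")
}

#' Volume-preserving quadric mesh decimation
#'
#' Iterative quadric edge collapse reducing the mesh to
#' `round((1 - target_reduction) * n_faces)` triangles (by default 0.5%
#' of the original count). With `preserve_volume` the collapse position
#' is constrained to conserve the local enclosed volume and the cost
#' penalises triangle-normal deviation, keeping closed surfaces
#' quantitatively congruent with the original geometry.
#'
#' @param mesh a [surface_mesh].
#' @param config a [decimation_config].
#' @param ledger optional ledger; records `target_reduction`.
#' @return The simplified [surface_mesh].
#' @export
decimate_mesh <- function(mesh, config = decimation_config(), ledger = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(config, "decimation_config"))
  if (config$target_reduction == 0) return(mesh)
  target <- max(4L, as.integer(round((1 - config$target_reduction) *
                                     nrow(mesh$faces))))
  res <- .decimate_qem(mesh$vertices, mesh$faces, target,
                       config$preserve_volume, config$alpha, config$beta)
  if (!is.null(ledger)) ledger_record(ledger, "target_reduction",
                                      config$target_reduction)
  surface_mesh(res$vertices, res$faces)
}

#' Geometric and topological mesh measures
#'
#' @param mesh a [surface_mesh].
#' @param need_volume if `TRUE` (default) the enclosed volume is
#'   computed via signed tetrahedra, which requires a closed mesh;
#'   with `FALSE`, `volume` is `NA` for open meshes instead of an
#'   error.
#' @return List with `area` (um^2), `volume` (um^3, signed), `n_vertices`,
#'   `n_faces`, `n_edges`, `euler_characteristic`, `n_boundary_edges`.
#' @export
mesh_measures <- function(mesh, need_volume = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  area <- sum(triangle_areas(mesh))
  ekey <- rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1])))
  keys <- paste(ekey[, 1], ekey[, 2])
  tab <- table(keys)
  n_edges <- length(tab)
  n_boundary <- sum(tab == 1L)
  closed <- n_boundary == 0L
  volume <- NA_real_
  if (closed) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    volume <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                  a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                  a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  } else if (need_volume) {
    stop("mesh_measures: volume undefined for open mesh (",
         n_boundary, " boundary edges)")
  }
  list(area = area, volume = volume,
       n_vertices = nrow(v), n_faces = nrow(f), n_edges = n_edges,
       euler_characteristic = nrow(v) - n_edges + nrow(f),
       n_boundary_edges = n_boundary)
}
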