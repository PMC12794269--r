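#' Orthogonal slice
#'
#' Exact copy of one index plane of the volume, no interpolation.
#'
#' @param grid a [voxel_grid].
#' @param axis axis 1, 2 or 3.
#' @param index 1-based index along `axis`.
#' @return 2D numeric matrix (the remaining two axes, in order).
#' @export
ortho_slice <- function(grid, axis, index) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!(axis %in% 1:3)) stop("ortho_slice: axis must be 1, 2 or 3")
  n <- dim(grid$data)[axis]
  if (index < 1 || index > n)
    stop("ortho_slice: index ", index, " out of range 1..", n)
  idx <- list(TRUE, TRUE, TRUE)
  idx[[axis]] <- index
  out <- do.call(`[`, c(list(grid$data), idx, list(drop = FALSE)))
  matrix(out, dim(grid$data)[setdiff(1:3, axis)][1])
}

#' Oblique (arbitrary-plane) slice of one or more channels
#'
#' Samples each channel trilinearly on a shared orthonormal in-plane
#' lattice, so multi-channel slices are directly comparable pixel by
#' pixel. The in-plane basis is deterministic: `u` is the standard axis
#' least aligned with the normal (ties to the lower axis index),
#' orthogonalized against the normal; `v = normal x u`. Samples outside
#' the volume are 0.
#'
#' @param grids a [voxel_grid] or list of them sharing one geometry.
#' @param plane_origin length-3 physical point on the plane (um).
#' @param plane_normal length-3 plane normal.
#' @param resolution in-plane sample spacing (um).
#' @param half_extent length-2 physical half-sizes of the lattice along
#'   `u` and `v` (um).
#' @return List with `images` (one matrix per channel), `u`, `v`
#'   (in-plane basis), and `lattice` (sample coordinates, n x 3).
#' @export
oblique_slice <- function(grids, plane_origin, plane_normal,
                          resolution = 1, half_extent = NULL) {
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  geo <- grids[[1]]
  for (g in grids)
    if (!identical(dim(g$data), dim(geo$data)) ||
        any(g$spacing != geo$spacing) || any(g$origin != geo$origin))
      stop("oblique_slice: channels must share one grid geometry")
  n <- as.numeric(plane_normal)
  n <- n / sqrt(sum(n^2))
  ref_axis <- which.min(abs(n))
  e <- c(0, 0, 0); e[ref_axis] <- 1
  u <- e - sum(e * n) * n
  u <- u / sqrt(sum(u^2))
  v <- crossprod3(n, u)
  if (is.null(half_extent)) {
    diag_len <- sqrt(sum(((dim(geo$data) - 1) * geo$spacing)^2))
    half_extent <- c(diag_len, diag_len) / 2
  }
  iu <- seq(-floor(half_extent[1] / resolution),
            floor(half_extent[1] / resolution)) * resolution
  iv <- seq(-floor(half_extent[2] / resolution),
            floor(half_extent[2] / resolution)) * resolution
  lattice <- cbind(
    plane_origin[1] + outer(iu * u[1], iv * v[1], "+"),
    plane_origin[2] + outer(iu * u[2], iv * v[2], "+"),
    plane_origin[3] + outer(iu * u[3], iv * v[3], "+"))
  pts <- matrix(lattice, ncol = 3)
  images <- lapply(grids, function(g)
    matrix(sample_trilinear(g, pts, outside = 0), length(iu), length(iv)))
  names(images) <- vapply(grids, function(g) g$channel_name, "")
  list(images = images, u = u, v = v, lattice = pts,
       offsets_u = iu, offsets_v = iv)
}

#' Slab projection (thick slice)
#'
#' Reduces a half-open index range `[lo, hi)` along one axis to a
#' single 2D image with the mean (average expression levels) or max
#' (highest activity) operation; range, axis and operation are kept as
#' metadata for reproducibility.
#'
#' @param grid a [voxel_grid].
#' @param axis axis 1, 2 or 3.
#' @param index_range length-2 integer `[lo, hi)`, 1-based voxel
#'   indices with `lo < hi <= axis length + 1`.
#' @param operation `"mean"` or `"max"`.
#' @param ledger optional ledger; records `slab_axis`, `slab_range`,
#'   `slab_operation`.
#' @return An object of class `slab_result`: list with `image`,
#'   `axis`, `index_range`, `operation`.
#' @export
slab_project <- function(grid, axis, index_range,
                         operation = c("mean", "max"), ledger = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  operation <- match.arg(operation)
  if (!(axis %in% 1:3)) stop("slab_project: axis must be 1, 2 or 3")
  n <- dim(grid$data)[axis]
  lo <- index_range[1]; hi <- index_range[2]
  if (!(lo >= 1 && lo < hi && hi <= n + 1))
    stop("slab_project: need 1 <= lo < hi <= ", n + 1, " (half-open range)")
  idx <- list(TRUE, TRUE, TRUE)
  idx[[axis]] <- lo:(hi - 1)
  sub <- do.call(`[`, c(list(grid$data), idx, list(drop = FALSE)))
  img <- apply(sub, setdiff(1:3, axis), if (operation == "mean") mean else max)
  if (!is.null(ledger)) {
    ledger_record(ledger, "slab_axis", axis)
    ledger_record(ledger, "slab_range", c(lo, hi))
    ledger_record(ledger, "slab_operation", operation)
  }
  structure(list(image = img, axis = axis, index_range = c(lo, hi),
                 operation = operation),
            class = "slab_result")
}

#' Intensity profile along a line probe
#'
#' Samples each channel trilinearly at `n_samples` evenly spaced points
#' on the segment from `start` to `end`; the same sample points are
#' applied across all channels so profiles are directly comparable.
#'
#' @param grids a [voxel_grid] or list of them.
#' @param start,end physical segment endpoints (um).
#' @param n_samples number of samples (>= 2).
#' @return An object of class `probe_result`: list with
#'   `sample_points`, `values` (per-channel list), `arclength`.
#' @export
probe_line <- function(grids, start, end, n_samples = 100) {
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  start <- as.numeric(start); end <- as.numeric(end)
  if (n_samples < 2) stop("probe_line: n_samples must be >= 2")
  L <- sqrt(sum((end - start)^2))
  if (L == 0) stop("probe_line: zero-length segment")
  tt <- seq(0, 1, length.out = n_samples)
  pts <- cbind(start[1] + tt * (end[1] - start[1]),
               start[2] + tt * (end[2] - start[2]),
               start[3] + tt * (end[3] - start[3]))
  values <- lapply(grids, function(g) sample_trilinear(g, pts, outside = 0))
  names(values) <- vapply(grids, function(g) g$channel_name, "")
  structure(list(sample_points = pts, values = values, arclength = tt * L),
            class = "probe_result")
}

#' Extract multiple nested isosurfaces
#'
#' Surfaces are extracted at `min(n, 10)` isovalues linearly spaced
#' over `[v_low, v_high]` (inclusive); the hard cap of 10 surfaces
#' keeps multi-level renderings interpretable. Levels whose surface is
#' empty are skipped with a warning record rather than failing.
#'
#' @param grid a [voxel_grid].
#' @param v_low,v_high isovalue range, `v_low < v_high`.
#' @param n requested number of surfaces (capped at 10).
#' @return List of [surface_mesh] objects; attributes `levels` (values
#'   used) and `skipped` (empty levels).
#' @export
multi_isosurfaces <- function(grid, v_low, v_high, n = 5) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!(v_low < v_high)) stop("multi_isosurfaces: need v_low < v_high")
  if (n < 1) stop("multi_isosurfaces: n must be >= 1")
  n_eff <- min(as.integer(n), 10L)
  levels <- if (n_eff == 1L) v_low
            else seq(v_low, v_high, length.out = n_eff)
  meshes <- list()
  used <- numeric(0)
  skipped <- numeric(0)
  for (lv in levels) {
    m <- tryCatch(extract_isosurface(grid, lv), error = function(e) NULL)
    if (is.null(m)) skipped <- c(skipped, lv)
    else { meshes[[length(meshes) + 1L]] <- m; used <- c(used, lv) }
  }
  structure(meshes, levels = used, skipped = skipped)
}

#' Histogram summary of voxel intensities
#'
#' @param grid a [voxel_grid].
#' @param n_bins number of equal-width bins (>= 1).
#' @param exclude_zeros summarize only strictly positive voxels (the
#'   statistic used by [auto_isovalue()]).
#' @return List with `bin_edges` (length `n_bins + 1`), `counts`
#'   (summing to the voxel count), `mean`, `min`, `max`.
#' @export
histogram_summary <- function(grid, n_bins = 64, exclude_zeros = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (n_bins < 1) stop("histogram_summary: n_bins must be >= 1")
  vals <- as.numeric(grid$data)
  if (exclude_zeros) vals <- vals[vals > 0]
  if (length(vals) == 0)
    return(list(bin_edges = c(0, 0), counts = 0L, mean = NaN,
                min = NA_real_, max = NA_real_))
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) hi <- lo + 1   # constant grid: one degenerate bin width
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  list(bin_edges = edges, counts = counts, mean = mean(vals),
       min = min(vals), max = max(vals))
}
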