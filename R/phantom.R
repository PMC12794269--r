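#' Synthetic limb-bud phantom specification
#'
#' Defines the geometry and noise of the synthetic test volumes: a
#' paddle-shaped (half-ellipsoid) tissue body protruding along +x (the
#' proximodistal axis) from a base plane, imaged on an anisotropic
#' light-sheet-like voxel grid. All randomness flows through `seed`;
#' equal specs produce bitwise-identical volumes.
#'
#' @param shape grid shape (voxels).
#' @param spacing voxel spacing (um); the default matches the common
#'   light-sheet acquisition setting.
#' @param semi_axes half-ellipsoid semi-axes (a, b, c) in um; `a` runs
#'   proximodistally.
#' @param noise_level multiplicative speckle noise level (s.d. of the
#'   relative fluctuation), mimicking cleared-tissue texture.
#' @param intensity tissue intensity before noise (background is 0).
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 140, 48),
                         spacing = c(0.65, 0.65, 2.0),
                         semi_axes = c(60, 35, 30),
                         noise_level = 0.05,
                         intensity = 100,
                         seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  semi_axes <- as.numeric(semi_axes)
  if (any(semi_axes <= 0)) stop("phantom_spec: degenerate semi-axes")
  if (noise_level < 0) stop("phantom_spec: noise_level must be >= 0")
  extent <- (shape - 1) * spacing
  centre <- extent / 2
  base_x <- centre[1] - semi_axes[1] / 2
  # the paddle must sit fully interior (at least one clean voxel margin)
  if (base_x + semi_axes[1] >= extent[1] - spacing[1] ||
      semi_axes[2] >= centre[2] - spacing[2] ||
      semi_axes[3] >= centre[3] - spacing[3])
    stop("phantom_spec: semi_axes do not fit inside the grid with a margin")
  structure(list(shape = shape, spacing = spacing, semi_axes = semi_axes,
                 noise_level = noise_level, intensity = intensity,
                 seed = as.integer(seed),
                 base = c(base_x, centre[2], centre[3])),
            class = "phantom_spec")
}

phantom_coords <- function(spec) {
  lapply(1:3, function(a) (seq_len(spec$shape[a]) - 1) * spec$spacing[a])
}

# squared normalized ellipsoid radius field, and the x >= base mask
phantom_fields <- function(spec) {
  ax <- phantom_coords(spec)
  b <- spec$base; sa <- spec$semi_axes
  dx2 <- ((ax[[1]] - b[1]) / sa[1])^2
  dy2 <- ((ax[[2]] - b[2]) / sa[2])^2
  dz2 <- ((ax[[3]] - b[3]) / sa[3])^2
  rho2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  distal <- outer(outer(ax[[1]] >= b[1], rep(TRUE, spec$shape[2]), "&"),
                  rep(TRUE, spec$shape[3]), "&")
  list(rho2 = rho2, distal = distal, ax = ax)
}

#' Generate the limb-bud nuclei phantom
#'
#' A half-ellipsoid "paddle" indicator (intensity `spec$intensity`
#' inside, 0 outside) with multiplicative speckle noise
#' `(1 + noise_level * N(0,1))`, plus analytic ground truth: the
#' enclosed volume `(2/3) pi a b c`, the base/semi-axes, and AER
#' landmark coordinates along the distal rim arc (all exactly on the
#' ideal surface).
#'
#' @param spec a [phantom_spec].
#' @param n_landmarks number of AER arc landmarks.
#' @return List with `nuclei` ([voxel_grid]), `truth` (list: `volume`,
#'   `area` of the flat base disc omitted, `semi_axes`, `base`,
#'   `intensity`), and `landmarks` ([landmark_set]).
#' @export
make_limb_phantom <- function(spec, n_landmarks = 9) {
  stopifnot(inherits(spec, "phantom_spec"))
  ff <- phantom_fields(spec)
  inside <- (ff$rho2 <= 1) & ff$distal
  data <- spec$intensity * inside
  if (spec$noise_level > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    eps <- array(stats::rnorm(prod(spec$shape)), spec$shape)
    data <- data * (1 + spec$noise_level * eps)
  }
  sa <- spec$semi_axes; b <- spec$base
  u <- seq(-pi / 2 + pi / (2 * n_landmarks), pi / 2 - pi / (2 * n_landmarks),
           length.out = n_landmarks)
  landmarks <- cbind(b[1] + sa[1] * cos(u), b[2] + sa[2] * sin(u),
                     rep(b[3], n_landmarks))
  truth <- list(volume = 2 / 3 * pi * prod(sa), semi_axes = sa, base = b,
                intensity = spec$intensity)
  list(nuclei = voxel_grid(data, spec$spacing, c(0, 0, 0), "nuclei"),
       truth = truth, landmarks = landmark_set(landmarks))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic gene-expression channel
#'
#' Expression domains emulating the patterns seen in volumetric
#' limb-bud data, on the same grid geometry as the nuclei channel:
#' \describe{
#'   \item{gradient}{linear proximodistal ramp masked by the paddle;}
#'   \item{bilobed}{sum of two Gaussians at mirrored dorsoventral foci
#'     — two expression maxima with reduced signal in the centre;}
#'   \item{torus}{a ring ("donut") around the proximodistal axis,
#'     defined by a Gaussian of the distance to a circle, whose
#'     isosurface has genus 1.}
#' }
#'
#' @param spec a [phantom_spec].
#' @param kind `"gradient"`, `"bilobed"` or `"torus"`.
#' @param intensity peak expression intensity.
#' @return A [voxel_grid] named after `kind`.
#' @export
make_gene_domain <- function(spec, kind = c("gradient", "bilobed", "torus"),
                             intensity = 200) {
  stopifnot(inherits(spec, "phantom_spec"))
  kind <- match.arg(kind)
  ff <- phantom_fields(spec)
  ax <- ff$ax; b <- spec$base; sa <- spec$semi_axes
  data <- if (kind == "gradient") {
    ramp <- pmax(outer(outer((ax[[1]] - b[1]) / sa[1], rep(1, spec$shape[2])),
                       rep(1, spec$shape[3])), 0)
    intensity * ramp * ((ff$rho2 <= 1) & ff$distal)
  } else if (kind == "bilobed") {
    sig <- 0.18 * min(sa)
    f1 <- c(b[1] + 0.55 * sa[1], b[2] - 0.45 * sa[2], b[3])
    f2 <- c(b[1] + 0.55 * sa[1], b[2] + 0.45 * sa[2], b[3])
    g_of <- function(f) {
      d2 <- outer(outer((ax[[1]] - f[1])^2, (ax[[2]] - f[2])^2, "+"),
                  (ax[[3]] - f[3])^2, "+")
      exp(-d2 / (2 * sig^2))
    }
    intensity * (g_of(f1) + g_of(f2))
  } else {
    ring_r <- 0.5 * min(sa[2], sa[3])
    tube_sig <- 0.18 * ring_r * 2
    xc <- b[1] + 0.5 * sa[1]
    rad_yz <- sqrt(outer(outer(0 * ax[[1]], (ax[[2]] - b[2])^2, "+"),
                         (ax[[3]] - b[3])^2, "+"))
    dx2 <- outer(outer((ax[[1]] - xc)^2, rep(1, spec$shape[2])),
                 rep(1, spec$shape[3]))
    d2 <- (rad_yz - ring_r)^2 + dx2
    intensity * exp(-d2 / (2 * tube_sig^2))
  }
  voxel_grid(data, spec$spacing, c(0, 0, 0), kind)
}

#' Generate a placeholder reference-mesh set over a stage range
#'
#' Writes one surface mesh per integer stage into `out_dir`
#' (`stage_<n>.vtk`), with size increasing smoothly (linearly in the
#' stage) so enclosed volume is monotone with stage — a synthetic
#' stand-in for a database of staged reference limb surfaces, not
#' biology.
#'
#' @param stage_range length-2 integer range (inclusive).
#' @param base_spec a [phantom_spec]; its semi-axes set the mid-range
#'   reference size.
#' @param out_dir output directory (created if needed).
#' @param subdivisions icosphere subdivision level of the placeholders.
#' @return The [registry_build()] result for the written set.
#' @export
make_reference_set <- function(stage_range, base_spec, out_dir,
                               subdivisions = 3) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("make_reference_set: cannot create directory ", out_dir)
  }
  stages <- seq(as.integer(stage_range[1]), as.integer(stage_range[2]))
  mid <- mean(range(stages))
  r0 <- mean(base_spec$semi_axes)
  for (s in stages) {
    r <- r0 * (1 + 0.01 * (s - mid))   # +1% radius per stage unit
    mesh <- icosphere(subdivisions, radius = r, center = base_spec$base)
    write_mesh(mesh, file.path(out_dir, sprintf("stage_%d.vtk", s)))
  }
  registry_build(stage_range, out_dir)
}

#' Perturb an object by a known random transform
#'
#' Produces a perturbed copy together with the exact ground-truth
#' transform applied, enabling recovery tests for registration. For
#' `rigid`/`similarity`, `magnitude` is the rotation angle in degrees
#' about a random axis through the object centroid; the translation
#' norm is `0.4 * magnitude` um and (similarity only) the scale is
#' `1 + 0.02 * magnitude`. For `tps`, 8 anchor landmarks are displaced
#' by random vectors of norm `magnitude` um and the fitted warp is
#' applied.
#'
#' @param x a [surface_mesh] or [voxel_grid].
#' @param kind `"rigid"`, `"similarity"` or `"tps"`.
#' @param magnitude perturbation magnitude (degrees / um, see above).
#' @param seed integer RNG seed.
#' @return List with `perturbed` (same class as `x`) and
#'   `ground_truth` (an [affine4] or [tps_warp]).
#' @export
perturb_with_known_transform <- function(x, kind = c("rigid", "similarity", "tps"),
                                         magnitude = 5, seed = 1L) {
  kind <- match.arg(kind)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pts <- if (inherits(x, "surface_mesh")) x$vertices
         else if (inherits(x, "voxel_grid"))
           matrix(x$origin + (dim(x$data) - 1) * x$spacing / 2, 1)
         else stop("perturb_with_known_transform: unsupported object")
  ctr <- colMeans(pts)
  gt <- if (kind %in% c("rigid", "similarity")) {
    if (magnitude == 0) affine4() else {
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      th <- magnitude * pi / 180
      K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                    axis[2], -axis[1], 0), 3, 3)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      tr <- stats::rnorm(3); tr <- tr / sqrt(sum(tr^2)) * 0.4 * magnitude
      s <- if (kind == "similarity") 1 + 0.02 * magnitude else 1
      # rotate/scale about the centroid, then translate
      t_total <- ctr - s * R %*% ctr + tr
      affine4_from_rts(R, t_total, s)
    }
  } else {
    if (magnitude == 0) {
      anchors <- sweep(matrix(stats::rnorm(24), 8, 3), 2, ctr, "+")
      tps_fit(anchors, anchors)
    } else {
      rng <- apply(pts, 2, range)
      anchors <- cbind(stats::runif(8, rng[1, 1], rng[2, 1]),
                       stats::runif(8, rng[1, 2], rng[2, 2]),
                       stats::runif(8, rng[1, 3], rng[2, 3]))
      disp <- matrix(stats::rnorm(24), 8, 3)
      disp <- disp / sqrt(rowSums(disp^2)) * magnitude
      tps_fit(anchors, anchors + disp)
    }
  }
  perturbed <- if (inherits(x, "surface_mesh")) transform_apply_mesh(gt, x)
               else warp_grid(x, gt)
  list(perturbed = perturbed, ground_truth = gt)
}
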