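#' Build a reference-mesh registry over a stage range
#'
#' The registry maps each integer morphological stage in the range
#' (inclusive) to a mesh file `stage_<n>.vtk` or `stage_<n>.ply` inside
#' `mesh_dir` — the layout produced by [make_reference_set()], which
#' stands in for a reference database of staged limb surfaces.
#'
#' @param stage_range length-2 integer range, e.g. `c(249, 290)`.
#' @param mesh_dir directory holding one mesh per integer stage.
#' @return An object of class `reference_registry`.
#' @export
registry_build <- function(stage_range, mesh_dir) {
  stages <- seq(as.integer(stage_range[1]), as.integer(stage_range[2]))
  paths <- vapply(stages, function(s) {
    for (ext in c("vtk", "ply")) {
      p <- file.path(mesh_dir, sprintf("stage_%d.%s", s, ext))
      if (file.exists(p)) return(p)
    }
    stop("registry_build: no mesh file for stage ", s, " in ", mesh_dir)
  }, "")
  structure(list(entries = stats::setNames(paths, stages)),
            class = "reference_registry")
}

#' Look up the reference mesh nearest to a (possibly fractional) stage
#'
#' Rounds half-up to the nearest integer stage.
#'
#' @param registry a [registry_build()] result.
#' @param stage numeric morphological stage.
#' @return List with `stage` (integer used) and `path`.
#' @export
registry_lookup <- function(registry, stage) {
  stopifnot(inherits(registry, "reference_registry"))
  s <- floor(as.numeric(stage) + 0.5)
  key <- as.character(as.integer(s))
  if (!key %in% names(registry$entries))
    stop("registry_lookup: stage ", s, " outside the registry range")
  list(stage = as.integer(s), path = unname(registry$entries[key]))
}

#' Least-squares similarity transform from paired landmarks
#'
#' Closed-form (SVD-based) estimate of the rotation, translation and
#' optional uniform scale minimizing `sum ||s R p_i + t - q_i||^2`. The
#' rotation is always proper (det +1): reflection-only correspondences
#' are corrected by sign-flipping the smallest singular direction.
#'
#' @param source,target paired [landmark_set]s or n x 3 matrices
#'   (>= 3 non-collinear pairs).
#' @param with_scale estimate a uniform scale (7-parameter similarity)
#'   rather than a 6-parameter rigid transform.
#' @return An [affine4]; attribute `"scale"` carries the scale factor.
#' @export
similarity_from_landmarks <- function(source, target, with_scale = TRUE) {
  p <- as_points(source); q <- as_points(target)
  if (nrow(p) != nrow(q)) stop("similarity_from_landmarks: unequal point counts")
  if (nrow(p) < 3) stop("similarity_from_landmarks: need >= 3 pairs")
  mp <- colMeans(p); mq <- colMeans(q)
  pc <- sweep(p, 2, mp); qc <- sweep(q, 2, mq)
  if (svd(pc)$d[2] <= svd(pc)$d[1] * 1e-12)
    stop("similarity_from_landmarks: source points are collinear")
  S <- crossprod(pc, qc) / nrow(p)
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (with_scale) {
    varp <- sum(pc^2) / nrow(p)
    sum(sv$d * c(1, 1, d)) / varp
  } else 1
  t <- mq - s * R %*% mp
  out <- affine4_from_rts(R, t, s)
  attr(out, "scale") <- s
  out
}

farthest_point_sample <- function(verts, n, seeds = NULL) {
  nv <- nrow(verts)
  if (n > nv) stop("farthest_point_sample: more samples than vertices")
  mind <- rep(Inf, nv)
  if (!is.null(seeds) && nrow(seeds) > 0) {
    for (i in seq_len(nrow(seeds)))
      mind <- pmin(mind, rowSums(sweep(verts, 2, seeds[i, ])^2))
  } else {
    # start from the vertex farthest from the centroid
    ctr <- colMeans(verts)
    mind <- rowSums(sweep(verts, 2, ctr)^2)
  }
  picked <- integer(n)
  for (k in seq_len(n)) {
    picked[k] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(verts, 2, verts[picked[k], ])^2))
  }
  picked
}

#' Augment landmark pairs with closest-point correspondences
#'
#' After the rough alignment implied by the seed pairs, additional
#' correspondences are generated automatically: `n_extra` source
#' vertices are chosen by farthest-point sampling (spreading them away
#' from the seeds and from each other) and each is paired with its
#' closest point on the target surface. The new pairs are appended
#' after the seeds, in the aligned source frame.
#'
#' @param source_mesh,target_mesh [surface_mesh] objects.
#' @param seed_pairs `NULL`, or a list with `source` and `target`
#'   [landmark_set]s / n x 3 matrices of equal count.
#' @param n_extra number of pairs to add (0 returns the seeds).
#' @return List with `source` and `target` [landmark_set]s and
#'   `alignment` (the seed-based [affine4], identity when < 3 seeds).
#' @export
augment_pairs_closest <- function(source_mesh, target_mesh,
                                  seed_pairs = NULL, n_extra = 20) {
  stopifnot(inherits(source_mesh, "surface_mesh"),
            inherits(target_mesh, "surface_mesh"))
  if (n_extra > nrow(source_mesh$vertices))
    stop("augment_pairs_closest: n_extra exceeds source vertex count")
  sp <- if (is.null(seed_pairs)) matrix(0, 0, 3) else as_points(seed_pairs$source)
  tp <- if (is.null(seed_pairs)) matrix(0, 0, 3) else as_points(seed_pairs$target)
  if (nrow(sp) != nrow(tp))
    stop("augment_pairs_closest: seed source/target counts differ")
  align <- if (nrow(sp) >= 3) similarity_from_landmarks(sp, tp) else affine4()
  sp_al <- if (nrow(sp) > 0) transform_apply_points(align, sp) else sp
  verts <- transform_apply_points(align, source_mesh$vertices)
  if (n_extra > 0) {
    idx <- farthest_point_sample(verts, n_extra, seeds = sp_al)
    src_new <- verts[idx, , drop = FALSE]
    cp <- .closest_point_mesh(src_new, target_mesh$vertices, target_mesh$faces)
    sp_al <- rbind(sp_al, src_new)
    tp <- rbind(tp, cp$points)
  }
  list(source = landmark_set(sp_al), target = landmark_set(tp),
       alignment = align)
}

#' Iterative closest point refinement
#'
#' Alternates closest-point correspondence (source vertices against the
#' target triangle surface) with a closed-form rigid or similarity
#' update. Correspondences farther than 3x the median distance are
#' rejected for robustness. Iterations stop when the mean closest-point
#' distance changes by less than `tol` or stops decreasing; the
#' returned transform includes the initialization.
#'
#' @param source_mesh,target_mesh [surface_mesh] objects.
#' @param init initial [affine4] (default identity).
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the mean distance (um).
#' @param estimate `"rigid"` (default) or `"similarity"` update.
#' @return An [affine4]; attribute `"trace"` holds the mean
#'   closest-point distance after each accepted iteration.
#' @export
icp_refine <- function(source_mesh, target_mesh, init = affine4(),
                       max_iter = 500, tol = 1e-6,
                       estimate = c("rigid", "similarity")) {
  stopifnot(inherits(source_mesh, "surface_mesh"),
            inherits(target_mesh, "surface_mesh"))
  estimate <- match.arg(estimate)
  src0 <- source_mesh$vertices
  current <- init
  trace <- numeric(0)
  prev_mean <- Inf
  for (it in seq_len(max_iter)) {
    moved <- transform_apply_points(current, src0)
    cp <- .closest_point_mesh(moved, target_mesh$vertices, target_mesh$faces)
    med <- stats::median(cp$dist)
    keep <- cp$dist <= 3 * med + .Machine$double.eps
    mean_d <- mean(cp$dist)
    if (mean_d > prev_mean) break          # keep the last accepted state
    trace <- c(trace, mean_d)
    if (prev_mean - mean_d < tol && it > 1) { prev_mean <- mean_d; break }
    prev_mean <- mean_d
    upd <- similarity_from_landmarks(moved[keep, , drop = FALSE],
                                     cp$points[keep, , drop = FALSE],
                                     with_scale = (estimate == "similarity"))
    current <- transform_compose(upd, current)
  }
  attr(current, "trace") <- trace
  current
}

tps_kernel <- function(r) r   # 3D biharmonic fundamental solution (up to constant)

#' Fit a thin-plate-spline warp to paired landmarks
#'
#' Solves the standard TPS linear system with the 3D kernel
#' `U(r) = r` and side conditions making the kernel weights orthogonal
#' to the affine monomials. With `lambda = 0` the warp interpolates the
#' landmarks exactly; `lambda > 0` trades exactness for smoothness
#' (ridge regularization of the kernel block). The bending energy is
#' the quadratic form of the kernel weights; it vanishes exactly when
#' the landmark relation is affine.
#'
#' @param source,target paired [landmark_set]s or n x 3 matrices
#'   (>= 4 non-coplanar pairs).
#' @param lambda ridge regularization (default 0 = exact interpolation).
#' @return An object of class `tps_warp`.
#' @export
tps_fit <- function(source, target, lambda = 0) {
  s <- as_points(source); t <- as_points(target)
  if (nrow(s) != nrow(t)) stop("tps_fit: unequal landmark counts")
  n <- nrow(s)
  if (n < 4) stop("tps_fit: need >= 4 landmark pairs")
  sv <- svd(sweep(s, 2, colMeans(s)))
  if (lambda == 0 && sv$d[3] <= sv$d[1] * 1e-10)
    stop("tps_fit: landmarks are coplanar/degenerate; ",
         "use lambda > 0 for a regularized fit")
  K <- as.matrix(stats::dist(s, diag = TRUE, upper = TRUE))
  K <- tps_kernel(K) + diag(lambda, n)
  P <- cbind(1, s)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(t, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    if (lambda > 0) {
      # coplanar landmarks leave the affine block rank-deficient even
      # with a kernel ridge; take the minimum-norm solution instead
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-12
      sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
    } else {
      stop("tps_fit: singular TPS system (degenerate landmarks); ",
           "consider lambda > 0")
    }
  })
  W <- sol[1:n, , drop = FALSE]
  Aff <- sol[(n + 1):(n + 4), , drop = FALSE]   # 4 x 3: [1, x, y, z] -> coords
  K0 <- K - diag(lambda, n)
  be <- -sum(vapply(1:3, function(k)
    drop(crossprod(W[, k], K0 %*% W[, k])), 0.0))
  structure(list(source_landmarks = s, target_landmarks = t,
                 affine_part = Aff, kernel_weights = W, lambda = lambda,
                 bending_energy = max(be, 0)),
            class = "tps_warp")
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp %d landmarks, lambda %g, bending energy %g>\n",
              nrow(x$source_landmarks), x$lambda, x$bending_energy))
  invisible(x)
}

tps_eval <- function(warp, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  aff <- cbind(1, p) %*% warp$affine_part
  s <- warp$source_landmarks
  # pairwise distances query x landmarks
  d2 <- outer(rowSums(p^2), rep(1, nrow(s))) +
        outer(rep(1, nrow(p)), rowSums(s^2)) - 2 * p %*% t(s)
  U <- tps_kernel(sqrt(pmax(d2, 0)))
  aff + U %*% warp$kernel_weights
}

#' Invert a TPS warp approximately
#'
#' Fits the reverse-direction TPS (landmark roles swapped) — exact for
#' affine warps and adequate for smooth morphs; `refine = "fixed-point"`
#' additionally sharpens each evaluation by fixed-point iteration on
#' the forward warp.
#'
#' @param warp a [tps_warp].
#' @param refine `"none"` or `"fixed-point"`.
#' @return A `tps_warp` (with an attribute carrying the refinement
#'   mode) usable wherever a transform is accepted.
#' @export
tps_invert <- function(warp, refine = c("none", "fixed-point")) {
  refine <- match.arg(refine)
  inv <- tps_fit(warp$target_landmarks, warp$source_landmarks,
                 lambda = warp$lambda)
  attr(inv, "refine") <- refine
  attr(inv, "forward") <- if (refine == "fixed-point") warp else NULL
  inv
}

#' Resample a volume through a spatial transform
#'
#' Inverse-mapping resampling: each output voxel centre of the
#' reference geometry is mapped through the inverse transform and the
#' input volume is sampled there trilinearly. For affine transforms the
#' inverse is exact; for TPS warps the reverse-fitted spline (see
#' [tps_invert()]) is used, optionally sharpened by fixed-point
#' iteration. Samples falling outside the input volume are 0.
#'
#' @param grid input [voxel_grid].
#' @param transform [affine4] or [tps_warp] mapping input coordinates
#'   to output coordinates.
#' @param reference a [voxel_grid] (or list with `shape`, `spacing`,
#'   `origin`) defining the output geometry; defaults to the input
#'   geometry.
#' @param tps_inverse `"reverse-tps"` (default) or `"fixed-point"`.
#' @return A [voxel_grid] on the reference geometry.
#' @export
warp_grid <- function(grid, transform, reference = NULL,
                      tps_inverse = c("reverse-tps", "fixed-point")) {
  stopifnot(inherits(grid, "voxel_grid"))
  tps_inverse <- match.arg(tps_inverse)
  if (is.null(reference)) reference <- grid
  shape <- if (inherits(reference, "voxel_grid")) dim(reference$data)
           else as.integer(reference$shape)
  spacing <- if (inherits(reference, "voxel_grid")) reference$spacing
             else as.numeric(reference$spacing)
  origin <- if (inherits(reference, "voxel_grid")) reference$origin
            else as.numeric(reference$origin)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  src_pts <- if (inherits(transform, "affine4")) {
    transform_apply_points(transform_invert(transform), pts)
  } else if (inherits(transform, "tps_warp")) {
    inv <- tps_invert(transform)
    p <- tps_eval(inv, pts)
    if (tps_inverse == "fixed-point") {
      for (it in 1:5) {
        err <- tps_eval(transform, p) - pts
        p <- p - err
      }
    }
    p
  } else stop("warp_grid: unsupported transform class")
  vals <- sample_trilinear(grid, src_pts, outside = 0)
  voxel_grid(array(vals, shape), spacing, origin, grid$channel_name)
}

#' Surface-to-surface distance map
#'
#' Per-vertex Euclidean distance from each source-mesh vertex to the
#' nearest point on any target triangle (not just target vertices),
#' with summary statistics — the standard check of registration
#' quality.
#'
#' @param source_mesh,target_mesh [surface_mesh] objects.
#' @param ledger optional ledger; records `rms_distance`.
#' @return An object of class `distance_map`: list with `distances`,
#'   `summary` (`mean`, `max`, `rms`) and `mesh` (the source mesh with
#'   distances attached as per-vertex scalars).
#' @export
distance_map <- function(source_mesh, target_mesh, ledger = NULL) {
  stopifnot(inherits(source_mesh, "surface_mesh"),
            inherits(target_mesh, "surface_mesh"))
  cp <- .closest_point_mesh(source_mesh$vertices, target_mesh$vertices,
                            target_mesh$faces)
  d <- cp$dist
  summary <- list(mean = mean(d), max = max(d), rms = sqrt(mean(d^2)))
  if (!is.null(ledger)) ledger_record(ledger, "rms_distance", summary$rms)
  structure(list(distances = d, summary = summary,
                 mesh = surface_mesh(source_mesh$vertices,
                                     source_mesh$faces, scalars = d)),
            class = "distance_map")
}
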