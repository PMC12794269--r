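#' Homogeneous 4x4 spatial transform
#'
#' Encodes rotation, translation and (optionally uniform) scaling as a
#' homogeneous matrix `T = [[R, t], [0', 1]]` acting on physical
#' micrometre coordinates: `p' = R p + t`.
#'
#' @param matrix 4x4 numeric; last row must be (0, 0, 0, 1) and the
#'   linear part must be invertible.
#' @return An object of class `affine4`.
#' @export
affine4 <- function(matrix = diag(4)) {
  m <- base::matrix(as.numeric(matrix), 4, 4)
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 0))
    stop("affine4: last row must be exactly (0, 0, 0, 1)")
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps)
    stop("affine4: linear part is singular")
  structure(list(matrix = m), class = "affine4")
}

#' @export
print.affine4 <- function(x, ...) {
  cat("<affine4>\n")
  print(x$matrix)
  invisible(x)
}

#' Build an affine transform from rotation, translation and scale
#'
#' @param R 3x3 rotation (or general linear) matrix.
#' @param t length-3 translation (um).
#' @param s uniform scale factor.
#' @return An [affine4].
#' @export
affine4_from_rts <- function(R = diag(3), t = c(0, 0, 0), s = 1) {
  m <- diag(4)
  m[1:3, 1:3] <- s * R
  m[1:3, 4] <- t
  affine4(m)
}

#' Compose two affine transforms
#'
#' Applying the result is equivalent to applying `b` first, then `a`.
#'
#' @param a,b [affine4] transforms.
#' @return The composed [affine4] with matrix `a$matrix %*% b$matrix`.
#' @export
transform_compose <- function(a, b) {
  stopifnot(inherits(a, "affine4"), inherits(b, "affine4"))
  affine4(a$matrix %*% b$matrix)
}

#' Invert an affine transform
#'
#' @param a an [affine4].
#' @return The inverse [affine4].
#' @export
transform_invert <- function(a) {
  stopifnot(inherits(a, "affine4"))
  affine4(solve(a$matrix))
}

#' Apply a spatial transform to points
#'
#' Works for both rigid/similarity ([affine4]) and thin-plate-spline
#' ([tps_warp]) transforms. Affine: `p' = R p + t`. TPS:
#' `p' = A [p; 1] + sum_i w_i U(||p - s_i||)` with the 3D kernel
#' `U(r) = r`.
#'
#' @param transform an [affine4] or [tps_warp].
#' @param pts a [landmark_set] or n x 3 numeric matrix (um).
#' @return Object of the same kind as `pts` with transformed coordinates.
#' @export
transform_apply_points <- function(transform, pts) {
  p <- as_points(pts)
  out <- if (inherits(transform, "affine4")) {
    ph <- cbind(p, 1) %*% t(transform$matrix)
    ph[, 1:3, drop = FALSE]
  } else if (inherits(transform, "tps_warp")) {
    tps_eval(transform, p)
  } else stop("transform_apply_points: unsupported transform class")
  if (inherits(pts, "landmark_set")) landmark_set(out, pts$labels) else out
}

#' Apply a transform to a surface mesh
#'
#' @param transform an [affine4] or [tps_warp].
#' @param mesh a [surface_mesh].
#' @return The mesh with transformed vertex coordinates.
#' @export
transform_apply_mesh <- function(transform, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  surface_mesh(transform_apply_points(transform, mesh$vertices),
               mesh$faces, mesh$scalars)
}

#' Serialize a transform to JSON
#'
#' Affine transforms store their matrix rows; TPS warps store both
#' landmark lists, the affine part and the kernel weights, so the ledger
#' can reference transforms by file path (`*.transform.json`).
#'
#' @param transform an [affine4] or [tps_warp].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
transform_write <- function(transform, path) {
  obj <- if (inherits(transform, "affine4")) {
    list(kind = "affine4",
         matrix = apply(transform$matrix, 1, function(r) r, simplify = FALSE))
  } else if (inherits(transform, "tps_warp")) {
    list(kind = "tps_warp",
         source_landmarks = transform$source_landmarks,
         target_landmarks = transform$target_landmarks,
         affine_part = transform$affine_part,
         kernel_weights = transform$kernel_weights,
         lambda = transform$lambda,
         bending_energy = transform$bending_energy)
  } else stop("transform_write: unsupported transform class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a transform written by [transform_write()]
#'
#' @param path JSON file path.
#' @return An [affine4] or [tps_warp].
#' @export
transform_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, ncol) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = ncol, byrow = TRUE)
  }
  if (identical(obj$kind, "affine4")) {
    affine4(as_mat(obj$matrix, 4))
  } else if (identical(obj$kind, "tps_warp")) {
    structure(list(
      source_landmarks = as_mat(obj$source_landmarks, 3),
      target_landmarks = as_mat(obj$target_landmarks, 3),
      affine_part = as_mat(obj$affine_part, 3),
      kernel_weights = as_mat(obj$kernel_weights, 3),
      lambda = obj$lambda,
      bending_energy = obj$bending_energy), class = "tps_warp")
  } else stop("transform_read: unrecognized transform file: ", path)
}
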