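#' Icosphere mesh
#'
#' Geodesic sphere obtained by repeated 4-to-1 subdivision of a regular
#' icosahedron with projection onto the sphere; handy as an analytic
#' test body and as a placeholder reference shape.
#'
#' @param subdivisions number of subdivision rounds (0 = icosahedron;
#'   each round quadruples the face count: 20 * 4^s faces).
#' @param radius sphere radius (um).
#' @param center length-3 centre (um).
#' @return A closed [surface_mesh] with outward-oriented faces.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # one shared midpoint vertex per unique undirected edge
    ea <- c(f[, 1], f[, 2], f[, 3])
    eb <- c(f[, 2], f[, 3], f[, 1])
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    key <- paste(lo, hi)
    first <- !duplicated(key)
    mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    mid_id <- nv + match(key, key[first])
    m <- nrow(f)
    ab <- mid_id[1:m]; bc <- mid_id[m + 1:m]; ca <- mid_id[2 * m + 1:m]
    f <- rbind(cbind(f[, 1], ab, ca),
               cbind(f[, 2], bc, ab),
               cbind(f[, 3], ca, bc),
               cbind(ab, bc, ca))
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f)
}

mesh_bbox_diagonal <- function(mesh) {
  rng <- apply(mesh$vertices, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)
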