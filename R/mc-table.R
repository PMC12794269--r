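# Generation of the marching-cubes case table from first principles.
#
# Cube corners 0..7 carry (x,y,z) offset bits (bit 0 = x, bit 1 = y,
# bit 2 = z). For each of the 256 inside/outside corner configurations
# the isosurface patch is constructed by: (1) running marching squares
# on each cube face, with face cycles oriented counter-clockwise as
# seen from outside the cube, pairing cut edges that bound a run of
# consecutive inside corners (this fixes the ambiguous diagonal case by
# always isolating the inside corners, a rule that depends only on the
# shared face values and therefore matches between neighbouring cells,
# so extracted surfaces are watertight); (2) linking the directed face
# segments into closed loops; (3) fan-triangulating each loop with a
# globally consistent winding so normals point out of the
# high-intensity region.

mc_corner_offsets <- function() {
  t(vapply(0:7, function(c)
    c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L), bitwShiftR(c, 2L)),
    integer(3)))
}

# 12 cube edges as corner-id pairs (0-based ids)
mc_edges <- function() {
  rbind(c(0L, 1L), c(2L, 3L), c(4L, 5L), c(6L, 7L),   # x-edges
        c(0L, 2L), c(1L, 3L), c(4L, 6L), c(5L, 7L),   # y-edges
        c(0L, 4L), c(1L, 5L), c(2L, 6L), c(3L, 7L))   # z-edges
}

# face corner cycles, CCW as seen from outside the cube
mc_face_cycles <- function() {
  offs <- mc_corner_offsets()
  faces <- list()
  for (axis in 1:3) for (side in 0:1) {
    ids <- which(offs[, axis] == side) - 1L
    pts <- offs[ids + 1L, , drop = FALSE]
    centre <- colMeans(pts)
    n <- c(0, 0, 0); n[axis] <- if (side == 1) 1 else -1
    others <- setdiff(1:3, axis)
    # in-plane right-handed basis (u, v) with u x v = n
    u <- c(0, 0, 0); v <- c(0, 0, 0)
    u[others[1]] <- 1; v[others[2]] <- 1
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (sum(cr * n) < 0) { tmp <- u; u <- v; v <- tmp }
    ang <- atan2((pts - rep(centre, each = 4)) %*% v,
                 (pts - rep(centre, each = 4)) %*% u)
    faces[[length(faces) + 1L]] <- ids[order(ang)]
  }
  faces
}

mc_edge_lookup <- function() {
  edges <- mc_edges()
  key <- function(a, b) paste(min(a, b), max(a, b))
  lut <- new.env()
  for (e in seq_len(nrow(edges)))
    assign(key(edges[e, 1], edges[e, 2]), e - 1L, envir = lut)
  function(a, b) get(paste(min(a, b), max(a, b)), envir = lut)
}

mc_case_table_build <- function() {
  cycles <- mc_face_cycles()
  elook <- mc_edge_lookup()
  offs <- mc_corner_offsets()
  table <- matrix(-1L, 256, 16)
  for (mask in 0:255) {
    inside <- bitwAnd(bitwShiftR(mask, 0:7), 1L) == 1L
    if (all(inside) || !any(inside)) next
    # directed segments: entering cut edge -> leaving cut edge per
    # inside-run on each face
    seg_from <- integer(0); seg_to <- integer(0)
    for (cyc in cycles) {
      ins <- inside[cyc + 1L]
      if (all(ins) || !any(ins)) next
      for (k in 1:4) {
        prev <- cyc[((k - 2) %% 4) + 1L]
        cur <- cyc[k]
        if (!inside[prev + 1L] && inside[cur + 1L]) {
          # run starts at position k; walk to its end
          endk <- k
          while (inside[cyc[(endk %% 4) + 1L] + 1L]) endk <- endk + 1L
          last <- cyc[((endk - 1) %% 4) + 1L]
          succ <- cyc[(endk %% 4) + 1L]
          seg_from <- c(seg_from, elook(prev, cur))
          seg_to <- c(seg_to, elook(last, succ))
        }
      }
    }
    nxt <- integer(12); nxt[] <- -1L
    nxt[seg_from + 1L] <- seg_to
    used <- logical(12)
    tris <- integer(0)
    for (start in seg_from) {
      if (used[start + 1L]) next
      loop <- start
      used[start + 1L] <- TRUE
      e <- nxt[start + 1L]
      while (e != start) {
        loop <- c(loop, e)
        used[e + 1L] <- TRUE
        e <- nxt[e + 1L]
      }
      if (length(loop) >= 3)
        for (i in 2:(length(loop) - 1))
          tris <- c(tris, loop[1], loop[i], loop[i + 1])
    }
    stopifnot(length(tris) <= 15)   # at most 5 triangles per cell
    if (length(tris) > 0) table[mask + 1L, seq_along(tris)] <- tris
  }
  # fix global winding: for the single-inside-corner case the triangle
  # normal must point away from that (high-intensity) corner, so that
  # closed surfaces around high regions have positive signed volume
  edges <- mc_edges()
  row <- table[2L, 1:3]   # mask = 1: corner 0 inside
  mid <- t(vapply(row + 1L, function(e)
    colMeans(offs[edges[e, ] + 1L, , drop = FALSE]), numeric(3)))
  nrm <- c(crossprod3(mid[2, ] - mid[1, ], mid[3, ] - mid[1, ]))
  away <- colMeans(mid) - offs[1, ]
  if (sum(nrm * away) < 0) {
    tmp <- table[, seq(2, 16, 3)]
    table[, seq(2, 16, 3)] <- table[, seq(3, 16, 3)]
    table[, seq(3, 16, 3)] <- tmp
  }
  table
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

mc_env <- new.env(parent = emptyenv())

mc_case_table <- function() {
  if (is.null(mc_env$table)) mc_env$table <- mc_case_table_build()
  mc_env$table
}
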