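# Vectorized trilinear sampling of a voxel grid at arbitrary physical
# points. Points outside the voxel-centre lattice hull evaluate to
# `outside`, which downstream operators fix at 0.
sample_trilinear <- function(grid, points, outside = 0) {
  p <- as_points(points)
  d <- dim(grid$data)
  # continuous 0-based voxel index per axis
  u <- sweep(sweep(p, 2, grid$origin, "-"), 2, grid$spacing, "/")
  i0 <- floor(u)
  f <- u - i0
  # clamp the degenerate single-slice axis so thickness-1 grids still sample
  for (a in 1:3) if (d[a] == 1L) { i0[, a] <- 0; f[, a] <- 0 }
  inside <- u[, 1] >= 0 & u[, 1] <= d[1] - 1 &
            u[, 2] >= 0 & u[, 2] <= d[2] - 1 &
            u[, 3] >= 0 & u[, 3] <= d[3] - 1
  # points exactly on the upper boundary: pull the base cell in by one
  for (a in 1:3) {
    hi <- i0[, a] >= d[a] - 1L & inside
    i0[hi, a] <- d[a] - 2L
    f[hi, a] <- u[hi, a] - i0[hi, a]
    if (d[a] == 1L) { i0[, a] <- 0; f[, a] <- 0 }
  }
  out <- rep(as.numeric(outside), nrow(p))
  idx <- which(inside)
  if (length(idx) == 0) return(out)
  x0 <- i0[idx, 1]; y0 <- i0[idx, 2]; z0 <- i0[idx, 3]
  fx <- f[idx, 1]; fy <- f[idx, 2]; fz <- f[idx, 3]
  sx <- if (d[1] > 1L) 1L else 0L
  sy <- if (d[2] > 1L) 1L else 0L
  sz <- if (d[3] > 1L) 1L else 0L
  lin <- function(ix, iy, iz) grid$data[1 + ix + d[1] * (iy + d[2] * iz)]
  v000 <- lin(x0,      y0,      z0)
  v100 <- lin(x0 + sx, y0,      z0)
  v010 <- lin(x0,      y0 + sy, z0)
  v110 <- lin(x0 + sx, y0 + sy, z0)
  v001 <- lin(x0,      y0,      z0 + sz)
  v101 <- lin(x0 + sx, y0,      z0 + sz)
  v011 <- lin(x0,      y0 + sy, z0 + sz)
  v111 <- lin(x0 + sx, y0 + sy, z0 + sz)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[idx] <- c0 * (1 - fz) + c1 * fz
  out
}
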