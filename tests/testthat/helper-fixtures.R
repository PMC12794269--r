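# Shared fixture builders. Everything is generated in code at test
# time; no stored binary data.

# smooth signed-distance-like sphere field: value r - dist(centre),
# isosurface at 0 is the sphere of radius r
sphere_field_grid <- function(spacing = 0.5, radius = 20, pad = 4) {
  n <- 2 * ceiling((radius + pad) / spacing) + 1
  ax <- (0:(n - 1)) * spacing - (n - 1) * spacing / 2
  d <- radius - sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  voxel_grid(d, rep(spacing, 3), rep(ax[1], 3))
}

torus_field_grid <- function(spacing = 0.5, ring_r = 10, tube_r = 4, pad = 4) {
  n <- 2 * ceiling((ring_r + tube_r + pad) / spacing) + 1
  ax <- (0:(n - 1)) * spacing - (n - 1) * spacing / 2
  rad_xy <- sqrt(outer(outer(ax^2, ax^2, "+"), 0 * ax, "+"))
  z2 <- outer(outer(0 * ax, 0 * ax, "+"), ax^2, "+")
  d <- tube_r - sqrt((rad_xy - ring_r)^2 + z2)
  voxel_grid(d, rep(spacing, 3), rep(ax[1], 3))
}

# small, fast phantom used across tests
test_phantom_spec <- function(noise = 0, seed = 1L) {
  phantom_spec(shape = c(110, 96, 40), spacing = c(1, 1, 2),
               semi_axes = c(42, 28, 24), noise_level = noise, seed = seed)
}

tmp_ledger <- function() ledger_open(tempfile(fileext = ".log"))

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
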