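test_that("intensity windowing zeroes below v0, clamps above v1, is idempotent", {
  g <- voxel_grid(array(c(10, 250, 100, 50, 200, 0, 199, 51),
                        c(2, 2, 2)))
  led <- tmp_ledger()
  out <- clamp_intensity(g, 50, 200, led)
  expect_equal(as.numeric(out$data), c(0, 200, 100, 50, 200, 0, 199, 51))
  expect_equal(ledger_read(led, "clip_low"), 50)
  expect_equal(ledger_read(led, "clip_high"), 200)
  # idempotent
  expect_identical(clamp_intensity(out, 50, 200)$data, out$data)
  # identity window
  g2 <- voxel_grid(array(runif(27, 1, 9), c(3, 3, 3)))
  expect_identical(clamp_intensity(g2, min(g2$data), max(g2$data))$data,
                   g2$data)
  expect_error(clamp_intensity(g, 200, 50), "v0")
})

test_that("mirroring maps index i to n-1-i, is an involution, keeps spacing", {
  arr <- array(0, c(10, 4, 4)); arr[3, 2, 2] <- 7   # 0-based x-index 2
  g <- voxel_grid(arr, spacing = c(0.65, 0.65, 2))
  m <- mirror_grid(g, 1)
  expect_equal(unname(which(m$data == 7, arr.ind = TRUE)[1, 1]), 8L)  # 0-based 7
  expect_identical(mirror_grid(m, 1)$data, g$data)
  expect_identical(m$spacing, g$spacing)
  expect_error(mirror_grid(g, 4), "axis")
})

test_that("Gaussian smoothing conserves mass, fixes constants, sigma 0 is identity", {
  const <- voxel_grid(array(5, c(20, 20, 20)))
  expect_lt(max(abs(gaussian_smooth(const, c(6, 6, 6))$data - 5)), 1e-9)
  set.seed(1)
  g <- voxel_grid(array(0, c(61, 61, 61)))
  g$data[26:36, 26:36, 26:36] <- runif(11^3, 0, 10)   # interior-supported
  sm <- gaussian_smooth(g, c(3, 3, 3))
  expect_rel_error(sum(sm$data), sum(g$data), 1e-3)
  expect_identical(gaussian_smooth(g, c(0, 0, 0))$data, g$data)
})

test_that("default smoothing impulse response has per-axis std 6 voxels", {
  imp <- array(0, c(97, 97, 97)); imp[49, 49, 49] <- 1
  out <- gaussian_smooth(voxel_grid(imp), c(6, 6, 6))$data
  idx <- 0:96
  for (axis in 1:3) {
    marg <- apply(out, axis, sum)
    mu <- sum(idx * marg) / sum(marg)
    sdv <- sqrt(sum((idx - mu)^2 * marg) / sum(marg))
    expect_equal(sdv, 6, tolerance = 0.05 / 6)
  }
})

test_that("low-pass keeps DC exactly and gates axial sinusoids at the cutoff", {
  const <- voxel_grid(array(3.7, c(16, 16, 16)))
  expect_lt(max(abs(lowpass_filter(const, 0.05)$data - 3.7)), 1e-9)
  nx <- 100
  mk <- function(f) voxel_grid(array(rep(cos(2 * pi * f * (0:(nx - 1))), 8 * 8),
                                     c(nx, 8, 8)))
  # 0.10 cycles/voxel: attenuated below 1%
  expect_lt(max(abs(lowpass_filter(mk(0.10), 0.05)$data)), 0.01)
  # 0.02 cycles/voxel: preserved within 1%
  out <- lowpass_filter(mk(0.02), 0.05)$data
  expect_lt(max(abs(out - mk(0.02)$data)), 0.01)
})

test_that("resampling is exact for identity, affine fields, and bookkeeping", {
  set.seed(2)
  g <- voxel_grid(array(runif(10 * 12 * 8), c(10, 12, 8)), c(1, 2, 3))
  same <- resample_grid(g, c(10, 12, 8))
  expect_lt(max(abs(same$data - g$data)), 1e-9)
  # linear ramp stays linear under 2x downsampling
  ramp <- voxel_grid(outer(outer(0:19, rep(1, 20)), rep(1, 20)) * 1.0)
  down <- resample_grid(ramp, c(10, 20, 20))
  slope <- diff(down$data[, 1, 1]) / down$spacing[1]
  expect_lt(max(abs(slope - 1)), 1e-6)
  # shape/spacing bookkeeping: halved counts ~ doubled spacing
  big <- voxel_grid(array(0, c(64, 64, 64)), c(1, 1, 1))
  half <- resample_grid(big, c(32, 32, 32))
  expect_equal(dim(half$data), c(32L, 32L, 32L))
  expect_equal(half$spacing, rep(63 / 31, 3))
  # physical extent preserved (endpoint-aligned lattice)
  expect_equal((dim(half$data) - 1) * half$spacing, c(63, 63, 63))
})

test_that("clean_volume applies the documented stage order and records it", {
  spec <- test_phantom_spec(noise = 0.05)
  ph <- make_limb_phantom(spec)
  md_r <- limb_metadata("right", "forelimb", spec$spacing)
  md_l <- limb_metadata("left", "forelimb", spec$spacing)
  cfg <- clean_config(20, 180, sigma = c(2, 2, 2))
  led <- tmp_ledger()
  out_r <- clean_volume(ph$nuclei, md_r, cfg, led)
  # defaults recorded
  expect_equal(ledger_read(led, "clip_low"), 20)
  expect_equal(ledger_read(led, "sigma"), c(2, 2, 2))
  expect_equal(ledger_read(led, "cutoff"), 0.05)
  expect_false(ledger_read(led, "mirrored"))
  # left-limb run is the mirrored right-limb run
  out_l <- clean_volume(ph$nuclei, md_l, cfg, tmp_ledger())
  expect_equal(out_l$data, mirror_grid(out_r, 1)$data, tolerance = 1e-12)
  # order regression: documented order is clamp -> smooth -> lowpass;
  # permuting clamp and smooth changes the result
  g0 <- voxel_grid(ph$nuclei$data, spec$spacing)
  manual <- lowpass_filter(gaussian_smooth(clamp_intensity(g0, 20, 180),
                                           c(2, 2, 2)), 0.05)
  expect_equal(out_r$data, manual$data, tolerance = 1e-12)
  permuted <- lowpass_filter(clamp_intensity(gaussian_smooth(g0, c(2, 2, 2)),
                                             20, 180), 0.05)
  expect_gt(max(abs(permuted$data - out_r$data)), 1e-3)
})

test_that("cleaning removes nearly all spectral power above the cutoff", {
  spec <- test_phantom_spec(noise = 0.05)
  ph <- make_limb_phantom(spec)
  md <- limb_metadata("right", "forelimb", spec$spacing)
  cl <- clean_volume(ph$nuclei, md, clean_config(20, 180), tmp_ledger())
  hi_frac <- function(g) {
    d <- dim(g$data); F <- fft(g$data)
    fax <- lapply(d, function(n) { k <- 0:(n - 1); pmin(k, n - k) / n })
    hi <- outer(outer(fax[[1]]^2, fax[[2]]^2, "+"), fax[[3]]^2, "+") > 0.05^2
    sum(Mod(F[hi])^2) / sum(Mod(F)^2)
  }
  before <- hi_frac(ph$nuclei)
  expect_gt(before, 0.01)            # speckle puts real power up there
  expect_lt(hi_frac(cl) / before, 0.01)
})

test_that("all-zero volumes clean to all-zero without errors", {
  g <- voxel_grid(array(0, c(24, 24, 24)))
  md <- limb_metadata("right", "forelimb", c(1, 1, 1))
  out <- clean_volume(g, md, clean_config(10, 20), tmp_ledger())
  expect_true(all(out$data == 0))
})
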