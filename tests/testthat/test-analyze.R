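test_that("ortho_slice copies planes exactly and validates the index", {
  set.seed(30)
  arr <- array(runif(6 * 7 * 8), c(6, 7, 8))
  g <- voxel_grid(arr)
  expect_identical(ortho_slice(g, 3, 5), arr[, , 5])
  expect_identical(ortho_slice(g, 1, 2), arr[2, , ])
  # ramp along the slicing axis: constant plane of value k * slope
  ramp <- voxel_grid(outer(outer(0:9, rep(1, 4)) * 2, rep(1, 4)))
  expect_true(all(ortho_slice(ramp, 1, 4) == 6))
  expect_error(ortho_slice(g, 3, 9), "out of range")
  # slice equals thickness-1 slab under either operation
  expect_equal(ortho_slice(g, 2, 3),
               slab_project(g, 2, c(3, 4), "mean")$image)
  expect_equal(ortho_slice(g, 2, 3),
               slab_project(g, 2, c(3, 4), "max")$image)
})

test_that("slab projection equals the brute-force reduction with metadata", {
  set.seed(31)
  arr <- array(runif(6 * 7 * 8), c(6, 7, 8))
  g <- voxel_grid(arr)
  led <- tmp_ledger()
  sl <- slab_project(g, 3, c(2, 6), "mean", ledger = led)
  brute <- apply(arr[, , 2:5], c(1, 2), mean)
  expect_equal(sl$image, brute)
  expect_equal(sl$index_range, c(2, 6))
  expect_equal(ledger_read(led, "slab_operation"), "mean")
  mx <- slab_project(g, 3, c(2, 6), "max")
  expect_equal(mx$image, apply(arr[, , 2:5], c(1, 2), max))
  # max projection dominates mean projection elementwise
  expect_true(all(mx$image >= sl$image - 1e-12))
  expect_error(slab_project(g, 3, c(5, 5)), "half-open")
})

test_that("oblique slice through voxel centres matches the orthogonal slice", {
  set.seed(32)
  arr <- array(runif(9^3), c(9, 9, 9))
  g <- voxel_grid(arr)
  ob <- oblique_slice(g, plane_origin = c(4, 4, 4), plane_normal = c(0, 0, 1),
                      resolution = 1, half_extent = c(4, 4))
  expect_lt(max(abs(ob$images[[1]] - ortho_slice(g, 3, 5))), 1e-9)
  # constant grid: constant image whatever the plane
  cg <- voxel_grid(array(4.2, c(9, 9, 9)))
  ob2 <- oblique_slice(cg, c(4, 4, 4), c(1, 2, 2) / 3, resolution = 0.8,
                       half_extent = c(3, 3))
  expect_true(all(abs(ob2$images[[1]] - 4.2) < 1e-9))
  # multi-channel slices share the sample lattice bitwise
  g2 <- voxel_grid(arr * 2)
  both <- oblique_slice(list(g, g2), c(4, 4, 4), c(0, 1, 0), 1, c(3, 3))
  expect_identical(both$lattice, oblique_slice(list(g2, g), c(4, 4, 4),
                                               c(0, 1, 0), 1, c(3, 3))$lattice)
  expect_equal(both$images[[2]], both$images[[1]] * 2)
  g_bad <- voxel_grid(arr, spacing = c(2, 1, 1))
  expect_error(oblique_slice(list(g, g_bad), c(4, 4, 4), c(0, 0, 1), 1),
               "geometry")
})

test_that("line probes reproduce affine fields exactly and share samples", {
  ramp <- voxel_grid(outer(outer(0:9, rep(1, 10)), rep(1, 10)) * 1.0)
  pr <- probe_line(ramp, c(0.5, 4, 4), c(8.5, 4, 4), 17)
  expect_equal(pr$values[[1]], seq(0.5, 8.5, length.out = 17),
               tolerance = 1e-12)
  expect_equal(pr$arclength, seq(0, 8, length.out = 17))
  expect_true(all(diff(pr$arclength) >= 0))
  # constant grid: constant profile
  cg <- voxel_grid(array(7, c(10, 10, 10)))
  expect_true(all(probe_line(cg, c(1, 1, 1), c(8, 8, 8), 25)$values[[1]] == 7))
  expect_error(probe_line(cg, c(1, 1, 1), c(1, 1, 1)), "zero-length")
})

test_that("torus probe through the hole shows the donut's central dip", {
  spec <- test_phantom_spec()
  torus <- make_gene_domain(spec, "torus")
  b <- spec$base; sa <- spec$semi_axes
  xc <- b[1] + 0.5 * sa[1]
  pr <- probe_line(torus, c(xc, b[2] - sa[2], b[3]), c(xc, b[2] + sa[2], b[3]),
                   201)
  v <- pr$values[[1]]
  centre <- v[101]
  flank <- max(v)
  expect_lt(centre, 0.5 * flank)
  expect_gt(flank, 0)
})

test_that("multi-isosurface extraction caps at 10 and nests monotonically", {
  g <- sphere_field_grid(spacing = 1, radius = 20)
  ms <- multi_isosurfaces(g, 2, 15, n = 25)
  expect_length(ms, 10L)
  vols <- vapply(ms, function(m) mesh_measures(m)$volume, 0.0)
  expect_true(all(diff(vols) < 0))   # higher level => smaller enclosed volume
  one <- multi_isosurfaces(g, 5, 10, n = 1)
  expect_length(one, 1L)
  expect_equal(attr(one, "levels"), 5)
  # out-of-range levels are skipped with a record, not an error
  sk <- multi_isosurfaces(g, 15, 1000, n = 3)
  expect_gt(length(attr(sk, "skipped")), 0)
  expect_error(multi_isosurfaces(g, 10, 5, 3), "v_low")
})

test_that("histogram summary is exact against brute-force binning", {
  set.seed(33)
  g <- voxel_grid(array(runif(4^3, 0, 10), c(4, 4, 4)))
  hs <- histogram_summary(g, 7)
  expect_equal(sum(hs$counts), length(g$data))
  expect_equal(hs$mean, mean(g$data))
  brute <- table(cut(as.numeric(g$data), hs$bin_edges, include.lowest = TRUE))
  expect_equal(as.integer(brute), hs$counts)
  # constant grid: a single nonzero bin
  hc <- histogram_summary(voxel_grid(array(3, c(3, 3, 3))), 5)
  expect_equal(sum(hc$counts > 0), 1L)
  # excluding zeros reproduces the auto-isovalue statistic
  g2 <- voxel_grid(array(c(rep(0, 20), rep(100, 4), rep(200, 3)), c(3, 3, 3)))
  expect_equal(histogram_summary(g2, 4, exclude_zeros = TRUE)$mean,
               auto_isovalue(g2))
})

test_that("analysis operators leave their input grids unmodified", {
  set.seed(34)
  arr <- array(runif(8^3), c(8, 8, 8))
  g <- voxel_grid(arr)
  before <- g$data
  invisible(ortho_slice(g, 1, 3))
  invisible(slab_project(g, 2, c(2, 5), "max"))
  invisible(probe_line(g, c(1, 1, 1), c(6, 6, 6), 10))
  invisible(histogram_summary(g, 5))
  expect_identical(g$data, before)
})

test_that("rotating before slab-projecting equals warp-then-slab", {
  set.seed(35)
  g <- gaussian_smooth(voxel_grid(array(runif(20^3), c(20, 20, 20))),
                       c(2, 2, 2))
  rot <- reorient_to_axis(c(0.2, -0.1, -0.97) / sqrt(sum(c(0.2, -0.1, -0.97)^2)))
  warped <- warp_grid(g, rot)
  a <- slab_project(warped, 3, c(5, 12), "mean")$image
  b <- slab_project(warp_grid(g, rot, reference = g), 3, c(5, 12), "mean")$image
  expect_equal(a, b, tolerance = 1e-12)
})
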