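test_that("noise-free phantom surface matches the analytic half-ellipsoid", {
  spec <- test_phantom_spec(noise = 0)
  ph <- make_limb_phantom(spec)
  m <- extract_isosurface(ph$nuclei, spec$intensity / 2)
  mm <- mesh_measures(largest_component(m))
  expect_rel_error(mm$volume, ph$truth$volume, 0.03)
  expect_equal(ph$truth$volume, 2 / 3 * pi * prod(spec$semi_axes))
  expect_equal(mm$n_boundary_edges, 0L)   # fully interior => watertight
})

test_that("phantom generation is bitwise deterministic in the seed", {
  spec <- test_phantom_spec(noise = 0.05, seed = 99L)
  a <- make_limb_phantom(spec)
  b <- make_limb_phantom(spec)
  expect_identical(a$nuclei$data, b$nuclei$data)
  other <- make_limb_phantom(test_phantom_spec(noise = 0.05, seed = 100L))
  expect_false(identical(a$nuclei$data, other$nuclei$data))
  # phantom RNG does not disturb the session RNG state
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(make_limb_phantom(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("AER landmarks lie exactly on the ideal phantom surface", {
  spec <- test_phantom_spec(noise = 0)
  ph <- make_limb_phantom(spec)
  p <- ph$landmarks$points
  rho <- rowSums(sweep(sweep(p, 2, ph$truth$base), 2,
                       ph$truth$semi_axes, "/")^2)
  expect_lt(max(abs(rho - 1)), 1e-12)
  expect_true(all(p[, 1] >= ph$truth$base[1]))
})

test_that("phantoms keep a clean margin so every surface is closed", {
  spec <- test_phantom_spec(noise = 0.05)
  ph <- make_limb_phantom(spec)
  d <- ph$nuclei$data
  edge_vals <- c(d[1, , ], d[dim(d)[1], , ], d[, 1, ], d[, dim(d)[2], ],
                 d[, , 1], d[, , dim(d)[3]])
  expect_true(all(edge_vals == 0))
  for (kind in c("gradient", "bilobed", "torus")) {
    g <- make_gene_domain(spec, kind)
    expect_lt(max(g$data[1, , ], g$data[dim(d)[1], , ]),
              0.01 * max(g$data))
  }
})

test_that("gene domains have their designed shapes", {
  spec <- test_phantom_spec()
  b <- spec$base; sa <- spec$semi_axes
  # gradient: monotone proximodistal profile
  gr <- make_gene_domain(spec, "gradient")
  pr <- probe_line(gr, c(b[1] + 1, b[2], b[3]),
                   c(b[1] + sa[1] - 2, b[2], b[3]), 50)
  expect_true(all(diff(pr$values[[1]]) > -1e-9))
  # bilobed: two maxima with a central dip along the probe through the foci
  bl <- make_gene_domain(spec, "bilobed")
  xf <- b[1] + 0.55 * sa[1]
  v <- probe_line(bl, c(xf, b[2] - sa[2], b[3]),
                  c(xf, b[2] + sa[2], b[3]), 201)$values[[1]]
  centre <- v[101]
  left_max <- max(v[1:90]); right_max <- max(v[112:201])
  expect_gt(left_max, 2 * centre)
  expect_gt(right_max, 2 * centre)
  # torus: genus-1 isosurface
  to <- make_gene_domain(spec, "torus")
  expect_equal(mesh_measures(extract_isosurface(to, 100))$euler_characteristic,
               0L)
  expect_error(make_gene_domain(spec, "stripe"), "arg")
})

test_that("reference sets cover the range with volume monotone in stage", {
  dir <- tempfile()
  reg <- make_reference_set(c(260, 266), test_phantom_spec(), dir,
                            subdivisions = 2)
  expect_length(reg$entries, 7L)
  vols <- vapply(reg$entries, function(p)
    mesh_measures(read_mesh(p))$volume, 0.0)
  expect_true(all(diff(vols) > 0))
  # rebuilding from the directory reproduces the registry
  expect_identical(registry_build(c(260, 266), dir)$entries, reg$entries)
})

test_that("known-transform perturbations report their exact ground truth", {
  m <- icosphere(3, 15)
  # magnitude 0: identity, object unchanged
  p0 <- perturb_with_known_transform(m, "rigid", magnitude = 0, seed = 3)
  expect_equal(p0$ground_truth$matrix, diag(4))
  expect_equal(p0$perturbed$vertices, m$vertices)
  # rigid: proper rotation + translation, and the stated magnitudes
  pr <- perturb_with_known_transform(m, "rigid", magnitude = 5, seed = 4)
  R <- pr$ground_truth$matrix[1:3, 1:3]
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(rotation_angle_deg(R), 5, tolerance = 1e-9)
  expect_equal(pr$perturbed$vertices,
               transform_apply_points(pr$ground_truth, m$vertices))
  # similarity carries the documented scale
  ps <- perturb_with_known_transform(m, "similarity", magnitude = 5, seed = 4)
  sv <- svd(ps$ground_truth$matrix[1:3, 1:3])$d
  expect_equal(sv, rep(1.1, 3), tolerance = 1e-9)
  # determinism
  pr2 <- perturb_with_known_transform(m, "rigid", magnitude = 5, seed = 4)
  expect_identical(pr2$ground_truth$matrix, pr$ground_truth$matrix)
})
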