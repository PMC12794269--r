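test_that("registry covers every integer stage and looks up by rounding", {
  dir <- tempfile()
  reg <- make_reference_set(c(249, 290), test_phantom_spec(), dir,
                            subdivisions = 1)
  expect_length(reg$entries, 42L)
  expect_equal(registry_lookup(reg, 267.4)$stage, 267L)
  expect_equal(registry_lookup(reg, 267.5)$stage, 268L)
  expect_true(file.exists(registry_lookup(reg, 249)$path))
  expect_error(registry_lookup(reg, 300), "outside")
  # single-stage registry
  one <- registry_build(c(250, 250), dir)
  expect_length(one$entries, 1L)
  # missing stage file is named
  expect_error(registry_build(c(240, 250), dir), "240")
})

test_that("similarity estimation recovers a known rotation/translation/scale", {
  set.seed(20)
  p <- matrix(runif(150, -40, 40), 50, 3)
  n <- rnorm(3); n <- n / sqrt(sum(n^2))
  R <- reorient_to_axis(n)$matrix[1:3, 1:3]
  s <- 1.3; tr <- c(5, -3, 11)
  q <- t(s * R %*% t(p)) + rep(tr, each = 50)
  est <- similarity_from_landmarks(p, q)
  truth <- rbind(cbind(s * R, tr), c(0, 0, 0, 1))
  expect_lt(max(abs(est$matrix - truth)), 1e-9)
  expect_equal(attr(est, "scale"), s, tolerance = 1e-12)
  # identity case
  id <- similarity_from_landmarks(p, p)
  expect_lt(max(abs(id$matrix - diag(4))), 1e-9)
  # rigid-only estimate ignores scale
  rig <- similarity_from_landmarks(p, q, with_scale = FALSE)
  expect_equal(attr(rig, "scale"), 1)
  expect_error(similarity_from_landmarks(p[1:2, ], q[1:2, ]), ">= 3")
})

test_that("reflective correspondences still yield a proper rotation", {
  set.seed(21)
  p <- matrix(runif(60, -10, 10), 20, 3)
  q <- p; q[, 1] <- -q[, 1]          # pure reflection
  est <- similarity_from_landmarks(p, q, with_scale = FALSE)
  expect_equal(det(est$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
  resid <- transform_apply_points(est, p) - q
  expect_gt(sqrt(mean(resid^2)), 0.1)   # reflection can't be fit exactly
})

test_that("similarity residual is invariant under joint rigid motions", {
  set.seed(22)
  p <- matrix(runif(90, -20, 20), 30, 3)
  q <- p + matrix(rnorm(90, 0, 0.5), 30, 3)
  resid_of <- function(a, b) {
    est <- similarity_from_landmarks(a, b)
    sqrt(mean((transform_apply_points(est, a) - b)^2))
  }
  base <- resid_of(p, q)
  M <- reorient_to_axis(c(2, -1, 2) / 3)
  M$matrix[1:3, 4] <- c(7, -4, 2)
  moved <- resid_of(transform_apply_points(M, p), transform_apply_points(M, q))
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("closest-point pair augmentation matches concentric geometry", {
  s1 <- icosphere(3, 10); s2 <- icosphere(3, 12)
  aug <- augment_pairs_closest(s1, s2, NULL, n_extra = 25)
  d <- sqrt(rowSums((aug$source$points - aug$target$points)^2))
  expect_equal(mean(d), 2, tolerance = 0.02)
  # identical meshes: zero distances regardless of seeds
  aug0 <- augment_pairs_closest(s1, s1, NULL, n_extra = 10)
  expect_lt(max(sqrt(rowSums((aug0$source$points - aug0$target$points)^2))),
            1e-9)
  # n_extra = 0 returns the seeds unchanged
  seeds <- list(source = s1$vertices[1:4, ], target = s2$vertices[1:4, ])
  aug_seed <- augment_pairs_closest(s1, s2, seeds, n_extra = 0)
  expect_equal(nrow(aug_seed$source$points), 4L)
  expect_error(augment_pairs_closest(s1, s2, NULL,
                                     n_extra = nrow(s1$vertices) + 1),
               "exceeds")
})

test_that("ICP recovers a known small rigid motion with a monotone trace", {
  spec <- test_phantom_spec()
  m <- decimate_mesh(largest_component(
    extract_isosurface(make_limb_phantom(spec)$nuclei, 50)),
    decimation_config(0.98))
  pert <- perturb_with_known_transform(m, "rigid", magnitude = 5, seed = 7)
  rec <- icp_refine(pert$perturbed, m, estimate = "rigid")
  resid <- rec$matrix %*% pert$ground_truth$matrix
  expect_lt(rotation_angle_deg(resid[1:3, 1:3]), 0.1)
  expect_lt(sqrt(sum(resid[1:3, 4]^2)), 0.05)
  trace <- attr(rec, "trace")
  expect_true(all(diff(trace) <= 1e-12))
  # already-aligned meshes return the init immediately
  rec0 <- icp_refine(m, m)
  expect_lt(max(abs(rec0$matrix - diag(4))), 1e-9)
})

test_that("TPS interpolates landmarks, reproduces affine maps, fixes identity", {
  set.seed(23)
  src <- matrix(runif(36, 0, 50), 12, 3)
  # exact interpolation at lambda = 0
  tgt <- src + matrix(rnorm(36, 0, 3), 12, 3)
  w <- tps_fit(src, tgt)
  expect_lt(max(abs(transform_apply_points(w, src) - tgt)), 1e-6)
  expect_gte(w$bending_energy, 0)
  # affine targets: zero bending energy, affine reproduced off-landmark
  A <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3); b <- c(1, -2, 3)
  tgt_a <- t(A %*% t(src)) + rep(b, each = 12)
  wa <- tps_fit(src, tgt_a)
  expect_lt(wa$bending_energy, 1e-8)
  probe <- matrix(runif(300, 0, 50), 100, 3)
  expect_lt(max(abs(transform_apply_points(wa, probe) -
                    (t(A %*% t(probe)) + rep(b, each = 100)))), 1e-6)
  # identity warp: no displacement anywhere on a probe lattice
  wi <- tps_fit(src, src)
  expect_equal(wi$bending_energy, 0, tolerance = 1e-10)
  lat <- as.matrix(expand.grid(seq(0, 50, length.out = 10),
                               seq(0, 50, length.out = 10),
                               seq(0, 50, length.out = 10)))
  expect_lt(max(abs(transform_apply_points(wi, lat) - lat)), 1e-8)
  # degenerate landmarks ask for regularization
  flat <- cbind(src[, 1:2], 0)
  expect_error(tps_fit(flat, tgt), "lambda")
  expect_s3_class(tps_fit(flat, tgt, lambda = 1e-3), "tps_warp")
  expect_error(tps_fit(src[1:3, ], tgt[1:3, ]), ">= 4")
})

test_that("volume warping: identity, exact integer shifts, affine round-trip", {
  set.seed(24)
  g <- voxel_grid(array(runif(16^3), c(16, 16, 16)))
  expect_lt(max(abs(warp_grid(g, affine4())$data - g$data)), 1e-9)
  shift <- affine4_from_rts(t = c(3, 0, 2))
  w <- warp_grid(g, shift)
  expect_equal(w$data[4:16, , 3:16], g$data[1:13, , 1:14], tolerance = 1e-12)
  expect_true(all(w$data[1:3, , ] == 0))
  # smooth field: warp then unwarp returns near the original
  sm <- gaussian_smooth(g, c(2, 2, 2))
  rot <- reorient_to_axis(c(0.1, 0.1, -0.99) / sqrt(sum(c(0.1, 0.1, -0.99)^2)))
  rot$matrix[1:3, 4] <- c(0.3, -0.2, 0.4)
  back <- warp_grid(warp_grid(sm, rot), transform_invert(rot))
  core <- back$data[5:12, 5:12, 5:12] - sm$data[5:12, 5:12, 5:12]
  expect_lt(max(abs(core)), 0.05)
  expect_error(warp_grid(g, "nope"), "unsupported")
})

test_that("TPS-warped gene channel stays inside the morphed surface", {
  spec <- test_phantom_spec()
  ph <- make_limb_phantom(spec)
  gene <- make_gene_domain(spec, "torus")
  pert <- perturb_with_known_transform(
    decimate_mesh(largest_component(extract_isosurface(ph$nuclei, 50)),
                  decimation_config(0.97)),
    "tps", magnitude = 3, seed = 31)
  warp <- pert$ground_truth
  gene_w <- warp_grid(gene, warp)
  surf_w <- pert$perturbed
  # every strongly expressing warped voxel lies within the warped
  # surface's bounding box (containment proxy on the voxel grid)
  idx <- which(gene_w$data > 100, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, gene_w$spacing, "*"), 2, gene_w$origin, "+")
  bb <- apply(surf_w$vertices, 2, range)
  inside <- pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
            pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2] &
            pts[, 3] >= bb[1, 3] & pts[, 3] <= bb[2, 3]
  expect_gt(mean(inside), 0.99)
})

test_that("distance maps match analytic constructions", {
  s1 <- icosphere(3, 10); s2 <- icosphere(3, 12)
  dm <- distance_map(s1, s2)
  expect_equal(dm$summary$mean, 2, tolerance = 0.02)
  expect_true(all(dm$distances >= 0))
  expect_equal(dm$summary$rms, sqrt(mean(dm$distances^2)))
  expect_equal(dm$summary$max, max(dm$distances))
  # mesh against itself: all zeros
  self <- distance_map(s1, s1)
  expect_lt(self$summary$max, 1e-12)
  # point at height d above a large flat patch
  patch <- surface_mesh(rbind(c(-50, -50, 0), c(50, -50, 0),
                              c(50, 50, 0), c(-50, 50, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  pt <- surface_mesh(rbind(c(1, 2, 7), c(2, 1, 7), c(1.5, 1.5, 7.5)),
                     matrix(c(1, 2, 3), 1))
  dmp <- distance_map(pt, patch)
  expect_equal(dmp$distances[1:2], c(7, 7), tolerance = 1e-9)
})

test_that("end-to-end morph: TPS on augmented pairs shrinks the distance map", {
  spec <- test_phantom_spec()
  ph <- make_limb_phantom(spec)
  mesh <- decimate_mesh(largest_component(
    extract_isosurface(ph$nuclei, 50)), decimation_config(0.97))
  pert <- perturb_with_known_transform(mesh, "tps", magnitude = 4, seed = 41)
  target <- pert$perturbed
  rigid <- icp_refine(mesh, target, max_iter = 50)
  aligned <- transform_apply_mesh(rigid, mesh)
  aug <- augment_pairs_closest(aligned, target, NULL, n_extra = 25)
  warp <- tps_fit(aug$source, aug$target)
  morphed <- transform_apply_mesh(warp, aligned)
  rms <- distance_map(morphed, target)$summary$rms
  expect_lt(rms, 0.05 * mesh_bbox_diagonal(mesh))
})
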