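test_that("AER spline interpolates its inputs and handles the linear limit", {
  # collinear points resample to the same line
  p <- cbind(seq(0, 9, length.out = 5), 2 * seq(0, 9, length.out = 5), 1)
  sp <- fit_spline_aer(p, 50)
  expect_lt(max(abs(sp$points[, 2] - 2 * sp$points[, 1])), 1e-9)
  expect_lt(max(abs(sp$points[, 3] - 1)), 1e-9)
  # passes through every input point (resample at the input parameters)
  set.seed(10)
  q <- matrix(cumsum(runif(18, 0.5, 2)), 6, 3)
  sp2 <- fit_spline_aer(q, 6)
  expect_lt(max(abs(sp2$points[1, ] - q[1, ])), 1e-9)
  expect_lt(max(abs(sp2$points[6, ] - q[6, ])), 1e-9)
  expect_error(fit_spline_aer(q[1:2, ]), "3")
})

test_that("AER spline follows a circle arc within 0.5% of the radius", {
  th <- seq(0, pi / 2, length.out = 8)
  p <- cbind(10 * cos(th), 10 * sin(th), 0)
  sp <- fit_spline_aer(p, 200)
  radial <- sqrt(rowSums(sp$points[, 1:2]^2))
  expect_lt(max(abs(radial - 10)) / 10, 0.005)
})

test_that("plane fit recovers known planes with the sign convention", {
  p <- cbind(runif(20, -5, 5), runif(20, -5, 5), 5)
  fp <- fit_plane(p)
  expect_equal(fp$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fp$centroid[3], 5, tolerance = 1e-12)
  # noisy tilted plane: normal within 1 degree
  set.seed(12)
  n_true <- c(0.3, -0.4, 0.865); n_true <- n_true / sqrt(sum(n_true^2))
  R <- reorient_to_axis(n_true)$matrix[1:3, 1:3]
  flat <- cbind(runif(200, -10, 10), runif(200, -10, 10), 0)
  pts <- flat %*% R + matrix(rnorm(600, 0, 0.01), 200, 3)
  fp2 <- fit_plane(pts)
  ang <- acos(min(1, abs(sum(fp2$normal * (t(R) %*% c(0, 0, 1)))))) * 180 / pi
  expect_lt(ang, 1)
  # permutation invariance and scale equivariance
  fp3 <- fit_plane(pts[sample(200), ])
  expect_equal(abs(sum(fp3$normal * fp2$normal)), 1, tolerance = 1e-9)
  fp4 <- fit_plane(pts * 7)
  expect_equal(abs(sum(fp4$normal * fp2$normal)), 1, tolerance = 1e-9)
  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("reorientation rotates any unit normal onto (0,0,-1)", {
  expect_equal(reorient_to_axis(c(0, 0, -1))$matrix, diag(4))
  flip <- reorient_to_axis(c(0, 0, 1))
  expect_equal(drop(transform_apply_points(flip, matrix(c(0, 0, 1), 1))),
               c(0, 0, -1), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:20) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    Tm <- reorient_to_axis(n)
    R <- Tm$matrix[1:3, 1:3]
    expect_lt(max(abs(drop(R %*% n) - c(0, 0, -1))), 1e-9)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(Tm$matrix[1:3, 4], c(0, 0, 0))
  }
})

test_that("reorienting fitted landmarks flattens them to the canonical plane", {
  set.seed(14)
  n_true <- c(-0.5, 0.1, 0.86); n_true <- n_true / sqrt(sum(n_true^2))
  R <- reorient_to_axis(n_true)$matrix[1:3, 1:3]
  pts <- cbind(runif(50, -8, 8), runif(50, -8, 8), 0) %*% R +
    rep(c(3, -2, 7), each = 50)
  proj <- project_staging_points(pts)
  flattened <- transform_apply_points(proj$rotation, pts)
  residual <- fit_plane(flattened)$normal
  expect_lt(min(sum((residual - c(0, 0, 1))^2),
                sum((residual + c(0, 0, 1))^2)), 1e-6)
  expect_equal(dim(proj$points_2d), c(50L, 2L))
})

test_that("mock staging is deterministic, fixture-keyed, and ledger-recorded", {
  pts2 <- cbind(seq(0, 10, length.out = 6), sin(seq(0, 10, length.out = 6)))
  req <- staging_request(pts2, "left", "forelimb")
  fixtures <- stats::setNames(list(267.0), point_hash(pts2))
  client <- mock_staging_client(fixtures)
  led <- tmp_ledger()
  res <- request_stage(req, client, ledger = led)
  expect_equal(res$stage, 267.0)
  expect_equal(ledger_read(led, "stage"), 267.0)
  # determinism
  res2 <- request_stage(req, client)
  expect_identical(res2$stage, res$stage)
  expect_identical(res2$summary, res$summary)
  # unknown points with no default: service error
  other <- staging_request(pts2 + 1, "left", "forelimb")
  expect_error(request_stage(other, client), "404")
})

test_that("service failures raise errors and never touch the ledger", {
  req <- staging_request(cbind(1:4, 1:4), "right", "hindlimb")
  failing <- function(body) list(status = 500L, body = "internal error")
  led <- tmp_ledger()
  ledger_record(led, "marker", 1)
  expect_error(request_stage(req, failing, ledger = led), "500")
  expect_false("stage" %in% ledger_keys(led))
  garbled <- function(body) list(status = 200L, body = "not json{{{")
  expect_error(request_stage(req, garbled), "unparseable|lacks")
})
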