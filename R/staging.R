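#' Interpolating spline through AER landmarks
#'
#' Fits an interpolating cubic spline (chord-length parameterization,
#' one spline per coordinate) through ordered landmarks traced along
#' the apical ectodermal ridge, and resamples it at parameter-uniform
#' locations. The curve passes through every input point.
#'
#' @param points a [landmark_set] or n x 3 matrix of ordered points
#'   (>= 3).
#' @param n_samples number of resampled points (>= 2); endpoints are
#'   always included.
#' @return A [landmark_set] of `n_samples` points along the spline.
#' @export
fit_spline_aer <- function(points, n_samples = 100) {
  p <- as_points(points)
  if (nrow(p) < 3) stop("fit_spline_aer: need at least 3 ordered points")
  if (n_samples < 2) stop("fit_spline_aer: n_samples must be >= 2")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) stop("fit_spline_aer: coincident consecutive points")
  s <- c(0, cumsum(seg))
  ss <- seq(0, s[length(s)], length.out = n_samples)
  out <- vapply(1:3, function(k)
    stats::splinefun(s, p[, k], method = "fmm")(ss), numeric(n_samples))
  landmark_set(matrix(out, ncol = 3))
}

#' Least-squares plane fit
#'
#' The plane normal is the eigenvector of the centred covariance with
#' the smallest eigenvalue (total least squares). Sign convention:
#' non-negative z component, ties broken by non-negative y, then x.
#'
#' @param points a [landmark_set] or n x 3 matrix (>= 3 non-collinear
#'   points).
#' @return List with `normal` (unit 3-vector) and `centroid`.
#' @export
fit_plane <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 3) stop("fit_plane: need at least 3 points")
  centroid <- colMeans(p)
  x <- sweep(p, 2, centroid)
  sv <- svd(x)
  if (sv$d[2] <= sv$d[1] * 1e-12)
    stop("fit_plane: points are collinear or coincident")
  n <- sv$v[, 3]
  flip <- if (abs(n[3]) > 1e-12) n[3] < 0
          else if (abs(n[2]) > 1e-12) n[2] < 0
          else n[1] < 0
  if (flip) n <- -n
  list(normal = n / sqrt(sum(n^2)), centroid = centroid)
}

#' Rotation reorienting a plane normal to the canonical direction
#'
#' Returns the minimal-angle pure rotation taking `normal` to
#' `(0, 0, -1)` — the canonical dorsal-view direction used before
#' projecting staging landmarks to 2D. The antiparallel input
#' `(0, 0, 1)` is handled by a 180-degree rotation about the x axis.
#'
#' @param normal unit 3-vector.
#' @return An [affine4] with pure rotation (det +1), no translation.
#' @export
reorient_to_axis <- function(normal) {
  n <- as.numeric(normal)
  n <- n / sqrt(sum(n^2))
  target <- c(0, 0, -1)
  c_ <- sum(n * target)
  if (c_ > 1 - 1e-14) return(affine4(diag(4)))
  if (c_ < -1 + 1e-14) {
    # antiparallel: rotate 180 degrees about the x axis
    R <- diag(c(1, -1, -1))
    return(affine4_from_rts(R))
  }
  v <- crossprod3(n, target)
  s <- sqrt(sum(v^2))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  R <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  affine4_from_rts(R)
}

#' Staging request payload
#'
#' @param points_2d n x 2 matrix of reoriented/projected landmark
#'   coordinates (>= 3 points).
#' @param side `"left"` or `"right"`.
#' @param limb_type `"forelimb"` or `"hindlimb"`.
#' @return An object of class `staging_request`.
#' @export
staging_request <- function(points_2d, side, limb_type) {
  points_2d <- matrix(as.numeric(points_2d), ncol = 2)
  if (nrow(points_2d) < 3 || any(!is.finite(points_2d)))
    stop("staging_request: need >= 3 finite 2D points")
  structure(list(points_2d = points_2d,
                 side = match.arg(side, c("left", "right")),
                 limb_type = match.arg(limb_type, c("forelimb", "hindlimb"))),
            class = "staging_request")
}

#' Deterministic hash of a point list
#'
#' Used to key mock staging fixtures: points are formatted to 6
#' decimals and hashed with a 32-bit polynomial string hash, so the
#' same landmark list always maps to the same fixture entry.
#'
#' @param points numeric matrix of coordinates.
#' @return Hash string (8 hex digits).
#' @export
point_hash <- function(points) {
  txt <- paste(sprintf("%.6f", t(as.matrix(points))), collapse = ",")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Mock staging client
#'
#' Deterministic stand-in for the remote staging service: the stage is
#' looked up in a fixture table keyed by [point_hash()] of the request
#' points. Unknown point lists fall back to `default_stage` when given,
#' otherwise produce a 404-style service error.
#'
#' @param fixtures named numeric vector (or named list with `stage` /
#'   `uncertainty` entries) keyed by point hash.
#' @param default_stage optional numeric fallback stage.
#' @param uncertainty uncertainty (hours) reported with fixture stages.
#' @return A client function usable with [request_stage()].
#' @export
mock_staging_client <- function(fixtures = c(), default_stage = NULL,
                                uncertainty = 1.5) {
  force(fixtures); force(default_stage); force(uncertainty)
  function(body_json) {
    req <- jsonlite::fromJSON(body_json, simplifyVector = TRUE)
    h <- point_hash(req$points)
    entry <- if (h %in% names(fixtures)) fixtures[[h]] else default_stage
    if (is.null(entry))
      return(list(status = 404L,
                  body = paste0('{"error":"no stage fixture for hash ', h, '"}')))
    st <- if (is.list(entry)) entry$stage else as.numeric(entry)
    un <- if (is.list(entry) && !is.null(entry$uncertainty))
            entry$uncertainty else uncertainty
    list(status = 200L,
         body = as.character(jsonlite::toJSON(
           list(stage = st, uncertainty = un,
                summary = paste0("mock stage ", st, " (hash ", h, ")")),
           auto_unbox = TRUE, digits = NA)))
  }
}

#' HTTP staging client
#'
#' Posts the JSON payload to a live staging-service endpoint using the
#' system `curl` binary. Requires network access; analyses that must be
#' reproducible offline should use [mock_staging_client()].
#'
#' @param endpoint service URL.
#' @param timeout request timeout in seconds.
#' @return A client function usable with [request_stage()].
#' @export
http_staging_client <- function(endpoint, timeout = 30) {
  force(endpoint); force(timeout)
  function(body_json) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    status <- system2("curl",
                      c("-s", "-o", tmp, "-w", "%{http_code}",
                        "-H", "Content-Type: application/json",
                        "--max-time", as.character(timeout),
                        "-d", shQuote(body_json), shQuote(endpoint)),
                      stdout = TRUE, stderr = FALSE)
    code <- suppressWarnings(as.integer(status[length(status)]))
    if (is.na(code)) code <- 0L
    list(status = code,
         body = if (file.exists(tmp))
           paste(readLines(tmp, warn = FALSE), collapse = "\n") else "")
  }
}

#' Request a morphological stage from the staging service
#'
#' Serializes the landmark points as JSON, posts them to the client
#' (live endpoint or deterministic mock), and parses the returned
#' stage, uncertainty and summary. On success the stage is
#' ledger-recorded; any service failure raises an error and leaves the
#' ledger untouched — there is never a silent default stage.
#'
#' @param request a [staging_request].
#' @param client a client function, e.g. [mock_staging_client()] or
#'   [http_staging_client()].
#' @param ledger optional ledger; records `stage`, `stage_uncertainty`.
#' @param fields field-name mapping used to build/parse the JSON
#'   (payload points field, response stage/uncertainty fields).
#' @return A [stage_result].
#' @export
request_stage <- function(request, client, ledger = NULL,
                          fields = list(points = "points", stage = "stage",
                                        uncertainty = "uncertainty")) {
  stopifnot(inherits(request, "staging_request"), is.function(client))
  payload <- list()
  payload[[fields$points]] <- request$points_2d
  payload$side <- request$side
  payload$limb_type <- request$limb_type
  body <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  resp <- client(body)
  if (!is.list(resp) || is.null(resp$status))
    stop("request_stage: malformed client response")
  if (resp$status < 200L || resp$status >= 300L)
    stop("request_stage: staging service failed with status ", resp$status,
         ": ", substr(resp$body, 1, 200))
  parsed <- tryCatch(jsonlite::fromJSON(resp$body, simplifyVector = TRUE),
                     error = function(e)
                       stop("request_stage: unparseable service response: ",
                            substr(resp$body, 1, 200)))
  st <- parsed[[fields$stage]]
  if (is.null(st) || !is.finite(as.numeric(st)))
    stop("request_stage: service response lacks a finite '",
         fields$stage, "' field")
  un <- parsed[[fields$uncertainty]]
  res <- stage_result(as.numeric(st),
                      if (is.null(un)) 0 else as.numeric(un),
                      if (is.null(parsed$summary)) resp$body
                      else as.character(parsed$summary))
  if (!is.null(ledger)) {
    ledger_record(ledger, "stage", res$stage)
    ledger_record(ledger, "stage_uncertainty", res$uncertainty)
  }
  res
}

#' Project reoriented staging landmarks to 2D
#'
#' Convenience for the staging workflow: fit the landmark plane,
#' reorient its normal to `(0, 0, -1)`, apply the rotation and drop the
#' z coordinate.
#'
#' @param points a [landmark_set] or n x 3 matrix.
#' @return List with `points_2d` (n x 2), `rotation` ([affine4]) and
#'   `plane` (the [fit_plane()] result).
#' @export
project_staging_points <- function(points) {
  p <- as_points(points)
  plane <- fit_plane(p)
  rot <- reorient_to_axis(plane$normal)
  p2 <- transform_apply_points(rot, p)
  list(points_2d = p2[, 1:2, drop = FALSE], rotation = rot, plane = plane)
}
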