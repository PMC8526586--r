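#' Pinhole camera model with radial distortion
#'
#' Constructs a calibrated camera: pinhole intrinsics (focal lengths and
#' principal point in pixels), a two-term radial distortion polynomial
#' (k1, k2 on normalised image coordinates), and a world-to-camera rigid pose.
#' World coordinates are millimetres in a Z-up right-handed frame; camera
#' coordinates follow the usual convention (x right, y down, z forward along
#' the optical axis).
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @param k1,k2 Radial distortion coefficients (dimensionless).
#' @param R 3x3 world-to-camera rotation (orthonormal, det +1).
#' @param t Length-3 world-to-camera translation (mm): `x_cam = R x_world + t`.
#' @param width,height Image size in pixels (> 0).
#' @param name Optional camera name.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, k1 = 0, k2 = 0,
                         R = diag(3), t = c(0, 0, 0),
                         width = 2560, height = 2048, name = "cam") {
  R <- matrix(as.numeric(R), 3, 3)
  if (!is_rotation_matrix(R))
    stop("camera_model: rotation must be orthonormal with determinant +1")
  if (fx <= 0 || fy <= 0) stop("camera_model: focal lengths must be positive")
  if (width <= 0 || height <= 0) stop("camera_model: image size must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, k1 = k1, k2 = k2,
                 R = R, t = as.numeric(t),
                 width = width, height = height, name = name),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model %s> f=(%.1f,%.1f) c=(%.1f,%.1f) k=(%.3g,%.3g) %dx%d\n",
              x$name, x$fx, x$fy, x$cx, x$cy, x$k1, x$k2, x$width, x$height))
  invisible(x)
}

#' Camera centre in world coordinates
#' @param cam A `camera_model`.
#' @return Length-3 position (mm).
#' @export
camera_centre <- function(cam) as.numeric(-crossprod(cam$R, cam$t))

#' Project world points to distorted pixel coordinates
#'
#' Applies the world-to-camera pose, the radial distortion polynomial
#' `x_d = x (1 + k1 r^2 + k2 r^4)` on normalised coordinates, and the pinhole
#' intrinsics. With `k1 = k2 = 0` this is the ideal pinhole model.
#'
#' @param cam A `camera_model`.
#' @param point Length-3 world point (mm), or an n x 3 matrix of points.
#' @return Length-2 pixel coordinate, or an n x 2 matrix.
#' @export
project_point <- function(cam, point) {
  p <- if (is.matrix(point)) point else matrix(point, 1, 3)
  pc <- p %*% t(cam$R) + matrix(cam$t, nrow(p), 3, byrow = TRUE)
  if (any(pc[, 3] <= 0))
    stop("project_point: point behind camera (non-positive depth)")
  xn <- pc[, 1] / pc[, 3]
  yn <- pc[, 2] / pc[, 3]
  r2 <- xn^2 + yn^2
  d <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  px <- cbind(x = cam$fx * xn * d + cam$cx,
              y = cam$fy * yn * d + cam$cy)
  if (is.matrix(point)) px else as.numeric(px)
}

#' A 3D ray
#' @param origin Length-3 origin (mm, world frame).
#' @param direction Length-3 direction; normalised on construction.
#' @param valid Logical; `FALSE` flags a ray whose undistortion failed.
#' @return Object of class `ray`.
#' @export
ray <- function(origin, direction, valid = TRUE) {
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("ray: zero direction")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / n,
                 valid = isTRUE(valid)),
            class = "ray")
}

# invert the radial distortion by fixed-point iteration on normalised coords
undistort_normalised <- function(cam, xd, yd, max_iter = 20, tol = 1e-10) {
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    d <- 1 + cam$k1 * r2 + cam$k2 * r2^2
    xn <- xd / d; yn <- yd / d
    if (max(abs(xn - x), abs(yn - y)) < tol) return(list(x = xn, y = yn, ok = TRUE))
    x <- xn; y <- yn
  }
  list(x = x, y = y, ok = FALSE)
}

#' Back-project a pixel to a world-frame ray
#'
#' Undoes the intrinsics and radial distortion (fixed-point iteration,
#' <= 20 steps, tolerance 1e-10 in normalised units) and rotates the viewing
#' direction into the world frame. The ray origin is the camera centre.
#' Pixels outside the image raise a warning but are still back-projected;
#' failed undistortion convergence yields a ray flagged `valid = FALSE`.
#'
#' @param cam A `camera_model`.
#' @param pixel Length-2 pixel coordinate.
#' @return A `ray`.
#' @export
backproject <- function(cam, pixel) {
  if (pixel[1] < 0 || pixel[1] > cam$width || pixel[2] < 0 || pixel[2] > cam$height)
    warning("backproject: pixel outside image bounds")
  xd <- (pixel[1] - cam$cx) / cam$fx
  yd <- (pixel[2] - cam$cy) / cam$fy
  u <- undistort_normalised(cam, xd, yd)
  dir_cam <- c(u$x, u$y, 1)
  dir_world <- as.numeric(crossprod(cam$R, dir_cam))
  ray(camera_centre(cam), dir_world, valid = u$ok)
}

#' Distance from points to a ray
#' @param r A `ray`.
#' @param points n x 3 matrix or length-3 vector.
#' @return Perpendicular distances (mm).
#' @export
point_ray_distance <- function(r, points) {
  p <- if (is.matrix(points)) points else matrix(points, 1, 3)
  v <- sweep(p, 2, r$origin)
  along <- as.numeric(v %*% r$direction)
  perp <- v - outer(along, r$direction)
  row_norms(perp)
}

# stack a list of rays into origin/direction matrices
stack_rays <- function(rays) {
  list(o = do.call(rbind, lapply(rays, `[[`, "origin")),
       d = do.call(rbind, lapply(rays, `[[`, "direction")))
}

# memoised C(n,2) index pairs for the exhaustive RANSAC hypothesis sweep
.pair_cache <- new.env(parent = emptyenv())
all_pairs <- function(n) {
  key <- as.character(n)
  if (is.null(.pair_cache[[key]])) .pair_cache[[key]] <- utils::combn(n, 2)
  .pair_cache[[key]]
}

#' Least-squares intersection of a bundle of rays
#'
#' Finds the world point minimising the sum of squared perpendicular
#' distances to all rays, by the closed-form normal equations
#' `sum_i (I - d_i d_i') x = sum_i (I - d_i d_i') o_i`.
#'
#' @param rays List of `ray` objects (>= 2, not all parallel).
#' @return List with `point` (length-3, mm) and `distances` (per-ray
#'   perpendicular distances, mm).
#' @export
triangulate <- function(rays) {
  if (length(rays) < 2)
    stop("triangulate: degenerate geometry (need at least 2 rays)")
  s <- stack_rays(rays)
  A <- diag(3) * nrow(s$d) - crossprod(s$d)
  b <- colSums(s$o) - colSums(s$d * as.numeric(rowSums(s$d * s$o)))
  if (rcond(A) < 1e-12)
    stop("triangulate: degenerate geometry (near-parallel rays)")
  x <- solve(A, b)
  v <- sweep(s$o, 2, x, "-")
  along <- rowSums(v * s$d)
  perp <- v - s$d * along
  list(point = as.numeric(x), distances = row_norms(perp))
}

# nearest point between two rays (minimal RANSAC hypothesis); NULL if parallel
two_ray_point <- function(o1, d1, o2, d2) {
  b <- sum(d1 * d2)
  denom <- 1 - b * b
  if (denom < 1e-12) return(NULL)
  w <- o1 - o2
  dw1 <- sum(d1 * w); dw2 <- sum(d2 * w)
  t1 <- (b * dw2 - dw1) / denom
  t2 <- (dw2 - b * dw1) / denom
  (o1 + t1 * d1 + o2 + t2 * d2) / 2
}

#' RANSAC-robust ray intersection
#'
#' Hypotheses are minimal two-ray intersections; the consensus set is every
#' ray whose perpendicular distance to the hypothesis point is within
#' `inlier_tol_mm`; the winning consensus (ties broken by smaller inlier rms)
#' is refit with [triangulate()]. When the number of rays is at most 12 all
#' C(n,2) pairs are enumerated, otherwise `max_iter` pairs are sampled with a
#' seeded RNG. With every ray an inlier the result equals `triangulate(rays)`.
#'
#' @param rays List of `ray` objects.
#' @param inlier_tol_mm Consensus threshold, perpendicular point-to-ray
#'   distance in mm (default 20).
#' @param max_iter Sampling budget when n > 12 (default 100).
#' @param seed Optional integer fixing the sampling sequence.
#' @return List with `point`, `inliers` (logical mask), `distances` and
#'   `failed`. A consensus of fewer than 2 rays sets `failed = TRUE` and a
#'   missing point: a trajectory gap, not an error.
#' @export
ransac_intersect <- function(rays, inlier_tol_mm = 20, max_iter = 100, seed = NULL) {
  n <- length(rays)
  failed <- list(point = rep(NA_real_, 3), inliers = rep(FALSE, n),
                 distances = rep(NA_real_, n), failed = TRUE)
  if (n < 2) return(failed)
  if (inlier_tol_mm <= 0) stop("ransac_intersect: inlier_tol_mm must be positive")
  s <- stack_rays(rays)

  pairs <- if (n <= 12) {
    all_pairs(n)
  } else {
    with_seed(seed, {
      matrix(replicate(max_iter, sample.int(n, 2)), nrow = 2)
    })
  }

  o1 <- s$o[, 1]; o2 <- s$o[, 2]; o3 <- s$o[, 3]
  d1 <- s$d[, 1]; d2 <- s$d[, 2]; d3 <- s$d[, 3]
  ray_dists <- function(h) {
    v1 <- o1 - h[1]; v2 <- o2 - h[2]; v3 <- o3 - h[3]
    along <- v1 * d1 + v2 * d2 + v3 * d3
    sqrt(pmax(v1 * v1 + v2 * v2 + v3 * v3 - along * along, 0))
  }
  best <- NULL
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    h <- two_ray_point(s$o[i1, ], s$d[i1, ], s$o[i2, ], s$d[i2, ])
    if (is.null(h)) next
    dist <- ray_dists(h)
    inl <- dist <= inlier_tol_mm
    k <- sum(inl)
    if (k < 2) next
    rms <- sqrt(mean(dist[inl]^2))
    if (is.null(best) || k > best$k || (k == best$k && rms < best$rms))
      best <- list(k = k, rms = rms, inliers = inl)
  }
  if (is.null(best)) return(failed)

  fit <- triangulate(rays[best$inliers])
  list(point = fit$point, inliers = best$inliers,
       distances = ray_dists(fit$point), failed = FALSE)
}

#' Read / write a camera calibration file
#'
#' One record per camera: `{name, fx, fy, cx, cy, k1, k2, R (row-major 9),
#' t (3), width, height}` in YAML or JSON (by file extension).
#'
#' @param path File path.
#' @return List of `camera_model` objects.
#' @export
read_calibration <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    R <- matrix(as.numeric(r$R), 3, 3, byrow = TRUE)
    # polish away serialisation round-off; reject anything genuinely bent
    sv <- svd(R)
    Rp <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
    if (max(abs(Rp - R)) > 1e-4)
      stop("read_calibration: rotation for '", r$name, "' is not orthonormal")
    camera_model(r$fx, r$fy, r$cx, r$cy, r$k1, r$k2,
                 R = Rp,
                 t = as.numeric(r$t), width = r$width, height = r$height,
                 name = r$name)
  })
}

#' @rdname read_calibration
#' @param cameras List of `camera_model` objects.
#' @export
write_calibration <- function(cameras, path) {
  recs <- lapply(cameras, function(cam) {
    list(name = cam$name, fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
         k1 = cam$k1, k2 = cam$k2, R = as.numeric(t(cam$R)), t = cam$t,
         width = cam$width, height = cam$height)
  })
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(recs, path, precision = 15)
  else jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
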