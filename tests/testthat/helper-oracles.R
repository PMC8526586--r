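# Independent oracles, coded separately from the package internals so the
# paths they cross-check share no implementation.

# --- geometry -----------------------------------------------------------

# pinhole + two-term radial distortion, straight from the model definition
oracle_project <- function(cam, p) {
  pc <- as.numeric(cam$R %*% p + cam$t)
  xn <- pc[1] / pc[3]; yn <- pc[2] / pc[3]
  r2 <- xn^2 + yn^2
  d <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  c(cam$fx * xn * d + cam$cx, cam$fy * yn * d + cam$cy)
}

# least-squares ray intersection by a generic linear solve of the stacked
# (I - d d') system, via qr.solve rather than the closed-form accumulation
oracle_triangulate <- function(origins, dirs) {
  A <- matrix(0, 0, 3); b <- numeric(0)
  for (i in seq_len(nrow(origins))) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    Pi <- diag(3) - outer(d, d)
    A <- rbind(A, Pi)
    b <- c(b, as.numeric(Pi %*% origins[i, ]))
  }
  as.numeric(qr.solve(A, b))
}

oracle_point_ray_dist <- function(p, o, d) {
  v <- p - o
  sqrt(max(sum(v^2) - sum(v * d)^2, 0))
}

# exhaustive two-ray-hypothesis consensus search (the RANSAC reference)
oracle_ransac <- function(origins, dirs, tol) {
  n <- nrow(origins)
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # nearest point between rays i and j by solving the 2x2 system
    d1 <- dirs[i, ]; d2 <- dirs[j, ]
    o1 <- origins[i, ]; o2 <- origins[j, ]
    bb <- sum(d1 * d2)
    den <- 1 - bb^2
    if (den < 1e-12) next
    w <- o1 - o2
    t1 <- (bb * sum(d2 * w) - sum(d1 * w)) / den
    t2 <- (sum(d2 * w) - bb * sum(d1 * w)) / den
    h <- (o1 + t1 * d1 + o2 + t2 * d2) / 2
    dist <- vapply(seq_len(n), function(k)
      oracle_point_ray_dist(h, origins[k, ], dirs[k, ]), numeric(1))
    inl <- dist <= tol
    if (sum(inl) < 2) next
    rms <- sqrt(mean(dist[inl]^2))
    if (is.null(best) || sum(inl) > sum(best$inl) ||
        (sum(inl) == sum(best$inl) && rms < best$rms))
      best <- list(inl = inl, rms = rms)
  }
  if (is.null(best)) return(NULL)
  list(point = oracle_triangulate(origins[best$inl, , drop = FALSE],
                                  dirs[best$inl, , drop = FALSE]),
       inliers = best$inl)
}

# --- smoothing ----------------------------------------------------------

# fixed-interval RTS smoother for the same per-axis constant-velocity model
# (dt = 1 frame, CWNA process noise), forward filter + backward recursion
oracle_rts <- function(y, valid, q, r) {
  A <- matrix(c(1, 0, 1, 1), 2, 2)
  Q <- q * matrix(c(1 / 3, 1 / 2, 1 / 2, 1), 2, 2)
  H <- matrix(c(1, 0), 1, 2)
  n <- length(y)
  xp <- matrix(0, n, 2); Pp <- array(0, c(2, 2, n))
  xf <- matrix(0, n, 2); Pf <- array(0, c(2, 2, n))
  x <- c(y[1], 0); P <- diag(c(r, 1e6))
  xp[1, ] <- x; Pp[, , 1] <- P; xf[1, ] <- x; Pf[, , 1] <- P
  for (k in seq_len(n)[-1]) {
    x <- A %*% x; P <- A %*% P %*% t(A) + Q
    xp[k, ] <- x; Pp[, , k] <- P
    if (valid[k]) {
      S <- as.numeric(H %*% P %*% t(H)) + r
      K <- P %*% t(H) / S
      x <- x + K %*% (y[k] - H %*% x)
      P <- (diag(2) - K %*% H) %*% P
    }
    xf[k, ] <- x; Pf[, , k] <- P
  }
  xs <- xf
  for (k in (n - 1):1) {
    G <- Pf[, , k] %*% t(A) %*% solve(Pp[, , k + 1])
    xs[k, ] <- xf[k, ] + as.numeric(G %*% (xs[k + 1, ] - xp[k + 1, ]))
  }
  xs[, 1]
}

# --- statistics ---------------------------------------------------------

# percentile by explicit linear interpolation between order statistics
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# --- builders -----------------------------------------------------------

# rays through a point from random origins, with optional direction jitter
rays_through <- function(point, n, jitter_rad = 0) {
  lapply(seq_len(n), function(i) {
    o <- stats::runif(3, -4000, 4000)
    d <- point - o
    if (jitter_rad > 0) d <- d + stats::rnorm(3, 0, jitter_rad * sqrt(sum(d^2)))
    ray(o, d)
  })
}

rays_to_mats <- function(rays) {
  list(o = do.call(rbind, lapply(rays, `[[`, "origin")),
       d = do.call(rbind, lapply(rays, `[[`, "direction")))
}

const_traj <- function(p, n, joint = "j", rate = 200, valid = NULL)
  trajectory3d(matrix(rep(p, each = n), n, 3), valid = valid, joint = joint,
               rate = rate)

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
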