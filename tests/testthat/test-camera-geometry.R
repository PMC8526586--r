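test_that("projection follows the pinhole + radial distortion model", {
  cam <- camera_model(1000, 1000, 960, 600, width = 1920, height = 1200)
  expect_equal(project_point(cam, c(0, 0, 2000)), c(960, 600))
  expect_equal(project_point(cam, c(200, 0, 2000)), c(1060, 600))

  camd <- camera_model(1000, 1000, 960, 600, k1 = 0.1,
                       width = 1920, height = 1200)
  # direct evaluation of x (1 + k1 r^2): xn = 0.1, r^2 = 0.01 -> 1060.1 px
  expect_equal(project_point(camd, c(200, 0, 2000)), c(1060.1, 600))
  expect_equal(project_point(camd, c(200, 0, 2000)),
               oracle_project(camd, c(200, 0, 2000)))

  expect_error(project_point(cam, c(0, 0, -100)), "behind camera")
  expect_error(camera_model(-1, 1000, 0, 0), "positive")
  expect_error(camera_model(1000, 1000, 0, 0, R = diag(3) * 2), "orthonormal")
})

test_that("back-projection inverts projection, with and without distortion", {
  cam <- camera_model(1000, 1000, 960, 600, width = 1920, height = 1200)
  r0 <- backproject(cam, c(960, 600))
  expect_equal(r0$origin, c(0, 0, 0))
  expect_equal(r0$direction, c(0, 0, 1))

  P <- c(123, -45, 1800)
  expect_lt(point_ray_distance(backproject(cam, project_point(cam, P)), P),
            1e-6)

  # property: 1000 random points, |k1| <= 0.1, round-trip < 1e-3 mm
  set.seed(41)
  for (k1 in c(-0.1, 0, 0.07)) {
    camk <- camera_model(1500, 1500, 1280, 1024, k1 = k1, k2 = 0.01,
                         R = random_rotation(), t = c(100, -50, 4000))
    pts <- cbind(runif(250, -800, 800), runif(250, -800, 800),
                 runif(250, -800, 800))
    for (i in seq_len(nrow(pts))) {
      px <- tryCatch(project_point(camk, pts[i, ]), error = function(e) NULL)
      if (is.null(px)) next
      expect_lt(point_ray_distance(
        suppressWarnings(backproject(camk, px)), pts[i, ]), 1e-3)
    }
  }
})

test_that("triangulation solves the least-squares ray intersection", {
  rA <- ray(c(0, 0, 0), c(1, 1, 0))
  rB <- ray(c(2000, 0, 0), c(-1, 1, 0))
  f <- triangulate(list(rA, rB))
  expect_equal(f$point, c(1000, 1000, 0))
  expect_equal(f$distances, c(0, 0))

  set.seed(7)
  exact <- rays_through(c(500, 500, 1000), 5)
  fe <- triangulate(exact)
  expect_equal(fe$point, c(500, 500, 1000), tolerance = 1e-9)
  expect_true(all(fe$distances < 1e-9))

  # perturbed skew rays match the independent qr-based normal-equations
  # oracle to 1e-9 mm, up to 10 rays
  for (rep_i in 1:20) {
    n <- sample(3:10, 1)
    rays <- rays_through(runif(3, -500, 500), n, jitter_rad = 2e-3)
    s <- rays_to_mats(rays)
    expect_equal(triangulate(rays)$point, oracle_triangulate(s$o, s$d),
                 tolerance = 1e-9)
  }

  expect_error(triangulate(list(rA)), "2 rays")
  par1 <- ray(c(0, 0, 0), c(0, 0, 1)); par2 <- ray(c(1, 0, 0), c(0, 0, 1))
  expect_error(triangulate(list(par1, par2)), "degenerate")
})

test_that("RANSAC keeps the consensus rays and refits on the inliers", {
  set.seed(11)
  P <- c(1000, 2000, 1000)
  rays <- c(rays_through(P, 8), rays_through(c(1000, 2000, 1500), 2))
  f <- ransac_intersect(rays, inlier_tol_mm = 10)
  expect_false(f$failed)
  expect_equal(which(f$inliers), 1:8)
  expect_lt(sqrt(sum((f$point - P)^2)), 1e-6)

  # all rays consistent -> identical to plain triangulation
  all_in <- rays_through(c(-500, 300, 800), 9)
  expect_identical(ransac_intersect(all_in, 20)$point,
                   triangulate(all_in)$point)

  expect_true(ransac_intersect(all_in[1], 20)$failed)
  expect_error(ransac_intersect(all_in, inlier_tol_mm = 0), "positive")
})

test_that("RANSAC equals the exhaustive two-ray-hypothesis oracle", {
  set.seed(23)
  for (case in 1:100) {
    n <- sample(4:10, 1)
    n_out <- sample(0:max(0, n - 3), 1)
    P <- runif(3, -1500, 1500)
    Pout <- P + runif(3, 300, 900) * sample(c(-1, 1), 3, replace = TRUE)
    rays <- c(rays_through(P, n - n_out, jitter_rad = 5e-4),
              if (n_out > 0) rays_through(Pout, n_out))
    s <- rays_to_mats(rays)
    got <- ransac_intersect(rays, inlier_tol_mm = 20)
    ref <- oracle_ransac(s$o, s$d, tol = 20)
    expect_identical(got$inliers, ref$inliers)
    expect_lt(max(abs(got$point - ref$point)), 1e-6)
  }
})

test_that("rigid alignment recovers exact and noisy transforms", {
  set.seed(3)
  src <- matrix(runif(30, -1000, 1000), 10, 3)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tgt <- sweep(src %*% t(R), 2, c(100, 0, 0), "+")
  tf <- estimate_rigid_transform(src, tgt)
  expect_equal(tf$rotation, R, tolerance = 1e-9)
  expect_equal(tf$translation, c(100, 0, 0), tolerance = 1e-9)
  expect_lt(tf$rms, 1e-9)

  # noiseless recovery of arbitrary proper rotations; rms invariant to order
  for (i in 1:10) {
    Rr <- random_rotation(); tr <- runif(3, -500, 500)
    tgt2 <- sweep(src %*% t(Rr), 2, tr, "+")
    tf2 <- estimate_rigid_transform(src, tgt2)
    expect_equal(tf2$rotation, Rr, tolerance = 1e-9)
    perm <- sample(nrow(src))
    expect_equal(estimate_rigid_transform(src[perm, ], tgt2[perm, ])$rms,
                 tf2$rms, tolerance = 1e-9)
  }

  # Monte-Carlo residual: sigma = 2 mm isotropic noise on 500 points
  src5 <- matrix(runif(1500, -1000, 1000), 500, 3)
  tgt5 <- sweep(src5 %*% t(R), 2, c(100, 0, 0), "+") +
    matrix(rnorm(1500, 0, 2), 500, 3)
  rms5 <- estimate_rigid_transform(src5, tgt5)$rms
  expect_gt(rms5, 1.8); expect_lt(rms5, 2.2)

  col <- cbind(1:3, 2 * (1:3), 3 * (1:3))
  expect_error(estimate_rigid_transform(col, col), "collinear|degenerate")
})

test_that("wand accuracy reports the endpoint-distance error", {
  n <- 200
  a <- const_traj(c(0, 0, 1000), n)
  b <- const_traj(c(500, 0, 1000), n)
  expect_equal(wand_accuracy(a, b, 500),
               list(mean_error_mm = 0, sd_error_mm = 0, n = n))
  b2 <- const_traj(c(502, 0, 1000), n)
  w2 <- wand_accuracy(a, b2, 500)
  expect_equal(w2$mean_error_mm, 2)
  expect_equal(w2$sd_error_mm, 0)

  # noisy endpoints vs a direct simulation oracle of the same process
  set.seed(19)
  sim <- replicate(20000, {
    pa <- rnorm(3, 0, 1); pb <- c(500, 0, 0) + rnorm(3, 0, 1)
    sqrt(sum((pa - pb)^2)) - 500
  })
  na <- 5000
  A <- trajectory3d(matrix(rnorm(3 * na, 0, 1), na, 3), joint = "a")
  B <- trajectory3d(matrix(rep(c(500, 0, 0), each = na), na, 3) +
                      matrix(rnorm(3 * na, 0, 1), na, 3), joint = "b")
  w3 <- wand_accuracy(A, B, 500)
  expect_lt(abs(w3$mean_error_mm - mean(sim)), 4 * sd(sim) / sqrt(na))
  expect_lt(abs(w3$sd_error_mm - sd(sim)), 0.1)

  av <- trajectory3d(matrix(0, 5, 3), valid = rep(FALSE, 5), joint = "a")
  expect_error(wand_accuracy(av, av, 500), "no frames")
})

test_that("calibration files round-trip through YAML and JSON", {
  rig <- make_camera_rig(n = 3)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("rig.", ext))
    write_calibration(rig, path)
    back <- read_calibration(path)
    expect_equal(length(back), 3)
    expect_equal(back[[2]]$R, rig[[2]]$R, tolerance = 1e-12)
    expect_equal(back[[2]]$t, rig[[2]]$t, tolerance = 1e-12)
    p <- c(300, -200, 1200)
    expect_equal(project_point(back[[1]], p), project_point(rig[[1]], p),
                 tolerance = 1e-9)
  }
})
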