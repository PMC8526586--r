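# shared small fixtures (built once; everything below is deterministic)
fixture_rig <- make_camera_rig()

mk_standing_person <- function(x0, y0, n = 40, vx = 0) {
  t <- seq_len(n) - 1
  list(hip_l = trajectory3d(cbind(x0 + vx * t, y0 + 95, 950), joint = "hip_l"),
       hip_r = trajectory3d(cbind(x0 + vx * t, y0 - 95, 950), joint = "hip_r"),
       head = trajectory3d(cbind(x0 + vx * t, y0 + 0 * t, 1650),
                           joint = "head"))
}

test_that("OpenPose-style JSON files round-trip people and missing keypoints", {
  scheme <- keypoint_scheme("body25")
  dir <- file.path(tempdir(), "op_json")
  det <- data.frame(camera = 1L, frame = rep(1:2, each = 25), person = 1L,
                    joint = rep(scheme$names, 2),
                    x = runif(50, 0, 2000), y = runif(50, 0, 1500),
                    confidence = 0.9)
  det$confidence[det$joint == "nose"] <- 0   # missing keypoint
  det$x[det$joint == "nose"] <- 0; det$y[det$joint == "nose"] <- 0
  write_openpose_json(det, scheme, dir, n_frames = 3)   # frame 3 empty
  back <- read_openpose_json(dir, scheme)
  expect_equal(nrow(back), 50)
  expect_equal(sum(back$frame == 3), 0)
  expect_equal(sum(back$confidence == 0), 2)
  b1 <- back[back$frame == 1, ]
  d1 <- det[det$frame == 1, ]
  expect_equal(b1$x[match(scheme$names, b1$joint)],
               d1$x[match(scheme$names, d1$joint)])

  # malformed: wrong keypoint count
  bad <- file.path(tempdir(), "bad.json")
  jsonlite::write_json(
    list(people = list(list(pose_keypoints_2d = rep(0.5, 74)))),
    bad, auto_unbox = TRUE)
  expect_error(read_openpose_json(bad, scheme), "length 74")
  writeLines("{not json", bad)
  expect_error(read_openpose_json(bad, scheme), "malformed")
})

test_that("keypoint schemes enforce unique names and known presets", {
  expect_equal(keypoint_scheme("body25")$count, 25)
  expect_equal(keypoint_scheme("body18")$count, 18)
  expect_equal(keypoint_scheme("body15")$count, 15)
  expect_equal(keypoint_scheme(c("a", "b"))$count, 2)
  expect_error(keypoint_scheme(c("a", "a")), "unique")
})

test_that("occupancy map localises people and ignores empty frames", {
  p1 <- mk_standing_person(1000, 1000, n = 2)
  rd <- render_detections(p1, fixture_rig, sigma_px = 0, seed = 10)
  om <- build_occupancy_map(rd$detections[rd$detections$frame == 1, ],
                            fixture_rig)
  expect_true(all(om$counts >= 0))
  expect_lte(sum(om$counts), sum(rd$detections$frame == 1 &
                                   rd$detections$confidence > 0))
  pk <- find_occupancy_peaks(om)
  expect_equal(nrow(pk), 1)
  expect_lt(max(abs(c(pk$x - 1000, pk$y - 1000))), om$grid$cell)

  empty <- build_occupancy_map(rd$detections[0, ], fixture_rig)
  expect_true(all(empty$counts == 0))
  expect_equal(nrow(find_occupancy_peaks(empty)), 0)

  # two people 2 m apart give two distinct peaks
  p2 <- mk_standing_person(-1000, 1000, n = 2)
  rd2 <- render_detections(p1, fixture_rig, sigma_px = 1,
                           extra_people = list(p2), seed = 11)
  pk2 <- find_occupancy_peaks(
    build_occupancy_map(rd2$detections[rd2$detections$frame == 1, ],
                        fixture_rig))
  expect_equal(nrow(pk2), 2)
  xs <- sort(pk2$x)
  expect_lt(abs(xs[1] + 1000), 150); expect_lt(abs(xs[2] - 1000), 150)
})

test_that("people association tracks without identity swaps", {
  n <- 40
  p1 <- mk_standing_person(500, 0, n = n)
  rd <- render_detections(p1, fixture_rig, sigma_px = 1, seed = 12)
  pks <- lapply(seq_len(n), function(f)
    find_occupancy_peaks(build_occupancy_map(
      rd$detections[rd$detections$frame == f, ], fixture_rig)))
  tr <- associate_people(pks)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(nrow(tr), n)

  # two people walking parallel 2 m apart: two tracks, no swaps
  pa <- mk_standing_person(-800, 1000, n = n, vx = 7)
  pb <- mk_standing_person(-800, -1000, n = n, vx = 7)
  rda <- render_detections(pa, fixture_rig, sigma_px = 1,
                           extra_people = list(pb), seed = 13)
  pks2 <- lapply(seq_len(n), function(f)
    find_occupancy_peaks(build_occupancy_map(
      rda$detections[rda$detections$frame == f, ], fixture_rig)))
  tr2 <- associate_people(pks2)
  expect_equal(length(unique(tr2$track)), 2)
  for (id in unique(tr2$track)) {
    g <- tr2[tr2$track == id, ]
    expect_equal(nrow(g), n)
    expect_lt(diff(range(g$y)), 500)    # stayed on its own side
  }
  # subject = track nearer the centre line when lengths tie is either; both
  # full-length tracks qualify
  st <- subject_track(tr2)
  expect_equal(nrow(st), n)

  # person leaving the volume: track terminates, no spurious continuation
  pc <- mk_standing_person(1500, 0, n = 60, vx = 50)
  rdc <- render_detections(pc, fixture_rig, sigma_px = 1, seed = 14)
  pks3 <- lapply(1:60, function(f)
    find_occupancy_peaks(build_occupancy_map(
      rdc$detections[rdc$detections$frame == f, ], fixture_rig)))
  tr3 <- associate_people(pks3)
  expect_lt(max(tr3$frame), 45)
  expect_equal(length(unique(tr3$track)), 1)
})

test_that("noiseless scenes reconstruct to better than a micron", {
  g <- simulate_gait("walk")
  rd <- render_detections(g$trajectories, fixture_rig, sigma_px = 0,
                          seed = 15)
  rec <- reconstruct_sequence(rd$detections, fixture_rig,
                              joints = c("hip_r", "ankle_l"),
                              n_frames = g$n_frames)
  for (jn in names(rec)) {
    ok <- rec[[jn]]$valid
    expect_gt(mean(ok), 0.99)
    err <- row_norms(rec[[jn]]$positions[ok, ] -
                       g$trajectories[[jn]]$positions[ok, ])
    expect_lt(max(err), 1e-3)
  }
})

test_that("reconstruction error grows monotonically with pixel noise", {
  g <- simulate_gait("walk")
  sub <- 1:150
  meds <- vapply(c(0, 1, 2, 4), function(sig) {
    rd <- render_detections(g$trajectories, fixture_rig, sigma_px = sig,
                            seed = 16)
    det <- rd$detections[rd$detections$frame %in% sub, ]
    rec <- reconstruct_sequence(det, fixture_rig, joints = "hip_r",
                                n_frames = max(sub))
    ok <- rec$hip_r$valid
    truth <- g$trajectories$hip_r$positions[sub, , drop = FALSE]
    stats::median(row_norms(rec$hip_r$positions[ok, ] - truth[ok, ]))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("RANSAC absorbs outlier detections that break plain triangulation", {
  g <- simulate_gait("walk")
  sub <- 1:200
  err_for <- function(outlier_rate, use_ransac) {
    rd <- render_detections(g$trajectories, fixture_rig, sigma_px = 2,
                            outlier_rate = outlier_rate, seed = 17)
    det <- rd$detections[rd$detections$frame %in% sub, ]
    rec <- reconstruct_sequence(det, fixture_rig, joints = "hip_r",
                                n_frames = max(sub), conf_min = 0,
                                use_ransac = use_ransac)
    ok <- rec$hip_r$valid
    truth <- g$trajectories$hip_r$positions[sub, , drop = FALSE]
    row_norms(rec$hip_r$positions[ok, ] - truth[ok, ])
  }
  base <- stats::median(err_for(0, TRUE))
  with_ransac <- err_for(0.2, TRUE)
  without <- err_for(0.2, FALSE)
  expect_lt(stats::median(with_ransac), 1.25 * base)
  expect_gt(stats::median(without), 2 * base)
  # masked-or-accurate: nearly all surviving frames near the noise floor
  expect_gt(mean(with_ransac < 3 * base), 0.95)
})

test_that("bi-directional smoother equals an RTS oracle and respects gaps", {
  set.seed(18)
  # 50 seeded gap-free trajectories, equality to 1e-9
  for (i in 1:50) {
    n <- sample(80:200, 1)
    pos <- apply(matrix(rnorm(3 * n, 0, 3), n, 3), 2, cumsum)
    tr <- trajectory3d(pos, joint = "j")
    q <- runif(1, 0.1, 5); r <- runif(1, 1, 50)
    sm <- bidirectional_kalman(tr, q, r)
    for (a in 1:3)
      expect_lt(max(abs(sm$positions[, a] -
                          oracle_rts(pos[, a], rep(TRUE, n), q, r))), 1e-9)
  }

  # noisy constant position: variance shrinks
  y <- 500 + rnorm(200, 0, 5)
  tr <- trajectory3d(cbind(y, y, y), joint = "j")
  sm <- bidirectional_kalman(tr, q = 0.1, r = 25)
  expect_lt(var(sm$positions[, 1]), var(y))

  # r/q -> 0: smoother converges to the measurements
  sm0 <- bidirectional_kalman(tr, q = 1, r = 1e-8)
  expect_lt(max(abs(sm0$positions[, 1] - y)), 1e-4)

  # 10-frame gap in straight-line motion is bridged near the oracle's
  # prediction through the gap
  lin <- seq(0, 1990, by = 10)
  v <- rep(TRUE, 200); v[100:109] <- FALSE
  trg <- trajectory3d(cbind(lin, 0 * lin, 0 * lin), valid = v, joint = "j")
  smg <- bidirectional_kalman(trg, q = 1, r = 25)
  expect_true(all(smg$valid[100:109]))
  orc <- oracle_rts(lin, v, 1, 25)
  expect_lt(max(abs(smg$positions[100:109, 1] - orc[100:109])), 1e-9)
  expect_lt(max(abs(smg$positions[100:109, 1] - lin[100:109])), 5)

  # gaps beyond the bridge policy and lead/tail gaps stay masked
  v2 <- rep(TRUE, 200); v2[50:120] <- FALSE; v2[1:5] <- FALSE
  trl <- trajectory3d(cbind(lin, lin, lin), valid = v2, joint = "j")
  sml <- bidirectional_kalman(trl, q = 1, r = 25)
  expect_false(any(sml$valid[50:120]))
  expect_false(any(sml$valid[1:5]))

  # fully masked input returned unchanged
  trm <- trajectory3d(matrix(NA_real_, 20, 3), valid = rep(FALSE, 20),
                      joint = "j")
  expect_identical(bidirectional_kalman(trm), trm)
})

test_that("trajectory CSV round-trips positions and masks losslessly", {
  set.seed(20)
  v <- rep(TRUE, 50); v[10:12] <- FALSE
  trajs <- list(
    hip_r = trajectory3d(matrix(rnorm(150, 0, 500), 50, 3), valid = v,
                         joint = "hip_r"),
    ankle_r = trajectory3d(matrix(rnorm(150, 0, 500), 50, 3),
                           joint = "ankle_r"))
  path <- file.path(tempdir(), "trajs.csv")
  write_trajectories_csv(trajs, path)
  back <- read_trajectories_csv(path)
  expect_equal(names(back), names(trajs))
  expect_identical(back$hip_r$valid, v)
  expect_equal(back$hip_r$positions, trajs$hip_r$positions)
  expect_equal(back$ankle_r$positions, trajs$ankle_r$positions)
  expect_equal(back$hip_r$rate, 200)

  expect_error(write_trajectories_csv(list(), path), "empty")
})
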