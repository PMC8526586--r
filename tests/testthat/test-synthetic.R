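test_that("the default ring rig covers the capture volume", {
  rig <- make_camera_rig()
  expect_length(rig, 9)
  vol <- list(x = c(-2000, 2000), y = c(-2000, 2000), z = c(0, 2000))
  vis <- rig_corner_visibility(rig, vol)
  expect_true(all(vis >= 6))
  # symmetric ring: mean camera position sits over the volume centre in X-Y
  centres <- t(vapply(rig, camera_centre, numeric(3)))
  expect_lt(max(abs(colMeans(centres)[1:2])), 1e-6)
  expect_error(make_camera_rig(n = 1), "at least 2")
})

test_that("gait kinematics are periodic with the configured stride", {
  g <- simulate_gait("walk")
  # autocorrelation oracle on a long trial: the ankle height cycles once per
  # stride, so the first off-zero acf peak sits at the stride lag (+/- 1)
  glong <- simulate_gait("walk", n_cycles = 20)
  z <- glong$trajectories$ankle_l$positions[, 3]
  lag <- round(glong$stride_time_s * glong$rate)
  ac <- stats::acf(z, lag.max = lag + 20, plot = FALSE)$acf
  expect_lte(abs(which.max(ac[-(1:(lag %/% 2))]) + lag %/% 2 - 1 - lag), 1)
  # left and right contact flags are anti-phased in walking
  ph_shift <- round(g$stride_time_s * g$rate / 2)
  n <- g$n_frames
  agree <- mean(g$contact$left[1:(n - ph_shift)] ==
                  g$contact$right[(ph_shift + 1):n])
  expect_gt(agree, 0.95)
  # defaults: 4 walking / 6 running step cycles per trial
  expect_equal(length(g$events$left$td) + length(g$events$right$td) - 2, 4)
  r <- simulate_gait("run")
  expect_equal(length(r$events$left$td) + length(r$events$right$td) - 2, 6)
  both_off <- !(r$contact$left | r$contact$right)
  expect_gt(sum(both_off), 0)     # flight phases exist in running
})

test_that("jump force traces obey impulse-momentum and the event rules", {
  j <- simulate_jump(jump_height_m = 0.3, seed = 71)
  # flight time consistent with the requested apex height
  expect_equal(j$flight_time_s, 2 * sqrt(2 * 0.3 / 9.81), tolerance = 1e-12)
  # flight force identically zero
  fl <- (j$events$takeoff):(j$events$landing - 1)
  expect_true(all(j$force[fl] == 0))
  # unweighting run below bodyweight lasts at least 20 frames
  below <- rle(j$force < j$bodyweight_n)
  expect_gte(max(below$lengths[below$values]), 20)
  # CoM rise during flight matches the ballistic apex
  com <- j$trajectories$hip_l$positions[, 3] -
    j$trajectories$hip_l$positions[1, 3]
  expect_equal(max(com[fl]), 300, tolerance = 15)
  # the detector recovers the analytic events exactly
  ev <- detect_jump_events(j$force)
  expect_equal(ev$first_movement, j$events$first_movement)
  expect_equal(ev$stabilisation, j$events$stabilisation)
})

test_that("rendered detections match projections and corruption rates", {
  rig <- make_camera_rig()
  g <- simulate_gait("walk")
  sub <- lapply(g$trajectories["hip_r"], function(tr)
    trajectory3d(tr$positions[1:100, ], joint = tr$joint))
  clean <- render_detections(sub, rig, sigma_px = 0, seed = 72)
  d1 <- clean$detections[clean$detections$confidence > 0, ]
  i <- 57
  cam <- rig[[d1$camera[i]]]
  expect_equal(c(d1$x[i], d1$y[i]),
               as.numeric(project_point(cam, sub$hip_r$positions[d1$frame[i], ])),
               tolerance = 1e-9)
  expect_equal(nrow(clean$log), 0)

  # empirical corruption frequencies agree with the parameters (binomial CI)
  rates <- render_detections(sub, rig, sigma_px = 1, outlier_rate = 0.1,
                             miss_rate = 0.1, seed = 73)
  n_vis <- sum(rates$detections$confidence > 0) + sum(rates$log$type == "miss")
  p_out <- sum(rates$log$type == "outlier_uniform") / n_vis
  p_miss <- sum(rates$log$type == "miss") / n_vis
  ci <- 3 * sqrt(0.1 * 0.9 / n_vis)
  expect_lt(abs(p_out - 0.1), ci)
  expect_lt(abs(p_miss - 0.1), ci)
  # corrupted detections carry low confidence, clean ones high
  out_rows <- merge(rates$detections,
                    rates$log[rates$log$type == "outlier_uniform", ])
  expect_true(all(out_rows$confidence <= 0.6 & out_rows$confidence >= 0.1))

  # background-person outliers sit at the second person's projected joints
  bg <- lapply(sub, function(tr)
    trajectory3d(sweep(tr$positions, 2, c(0, 1500, 0), "+"),
                 joint = tr$joint))
  rb <- render_detections(sub, rig, sigma_px = 0, outlier_rate = 0.3,
                          outlier_mode = "background", extra_people = list(bg),
                          seed = 74)
  lg <- rb$log[rb$log$type == "outlier_background", ][1, ]
  row <- rb$detections[rb$detections$camera == lg$camera &
                         rb$detections$frame == lg$frame &
                         rb$detections$joint == lg$joint &
                         rb$detections$person == 1, ]
  expect_equal(c(row$x, row$y),
               as.numeric(project_point(rig[[lg$camera]],
                                        bg$hip_r$positions[lg$frame, ])),
               tolerance = 1e-9)
  expect_error(render_detections(sub, rig, outlier_rate = 0.1,
                                 outlier_mode = "background"), "extra_people")
})

test_that("marker references embed exactly the logged systematic offsets", {
  g <- simulate_gait("walk")
  # zero offsets and noise: reference equals ground truth
  r0 <- make_marker_reference(g$trajectories)
  expect_equal(r0$reference$knee_l$positions, g$trajectories$knee_l$positions)
  # soft-tissue noise is band-limited below ~6 Hz
  rn <- make_marker_reference(g$trajectories, soft_tissue_sd_mm = 3,
                              seed = 75)
  noise <- rn$reference$knee_l$positions[, 1] -
    g$trajectories$knee_l$positions[, 1]
  expect_equal(sd(noise), 3, tolerance = 0.2)
  sp <- stats::spec.pgram(noise, plot = FALSE, taper = 0.1)
  f_hz <- sp$freq * 200
  expect_gt(sum(sp$spec[f_hz < 6]) / sum(sp$spec), 0.95)
})

test_that("wand and alignment trials recover their construction exactly", {
  w <- simulate_wand_trial()
  expect_equal(unlist(wand_accuracy(w$a, w$b, w$length_mm)[1:2]),
               c(mean_error_mm = 0, sd_error_mm = 0), tolerance = 1e-9)

  al <- simulate_alignment_trial(seed = 76)
  ok <- al$points_b$valid
  tf <- estimate_rigid_transform(al$points_a$positions[which(ok) - al$frame_offset, ],
                                 al$points_b$positions[ok, ])
  expect_equal(tf$rotation, al$transform$rotation, tolerance = 1e-9)
  expect_equal(tf$translation, al$transform$translation, tolerance = 1e-6)
  expect_lt(tf$rms, 1e-6)
  expect_identical(estimate_frame_offset(al$flash_a, al$flash_b),
                   al$frame_offset)
  # negative offsets recovered too
  aln <- simulate_alignment_trial(frame_offset = -5L, seed = 77)
  expect_identical(estimate_frame_offset(aln$flash_a, aln$flash_b), -5L)
})

test_that("scenes regenerate bit-identically under a fixed seed", {
  s1 <- simulate_scene("walk", seed = 123, sigma_px = 2, outlier_rate = 0.05,
                       miss_rate = 0.05,
                       marker_offsets_mm = list(hip_r = c(0, 0, 30)),
                       soft_tissue_sd_mm = 2)
  s2 <- simulate_scene("walk", seed = 123, sigma_px = 2, outlier_rate = 0.05,
                       miss_rate = 0.05,
                       marker_offsets_mm = list(hip_r = c(0, 0, 30)),
                       soft_tissue_sd_mm = 2)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$reference$hip_r$positions, s2$reference$hip_r$positions)
  expect_identical(s1$corruption_log, s2$corruption_log)
  expect_equal(s1$answer_key$offsets_mm$hip_r, c(0, 0, 30))
  # a different seed changes the realisation
  s3 <- simulate_scene("walk", seed = 124, sigma_px = 2, outlier_rate = 0.05,
                       miss_rate = 0.05)
  expect_false(identical(s1$detections, s3$detections))
})
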