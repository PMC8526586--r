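#' Build a ring camera rig around a capture volume
#'
#' Places `n` calibrated cameras on a ring, at alternating heights, all
#' oriented at the volume centre — the layout of a multi-camera motion
#' capture laboratory with a floor-centred, Z-up right-handed world frame.
#'
#' @param n Number of cameras (default 9; must be >= 2).
#' @param radius_mm Ring radius (default 6000).
#' @param heights_mm Camera heights, recycled around the ring
#'   (default `c(1700, 2400, 2000)`).
#' @param volume List `x`, `y`, `z` of axis ranges (mm) of the capture
#'   volume (default 4 x 4 x 2 m over the floor).
#' @param fx,fy,cx,cy,k1,k2,width,height Shared intrinsics.
#' @return List of `camera_model` objects.
#' @export
make_camera_rig <- function(n = 9, radius_mm = 6000,
                            heights_mm = c(1700, 2400, 2000),
                            volume = list(x = c(-2000, 2000),
                                          y = c(-2000, 2000),
                                          z = c(0, 2000)),
                            fx = 1500, fy = 1500, cx = 1280, cy = 1024,
                            k1 = -0.05, k2 = 0, width = 2560, height = 2048) {
  if (n < 2) stop("make_camera_rig: need at least 2 cameras")
  centre <- vapply(volume, mean, numeric(1))
  angles <- 2 * pi * (seq_len(n) - 1) / n
  lapply(seq_len(n), function(i) {
    pos <- c(radius_mm * cos(angles[i]), radius_mm * sin(angles[i]),
             heights_mm[(i - 1) %% length(heights_mm) + 1])
    fwd <- centre - pos
    fwd <- fwd / sqrt(sum(fwd^2))
    right <- cross3(fwd, c(0, 0, 1))
    right <- right / sqrt(sum(right^2))
    down <- cross3(fwd, right)
    R <- rbind(right, down, fwd)
    dimnames(R) <- NULL
    camera_model(fx, fy, cx, cy, k1, k2, R = R,
                 t = as.numeric(-R %*% pos), width = width, height = height,
                 name = sprintf("cam%02d", i))
  })
}

#' Count cameras that see each corner of a volume
#' @param cameras List of `camera_model`.
#' @param volume Volume as in [make_camera_rig()].
#' @return Integer vector, one count per corner (8 corners).
#' @export
rig_corner_visibility <- function(cameras, volume) {
  corners <- as.matrix(expand.grid(volume$x, volume$y, volume$z))
  apply(corners, 1, function(p) {
    sum(vapply(cameras, function(cam) {
      px <- tryCatch(project_point(cam, p), error = function(e) NULL)
      !is.null(px) && px[1] >= 0 && px[1] <= cam$width &&
        px[2] >= 0 && px[2] <= cam$height
    }, logical(1)))
  })
}

# project points, returning NA rows for points behind the camera or outside
# the image
project_visible <- function(cam, pts) {
  pc <- pts %*% t(cam$R) + matrix(cam$t, nrow(pts), 3, byrow = TRUE)
  ok <- pc[, 3] > 0
  out <- matrix(NA_real_, nrow(pts), 2)
  if (any(ok)) out[ok, ] <- project_point(cam, pts[ok, , drop = FALSE])
  inb <- ok & !is.na(out[, 1]) &
    out[, 1] >= 0 & out[, 1] <= cam$width &
    out[, 2] >= 0 & out[, 2] <= cam$height
  out[!inb, ] <- NA_real_
  out
}

#' Simulate walking or running kinematics
#'
#' A stylised parametric kinematic chain: the pelvis translates through the
#' volume while limb joints oscillate with anti-phased left/right stride
#' phases; running uses a shorter stride with a lower duty factor so flight
#' phases occur. Contact flags are analytic functions of the stride phase
#' and are the ground truth for gait events. Defaults give 4 complete
#' TD-to-TD step cycles per walking trial and 6 per running trial (both
#' sides pooled), within the camera ring's field of view.
#'
#' @param activity `"walk"` or `"run"`.
#' @param speed_mm_s Progression speed (defaults: walk 1300, run 2200).
#' @param stride_time_s Stride (TD to same-side TD) duration (defaults:
#'   walk 1.15, run 0.65).
#' @param n_cycles Complete step cycles per trial, both sides pooled
#'   (defaults: walk 4, run 6).
#' @param rate Sample rate, Hz (default 200).
#' @param subject_scale Multiplies all segment heights/offsets (default 1).
#' @return List: `trajectories` (named `trajectory3d` list), `contact`
#'   (per-side logical vectors), `events` (analytic per-side TD/TO frames),
#'   `stride_time_s`, `duty`, `n_frames`.
#' @export
simulate_gait <- function(activity = c("walk", "run"), speed_mm_s = NULL,
                          stride_time_s = NULL, n_cycles = NULL, rate = 200,
                          subject_scale = 1) {
  activity <- match.arg(activity)
  p <- switch(activity,
              walk = list(speed = 1300, stride = 1.15, cycles = 4, duty = 0.62,
                          lift = 120),
              run = list(speed = 2200, stride = 0.65, cycles = 6, duty = 0.35,
                         lift = 220))
  speed <- if (is.null(speed_mm_s)) p$speed else speed_mm_s
  stride <- if (is.null(stride_time_s)) p$stride else stride_time_s
  cycles <- if (is.null(n_cycles)) p$cycles else n_cycles
  duty <- p$duty
  s <- subject_scale

  start_phase <- 0.8    # trial opens mid left swing, so no mid-stance edge
  dur <- (cycles / 2 + 0.95) * stride
  n <- ceiling(dur * rate)
  t <- (seq_len(n) - 1) / rate
  x0 <- -speed * dur / 2

  pelvis_x <- x0 + speed * t + 15 * s * sin(4 * pi * t / stride)
  pelvis_y <- 30 * s * sin(2 * pi * t / stride)
  pelvis_z <- 920 * s + 25 * s * sin(4 * pi * t / stride + pi / 2)

  phase <- function(off) (t / stride + start_phase + off) %% 1
  swing_bump <- function(ph) {
    sw <- pmax(0, (ph - duty) / (1 - duty))
    sin(pi * sw)^2 * (ph > duty)
  }
  side <- function(off, lat_sign) {
    ph <- phase(off)
    step_len <- speed * stride / 2
    ankle <- cbind(pelvis_x - step_len * cos(2 * pi * ph) / 2,
                   pelvis_y + lat_sign * 110 * s,
                   90 * s + p$lift * s * swing_bump(ph))
    hip <- cbind(pelvis_x, pelvis_y + lat_sign * 95 * s, pelvis_z)
    knee <- (hip + ankle) / 2 +
      cbind(60 * s * sin(2 * pi * ph + pi / 3), 0, 20 * s * swing_bump(ph))
    shoulder <- cbind(pelvis_x + 60 * s * sin(2 * pi * ph + pi),
                      pelvis_y + lat_sign * 190 * s, 1420 * s + 0 * t)
    list(ankle = ankle, knee = knee, hip = hip, shoulder = shoulder,
         contact = ph < duty)
  }
  lft <- side(0, +1)
  rgt <- side(0.5, -1)
  head <- cbind(pelvis_x, pelvis_y, 1650 * s + 10 * s * sin(4 * pi * t / stride))

  mk <- function(m, nm) trajectory3d(m, joint = nm, rate = rate)
  trajectories <- list(
    head = mk(head, "head"),
    shoulder_l = mk(lft$shoulder, "shoulder_l"),
    shoulder_r = mk(rgt$shoulder, "shoulder_r"),
    hip_l = mk(lft$hip, "hip_l"), hip_r = mk(rgt$hip, "hip_r"),
    knee_l = mk(lft$knee, "knee_l"), knee_r = mk(rgt$knee, "knee_r"),
    ankle_l = mk(lft$ankle, "ankle_l"), ankle_r = mk(rgt$ankle, "ankle_r"))

  # first frame index at or after time x (frames are t = (f-1)/rate)
  frame_at <- function(x) as.integer(ceiling(x * rate - 1e-9)) + 1L
  an_events <- function(off) {
    k <- 0:(cycles + 3)
    t_td <- (k - start_phase - off) * stride
    t_td <- t_td[t_td > -1e-9]
    td <- frame_at(t_td)
    to <- frame_at(t_td + duty * stride)
    list(td = td[td <= n], to = to[to <= n])
  }
  events <- list(left = an_events(0), right = an_events(0.5))
  list(trajectories = trajectories,
       contact = list(left = lft$contact, right = rgt$contact),
       events = events, activity = activity, speed_mm_s = speed,
       stride_time_s = stride, duty = duty, n_frames = n, rate = rate)
}

#' Simulate a counter-movement jump with its vertical force trace
#'
#' Quiet standing (noisy force around bodyweight), an unweighting phase
#' whose force stays below bodyweight for well over 20 frames, a propulsive
#' phase sized by impulse-momentum to reach the requested jump height,
#' a flight phase with identically zero force, a landing impulse and a
#' damped settling oscillation. The centre-of-mass kinematics are the double
#' integral of the same acceleration profile, so force and motion are
#' mutually consistent; all event frames are computed analytically into the
#' answer key.
#'
#' @param rate Sample rate, Hz (default 200).
#' @param bodyweight_n Bodyweight (N, default 700).
#' @param jump_height_m Flight apex height (m, default 0.30).
#' @param quiet_s Quiet-standing duration (default 1.5 s).
#' @param noise_sd_n SD of quiet-standing force noise (N, default 5);
#'   applied only during quiet standing so settling is analytic.
#' @param seed RNG seed for the quiet-standing noise.
#' @return List: `force` (N), `trajectories` (joint `trajectory3d`s),
#'   `events` (analytic `first_movement`, `takeoff`, `landing`,
#'   `stabilisation` frames), `bodyweight_n`, `rate`.
#' @export
simulate_jump <- function(rate = 200, bodyweight_n = 700, jump_height_m = 0.3,
                          quiet_s = 1.5, noise_sd_n = 5, seed = NULL) {
  g <- 9.81
  mass <- bodyweight_n / g
  v_to <- sqrt(2 * g * jump_height_m)
  t1 <- 0.3; a1 <- 4                       # unweighting half-sine, m/s^2
  v1 <- -a1 * 2 * t1 / pi
  t2 <- 0.3
  a2 <- (v_to - v1) * pi / (2 * t2)        # propulsion amplitude
  t_fl <- 2 * v_to / g
  t_land <- 0.15
  a_l <- (v_to + g * t_land) * pi / (2 * t_land)  # landing absorption
  settle_s <- 2.5

  seg <- function(dur) round(dur * rate)
  nq <- seg(quiet_s); n1 <- seg(t1); n2 <- seg(t2)
  nfl <- seg(t_fl); nl <- seg(t_land); ns <- seg(settle_s)
  acc <- c(rep(0, nq),
           -a1 * sin(pi * seq_len(n1) / n1),
           a2 * sin(pi * seq_len(n2) / n2),
           rep(-g, nfl),
           a_l * sin(pi * seq_len(nl) / nl) - g,
           rep(0, ns))
  n <- length(acc)
  t_set <- (seq_len(ns) - 1) / rate
  osc <- 280 * exp(-t_set / 0.35) * cos(2 * pi * 3.2 * t_set)
  force <- mass * (g + acc)
  force[(nq + n1 + n2 + 1):(nq + n1 + n2 + nfl)] <- 0
  set_idx <- (n - ns + 1):n
  force[set_idx] <- bodyweight_n + osc
  noise <- with_seed(seed, stats::rnorm(nq, 0, noise_sd_n))
  force[seq_len(nq)] <- bodyweight_n + noise

  # analytic events, using the same estimates a detector would form
  bw_hat <- mean(force[seq_len(seg(1))])
  sd_hat <- stats::sd(force[seq_len(seg(1))])
  # the unweighting dip is adjacent to noisy quiet frames, so the first run
  # of >= 20 below-bodyweight frames can open a frame or two early: apply
  # the run rule to the realised trace
  rl_b <- rle(force < bw_hat)
  ends_b <- cumsum(rl_b$lengths)
  kb <- which(rl_b$values & rl_b$lengths >= 20)[1]
  first_movement <- ends_b[kb] - rl_b$lengths[kb] + 1L
  takeoff <- nq + n1 + n2 + 1L
  landing <- nq + n1 + n2 + nfl + 1L
  inband <- abs(bodyweight_n + osc - bw_hat) <= 3 * sd_hat
  hold <- seg(0.5)
  stab_rel <- NA_integer_
  run <- 0L
  for (k in ns:1) {
    run <- if (inband[k]) run + 1L else 0L
    if (run >= hold) stab_rel <- k
  }
  stabilisation <- n - ns + stab_rel

  # CoM kinematics by trapezoidal integration of the same acceleration
  vel <- cumsum(acc) / rate
  com_z <- 920 + cumsum(vel) / rate * 1000
  tt <- (seq_len(n) - 1) / rate      # gentle postural sway in the plane
  pel_x <- 8 * sin(2 * pi * 0.4 * tt)
  pel_y <- 6 * sin(2 * pi * 0.3 * tt + 1)
  mk <- function(dx, dy, dz, nm)
    trajectory3d(cbind(pel_x + dx, pel_y + dy, com_z + dz), joint = nm,
                 rate = rate)
  trajectories <- list(
    head = mk(0, 0, 730, "head"),
    shoulder_l = mk(0, 190, 500, "shoulder_l"),
    shoulder_r = mk(0, -190, 500, "shoulder_r"),
    hip_l = mk(0, 95, 0, "hip_l"), hip_r = mk(0, -95, 0, "hip_r"),
    knee_l = mk(30, 110, -420, "knee_l"), knee_r = mk(30, -110, -420, "knee_r"),
    ankle_l = mk(0, 110, -830, "ankle_l"), ankle_r = mk(0, -110, -830, "ankle_r"))
  list(force = force, trajectories = trajectories,
       events = list(first_movement = first_movement, takeoff = takeoff,
                     landing = landing, stabilisation = stabilisation),
       bodyweight_n = bodyweight_n, jump_height_m = jump_height_m,
       flight_time_s = t_fl, rate = rate, n_frames = n)
}

#' Render 2D detections from ground-truth trajectories
#'
#' Projects every joint into every camera and corrupts the detections the
#' way CNN pose estimators fail: isotropic Gaussian pixel noise on clean
#' detections; misses (confidence 0) with probability `miss_rate`; outliers
#' with probability `outlier_rate`, replaced either by a uniform-random
#' image pixel or by the corresponding joint of a background person.
#' Clean detections draw confidence ~ U(0.7, 1), corrupted ones ~ U(0.1,
#' 0.6). Joints behind a camera or outside its image are missing. Every
#' corruption is logged so downstream statistics are predictable from the
#' answer key.
#'
#' @param trajectories Named list of ground-truth `trajectory3d` (subject).
#' @param cameras List of `camera_model`.
#' @param sigma_px Gaussian pixel noise SD (default 0).
#' @param outlier_rate,miss_rate Corruption probabilities (default 0).
#' @param outlier_mode `"uniform"` or `"background"`.
#' @param extra_people Optional list of trajectory lists for additional
#'   people; rendered as persons 2, 3, ... and used as the outlier source in
#'   `"background"` mode.
#' @param seed RNG seed.
#' @return List: `detections` data frame (`camera, frame, person, joint, x,
#'   y, confidence`) and `log` data frame of corruptions
#'   (`camera, frame, joint, type`).
#' @export
render_detections <- function(trajectories, cameras, sigma_px = 0,
                              outlier_rate = 0, miss_rate = 0,
                              outlier_mode = c("uniform", "background"),
                              extra_people = NULL, seed = NULL) {
  outlier_mode <- match.arg(outlier_mode)
  if (outlier_mode == "background" && length(extra_people) == 0)
    stop("render_detections: background outlier mode needs extra_people")
  with_seed(seed, {
    det <- list(); logs <- list()
    person_sets <- c(list(trajectories), extra_people)
    for (ci in seq_along(cameras)) {
      cam <- cameras[[ci]]
      for (pi in seq_along(person_sets)) {
        trajs <- person_sets[[pi]]
        for (jn in names(trajs)) {
          tr <- trajs[[jn]]
          n <- length(tr)
          px <- matrix(NA_real_, n, 2)
          ok <- tr$valid
          if (any(ok))
            px[ok, ] <- project_visible(cam, tr$positions[ok, , drop = FALSE])
          vis <- !is.na(px[, 1])
          conf <- numeric(n)
          if (pi == 1) {
            u <- stats::runif(n)
            miss <- vis & u < miss_rate
            outl <- vis & !miss & u < miss_rate + outlier_rate
            clean <- vis & !miss & !outl
            px[clean, ] <- px[clean, , drop = FALSE] +
              matrix(stats::rnorm(2 * sum(clean), 0, sigma_px), ncol = 2)
            if (any(outl)) {
              if (outlier_mode == "uniform") {
                px[outl, ] <- cbind(stats::runif(sum(outl), 0, cam$width),
                                    stats::runif(sum(outl), 0, cam$height))
              } else {
                bg <- extra_people[[1]][[jn]]
                bpx <- project_visible(cam, bg$positions)
                px[outl, ] <- bpx[outl, , drop = FALSE] +
                  matrix(stats::rnorm(2 * sum(outl), 0, sigma_px), ncol = 2)
                lost <- outl & is.na(px[, 1])
                miss <- miss | lost
                outl <- outl & !lost
              }
            }
            conf[clean] <- stats::runif(sum(clean), 0.7, 1.0)
            conf[outl] <- stats::runif(sum(outl), 0.1, 0.6)
            conf[miss] <- 0
            px[, 1] <- pmin(pmax(px[, 1], 0), cam$width)
            px[, 2] <- pmin(pmax(px[, 2], 0), cam$height)
            px[miss | !vis, ] <- 0
            if (any(miss))
              logs[[length(logs) + 1]] <- data.frame(
                camera = ci, frame = which(miss), joint = jn, type = "miss")
            if (any(outl))
              logs[[length(logs) + 1]] <- data.frame(
                camera = ci, frame = which(outl), joint = jn,
                type = paste0("outlier_", outlier_mode))
          } else {
            px[vis, ] <- px[vis, , drop = FALSE] +
              matrix(stats::rnorm(2 * sum(vis), 0, sigma_px), ncol = 2)
            conf[vis] <- stats::runif(sum(vis), 0.7, 1.0)
            px[, 1] <- pmin(pmax(px[, 1], 0), cam$width)
            px[, 2] <- pmin(pmax(px[, 2], 0), cam$height)
            px[!vis, ] <- 0
          }
          det[[length(det) + 1]] <- data.frame(
            camera = ci, frame = seq_len(n), person = pi, joint = jn,
            x = px[, 1], y = px[, 2], confidence = conf)
        }
      }
    }
    list(detections = do.call(rbind, det),
         log = if (length(logs)) do.call(rbind, logs)
               else data.frame(camera = integer(), frame = integer(),
                               joint = character(), type = character()))
  })
}

#' Derive biased marker-based reference trajectories
#'
#' Emulates the discrepancy between a marker-derived reference and the true
#' joint centre: a constant per-joint offset (systematic bias, e.g. a
#' CNN-vs-marker labelling difference projected on the reference) plus
#' low-frequency correlated noise emulating soft-tissue artefact. Offsets
#' are recorded in the returned answer key.
#'
#' @param trajectories Named list of ground-truth `trajectory3d`.
#' @param offsets_mm Named list of length-3 offsets added to the truth
#'   (joints absent from the list get zero offset).
#' @param soft_tissue_sd_mm Per-axis SD of the correlated noise (default 0).
#' @param noise_cutoff_hz Low-pass corner of the noise (default 4, keeping
#'   its power below ~6 Hz).
#' @param seed RNG seed.
#' @return List: `reference` (named `trajectory3d` list) and `answer_key`
#'   (named list of applied offsets).
#' @export
make_marker_reference <- function(trajectories, offsets_mm = list(),
                                  soft_tissue_sd_mm = 0, noise_cutoff_hz = 4,
                                  seed = NULL) {
  with_seed(seed, {
    reference <- lapply(names(trajectories), function(jn) {
      tr <- trajectories[[jn]]
      off <- if (jn %in% names(offsets_mm)) as.numeric(offsets_mm[[jn]])
             else c(0, 0, 0)
      pos <- sweep(tr$positions, 2, off, "+")
      if (soft_tissue_sd_mm > 0) {
        n <- length(tr)
        w <- matrix(stats::rnorm(3 * n), n, 3)
        w <- butterworth_lowpass(w, cutoff = noise_cutoff_hz, order = 4,
                                 rate = tr$rate)
        w <- sweep(w, 2, apply(w, 2, stats::sd), "/") * soft_tissue_sd_mm
        pos <- pos + w
      }
      trajectory3d(pos, tr$valid, tr$joint, tr$rate, tr$offset)
    })
    names(reference) <- names(trajectories)
    key <- lapply(names(trajectories), function(jn)
      if (jn %in% names(offsets_mm)) as.numeric(offsets_mm[[jn]])
      else c(0, 0, 0))
    names(key) <- names(trajectories)
    list(reference = reference, answer_key = key)
  })
}

#' Simulate a wand calibration-check trial
#'
#' Two markers at a fixed known separation sweep the volume on a smooth
#' Lissajous path while the wand slowly reorients.
#'
#' @param length_mm Known wand length (default 500).
#' @param n_frames Trial length (default 1000).
#' @param rate Sample rate, Hz (default 200).
#' @param noise_sd_mm Per-axis Gaussian noise per endpoint (default 0).
#' @param seed RNG seed.
#' @return List: endpoint `trajectory3d`s `a` and `b`, `length_mm`.
#' @export
simulate_wand_trial <- function(length_mm = 500, n_frames = 1000, rate = 200,
                                noise_sd_mm = 0, seed = NULL) {
  t <- (seq_len(n_frames) - 1) / rate
  a <- cbind(900 * sin(2 * pi * 0.31 * t),
             900 * sin(2 * pi * 0.23 * t + 1),
             1000 + 450 * sin(2 * pi * 0.17 * t + 2))
  th <- 1.1 + 0.8 * sin(2 * pi * 0.13 * t)
  ph <- 2 * pi * 0.19 * t
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  b <- a + length_mm * u
  with_seed(seed, {
    if (noise_sd_mm > 0) {
      a <- a + matrix(stats::rnorm(3 * n_frames, 0, noise_sd_mm), ncol = 3)
      b <- b + matrix(stats::rnorm(3 * n_frames, 0, noise_sd_mm), ncol = 3)
    }
    list(a = trajectory3d(a, joint = "wand_a", rate = rate),
         b = trajectory3d(b, joint = "wand_b", rate = rate),
         length_mm = length_mm)
  })
}

#' Simulate a spatial/temporal alignment trial
#'
#' A single marker moves randomly through the volume and is tracked by two
#' systems whose Euclidean frames differ by a known rigid transform and
#' whose clocks differ by a known integer frame offset. Both systems also
#' record a shared pseudo-random LED flash sequence for temporal alignment.
#'
#' @param n_frames Trial length (default 2000).
#' @param rate Sample rate, Hz (default 200).
#' @param rotation_deg Rotation of system B's frame about Z (default 7).
#' @param translation_mm Translation of system B's frame
#'   (default `c(150, -80, 40)`).
#' @param frame_offset Integer frames by which system B lags A (default 3).
#' @param noise_sd_mm Per-axis tracking noise in each system (default 0).
#' @param seed RNG seed (path and flash sequence).
#' @return List: `points_a`, `points_b` (`trajectory3d`), `flash_a`,
#'   `flash_b` (0/1 vectors), `transform` (true `rigid_transform` mapping A
#'   to B), `frame_offset`.
#' @export
simulate_alignment_trial <- function(n_frames = 2000, rate = 200,
                                     rotation_deg = 7,
                                     translation_mm = c(150, -80, 40),
                                     frame_offset = 3L, noise_sd_mm = 0,
                                     seed = NULL) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  with_seed(seed, {
    t <- (seq_len(n_frames + abs(frame_offset)) - 1) / rate
    f <- stats::runif(6, 0.1, 0.5); p0 <- stats::runif(6, 0, 2 * pi)
    path <- cbind(800 * sin(2 * pi * f[1] * t + p0[1]) +
                    500 * sin(2 * pi * f[2] * t + p0[2]),
                  800 * sin(2 * pi * f[3] * t + p0[3]) +
                    500 * sin(2 * pi * f[4] * t + p0[4]),
                  1000 + 400 * sin(2 * pi * f[5] * t + p0[5]) +
                    250 * sin(2 * pi * f[6] * t + p0[6]))
    flash <- as.numeric(stats::runif(n_frames + abs(frame_offset)) < 0.5)
    ia <- seq_len(n_frames)
    ib <- ia - frame_offset
    ib_ok <- ib >= 1 & ib <= nrow(path)
    pa <- path[ia, , drop = FALSE]
    pb <- matrix(NA_real_, n_frames, 3)
    pb[ib_ok, ] <- sweep(path[ib[ib_ok], , drop = FALSE] %*% t(R), 2,
                         translation_mm, "+")
    if (noise_sd_mm > 0) {
      pa <- pa + matrix(stats::rnorm(3 * n_frames, 0, noise_sd_mm), ncol = 3)
      pb <- pb + matrix(stats::rnorm(3 * n_frames, 0, noise_sd_mm), ncol = 3)
    }
    fa <- flash[ia]
    fb <- rep(0, n_frames)
    fb[ib_ok] <- flash[ib[ib_ok]]
    list(points_a = trajectory3d(pa, joint = "align", rate = rate),
         points_b = trajectory3d(pb, joint = "align", rate = rate),
         flash_a = fa, flash_b = fb,
         transform = structure(list(rotation = R,
                                    translation = as.numeric(translation_mm),
                                    rms = 0), class = "rigid_transform"),
         frame_offset = as.integer(frame_offset))
  })
}

#' Assemble a complete synthetic capture scene
#'
#' The virtual laboratory in one call: a camera rig, ground-truth kinematics
#' for one activity, corrupted per-camera detection streams, a biased marker
#' reference, and (for jumps) the force trace — everything downstream of the
#' CNN detectors, with a machine-readable answer key.
#'
#' @param activity `"walk"`, `"run"` or `"jump"`.
#' @param seed Master RNG seed for this scene.
#' @param n_cameras Cameras on the ring (default 9).
#' @param sigma_px,outlier_rate,miss_rate Detection corruption (defaults
#'   2 px, 0, 0).
#' @param marker_offsets_mm Named per-joint systematic offsets for the
#'   reference (default none).
#' @param soft_tissue_sd_mm Reference soft-tissue noise SD (default 0).
#' @param extra_people Background-person trajectory lists (default none).
#' @param ... Passed to [simulate_gait()] / [simulate_jump()].
#' @return Object of class `synthetic_scene`.
#' @export
simulate_scene <- function(activity = c("walk", "run", "jump"), seed = 1,
                           n_cameras = 9, sigma_px = 2, outlier_rate = 0,
                           miss_rate = 0, marker_offsets_mm = list(),
                           soft_tissue_sd_mm = 0, extra_people = NULL, ...) {
  activity <- match.arg(activity)
  cameras <- make_camera_rig(n = n_cameras)
  motion <- if (activity == "jump")
    simulate_jump(seed = seed %% 2147483647L, ...)
  else simulate_gait(activity = activity, ...)
  rend <- render_detections(motion$trajectories, cameras, sigma_px = sigma_px,
                            outlier_rate = outlier_rate, miss_rate = miss_rate,
                            extra_people = extra_people,
                            seed = (seed + 1) %% 2147483647L)
  ref <- make_marker_reference(motion$trajectories,
                               offsets_mm = marker_offsets_mm,
                               soft_tissue_sd_mm = soft_tissue_sd_mm,
                               seed = (seed + 2) %% 2147483647L)
  structure(list(activity = activity, cameras = cameras,
                 truth = motion$trajectories,
                 detections = rend$detections,
                 corruption_log = rend$log,
                 reference = ref$reference,
                 contact = motion$contact, events = motion$events,
                 force = motion$force,
                 answer_key = list(offsets_mm = ref$answer_key,
                                   sigma_px = sigma_px,
                                   outlier_rate = outlier_rate,
                                   miss_rate = miss_rate,
                                   events = motion$events),
                 rate = motion$rate, n_frames = motion$n_frames,
                 seed = seed),
            class = "synthetic_scene")
}
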