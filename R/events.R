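#' Detect counter-movement-jump events from a vertical force trace
#'
#' Bodyweight and its SD are taken from a quiet-standing window. First
#' movement is the first frame of the first run of at least
#' `below_frames` consecutive frames with vertical force below bodyweight.
#' Stabilisation is the first frame, at or after the landing (the end of the
#' flight phase), from which the force remains within `sd_mult` standard
#' deviations of bodyweight for `hold_s` seconds.
#'
#' @param force Vertical ground-reaction force (N) at `rate` Hz.
#' @param rate Sample rate, Hz (default 200).
#' @param quiet_window Frame indices of quiet standing (default: first 1 s).
#' @param below_frames Consecutive frames below bodyweight defining first
#'   movement (default 20).
#' @param sd_mult Stabilisation band half-width in baseline SDs (default 3).
#' @param hold_s Duration the force must stay in band (default 0.5 s).
#' @param flight_threshold_n Force below this is flight (default 10 N).
#' @return Object of class `jump_events`: `first_movement`, `stabilisation`
#'   (frame indices), `bodyweight_n`, `baseline_sd_n`, plus the takeoff /
#'   landing frames found on the way.
#' @export
detect_jump_events <- function(force, rate = 200,
                               quiet_window = seq_len(round(rate)),
                               below_frames = 20, sd_mult = 3,
                               hold_s = 0.5, flight_threshold_n = 10) {
  bw <- mean(force[quiet_window])
  bsd <- stats::sd(force[quiet_window])

  below <- force < bw
  rl <- rle(below)
  ends <- cumsum(rl$lengths)
  cand <- which(rl$values & rl$lengths >= below_frames)
  if (length(cand) == 0)
    stop("detect_jump_events: no run of ", below_frames,
         " consecutive frames below bodyweight")
  first_movement <- ends[cand[1]] - rl$lengths[cand[1]] + 1L

  # flight = contiguous near-zero force after first movement
  flight <- which(force < flight_threshold_n &
                    seq_along(force) > first_movement)
  if (length(flight) == 0)
    stop("detect_jump_events: no flight phase found")
  takeoff <- flight[1]
  landing <- flight[max(which(diff(c(flight, Inf)) > 1)[1], 1)] + 1L

  hold <- round(hold_s * rate)
  inband <- abs(force - bw) <= sd_mult * bsd
  n <- length(force)
  stabilisation <- NA_integer_
  run <- 0L
  for (k in n:landing) {             # suffix run lengths of in-band frames
    run <- if (inband[k]) run + 1L else 0L
    if (k + hold - 1L <= n && run >= hold) stabilisation <- k
  }
  if (is.na(stabilisation))
    stop("detect_jump_events: force never stabilises within ", sd_mult,
         " SD of bodyweight for ", hold_s, " s")
  if (first_movement >= stabilisation)
    stop("detect_jump_events: first movement must precede stabilisation")
  structure(list(first_movement = first_movement,
                 stabilisation = stabilisation,
                 takeoff = takeoff, landing = landing,
                 bodyweight_n = bw, baseline_sd_n = bsd),
            class = "jump_events")
}

#' Detect gait touch-down and toe-off events
#'
#' With synthetic ground-truth contact flags the events are exact: touch-down
#' (TD) at each rising edge, toe-off (TO) at each falling edge. Without
#' flags, a kinematic stand-in is used on the foot (ankle/heel) trajectory:
#' TD at local minima of vertical position with near-zero vertical velocity,
#' TO at the subsequent upward velocity crossing.
#'
#' @param foot Named list with per-side input: either `contact` (logical
#'   vector) or `z` (vertical foot position, mm). E.g.
#'   `list(left = list(contact = ...), right = list(contact = ...))`.
#' @param rate Sample rate, Hz (default 200).
#' @param vel_tol_mm_s Near-zero velocity tolerance for the kinematic
#'   stand-in (default 150 mm/s).
#' @return Object of class `gait_events`: per side, increasing `td` and `to`
#'   frame vectors that alternate TD, TO, TD, ...
#' @export
detect_gait_events <- function(foot, rate = 200, vel_tol_mm_s = 150) {
  side_events <- function(s) {
    if (!is.null(s$contact)) {
      c0 <- as.logical(s$contact)
      # rising/falling edges only: contact already present at frame 1 is a
      # trial-start artifact, not a touch-down
      td <- which(diff(c0) == 1) + 1L
      to <- which(diff(c0) == -1) + 1L   # first airborne frame
    } else {
      z <- s$z
      v <- c(0, diff(z)) * rate
      n <- length(z)
      is_min <- c(FALSE, z[2:(n - 1)] <= z[1:(n - 2)] &
                    z[2:(n - 1)] <= z[3:n], FALSE)
      td <- which(is_min & abs(v) < vel_tol_mm_s)
      td <- td[c(TRUE, diff(td) > round(0.25 * rate))]  # debounce plateaus
      to <- integer(0)
      for (t0 in td) {
        up <- which(v > vel_tol_mm_s & seq_len(n) > t0)
        if (length(up) > 0) to <- c(to, up[1])
      }
    }
    # enforce alternation TD, TO, TD, ...
    ev <- data.frame(f = c(td, to),
                     type = c(rep("td", length(td)), rep("to", length(to))))
    ev <- ev[order(ev$f), , drop = FALSE]
    keep_td <- integer(0); keep_to <- integer(0)
    expect <- "td"
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == expect) {
        if (expect == "td") keep_td <- c(keep_td, ev$f[i])
        else keep_to <- c(keep_to, ev$f[i])
        expect <- if (expect == "td") "to" else "td"
      }
    }
    list(td = keep_td, to = keep_to)
  }
  out <- lapply(foot, side_events)
  if (all(vapply(out, function(s) length(s$td) < 2, logical(1))))
    stop("detect_gait_events: fewer than one complete cycle on every side")
  structure(out, class = "gait_events")
}

#' Register a trajectory segment to 101 points
#'
#' Linear interpolation of each coordinate at `n` equally spaced time points
#' spanning `[start, end]` inclusive — the standard 0..100% cycle
#' registration, independent of the cycle's frame length.
#'
#' @param traj A `trajectory3d`.
#' @param start,end Cycle-delimiting frame indices (`start < end`), e.g. TD
#'   to the next same-side TD.
#' @param n Number of registered samples (default 101).
#' @param max_gap_s Longest masked gap tolerated inside the cycle
#'   (default 0.25 s); masked samples are bridged by linear interpolation.
#' @return Object of class `normalized_cycle`: `positions` (n x 3), `joint`,
#'   `source` (the event pair).
#' @export
time_normalize <- function(traj, start, end, n = 101, max_gap_s = 0.25) {
  if (start >= end) stop("time_normalize: start must precede end")
  if (end > length(traj)) stop("time_normalize: cycle exceeds trajectory")
  idx <- start:end
  vm <- traj$valid[idx]
  if (!all(vm)) {
    rl <- rle(vm)
    if (any(!rl$values & rl$lengths > round(max_gap_s * traj$rate)))
      stop("time_normalize: masked gap inside the cycle exceeds gap policy")
    if (!vm[1] || !vm[length(vm)])
      stop("time_normalize: cycle endpoints must be valid")
  }
  tq <- seq(start, end, length.out = n)
  src_t <- idx[vm]
  pos <- vapply(1:3, function(a)
    stats::approx(src_t, traj$positions[idx[vm], a], xout = tq)$y,
    numeric(n))
  structure(list(joint = traj$joint, positions = pos,
                 source = c(start = start, end = end)),
            class = "normalized_cycle")
}
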