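#' Assign per-camera detections to the subject track
#'
#' For frames where a camera sees several people, the person whose detected
#' keypoint centroid lies closest to the projection of the subject's
#' ground-plane position (at torso height) is kept; all other people are
#' dropped. Frames absent from the track keep no detections.
#'
#' @param detections Detection data frame (all cameras, all frames).
#' @param cameras List of `camera_model`.
#' @param track Subject rows from [subject_track()].
#' @param torso_height_mm Height at which the track position is projected
#'   (default 1000).
#' @return Filtered detection data frame containing one person per
#'   camera-frame.
#' @export
assign_subject_detections <- function(detections, cameras, track,
                                      torso_height_mm = 1000) {
  keep <- logical(nrow(detections))
  pos <- track[match(detections$frame, track$frame), c("x", "y")]
  key <- paste(detections$camera, detections$frame)
  for (k in unique(key)) {
    idx <- which(key == k)
    f <- detections$frame[idx[1]]
    ti <- match(f, track$frame)
    if (is.na(ti)) next
    persons <- unique(detections$person[idx])
    if (length(persons) == 1) { keep[idx] <- TRUE; next }
    cam <- cameras[[detections$camera[idx[1]]]]
    target <- tryCatch(
      project_point(cam, c(track$x[ti], track$y[ti], torso_height_mm)),
      error = function(e) NULL)
    if (is.null(target)) next
    cent <- vapply(persons, function(p) {
      pi <- idx[detections$person[idx] == p & detections$confidence[idx] > 0]
      if (length(pi) == 0) return(Inf)
      sqrt((mean(detections$x[pi]) - target[1])^2 +
           (mean(detections$y[pi]) - target[2])^2)
    }, numeric(1))
    keep[idx[detections$person[idx] == persons[which.min(cent)]]] <- TRUE
  }
  detections[keep, , drop = FALSE]
}

#' Reconstruct 3D joint-centre trajectories from subject detections
#'
#' Per joint and frame: every valid detection with confidence at or above
#' `conf_min` is back-projected to a ray and the rays fused with
#' [ransac_intersect()]; RANSAC failures (fewer than two consistent rays)
#' leave the frame masked — a gap for the smoother to bridge, not an error.
#'
#' @param detections Subject-assigned detection data frame.
#' @param cameras List of `camera_model`.
#' @param joints Joint names to reconstruct (default: all present).
#' @param n_frames Trajectory length (default: max frame seen).
#' @param conf_min Confidence gate before back-projection (default 0.3).
#' @param inlier_tol_mm RANSAC consensus threshold (default 20).
#' @param max_iter RANSAC sampling budget for > 12 rays (default 100).
#' @param use_ransac Set `FALSE` to fuse by plain least-squares triangulation
#'   of all rays (no outlier rejection) — the baseline the robust pipeline is
#'   compared against.
#' @param rate Sample rate (Hz, default 200).
#' @param seed Optional seed for RANSAC sampling.
#' @return Named list of `trajectory3d`, one per joint.
#' @export
reconstruct_sequence <- function(detections, cameras,
                                 joints = unique(detections$joint),
                                 n_frames = max(detections$frame),
                                 conf_min = 0.3, inlier_tol_mm = 20,
                                 max_iter = 100, use_ransac = TRUE,
                                 rate = 200, seed = NULL) {
  det <- detections[detections$confidence >= conf_min &
                      detections$confidence > 0, , drop = FALSE]
  out <- vector("list", length(joints))
  names(out) <- joints
  for (jn in joints) {
    dj <- det[det$joint == jn, , drop = FALSE]
    pos <- matrix(NA_real_, n_frames, 3)
    valid <- logical(n_frames)
    if (nrow(dj) > 0) {
      by_frame <- split(seq_len(nrow(dj)), dj$frame)
      for (fs in names(by_frame)) {
        idx <- by_frame[[fs]]
        if (length(idx) < 2) next
        f <- as.integer(fs)
        rays <- lapply(idx, function(i)
          backproject(cameras[[dj$camera[i]]], c(dj$x[i], dj$y[i])))
        rays <- rays[vapply(rays, `[[`, logical(1), "valid")]
        if (length(rays) < 2) next
        if (use_ransac) {
          fit <- ransac_intersect(rays, inlier_tol_mm, max_iter, seed)
          if (fit$failed) next
          pos[f, ] <- fit$point
        } else {
          fit <- tryCatch(triangulate(rays), error = function(e) NULL)
          if (is.null(fit)) next
          pos[f, ] <- fit$point
        }
        valid[f] <- TRUE
      }
    }
    if (!any(valid))
      warning("reconstruct_sequence: joint '", jn,
              "' was never reconstructed")
    out[[jn]] <- trajectory3d(pos, valid, jn, rate)
  }
  out
}
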