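#' Keypoint schemes
#'
#' Ordered, uniquely named body keypoints. Presets mirror the common
#' pose-estimation outputs: `body25` (OpenPose), `body18` (AlphaPose) and
#' `body15` (DeepLabCut's pre-trained human model). Arbitrary custom schemes
#' are allowed for synthetic work.
#'
#' @param x Preset name (`"body25"`, `"body18"`, `"body15"`) or a character
#'   vector of unique joint names.
#' @return Object of class `keypoint_scheme` with `names` and `count`.
#' @export
keypoint_scheme <- function(x) {
  presets <- list(
    body25 = c("nose", "neck", "shoulder_r", "elbow_r", "wrist_r",
               "shoulder_l", "elbow_l", "wrist_l", "mid_hip", "hip_r",
               "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l", "eye_r",
               "eye_l", "ear_r", "ear_l", "big_toe_l", "small_toe_l",
               "heel_l", "big_toe_r", "small_toe_r", "heel_r"),
    body18 = c("nose", "neck", "shoulder_r", "elbow_r", "wrist_r",
               "shoulder_l", "elbow_l", "wrist_l", "hip_r", "knee_r",
               "ankle_r", "hip_l", "knee_l", "ankle_l", "eye_r", "eye_l",
               "ear_r", "ear_l"),
    body15 = c("nose", "shoulder_r", "elbow_r", "wrist_r", "shoulder_l",
               "elbow_l", "wrist_l", "hip_r", "knee_r", "ankle_r", "hip_l",
               "knee_l", "ankle_l", "eye_r", "eye_l")
  )
  nm <- if (length(x) == 1 && x %in% names(presets)) presets[[x]] else x
  if (anyDuplicated(nm)) stop("keypoint_scheme: joint names must be unique")
  structure(list(names = nm, count = length(nm)), class = "keypoint_scheme")
}

#' Read OpenPose-style per-frame JSON keypoint files
#'
#' Each file holds one frame: `{"people": [{"pose_keypoints_2d":
#' [x1,y1,c1, x2,y2,c2, ...]}, ...]}`. People are preserved in file order;
#' keypoints with confidence 0 are missing detections and are never
#' back-projected.
#'
#' @param files Character vector of JSON file paths in frame order, or a
#'   directory (files are sorted lexically).
#' @param scheme A `keypoint_scheme`; the flat array length must equal
#'   `3 * scheme$count`.
#' @param camera Camera id recorded in the output (default 1).
#' @return Data frame of detections: `camera, frame, person, joint, x, y,
#'   confidence`, one row per (person, keypoint); `frame` indexes the file
#'   order from 1.
#' @export
read_openpose_json <- function(files, scheme, camera = 1L) {
  if (length(files) == 1 && dir.exists(files))
    files <- sort(list.files(files, pattern = "\\.json$", full.names = TRUE))
  frames <- lapply(seq_along(files), function(fi) {
    doc <- tryCatch(jsonlite::fromJSON(files[fi], simplifyDataFrame = FALSE),
                    error = function(e)
                      stop("read_openpose_json: malformed JSON in ",
                           files[fi], ": ", conditionMessage(e)))
    people <- doc$people
    if (length(people) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(people), function(pi) {
      kp <- as.numeric(people[[pi]]$pose_keypoints_2d)
      if (length(kp) != 3 * scheme$count)
        stop("read_openpose_json: keypoint array length ", length(kp),
             " does not match scheme of ", scheme$count, " joints in ",
             files[fi])
      m <- matrix(kp, ncol = 3, byrow = TRUE)
      data.frame(camera = camera, frame = fi, person = pi,
                 joint = scheme$names, x = m[, 1], y = m[, 2],
                 confidence = m[, 3])
    }))
  })
  out <- do.call(rbind, frames)
  if (is.null(out))
    out <- data.frame(camera = integer(), frame = integer(),
                      person = integer(), joint = character(),
                      x = numeric(), y = numeric(), confidence = numeric())
  if (any(out$confidence < 0 | out$confidence > 1))
    stop("read_openpose_json: confidences must lie in [0, 1]")
  out
}

#' Write detections to OpenPose-style per-frame JSON files
#'
#' Inverse of [read_openpose_json()] for one camera's detection stream.
#'
#' @param detections Detection data frame for a single camera.
#' @param scheme A `keypoint_scheme`.
#' @param dir Output directory (created if needed).
#' @param n_frames Total frames to emit (frames without people get
#'   `"people": []`).
#' @return Invisibly, the written file paths.
#' @export
write_openpose_json <- function(detections, scheme, dir,
                                n_frames = max(detections$frame)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_frames)
  for (f in seq_len(n_frames)) {
    df <- detections[detections$frame == f, , drop = FALSE]
    people <- lapply(split(df, df$person), function(p) {
      kp <- matrix(0, scheme$count, 3)
      idx <- match(p$joint, scheme$names)
      kp[idx, ] <- cbind(p$x, p$y, p$confidence)
      kp[kp[, 3] == 0, 1:2] <- 0
      list(pose_keypoints_2d = as.numeric(t(kp)))
    })
    names(people) <- NULL
    paths[f] <- file.path(dir, sprintf("frame_%06d_keypoints.json", f))
    jsonlite::write_json(list(people = people), paths[f],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
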