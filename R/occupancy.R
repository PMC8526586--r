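#' Build a ground-plane occupancy map for one frame
#'
#' Every valid pelvis-level detection (confidence above the gate) is
#' back-projected and the ray intersected with a floor-parallel plane at
#' torso (pelvis) height; the crossing increments its grid cell. Peaks in
#' the accumulated counts mark candidate people, which makes frame-to-frame
#' association robust to per-joint detection failures. Only joints whose
#' height matches the plane localise sharply, so accumulation is restricted
#' to pelvis keypoints (`torso_pattern`); rays from joints well above or
#' below the plane cross it far from the person and would only blur the map.
#'
#' @param detections Detection data frame for a single frame (all cameras).
#' @param cameras Named or indexed list of `camera_model`; `detections$camera`
#'   indexes into it.
#' @param grid List with `xlim`, `ylim` (mm) and `cell` size (mm, default 100).
#' @param plane_height_mm Height of the intersection plane; set it at the
#'   expected pelvis height (default 950).
#' @param torso_pattern Regex selecting the contributing joints
#'   (default `"hip"`).
#' @param conf_min Confidence gate (default 0.3).
#' @return Object of class `occupancy_map`: integer count matrix (rows = x
#'   cells, cols = y cells) plus grid metadata.
#' @export
build_occupancy_map <- function(detections, cameras,
                                grid = list(xlim = c(-3000, 3000),
                                            ylim = c(-3000, 3000),
                                            cell = 100),
                                plane_height_mm = 950,
                                torso_pattern = "hip", conf_min = 0.3) {
  nx <- ceiling(diff(grid$xlim) / grid$cell)
  ny <- ceiling(diff(grid$ylim) / grid$cell)
  counts <- matrix(0L, nx, ny)
  sx <- matrix(0, nx, ny)     # coordinate sums for sub-cell peak refinement
  sy <- matrix(0, nx, ny)
  det <- detections[detections$confidence >= conf_min &
                      detections$confidence > 0 &
                      grepl(torso_pattern, detections$joint), , drop = FALSE]
  for (i in seq_len(nrow(det))) {
    cam <- cameras[[det$camera[i]]]
    r <- backproject(cam, c(det$x[i], det$y[i]))
    if (!r$valid || abs(r$direction[3]) < 1e-9) next
    s <- (plane_height_mm - r$origin[3]) / r$direction[3]
    if (s <= 0) next
    p <- r$origin + s * r$direction
    ix <- floor((p[1] - grid$xlim[1]) / grid$cell) + 1
    iy <- floor((p[2] - grid$ylim[1]) / grid$cell) + 1
    if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny) {
      counts[ix, iy] <- counts[ix, iy] + 1L
      sx[ix, iy] <- sx[ix, iy] + p[1]
      sy[ix, iy] <- sy[ix, iy] + p[2]
    }
  }
  structure(list(counts = counts, sx = sx, sy = sy, grid = grid,
                 plane_height_mm = plane_height_mm),
            class = "occupancy_map")
}

# sum counts over each cell's 3x3 neighbourhood by shift-and-add
neighbourhood_sum <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- m
  out <- matrix(0, nx, ny)
  for (di in 0:2) for (dj in 0:2)
    out <- out + p[di + seq_len(nx), dj + seq_len(ny)]
  out
}

#' Extract candidate-person peaks from an occupancy map
#'
#' Candidate people are local maxima of the 3x3-neighbourhood ray count
#' (plateau ties kept once) at or above a count threshold, refined to the
#' count-weighted centroid of the neighbourhood; peaks within two cells of a
#' stronger peak are suppressed.
#'
#' @param map An `occupancy_map`.
#' @param min_count Minimum neighbourhood ray count for a peak (default 3).
#' @return Data frame `x, y, count` (mm, ground plane), strongest first.
#' @export
find_occupancy_peaks <- function(map, min_count = 3) {
  m <- map$counts
  S <- neighbourhood_sum(m)
  nx <- nrow(m); ny <- ncol(m)
  cand <- which(S >= min_count, arr.ind = TRUE)
  peaks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    i0 <- max(1, i - 1); i1 <- min(nx, i + 1)
    j0 <- max(1, j - 1); j1 <- min(ny, j + 1)
    nb <- S[i0:i1, j0:j1]
    if (S[i, j] < max(nb)) next
    idx <- which(nb == S[i, j], arr.ind = TRUE)
    first <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE][1, ]
    if (!(i0 + first[1] - 1 == i && j0 + first[2] - 1 == j)) next
    ws <- sum(m[i0:i1, j0:j1])
    if (ws == 0) next
    peaks[[length(peaks) + 1]] <- data.frame(
      x = sum(map$sx[i0:i1, j0:j1]) / ws,
      y = sum(map$sy[i0:i1, j0:j1]) / ws,
      count = S[i, j], i = i, j = j)
  }
  if (length(peaks) == 0) return(data.frame(x = numeric(), y = numeric(),
                                            count = numeric()))
  out <- do.call(rbind, peaks)
  out <- out[order(-out$count), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (a in seq_len(nrow(out))) {
    if (!keep[a]) next
    later <- which(keep & seq_len(nrow(out)) > a)
    close <- later[pmax(abs(out$i[later] - out$i[a]),
                        abs(out$j[later] - out$j[a])) <= 2]
    keep[close] <- FALSE
  }
  out <- out[keep, c("x", "y", "count"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate occupancy peaks across frames into person tracks
#'
#' Greedy nearest-neighbour linkage on ground-plane position with a maximum
#' per-frame jump; unmatched peaks start new tracks, tracks unmatched in a
#' frame terminate (no coasting).
#'
#' @param peaks_by_frame List (one element per frame) of peak data frames
#'   from [find_occupancy_peaks()].
#' @param max_jump_mm Linkage gate in mm per frame (default 100).
#' @return Data frame `frame, track, x, y`; track ids are stable integers.
#' @export
associate_people <- function(peaks_by_frame, max_jump_mm = 100) {
  rows <- list()
  active <- data.frame(track = integer(), x = numeric(), y = numeric())
  next_id <- 1L
  for (f in seq_along(peaks_by_frame)) {
    pk <- peaks_by_frame[[f]]
    matched <- data.frame(track = integer(), x = numeric(), y = numeric())
    if (nrow(pk) > 0) {
      assigned <- rep(NA_integer_, nrow(pk))
      if (nrow(active) > 0) {
        d <- sqrt(outer(pk$x, active$x, "-")^2 + outer(pk$y, active$y, "-")^2)
        repeat {
          mn <- min(d)
          if (!is.finite(mn) || mn > max_jump_mm) break
          best <- which(d == mn, arr.ind = TRUE)[1, , drop = TRUE]
          assigned[best[1]] <- active$track[best[2]]
          d[best[1], ] <- Inf
          d[, best[2]] <- Inf
        }
      }
      for (a in seq_len(nrow(pk))) {
        if (is.na(assigned[a])) {
          assigned[a] <- next_id
          next_id <- next_id + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(frame = f, track = assigned[a],
                                               x = pk$x[a], y = pk$y[a])
        matched <- rbind(matched, data.frame(track = assigned[a],
                                             x = pk$x[a], y = pk$y[a]))
      }
    }
    active <- matched
  }
  if (length(rows) == 0) return(data.frame(frame = integer(),
                                           track = integer(),
                                           x = numeric(), y = numeric()))
  do.call(rbind, rows)
}

#' Select the subject track
#'
#' The study participant is taken as the longest track; ties are resolved by
#' smaller mean ground-plane distance to the volume centre.
#'
#' @param tracks Output of [associate_people()].
#' @param centre Volume centre `(x, y)` in mm (default origin).
#' @return The subject's rows of `tracks`.
#' @export
subject_track <- function(tracks, centre = c(0, 0)) {
  if (nrow(tracks) == 0) stop("subject_track: no tracks")
  stats_by <- lapply(split(tracks, tracks$track), function(g)
    c(len = nrow(g),
      dist = mean(sqrt((g$x - centre[1])^2 + (g$y - centre[2])^2))))
  st <- do.call(rbind, stats_by)
  ids <- as.integer(names(stats_by))
  best <- ids[order(-st[, "len"], st[, "dist"])][1]
  tracks[tracks$track == best, , drop = FALSE]
}
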