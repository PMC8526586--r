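#' 3D joint-centre trajectory
#'
#' A per-joint time series of 3D positions (mm) on a fixed-rate clock with a
#' validity mask. Frames masked invalid carry no position claim (their rows
#' may be `NA`).
#'
#' @param positions T x 3 numeric matrix (mm).
#' @param valid Logical vector of length T (default: rows with no `NA`).
#' @param joint Joint name.
#' @param rate Sample rate in Hz (default 200).
#' @param offset Integer frame offset of this trajectory's clock relative to
#'   the reference clock (default 0).
#' @return Object of class `trajectory3d`.
#' @export
trajectory3d <- function(positions, valid = NULL, joint = "joint",
                         rate = 200, offset = 0L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("trajectory3d: positions must be T x 3")
  if (is.null(valid)) valid <- stats::complete.cases(positions)
  if (length(valid) != nrow(positions))
    stop("trajectory3d: validity mask length mismatch")
  if (rate <= 0) stop("trajectory3d: sample rate must be positive")
  positions[!valid, ] <- NA_real_
  colnames(positions) <- c("x", "y", "z")
  structure(list(joint = joint, positions = positions,
                 valid = as.logical(valid), rate = rate,
                 offset = as.integer(offset)),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d %s> %d frames @ %g Hz, %d valid (%.1f%%)\n",
              x$joint, nrow(x$positions), x$rate, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
length.trajectory3d <- function(x) nrow(x$positions)

#' Write / read joint trajectories as CSV
#'
#' Long format `frame, joint, x, y, z, valid`; masked frames are written with
#' empty coordinates and restored as masked, so the round trip is lossless at
#' full double precision.
#'
#' @param trajectories Named list of `trajectory3d` (equal lengths and rates).
#' @param path Output file.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  if (length(trajectories) == 0)
    stop("write_trajectories_csv: empty trajectory set (", path, ")")
  rates <- vapply(trajectories, `[[`, numeric(1), "rate")
  lens <- vapply(trajectories, length, integer(1))
  if (length(unique(rates)) != 1 || length(unique(lens)) != 1)
    stop("write_trajectories_csv: inconsistent lengths or rates (", path, ")")
  rows <- lapply(trajectories, function(tr) {
    data.frame(frame = seq_len(length(tr)), joint = tr$joint,
               x = tr$positions[, 1], y = tr$positions[, 2],
               z = tr$positions[, 3], valid = tr$valid)
  })
  df <- do.call(rbind, rows)
  df$rate <- rates[[1]]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_trajectories_csv: failed writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @return `read_trajectories_csv` returns a named list of `trajectory3d`.
#' @export
read_trajectories_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("read_trajectories_csv: failed reading ", path, ": ",
         conditionMessage(e)))
  out <- lapply(split(df, df$joint), function(g) {
    g <- g[order(g$frame), ]
    trajectory3d(cbind(g$x, g$y, g$z), valid = as.logical(g$valid),
                 joint = as.character(g$joint[1]),
                 rate = if ("rate" %in% names(g)) g$rate[1] else 200)
  })
  out[unique(as.character(df$joint))]
}
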