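#' Rigid least-squares alignment of paired point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum_i ||R p_i + t - q_i||^2` (no scaling) by the orthogonal-Procrustes /
#' Kabsch SVD solution. Used to align the markerless system's Euclidean space
#' onto the marker-based system's from a shared single-marker trial.
#'
#' @param source n x 3 matrix of source points (mm), n >= 3, non-collinear.
#' @param target n x 3 matrix of paired target points (mm).
#' @return Object of class `rigid_transform`: `rotation` (3x3), `translation`
#'   (mm) and `rms` residual (mm).
#' @export
estimate_rigid_transform <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(source) != nrow(target))
    stop("estimate_rigid_transform: need >= 3 paired points")
  cs <- colMeans(source); ct <- colMeans(target)
  P <- sweep(source, 2, cs); Q <- sweep(target, 2, ct)
  sv <- svd(crossprod(P, Q))          # H = P'Q, R = V S U' with det fix
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("estimate_rigid_transform: degenerate (collinear) point configuration")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- unname(ct - as.numeric(R %*% cs))
  res <- sweep(source %*% t(R), 2, t, "+") - target
  # rms over coordinate residuals: equals the per-axis noise SD for
  # isotropic perturbations
  structure(list(rotation = R, translation = t,
                 rms = sqrt(mean(res^2))),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a trajectory
#' @param tf A `rigid_transform`.
#' @param x n x 3 matrix, length-3 vector, or `trajectory3d`.
#' @return Transformed object of the same shape.
#' @export
apply_rigid_transform <- function(tf, x) {
  if (inherits(x, "trajectory3d")) {
    p <- x$positions
    p[x$valid, ] <- sweep(p[x$valid, , drop = FALSE] %*% t(tf$rotation),
                          2, tf$translation, "+")
    return(trajectory3d(p, x$valid, x$joint, x$rate, x$offset))
  }
  p <- if (is.matrix(x)) x else matrix(x, 1, 3)
  out <- sweep(p %*% t(tf$rotation), 2, tf$translation, "+")
  if (is.matrix(x)) out else as.numeric(out)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rms %.4g mm, t = (%.2f, %.2f, %.2f)\n",
              x$rms, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Wand reconstruction-accuracy check
#'
#' A wand of known length is moved through the volume; both endpoints are
#' tracked. Per valid frame the resultant endpoint-to-endpoint distance is
#' compared to the known length; the mean and SD of the error over valid
#' frames summarise the system's reconstruction accuracy.
#'
#' @param endpoint_a,endpoint_b `trajectory3d` objects of equal length.
#' @param known_length_mm True wand length (mm).
#' @return List with `mean_error_mm`, `sd_error_mm` and `n` valid frames.
#' @export
wand_accuracy <- function(endpoint_a, endpoint_b, known_length_mm) {
  if (length(endpoint_a) != length(endpoint_b))
    stop("wand_accuracy: endpoint trajectories differ in length")
  ok <- endpoint_a$valid & endpoint_b$valid
  if (!any(ok)) stop("wand_accuracy: no frames with both endpoints valid")
  d <- row_norms(endpoint_a$positions[ok, , drop = FALSE] -
                 endpoint_b$positions[ok, , drop = FALSE])
  err <- d - known_length_mm
  list(mean_error_mm = mean(err),
       sd_error_mm = if (sum(ok) > 1) stats::sd(err) else 0,
       n = sum(ok))
}

#' Estimate the integer frame offset between two synchronised recordings
#'
#' Maximises the cross-correlation of a signal recorded by both systems
#' (a flashing LED in the shared volume) over integer lags. A positive lag
#' means `signal_b` starts `lag` frames later than `signal_a`.
#'
#' @param signal_a,signal_b Numeric vectors (e.g. binary flash states).
#' @param max_lag Maximum |lag| searched (default 50 frames).
#' @return Integer lag.
#' @export
estimate_frame_offset <- function(signal_a, signal_b, max_lag = 50L) {
  a <- signal_a - mean(signal_a)
  b <- signal_b - mean(signal_b)
  lags <- seq(-max_lag, max_lag)
  score <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(a), length(b) - l)
      if (n < 2) return(-Inf)
      sum(a[seq_len(n)] * b[seq_len(n) + l])
    } else {
      n <- min(length(a) + l, length(b))
      if (n < 2) return(-Inf)
      sum(a[seq_len(n) - l] * b[seq_len(n)])
    }
  }, numeric(1))
  as.integer(lags[which.max(score)])
}
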