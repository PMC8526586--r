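#' Bi-directional Kalman smoothing of a joint trajectory
#'
#' Zero-lag smoothing of each coordinate axis with a constant-velocity
#' Kalman filter run forward and backward in time, the two passes fused by
#' their information (inverse covariance). The state is per-axis position and
#' velocity with a time step of one frame (`dt = 1`, velocities in
#' mm/frame): transition
#' `A = [[1, 1], [0, 1]]`, continuous white-noise-acceleration process
#' covariance `Q = q [[1/3, 1/2], [1/2, 1]]`, position-only measurements
#' with variance `r`. The forward pass is initialised at the
#' first valid frame with the measured position, zero velocity, and prior
#' covariance `diag(r, 1e6)`; the backward pass starts from zero information.
#' This two-filter fusion is algebraically identical to a fixed-interval
#' (Rauch-Tung-Striebel) smoother on gap-free input.
#'
#' Masked frames are bridged by prediction only; interior gaps longer than
#' `max_gap_s` seconds, and any frames before the first or after the last
#' valid sample, remain masked in the output. A fully masked trajectory is
#' returned unchanged.
#'
#' @param traj A `trajectory3d`.
#' @param q Process noise intensity (mm^2/frame^2 scale; default 1).
#' @param r Measurement noise variance (mm^2; default 25).
#' @param max_gap_s Longest gap bridged as valid output (default 0.25 s).
#' @return A smoothed `trajectory3d`.
#' @export
bidirectional_kalman <- function(traj, q = 1, r = 25, max_gap_s = 0.25) {
  if (q <= 0 || r <= 0) stop("bidirectional_kalman: q and r must be positive")
  valid <- traj$valid
  if (!any(valid)) return(traj)
  A <- matrix(c(1, 0, 1, 1), 2, 2)        # dt = 1 frame
  Q <- q * matrix(c(1 / 3, 1 / 2, 1 / 2, 1), 2, 2)
  first <- which(valid)[1]
  last <- max(which(valid))
  span <- first:last
  y <- traj$positions[span, , drop = FALSE]
  vmask <- valid[span]
  n <- length(span)

  smooth_axis <- function(ya) {
    # forward constant-velocity filter
    xf <- matrix(NA_real_, n, 2)
    Pf <- array(NA_real_, c(2, 2, n))
    x <- c(ya[1], 0)
    P <- diag(c(r, 1e6))
    xf[1, ] <- x; Pf[, , 1] <- P
    for (k in seq_len(n)[-1]) {
      x <- A %*% x
      P <- A %*% P %*% t(A) + Q
      if (vmask[k]) {
        S <- P[1, 1] + r
        K <- P[, 1] / S
        x <- x + K * (ya[k] - x[1])
        P <- P - outer(K, P[1, ])
      }
      xf[k, ] <- x; Pf[, , k] <- P
    }
    # backward information filter + fusion with the forward pass
    out <- numeric(n)
    Sb <- matrix(0, 2, 2)   # information about x_k from y_{k+1..n}
    zb <- c(0, 0)
    for (k in n:1) {
      Pfi <- solve(Pf[, , k])
      xs <- solve(Pfi + Sb, Pfi %*% xf[k, ] + zb)
      out[k] <- xs[1]
      # absorb measurement k, then pass the information through the dynamics
      Sm <- Sb; zm <- zb
      if (vmask[k]) {
        Sm[1, 1] <- Sm[1, 1] + 1 / r
        zm[1] <- zm[1] + ya[k] / r
      }
      if (k > 1) {
        B <- solve(diag(2) + Sm %*% Q)
        Sb <- t(A) %*% B %*% Sm %*% A
        Sb <- (Sb + t(Sb)) / 2
        zb <- as.numeric(t(A) %*% B %*% zm)
      }
    }
    out
  }

  pos <- matrix(NA_real_, length(traj$valid), 3)
  for (a in 1:3) pos[span, a] <- smooth_axis(y[, a])

  # bridge only short interior gaps
  out_valid <- logical(length(valid))
  out_valid[span] <- TRUE
  max_gap <- round(max_gap_s * traj$rate)
  rl <- rle(vmask)
  pos_end <- cumsum(rl$lengths)
  for (i in seq_along(rl$lengths)) {
    if (!rl$values[i] && rl$lengths[i] > max_gap) {
      gap <- (pos_end[i] - rl$lengths[i] + 1):pos_end[i]
      out_valid[span[gap]] <- FALSE
    }
  }
  pos[!out_valid, ] <- NA_real_
  trajectory3d(pos, out_valid, traj$joint, traj$rate, traj$offset)
}
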