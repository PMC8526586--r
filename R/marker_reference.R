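#' Zero-phase Butterworth low-pass filtering
#'
#' Forward-backward (zero-phase) application of a Butterworth low-pass
#' filter, the conventional conditioning of marker trajectories before joint
#' centres are computed. Defaults: 4th order, 12 Hz cut-off at 200 Hz. The
#' two passes square the magnitude response, so a sinusoid at the cut-off is
#' attenuated to ~0.5 of its amplitude while the DC gain is exactly 1.
#' Edge transients are suppressed by odd-reflection padding (three cut-off
#' periods) before `signal::filtfilt`.
#'
#' @param x Numeric vector, T x d matrix, or `trajectory3d` (must be
#'   gap-free; fill gaps upstream).
#' @param cutoff Cut-off frequency, Hz (default 12).
#' @param order Filter order per pass (default 4).
#' @param rate Sample rate, Hz (default 200); must exceed `2 * cutoff`.
#' @return Filtered object of the same shape.
#' @export
butterworth_lowpass <- function(x, cutoff = 12, order = 4, rate = 200) {
  if (rate <= 2 * cutoff)
    stop("butterworth_lowpass: rate must exceed twice the cut-off")
  if (inherits(x, "trajectory3d")) {
    if (!all(x$valid))
      stop("butterworth_lowpass: trajectory has gaps; fill before filtering")
    return(trajectory3d(butterworth_lowpass(x$positions, cutoff, order, rate),
                        x$valid, x$joint, x$rate, x$offset))
  }
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(m)
  settle <- ceiling(rate / cutoff)
  if (n < 3 * settle)
    stop("butterworth_lowpass: signal shorter than 3x the filter settle length (",
         3 * settle, " samples)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  npad <- min(n - 1, 3 * settle)
  out <- apply(m, 2, function(col) {
    mu <- mean(col)          # centre so the DC component passes untouched
    col <- col - mu
    head_pad <- 2 * col[1] - col[(npad + 1):2]
    tail_pad <- 2 * col[n] - col[(n - 1):(n - npad)]
    y <- signal::filtfilt(bf, c(head_pad, col, tail_pad))
    y[(npad + 1):(npad + n)] + mu
  })
  if (is.matrix(x)) out else as.numeric(out)
}

#' Joint centre as the medial/lateral marker midpoint
#'
#' The reference model's joint centres (all joints except the hip) are the
#' point 50% between the medial and the lateral marker of the joint.
#'
#' @param medial,lateral `trajectory3d` objects of equal length.
#' @return A `trajectory3d`, valid only where both inputs are valid.
#' @export
midpoint_joint_centre <- function(medial, lateral) {
  if (length(medial) != length(lateral))
    stop("midpoint_joint_centre: trajectories differ in length")
  valid <- medial$valid & lateral$valid
  pos <- (medial$positions + lateral$positions) / 2
  trajectory3d(pos, valid, sub("_(med|lat)[a-z]*$", "", medial$joint),
               medial$rate, medial$offset)
}

#' Hip-centre regression coefficients
#'
#' Fractions of the inter-ASIS distance by which each hip joint centre is
#' offset from its ASIS marker, after the Bell et al. regression approach.
#' A single source of truth: change here (or pass explicitly) to use a
#' different calibration.
#'
#' @return Named numeric vector: `medial`, `posterior`, `inferior`.
#' @export
bell_hip_coefficients <- function() {
  c(medial = 0.36, posterior = 0.22, inferior = 0.30)
}

#' Hip joint centres from pelvis markers (Bell regression)
#'
#' Builds a pelvis anatomical frame (origin at the ASIS midpoint, lateral
#' axis along the ASIS line, anterior axis from the sacrum towards the ASIS
#' midpoint, superior axis completing the right-handed triad) and offsets
#' each hip centre from its ASIS by fixed fractions of the inter-ASIS
#' distance: medial, posterior and inferior along the pelvis axes.
#'
#' @param asis_left,asis_right,sacrum Pelvis marker `trajectory3d`s.
#' @param coefficients Named fractions (see [bell_hip_coefficients()]).
#' @return List with `left` and `right` hip-centre `trajectory3d`s.
#' @export
bell_hip_centre <- function(asis_left, asis_right, sacrum,
                            coefficients = bell_hip_coefficients()) {
  n <- length(asis_left)
  if (length(asis_right) != n || length(sacrum) != n)
    stop("bell_hip_centre: marker trajectories differ in length")
  valid <- asis_left$valid & asis_right$valid & sacrum$valid
  L <- matrix(NA_real_, n, 3); R <- matrix(NA_real_, n, 3)
  for (f in which(valid)) {
    al <- asis_left$positions[f, ]; ar <- asis_right$positions[f, ]
    sc <- sacrum$positions[f, ]
    lat <- ar - al
    d <- sqrt(sum(lat^2))
    if (d < 1e-6) stop("bell_hip_centre: degenerate pelvis (ASIS coincident)")
    lat <- lat / d
    mid <- (al + ar) / 2
    ant0 <- mid - sc
    sup <- cross3(lat, ant0)
    ns <- sqrt(sum(sup^2))
    if (ns < 1e-9) stop("bell_hip_centre: degenerate pelvis (sacrum collinear with ASIS line)")
    sup <- sup / ns
    ant <- cross3(sup, lat)
    off_common <- -coefficients["posterior"] * d * ant -
      coefficients["inferior"] * d * sup
    L[f, ] <- al + coefficients["medial"] * d * lat + off_common
    R[f, ] <- ar - coefficients["medial"] * d * lat + off_common
  }
  list(left = trajectory3d(L, valid, "hip_l", asis_left$rate),
       right = trajectory3d(R, valid, "hip_r", asis_left$rate))
}
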