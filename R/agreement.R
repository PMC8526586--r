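#' Per-sample 3D Euclidean differences between two trajectories
#'
#' @param traj_a,traj_b `trajectory3d` objects of equal length (A is the
#'   markerless estimate, B the marker-based reference by convention).
#' @return Numeric vector of distances (mm), one per common valid frame,
#'   with the frame indices as an attribute.
#' @export
euclidean_differences <- function(traj_a, traj_b) {
  if (length(traj_a) != length(traj_b))
    stop("euclidean_differences: trajectories differ in length")
  ok <- traj_a$valid & traj_b$valid
  if (!any(ok)) stop("euclidean_differences: no common valid frames")
  d <- row_norms(traj_a$positions[ok, , drop = FALSE] -
                 traj_b$positions[ok, , drop = FALSE])
  structure(d, frames = which(ok))
}

#' Per-axis signed differences between two trajectories
#'
#' Sign convention is A minus B: with A the markerless estimate and B the
#' marker reference, a negative Z difference means the markerless joint
#' centre sits below the reference.
#'
#' @inheritParams euclidean_differences
#' @return n x 3 matrix of signed differences (mm, columns x/y/z) over common
#'   valid frames, frame indices as an attribute.
#' @export
axis_differences <- function(traj_a, traj_b) {
  if (length(traj_a) != length(traj_b))
    stop("axis_differences: trajectories differ in length")
  ok <- traj_a$valid & traj_b$valid
  if (!any(ok)) stop("axis_differences: no common valid frames")
  d <- traj_a$positions[ok, , drop = FALSE] -
    traj_b$positions[ok, , drop = FALSE]
  colnames(d) <- c("x", "y", "z")
  attr(d, "frames") <- which(ok)
  d
}

#' Bland-Altman agreement with a normality-gated choice of limits
#'
#' Bias is the mean difference and the random error its SD. The 95% limits
#' of agreement are parametric (`bias +/- 1.96 SD`) when a Shapiro-Wilk test
#' does not reject normality at `alpha`, and non-parametric (the 5th and
#' 95th percentiles of the differences, linear interpolation between order
#' statistics, i.e. `stats::quantile` type 7) otherwise. Shapiro-Wilk is
#' limited to 5000 observations; longer vectors are gated on a deterministic
#' evenly spaced subsample of 5000.
#'
#' @param differences Numeric vector of differences (n >= 3, finite).
#' @param alpha Normality test level (default 0.05).
#' @param force_method Override the gate: `"parametric"` or
#'   `"nonparametric"` (default `NULL`, gate decides).
#' @return Object of class `agreement_result`: `bias`, `sd`, `loa_lower`,
#'   `loa_upper`, `loa_method`, `shapiro_w`, `shapiro_p`, `n`.
#' @export
bland_altman <- function(differences, alpha = 0.05, force_method = NULL) {
  d <- as.numeric(differences)
  if (length(d) < 3 || any(!is.finite(d)))
    stop("bland_altman: need >= 3 finite differences")
  sw <- local({
    ds <- if (length(d) > 5000)
      d[round(seq(1, length(d), length.out = 5000))] else d
    if (stats::sd(ds) == 0) list(statistic = NA_real_, p.value = NA_real_)
    else stats::shapiro.test(ds)
  })
  method <- if (!is.null(force_method)) force_method
            else if (!is.na(sw$p.value) && sw$p.value < alpha) "nonparametric"
            else "parametric"
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- if (method == "parametric") c(bias - 1.96 * s, bias + 1.96 * s)
         else unname(stats::quantile(d, c(0.05, 0.95), type = 7))
  structure(list(bias = bias, sd = s, loa_lower = loa[1], loa_upper = loa[2],
                 loa_method = method, shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value, n = length(d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement> bias %.2f mm, SD %.2f mm, 95%% LoA [%.2f, %.2f] (%s, n=%d)\n",
              x$bias, x$sd, x$loa_lower, x$loa_upper, x$loa_method, x$n))
  invisible(x)
}

#' Linear-regression waveform comparison
#'
#' Ordinary least squares of waveform B on waveform A. R^2 measures the
#' strength of the linear relationship, the intercept the offset between the
#' waveforms, and the gradient the scaling of one relative to the other.
#'
#' @param wave_a Predictor waveform (e.g. marker-based), non-constant.
#' @param wave_b Response waveform (e.g. markerless), equal length.
#' @return Object of class `regression_result`: `r_squared`, `intercept`
#'   (mm), `gradient`.
#' @export
regression_compare <- function(wave_a, wave_b) {
  if (length(wave_a) != length(wave_b))
    stop("regression_compare: waveforms differ in length")
  va <- stats::var(wave_a)
  if (va == 0) stop("regression_compare: constant predictor, gradient undefined")
  gradient <- stats::cov(wave_a, wave_b) / va
  intercept <- mean(wave_b) - gradient * mean(wave_a)
  resid <- wave_b - (intercept + gradient * wave_a)
  tss <- sum((wave_b - mean(wave_b))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(resid^2) / tss
  structure(list(r_squared = max(0, min(1, r2)), intercept = intercept,
                 gradient = gradient),
            class = "regression_result")
}
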