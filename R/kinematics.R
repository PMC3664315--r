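#' Zero-phase FIR low-pass filtering of a trajectory
#'
#' Designs a windowed-sinc (Hamming) linear-phase FIR low-pass filter and
#' applies it forward and backward, so the output has exactly zero phase and
#' segment boundaries stay aligned with the time stamps. The linear-phase
#' design has its -6 dB point at the cutoff frequency; the two-pass
#' application doubles that attenuation. Motion-capture recordings at 240 Hz
#' are conventionally smoothed with a 50-tap 6 Hz filter before computing
#' differential invariants.
#'
#' @param traj A [trajectory()].
#' @param cutoff_hz Cutoff frequency in Hz (must be below Nyquist).
#' @param n_taps Number of filter taps (must be smaller than the number of
#'   samples).
#' @return A filtered [trajectory()] of identical length and time stamps.
#' @details Edge effects are controlled by odd (point-mirror) reflection
#'   padding, as in conventional zero-phase filtering. A constant signal
#'   passes unchanged (unit DC gain).
#' @export
lowpass_filter <- function(traj, cutoff_hz = 6, n_taps = 50L) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_samples(traj)
  fs <- traj$sample_rate
  if (n_taps >= n)
    stop("trajectory too short to filter: need more than n_taps = ", n_taps,
         " samples, got ", n, call. = FALSE)
  if (cutoff_hz >= fs / 2)
    stop("cutoff must be below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  h <- fir_lowpass_taps(n_taps, cutoff_hz, fs)
  out <- apply(traj$positions, 2L, filtfilt_fir, h = h)
  trajectory(traj$times, out, sample_rate = fs)
}

## Hamming-windowed sinc taps, unit DC gain.
fir_lowpass_taps <- function(n_taps, cutoff_hz, fs) {
  n_taps <- as.integer(n_taps)
  stopifnot(n_taps >= 4L)
  m <- seq_len(n_taps) - 1
  center <- (n_taps - 1) / 2
  fc <- cutoff_hz / fs                    # normalized cutoff (cycles/sample)
  x <- 2 * fc * (m - center)
  h <- 2 * fc * ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * m / (n_taps - 1))
  h <- h * w
  h / sum(h)
}

## Forward-backward application of a causal FIR with odd-reflection padding.
filtfilt_fir <- function(x, h) {
  n <- length(x)
  p <- 3L * length(h)
  if (p >= n) p <- n - 1L
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(left, x, right)
  f1 <- stats::filter(xp, h, method = "convolution", sides = 1)
  f2 <- rev(stats::filter(rev(f1), h, method = "convolution", sides = 1))
  as.numeric(f2[(p + 1):(p + n)])
}

## First and second time derivatives of each coordinate.
## scheme "spline": cubic interpolating spline, analytic derivatives
## (continuous 2nd derivative, as curvature needs).
## scheme "central": 2nd-order central differences, one-sided at the ends.
trajectory_derivatives <- function(traj, scheme = c("spline", "central")) {
  scheme <- match.arg(scheme)
  tt <- traj$times
  P <- traj$positions
  if (scheme == "spline") {
    d1 <- matrix(0, nrow(P), ncol(P))
    d2 <- d1
    for (j in seq_len(ncol(P))) {
      f <- stats::splinefun(tt, P[, j], method = "fmm")
      d1[, j] <- f(tt, deriv = 1L)
      d2[, j] <- f(tt, deriv = 2L)
    }
  } else {
    dt <- 1 / traj$sample_rate
    n <- nrow(P)
    d1 <- (P[c(2:n, n), , drop = FALSE] - P[c(1, 1:(n - 1)), , drop = FALSE]) /
      (dt * c(1, rep(2, n - 2), 1))
    d2 <- (P[c(2:n, n), , drop = FALSE] - 2 * P +
             P[c(1, 1:(n - 1)), , drop = FALSE]) / dt^2
    ## one-sided second differences at the ends
    d2[1, ] <- (P[3, ] - 2 * P[2, ] + P[1, ]) / dt^2
    d2[n, ] <- (P[n, ] - 2 * P[n - 1, ] + P[n - 2, ]) / dt^2
  }
  list(velocity = d1, acceleration = d2)
}

#' Per-sample speed and Euclidean curvature of a trajectory
#'
#' Computes the differential invariants used throughout the package: the
#' Euclidean speed v(t) = ||dr/dt|| and the Euclidean curvature
#' kappa(t) = ||r' x r''|| / ||r'||^3, the reciprocal of the radius of the
#' osculating circle. Samples where the speed is below `1e-6` times the
#' maximum speed have undefined curvature and are flagged invalid rather
#' than silently zeroed.
#'
#' @param traj A [trajectory()] with 3 coordinates.
#' @param scheme Differentiation scheme: `"spline"` (default; analytic
#'   derivatives of a cubic interpolating spline) or `"central"` (central
#'   differences).
#' @return An object of class `kinematic_profile`: list with `times`,
#'   `speed` (cm/s), `curvature` (1/cm, `NA` where invalid), `valid`
#'   (logical) and `sample_rate`.
#' @export
kinematic_profile <- function(traj, scheme = c("spline", "central")) {
  stopifnot(inherits(traj, "trajectory"))
  if (ncol(traj$positions) != 3L)
    stop("curvature requires 3 coordinates", call. = FALSE)
  d <- trajectory_derivatives(traj, scheme)
  v <- d$velocity
  a <- d$acceleration
  speed <- sqrt(rowSums(v^2))
  cr <- cbind(v[, 2] * a[, 3] - v[, 3] * a[, 2],
              v[, 3] * a[, 1] - v[, 1] * a[, 3],
              v[, 1] * a[, 2] - v[, 2] * a[, 1])
  valid <- speed > 1e-6 * max(speed)
  if (!any(valid))
    stop("degenerate input: speed is (numerically) zero at every sample, ",
         "curvature undefined", call. = FALSE)
  curv <- rep(NA_real_, length(speed))
  curv[valid] <- sqrt(rowSums(cr[valid, , drop = FALSE]^2)) / speed[valid]^3
  structure(list(times = traj$times, speed = speed, curvature = curv,
                 valid = valid, sample_rate = traj$sample_rate),
            class = "kinematic_profile")
}

#' @export
print.kinematic_profile <- function(x, ...) {
  cat(sprintf(paste0("kinematic_profile: %d samples, speed %.3g-%.3g cm/s, ",
                     "curvature %.3g-%.3g 1/cm (%d invalid)\n"),
              length(x$speed), min(x$speed), max(x$speed),
              min(x$curvature, na.rm = TRUE), max(x$curvature, na.rm = TRUE),
              sum(!x$valid)))
  invisible(x)
}

#' Per-sample speed
#' @inheritParams kinematic_profile
#' @return Numeric vector of speeds (cm/s), one per sample.
#' @export
compute_speed <- function(traj, scheme = c("spline", "central")) {
  d <- trajectory_derivatives(traj, match.arg(scheme))
  sqrt(rowSums(d$velocity^2))
}

#' Per-sample Euclidean curvature
#' @inheritParams kinematic_profile
#' @return Numeric vector of curvatures (1/cm); `NA` at invalid (near-zero
#'   speed) samples.
#' @export
compute_curvature <- function(traj, scheme = c("spline", "central")) {
  kinematic_profile(traj, scheme)$curvature
}

#' Export a kinematic profile to CSV
#' @param profile A [kinematic_profile()].
#' @param path Output file path; columns `t,speed,curvature,valid`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(t = profile$times, speed = profile$speed,
                   curvature = profile$curvature,
                   valid = as.integer(profile$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Power-law compliance score
#'
#' The compliance of observed speeds with a predicted speed profile:
#' `1 - sum((v - v_hat)^2) / sum((v - mean(v))^2)`, the coefficient of
#' determination about the segment-mean speed. May be negative when the
#' prediction is worse than the mean.
#'
#' @param v Observed speeds.
#' @param v_hat Predicted speeds (same length).
#' @return Compliance score (dimensionless, `<= 1`).
#' @export
compliance_r2 <- function(v, v_hat) {
  if (length(v) != length(v_hat) || length(v) < 2L)
    stop("v and v_hat must have equal length >= 2", call. = FALSE)
  sst <- sum((v - mean(v))^2)
  if (sst == 0)
    stop("compliance undefined: observed speed is constant", call. = FALSE)
  1 - sum((v - v_hat)^2) / sst
}

#' Fit a generalized speed-curvature power law to a segment
#'
#' Fits v = alpha * kappa^beta by bound-constrained least squares in the
#' original (not log) space. The gain alpha is profiled out in closed form
#' for each beta (the model is linear in alpha), so the optimization reduces
#' to a 1D search over beta, seeded by a coarse grid and an ordinary
#' least-squares fit of log v on log kappa.
#'
#' @param profile A [kinematic_profile()].
#' @param interval Sample index range, either `c(from, to)` or a vector of
#'   indices (its range is used).
#' @param beta_bounds Box constraint for the exponent; default `c(-1, 0)`,
#'   the range within which the generalized power law of natural movements
#'   lives.
#' @return An object of class `power_law_fit`: `alpha_hat`, `beta_hat`,
#'   `r_squared` (compliance), `v_average` (mean segment speed), `n_used`,
#'   `at_bound` (TRUE if the fitted beta lies on a bound) and `interval`.
#' @details Samples flagged invalid by the kinematic profile (near-zero
#'   speed) are excluded from the regression. All curvatures used must be
#'   strictly positive. If the observed speed is exactly constant the
#'   compliance is reported as 1 when the fit is exact (a constant law
#'   reproduces it), since the usual denominator vanishes.
#' @export
fit_power_law <- function(profile, interval = NULL, beta_bounds = c(-1, 0)) {
  stopifnot(inherits(profile, "kinematic_profile"))
  n <- length(profile$speed)
  if (is.null(interval)) interval <- c(1L, n)
  from <- min(interval); to <- max(interval)
  stopifnot(from >= 1L, to <= n)
  idx <- (from:to)[profile$valid[from:to]]
  if (length(idx) < 5L)
    stop("interval must contain at least 5 valid samples (got ",
         length(idx), ")", call. = FALSE)
  v <- profile$speed[idx]
  k <- profile$curvature[idx]
  bad <- which(k <= 0 | !is.finite(k))
  if (length(bad) > 0L)
    stop("non-positive curvature in interval at sample ", idx[bad[1]],
         "; power-law regression needs kappa > 0", call. = FALSE)

  ## alpha profiled out: for fixed beta, SSE is minimized by
  ## alpha(beta) = sum(v * k^beta) / sum(k^(2 beta))
  sse_of_beta <- function(b) {
    kb <- k^b
    al <- sum(v * kb) / sum(kb^2)
    sum((v - al * kb)^2)
  }
  lo <- beta_bounds[1]; hi <- beta_bounds[2]
  grid <- seq(lo, hi, length.out = 41L)
  gs <- vapply(grid, sse_of_beta, numeric(1))
  i0 <- which.min(gs)
  bracket <- c(grid[max(1L, i0 - 1L)], grid[min(length(grid), i0 + 1L)])
  beta_hat <- if (bracket[1] < bracket[2]) {
    opt <- stats::optimize(sse_of_beta, interval = bracket, tol = 1e-10)
    if (opt$objective < gs[i0]) opt$minimum else grid[i0]
  } else grid[i0]
  ## compare against the exact bounds as candidate minima
  for (cand in c(lo, hi))
    if (sse_of_beta(cand) < sse_of_beta(beta_hat)) beta_hat <- cand
  kb <- k^beta_hat
  alpha_hat <- sum(v * kb) / sum(kb^2)
  v_hat <- alpha_hat * kb
  sst <- sum((v - mean(v))^2)
  sse <- sum((v - v_hat)^2)
  r2 <- if (sst > 0) 1 - sse / sst else if (sse <= 1e-12 * sum(v^2)) 1 else NA_real_
  structure(list(alpha_hat = alpha_hat, beta_hat = beta_hat,
                 r_squared = r2, v_average = mean(v), n_used = length(idx),
                 at_bound = min(beta_hat - lo, hi - beta_hat) < 1e-6,
                 interval = c(from, to)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: v = %.4g * kappa^%.4g, R2 = %.4f (n = %d%s)\n",
              x$alpha_hat, x$beta_hat, x$r_squared, x$n_used,
              if (x$at_bound) ", beta at bound" else ""))
  invisible(x)
}
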