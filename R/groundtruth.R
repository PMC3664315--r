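#' Specification for power-law ground-truth synthesis
#'
#' Collects the tunable parameters of the ground-truth generator: a
#' recorded-like trajectory is randomly partitioned into `n_segments`
#' consecutive intervals, each assigned a power-law exponent, and
#' time-warped so that within every segment the speed exactly obeys
#' `v = alpha_i * kappa^beta_i` with speed continuous at the boundaries.
#'
#' @param n_segments Number of consecutive power-law segments N (default 3).
#' @param min_duration Minimum segment duration in seconds (default 0.3).
#' @param beta_gap Minimum absolute difference between adjacent exponents
#'   (default 0.1).
#' @param beta_range Interval from which exponents are drawn uniformly
#'   (default `c(-1, 0)`).
#' @param low_speed_cut Fraction of the maximal speed below which the
#'   initial and terminal parts of the movement are excluded (default 0.15).
#' @param speed_ratio_band Acceptance interval for the per-segment ratio of
#'   maximal warped to maximal original speed (default `c(1/3, 3)`);
#'   draws outside it are rejected as biologically improbable.
#' @param band_limit_hz Spectral budget for the imposed kinematics
#'   (default 6, the low-pass band of the emulated recordings). Draws
#'   whose imposed speed profile would vary faster than this on the warped
#'   clock (log-slope `|beta * d log kappa / d tau|` above `2 pi *
#'   band_limit_hz`) are rejected: the deposited sample rate could not
#'   carry such kinematics, so the synthesized trajectory could not
#'   actually comply with its own law. This happens when a steep exponent
#'   meets a sharp curvature dip, which the warp compresses into a few
#'   samples.
#' @param duration_ratio_band Acceptance interval for the per-segment
#'   ratio of warped to original duration (default `c(0.5, 2)`). The warp
#'   preserves the total duration exactly but individual segments may
#'   stretch or shrink; draws far from duration preservation are rejected
#'   so the synthesized timing stays close to the natural one.
#' @param refit_edge_trim Number of samples excluded at each interior
#'   boundary when refitting a segment's power law (default 4, about 17 ms
#'   at 240 Hz). The boundary samples carry a brief transition that does
#'   not comply with either adjacent law - the speed profile has a kink
#'   there, which finite differentiation smears over a few samples.
#' @param refit_end_trim Number of samples excluded at the two ends of the
#'   whole warped record (default 12, 50 ms). Derivatives at record ends
#'   are one-sided and least accurate; with near-reciprocal exponents the
#'   resulting speed error is several percent, which would be misread as
#'   non-compliance.
#' @param max_iter Maximum number of randomization attempts (default
#'   1000; attempts are cheap because rejected draws are discarded before
#'   the warp is computed).
#' @param seed Optional RNG seed for reproducible synthesis.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_segments = 3L, min_duration = 0.3,
                              beta_gap = 0.1, beta_range = c(-1, 0),
                              low_speed_cut = 0.15,
                              speed_ratio_band = c(1 / 3, 3),
                              band_limit_hz = 6,
                              duration_ratio_band = c(0.5, 2),
                              refit_edge_trim = 4L, refit_end_trim = 12L,
                              max_iter = 1000L, seed = NULL) {
  stopifnot(n_segments >= 1L, min_duration > 0, beta_gap > 0,
            length(beta_range) == 2L, beta_range[1] < beta_range[2],
            low_speed_cut > 0, low_speed_cut < 1,
            length(speed_ratio_band) == 2L,
            speed_ratio_band[1] < speed_ratio_band[2])
  structure(list(n_segments = as.integer(n_segments),
                 min_duration = min_duration, beta_gap = beta_gap,
                 beta_range = beta_range, low_speed_cut = low_speed_cut,
                 speed_ratio_band = speed_ratio_band,
                 band_limit_hz = band_limit_hz,
                 duration_ratio_band = duration_ratio_band,
                 refit_edge_trim = as.integer(refit_edge_trim),
                 refit_end_trim = as.integer(refit_end_trim),
                 max_iter = as.integer(max_iter), seed = seed),
            class = "ground_truth_spec")
}

#' Trim low-speed endpoints of a movement
#'
#' Returns the largest contiguous sample range whose first and last samples
#' are the first and last crossings of the speed above
#' `cut_fraction * max(speed)`. Interior dips below the threshold are
#' retained; only the ends are trimmed. This avoids the power-law
#' singularities at near-rest endpoints.
#'
#' @param profile A [kinematic_profile()].
#' @param cut_fraction Threshold as a fraction of maximal speed, in (0, 1).
#' @return Integer vector `c(from, to)` of sample indices.
#' @export
trim_low_speed <- function(profile, cut_fraction = 0.15) {
  stopifnot(cut_fraction > 0, cut_fraction < 1)
  thr <- cut_fraction * max(profile$speed)
  above <- which(profile$speed >= thr)
  if (length(above) == 0L)
    stop("degenerate input: no sample above ", signif(thr, 4),
         " cm/s (", cut_fraction, " of maximal speed)", call. = FALSE)
  c(above[1], above[length(above)])
}

#' Random partition of a duration into segments
#'
#' Draws `n_segments - 1` interior breakpoints uniformly on `(0, duration)`
#' by rejection until every segment is longer than `min_duration`. Uses the
#' current RNG state, so results are reproducible under `set.seed()`.
#'
#' @param duration Total duration in seconds.
#' @param n_segments Number of segments N.
#' @param min_duration Minimal admissible segment duration (seconds).
#' @param max_iter Rejection cap.
#' @return Sorted numeric vector of `n_segments - 1` interior breakpoint
#'   times in `(0, duration)`.
#' @export
random_partition <- function(duration, n_segments = 3L, min_duration = 0.3,
                             max_iter = 10000L) {
  if (duration <= n_segments * min_duration)
    stop("duration ", duration, " s cannot hold ", n_segments,
         " segments of at least ", min_duration, " s", call. = FALSE)
  if (n_segments == 1L) return(numeric(0))
  for (it in seq_len(max_iter)) {
    br <- sort(stats::runif(n_segments - 1L, 0, duration))
    if (min(diff(c(0, br, duration))) > min_duration) return(br)
  }
  stop("random_partition: no admissible partition in ", max_iter,
       " draws", call. = FALSE)
}

#' Sample power-law exponents with an adjacency gap
#'
#' Draws N exponents i.i.d. uniformly from `beta_range`, resampling until
#' every pair of adjacent values differs by more than `beta_gap`.
#'
#' @param n_segments Number of exponents N.
#' @param beta_range Sampling interval (default `c(-1, 0)`).
#' @param beta_gap Minimal adjacent gap (default 0.1).
#' @return Numeric vector of length N.
#' @export
sample_betas <- function(n_segments = 3L, beta_range = c(-1, 0),
                         beta_gap = 0.1) {
  repeat {
    b <- stats::runif(n_segments, beta_range[1], beta_range[2])
    if (n_segments == 1L || min(abs(diff(b))) > beta_gap) return(b)
  }
}

#' Continuity-constrained power-law gain factors
#'
#' The first gain is set from the empirical speed and curvature at the
#' start of the analyzed range, `alpha_1 = v(0) * kappa(0)^(-beta_1)`; each
#' subsequent gain enforces speed continuity at the segment boundary,
#' `alpha_(i+1) = alpha_i * kappa(t_(i+1))^(beta_i - beta_(i+1))`.
#'
#' @param profile A [kinematic_profile()].
#' @param boundary_idx Sample indices of the interior segment boundaries
#'   (length N-1).
#' @param betas Exponents (length N).
#' @param start_idx Sample index of the start of the analyzed range.
#' @return Numeric vector of N gain factors.
#' @export
compute_alphas <- function(profile, boundary_idx, betas, start_idx = 1L) {
  n <- length(betas)
  stopifnot(length(boundary_idx) == n - 1L)
  k0 <- profile$curvature[start_idx]
  if (!isTRUE(k0 > 0))
    stop("curvature is not positive at the range start; ",
         "re-randomize the partition", call. = FALSE)
  alphas <- numeric(n)
  alphas[1] <- profile$speed[start_idx] * k0^(-betas[1])
  if (n > 1L) for (i in seq_len(n - 1L)) {
    kb <- profile$curvature[boundary_idx[i]]
    if (!isTRUE(kb > 0))
      stop("curvature is not positive at boundary ", i,
           "; re-randomize the partition", call. = FALSE)
    alphas[i + 1] <- alphas[i] * kb^(betas[i] - betas[i + 1])
  }
  alphas
}

## Cumulative trapezoidal integral on a uniform-or-not grid.
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))

#' Time-warp a trajectory onto segment-wise power-law kinematics
#'
#' Reparameterizes the clock of the (trimmed) trajectory so that within each
#' segment the output speed equals `alpha_i * kappa^beta_i` while the
#' spatial path is unchanged. The warp integrates
#' `d tau / d t = v(t) * kappa(t)^(-beta_i) / alpha_i` cumulatively
#' (trapezoidal rule), re-interpolates the positions against tau with cubic
#' splines, and resamples uniformly at the original rate.
#'
#' @param traj A [trajectory()] (typically already low-pass filtered).
#' @param profile Its [kinematic_profile()].
#' @param breakpoints Interior boundary times (seconds, absolute), length
#'   N-1.
#' @param alphas,betas Power-law parameters per segment (length N).
#' @param range_idx Sample range `c(from, to)` to warp (default: all).
#' @param rescale_duration Rescale the warped time axis by one global
#'   factor so its total duration matches the source range (default TRUE).
#'   Continuity and the power-law form are preserved (all gains are divided
#'   by the factor); per-segment durations then match only approximately.
#' @return An object of class `warped_trajectory`: list with `trajectory`
#'   (the warped, uniformly resampled trajectory starting at the source
#'   range start time), `segments` (data frame `t_start`, `t_end`, `alpha`,
#'   `beta` on the warped clock), `source_arclength` (cumulative arc length
#'   of the source range), `tau` (the warp map sampled on the source grid)
#'   and `duration_factor` (the global rescaling applied).
#' @export
time_warp <- function(traj, profile, breakpoints, alphas, betas,
                      range_idx = NULL, rescale_duration = TRUE) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(profile, "kinematic_profile"),
            length(alphas) == length(betas),
            length(breakpoints) == length(betas) - 1L)
  if (is.null(range_idx)) range_idx <- c(1L, n_samples(traj))
  idx <- range_idx[1]:range_idx[2]
  tt <- traj$times[idx]
  v <- profile$speed[idx]
  k <- profile$curvature[idx]
  if (any(!is.finite(k)) || any(k <= 0))
    stop("curvature must be positive and finite over the warped range",
         call. = FALSE)
  seg_of <- findInterval(tt, breakpoints) + 1L   # segment index per sample
  dtau_dt <- v * k^(-betas[seg_of]) / alphas[seg_of]
  tau <- cumtrapz(tt, dtau_dt)
  if (any(diff(tau) <= 0))
    stop("warp map is not strictly increasing (speed vanishes inside a ",
         "segment)", call. = FALSE)
  g <- 1
  if (rescale_duration) {
    g <- (tt[length(tt)] - tt[1]) / tau[length(tau)]
    tau <- tau * g
  }
  dt <- 1 / traj$sample_rate
  t0 <- tt[1]
  new_times <- seq(t0, t0 + tau[length(tau)], by = dt)
  P <- traj$positions[idx, , drop = FALSE]
  out <- vapply(seq_len(ncol(P)), function(j)
    stats::splinefun(t0 + tau, P[, j], method = "fmm")(new_times),
    numeric(length(new_times)))
  bounds <- t0 + c(0, stats::approx(tt, tau, xout = breakpoints)$y,
                   tau[length(tau)])
  segs <- data.frame(t_start = bounds[-length(bounds)],
                     t_end = bounds[-1],
                     alpha = alphas / g, beta = betas)
  structure(list(trajectory = trajectory(new_times, out,
                                         sample_rate = traj$sample_rate),
                 segments = segs,
                 source_arclength = cumtrapz(tt, v),
                 tau = tau, duration_factor = g),
            class = "warped_trajectory")
}

#' @export
print.warped_trajectory <- function(x, ...) {
  cat("warped_trajectory:", nrow(x$segments), "power-law segments\n")
  print(x$segments, digits = 4)
  invisible(x)
}

#' Synthesize a power-law ground-truth trajectory
#'
#' Full randomized synthesis loop: trim low-speed endpoints, draw a random
#' partition and exponents, derive continuity-constrained gains, time-warp,
#' and accept only draws whose per-segment maximal-speed ratio
#' (warped/original) stays inside `spec$speed_ratio_band`. Accepted outputs
#' are refitted segment-by-segment with [fit_power_law()] on the warped
#' kinematics, and the refitted gain, exponent and compliance are stored.
#'
#' @param traj A [trajectory()] (already low-pass filtered; the synthetic
#'   base generator returns filtered trajectories).
#' @param spec A [ground_truth_spec()].
#' @return A `warped_trajectory` whose `segments` data frame additionally
#'   carries `alpha_hat`, `beta_hat` and `r_squared`, with attributes
#'   `n_attempts` and `rejections` (named counts by cause).
#' @export
synthesize_ground_truth <- function(traj, spec = ground_truth_spec()) {
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "ground_truth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  profile <- kinematic_profile(traj)
  rng <- trim_low_speed(profile, spec$low_speed_cut)
  idx <- rng[1]:rng[2]
  tt <- traj$times[idx]
  dur <- tt[length(tt)] - tt[1]
  rej <- c(partition = 0L, curvature = 0L, warp = 0L, speed_ratio = 0L,
           band_limit = 0L, duration = 0L)
  for (it in seq_len(spec$max_iter)) {
    br <- tt[1] + random_partition(dur, spec$n_segments, spec$min_duration)
    betas <- sample_betas(spec$n_segments, spec$beta_range, spec$beta_gap)
    bidx <- rng[1] - 1L + vapply(br, function(b)
      which.min(abs(tt - b)), integer(1))
    alphas <- tryCatch(
      compute_alphas(profile, bidx, betas, start_idx = rng[1]),
      error = function(e) NULL)
    if (is.null(alphas)) { rej["curvature"] <- rej["curvature"] + 1L; next }
    ## per-segment maximal-speed ratio acceptance, evaluated on the
    ## *imposed* speeds alpha_i kappa(t)^beta_i at the source samples:
    ## the induced law is known analytically, and judging it before
    ## resampling also catches spikes too brief for the sample rate to
    ## carry (near-inflection curvature dips under a steep exponent)
    ok <- TRUE
    obounds <- c(tt[1], br, tt[length(tt)])
    seg_of <- findInterval(tt, br) + 1L
    v_imposed <- alphas[seg_of] *
      profile$curvature[idx]^(betas[seg_of])
    for (i in seq_len(spec$n_segments)) {
      osel <- tt >= obounds[i] & tt <= obounds[i + 1]
      ratio <- max(v_imposed[osel]) / max(profile$speed[idx][osel])
      if (ratio < spec$speed_ratio_band[1] ||
          ratio > spec$speed_ratio_band[2]) { ok <- FALSE; break }
    }
    if (!ok) { rej["speed_ratio"] <- rej["speed_ratio"] + 1L; next }
    ## imposed kinematics must stay inside the world's spectral band on
    ## the warped clock: |d log v_imposed / d tau| <= 2 pi band_limit
    kap <- profile$curvature[idx]
    dlogk_dt <- c(0, diff(log(kap))) * traj$sample_rate
    dtau_dt <- profile$speed[idx] * kap^(-betas[seg_of]) / alphas[seg_of]
    logslope <- abs(betas[seg_of] * dlogk_dt / dtau_dt)
    if (max(logslope) > 2 * pi * spec$band_limit_hz) {
      rej["band_limit"] <- rej["band_limit"] + 1L
      next
    }
    wt <- tryCatch(
      time_warp(traj, profile, br, alphas, betas, range_idx = rng),
      error = function(e) NULL)
    if (is.null(wt)) { rej["warp"] <- rej["warp"] + 1L; next }
    ## stay close to duration preservation segment by segment
    dr <- (wt$segments$t_end - wt$segments$t_start) / diff(obounds)
    if (any(dr < spec$duration_ratio_band[1]) ||
        any(dr > spec$duration_ratio_band[2])) {
      rej["duration"] <- rej["duration"] + 1L
      next
    }
    wprof <- kinematic_profile(wt$trajectory)
    ## refit each segment on the warped (self-consistent) kinematics,
    ## dropping the boundary-transition samples at the segment edges
    fits <- lapply(seq_len(spec$n_segments), function(i) {
      sel <- which(wprof$times >= wt$segments$t_start[i] &
                     wprof$times <= wt$segments$t_end[i])
      kl <- if (i == 1L) spec$refit_end_trim else spec$refit_edge_trim
      kr <- if (i == spec$n_segments) spec$refit_end_trim
            else spec$refit_edge_trim
      if (length(sel) > kl + kr + 5L)
        sel <- sel[(1L + kl):(length(sel) - kr)]
      fit_power_law(wprof, range(sel), beta_bounds = spec$beta_range)
    })
    wt$segments$alpha_hat <- vapply(fits, `[[`, numeric(1), "alpha_hat")
    wt$segments$beta_hat <- vapply(fits, `[[`, numeric(1), "beta_hat")
    wt$segments$r_squared <- vapply(fits, `[[`, numeric(1), "r_squared")
    attr(wt, "n_attempts") <- it
    attr(wt, "rejections") <- rej
    attr(wt, "spec") <- spec
    return(wt)
  }
  stop("synthesize_ground_truth: no acceptable draw in ", spec$max_iter,
       " attempts (rejections: ",
       paste(names(rej), rej, sep = "=", collapse = ", "), ")",
       call. = FALSE)
}

#' Write a ground-truth bundle to disk
#'
#' Writes the warped trajectory as CSV and a JSON sidecar with the segment
#' table (sampled and refitted parameters), the generator spec and the
#' seed.
#'
#' @param wt A `warped_trajectory` from [synthesize_ground_truth()].
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(wt, csv_path, json_path) {
  write_trajectory_csv(wt$trajectory, csv_path)
  spec <- attr(wt, "spec")
  side <- list(segments = wt$segments,
               duration_factor = wt$duration_factor,
               spec = if (is.null(spec)) NULL else unclass(spec),
               n_attempts = attr(wt, "n_attempts"))
  writeLines(jsonlite::toJSON(side, digits = 12, auto_unbox = TRUE,
                              null = "null"), json_path)
  invisible(csv_path)
}
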