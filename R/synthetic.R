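#' Specification for smooth synthetic base trajectories
#'
#' Parameters of the generator that emulates low-pass-filtered 240 Hz
#' motion-capture recordings of sign-scale wrist movements: smooth 3D paths
#' of one to a few seconds, bell-shaped speed profiles, and curvature
#' bounded away from zero over the speed-trimmed range.
#'
#' @param duration Movement duration in seconds (default 2).
#' @param sample_rate Sampling rate in Hz (default 240).
#' @param spectral_cutoff Low-pass cutoff in Hz applied after adding noise
#'   (default 6; must be below Nyquist).
#' @param min_speed_fraction Fraction of maximal speed defining the
#'   retained range (default 0.15).
#' @param min_curvature Curvature floor (1/cm) required over the retained
#'   range (default 0.05, i.e. osculating radius at most 20 cm). The floor
#'   keeps the power law well-posed: near-inflection curvature dips under a
#'   steep exponent would impose speed spikes too brief for the sample
#'   rate to carry, so the synthesized ground truth could not actually be
#'   compliant at the deposited resolution.
#' @param noise_sd Additive Gaussian measurement noise in cm (default 0.08,
#'   the nominal accuracy of the emulated motion-capture sensor).
#' @param amplitude Per-coordinate path amplitude scale in cm (default 8;
#'   yields paths spanning roughly 20-40 cm).
#' @param n_harmonics Range of the number of random-phase harmonics per
#'   coordinate (default `c(2, 3)`). Few, slow harmonics keep the speed
#'   profile a single bell; more or faster harmonics produce multi-humped
#'   speed profiles unlike a single movement unit.
#' @param freq_range Harmonic frequency range in cycles per movement
#'   (default `c(0.3, 1.2)`).
#' @param max_iter Rejection-resampling cap (default 100).
#' @param seed Optional RNG seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(duration = 2, sample_rate = 240,
                       spectral_cutoff = 6, min_speed_fraction = 0.15,
                       min_curvature = 0.05, noise_sd = 0.08,
                       amplitude = 8, n_harmonics = c(2L, 3L),
                       freq_range = c(0.3, 1.2),
                       max_iter = 100L, seed = NULL) {
  stopifnot(spectral_cutoff < sample_rate / 2,
            duration * sample_rate >= 100)
  structure(list(duration = duration, sample_rate = sample_rate,
                 spectral_cutoff = spectral_cutoff,
                 min_speed_fraction = min_speed_fraction,
                 min_curvature = min_curvature, noise_sd = noise_sd,
                 amplitude = amplitude, n_harmonics = as.integer(n_harmonics),
                 freq_range = freq_range,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "synth_spec")
}

## Minimum-jerk unit time profile and its derivative: bell-shaped speed.
minjerk_profile <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

#' Generate a smooth synthetic base trajectory
#'
#' Each coordinate is a sum of random-phase sinusoids in a progress
#' variable that follows a minimum-jerk profile, giving the bell-shaped
#' speed of natural point-to-point movements; the mix of slow harmonics
#' produces curvature spanning roughly a decade, as recorded signing paths
#' do. Seeded Gaussian sensor noise is added and the result is low-pass
#' filtered at the spectral cutoff. Draws whose curvature over the
#' speed-trimmed range dips below the configured floor (near-inflection
#' paths, on which power-law kinematics are ill-posed) are rejected and
#' resampled.
#'
#' @param spec A [synth_spec()].
#' @return A [trajectory()] (filtered). Attribute `n_attempts` records the
#'   number of rejection-sampling draws used.
#' @export
generate_base_trajectory <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  tt <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  u <- minjerk_profile(tt / spec$duration)
  for (it in seq_len(spec$max_iter)) {
    P <- vapply(1:3, function(j) {
      K <- sample(spec$n_harmonics[1]:spec$n_harmonics[2], 1L)
      f <- stats::runif(K, spec$freq_range[1], spec$freq_range[2])
      ph <- stats::runif(K, 0, 2 * pi)
      A <- spec$amplitude / seq_len(K)^2 * stats::runif(K, 0.5, 1.5)
      colSums(A * sin(2 * pi * outer(f, u) + ph))
    }, numeric(length(tt)))
    P <- P + matrix(stats::rnorm(length(P), 0, spec$noise_sd),
                    nrow(P), ncol(P))
    traj <- lowpass_filter(trajectory(tt, P, sample_rate = spec$sample_rate),
                           cutoff_hz = spec$spectral_cutoff)
    prof <- tryCatch(kinematic_profile(traj), error = function(e) NULL)
    if (is.null(prof)) next
    rng <- tryCatch(trim_low_speed(prof, spec$min_speed_fraction),
                    error = function(e) NULL)
    if (is.null(rng)) next
    kseg <- prof$curvature[rng[1]:rng[2]]
    if (anyNA(kseg) || min(kseg) < spec$min_curvature) next
    attr(traj, "n_attempts") <- it
    return(traj)
  }
  stop("generate_base_trajectory: curvature floor ", spec$min_curvature,
       " 1/cm not met in ", spec$max_iter, " draws", call. = FALSE)
}

#' Specification for piecewise-polynomial test trajectories
#'
#' Describes trajectories built as consecutive polynomial strokes of known
#' order with derivative continuity across boundaries - the kind of data
#' for which the segmentation engine's polynomial order and boundary
#' recovery can be scored against an exact truth. The construction mimics
#' movement primitives: each segment travels between random knot positions
#' with small random knot velocities, so transitions happen near holds and
#' the acceleration changes sharply across boundaries, as in natural
#' signing movements.
#'
#' @param duration Total duration in seconds (default 2). Ignored when
#'   `breakpoints` is given.
#' @param breakpoints Interior boundary times in seconds (strictly
#'   increasing). If `NULL` (default), they are drawn by
#'   [random_partition()] at generation time.
#' @param n_segments Number of segments when breakpoints are drawn
#'   (default 3).
#' @param min_duration Minimal segment duration for drawn breakpoints
#'   (default 0.4 s).
#' @param order Polynomial order per segment (scalar, recycled; default 3).
#' @param continuity_order Highest derivative continuous across boundaries
#'   (default 1: position and velocity). Must not exceed the smallest
#'   segment order.
#' @param path_span Edge length (cm) of the box from which knot positions
#'   are drawn (default 30, a sign-scale movement).
#' @param knot_speed Standard deviation (cm/s) of the per-coordinate knot
#'   velocities (default 30). Transitions between signing strokes are
#'   flowing and co-articulated: the wrist keeps moving while its velocity
#'   direction changes sharply, so boundary speeds are comparable to
#'   mid-stroke speeds and the segment structure is carried by strong
#'   acceleration contrasts. Small values produce near-holds with weakly
#'   contrasting strokes that a single high-order polynomial can absorb.
#' @param coefficient_scale Scale (cm) of any free polynomial coefficients
#'   beyond the knot constraints (orders above `2 * continuity_order + 1`):
#'   the k-th order free term of a segment of duration d has standard
#'   deviation `coefficient_scale / d^k` (default 5).
#' @param snap_to_bins If non-`NULL` (default 100), breakpoints are snapped
#'   to the grid of `duration / snap_to_bins`, so that segment boundaries
#'   coincide with the bin edges of a subsequent analysis with that many
#'   bins - the situation of trajectories that were themselves produced by
#'   a binned piecewise fit.
#' @param noise_sd Additive Gaussian noise in cm (default 0.08, the
#'   nominal sensor accuracy).
#' @param sample_rate Sampling rate in Hz (default 240).
#' @param dim Number of coordinates (default 3).
#' @param seed Optional RNG seed.
#' @return An object of class `piecewise_poly_spec`.
#' @export
piecewise_poly_spec <- function(duration = 2, breakpoints = NULL,
                                n_segments = 3L, min_duration = 0.4,
                                order = 3L, continuity_order = 1L,
                                path_span = 30, knot_speed = 30,
                                coefficient_scale = 5, snap_to_bins = 100L,
                                noise_sd = 0.08,
                                sample_rate = 240, dim = 3L, seed = NULL) {
  if (!is.null(breakpoints)) {
    stopifnot(all(diff(breakpoints) > 0), all(breakpoints > 0),
              all(breakpoints < duration))
    n_segments <- length(breakpoints) + 1L
  }
  order <- rep_len(as.integer(order), n_segments)
  if (any(order < continuity_order))
    stop("every segment order must be >= continuity_order", call. = FALSE)
  structure(list(duration = duration, breakpoints = breakpoints,
                 n_segments = as.integer(n_segments),
                 min_duration = min_duration, order = order,
                 continuity_order = as.integer(continuity_order),
                 path_span = path_span, knot_speed = knot_speed,
                 coefficient_scale = coefficient_scale,
                 snap_to_bins = snap_to_bins, noise_sd = noise_sd,
                 sample_rate = sample_rate, dim = as.integer(dim),
                 seed = seed),
            class = "piecewise_poly_spec")
}

## Derivatives 0..k of a polynomial (coefficients in increasing powers of
## local time u) evaluated at u.
poly_derivs <- function(coef, u, k) {
  vapply(0:k, function(d) {
    if (d >= length(coef)) return(0)
    j <- d:(length(coef) - 1L)
    sum(coef[j + 1L] * exp(lgamma(j + 1) - lgamma(j - d + 1)) * u^(j - d))
  }, numeric(1))
}

## Row of the constraint system: derivative `d` of (1, u, ..., u^S) at u.
poly_deriv_row <- function(S, u, d) {
  k <- 0:S
  r <- numeric(S + 1L)
  ok <- k >= d
  r[ok] <- exp(lgamma(k[ok] + 1) - lgamma(k[ok] - d + 1)) * u^(k[ok] - d)
  r
}

## Coefficients (increasing powers of local u) of one segment: match
## derivatives 0..C to `left` at u = 0 and, when the order allows
## (S >= 2C+1), to `right` at u = d; remaining degrees of freedom are
## filled with random coefficients. Returns a length-(S+1) vector.
segment_coefficients <- function(S, d, C, left, right, coefficient_scale) {
  if (S >= 2L * C + 1L) {
    base_deg <- 2L * C + 1L
    A <- rbind(t(vapply(0:C, function(k) poly_deriv_row(base_deg, 0, k),
                        numeric(base_deg + 1L))),
               t(vapply(0:C, function(k) poly_deriv_row(base_deg, d, k),
                        numeric(base_deg + 1L))))
    h <- solve(A, c(left, right))
    cf <- c(h, rep(0, S - base_deg))
    n_free <- S - base_deg
    if (n_free > 0L) {
      ## add w(u) = (u (u - d))^(C+1) r(u): vanishes with C derivatives at
      ## both ends, so the knot constraints are preserved; r is random with
      ## scale chosen so each term contributes ~coefficient_scale cm
      r <- stats::rnorm(n_free, 0,
                        coefficient_scale /
                          ((d^2 / 4)^(C + 1L) * d^(0:(n_free - 1L))))
      base <- c(0, -d, 1)                 # u^2 - d u, as polynomial coeffs
      w <- 1
      for (rep in seq_len(C + 1L)) w <- poly_mult(w, base)
      w <- poly_mult(w, r)                # length (2C+2) + n_free = S + 1
      cf <- cf + w
    }
    cf
  } else {
    ## not enough freedom for both ends: match the left end only and draw
    ## the remaining coefficients at random (sequential construction)
    cf <- numeric(S + 1L)
    cf[1:(C + 1L)] <- left / factorial(0:C)
    if (S > C)
      for (k in (C + 1L):S)
        cf[k + 1L] <- stats::rnorm(1L, 0, coefficient_scale / d^k)
    cf
  }
}

## Polynomial product in coefficient (increasing-power) representation.
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Generate a piecewise-polynomial trajectory with known boundaries
#'
#' Draws random knot positions (uniform in a `path_span` box) and small
#' random knot velocities, then builds each segment as the polynomial
#' interpolating the knot values and derivatives up to `continuity_order`
#' at both ends (orders above `2 * continuity_order + 1` receive additional
#' random coefficients through terms vanishing at the knots; lower orders
#' fall back to matching the left end only). Optional Gaussian noise is
#' added after construction.
#'
#' @param spec A [piecewise_poly_spec()].
#' @return A list of class `piecewise_poly_trajectory`: `trajectory`
#'   (with noise), `clean` (noise-free trajectory), `boundaries` (interior
#'   boundary times, the ground truth), and `coefficients` (list over
#'   segments of (order+1) x dim matrices, local-time parameterization).
#' @export
generate_piecewise_poly <- function(spec = piecewise_poly_spec()) {
  stopifnot(inherits(spec, "piecewise_poly_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  br <- spec$breakpoints
  if (is.null(br))
    br <- random_partition(spec$duration, spec$n_segments, spec$min_duration)
  if (!is.null(spec$snap_to_bins)) {
    g <- spec$duration / spec$snap_to_bins
    br <- unique(round(br / g) * g)
    if (length(br) != spec$n_segments - 1L || min(diff(c(0, br, spec$duration))) <= 0)
      stop("breakpoints collapsed under bin snapping; use more bins or ",
           "longer segments", call. = FALSE)
  }
  edges <- c(0, br, spec$duration)
  tt <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  C <- spec$continuity_order
  nk <- spec$n_segments + 1L
  ## knot derivative stacks: rows deriv 0..C, one matrix per coordinate
  knot <- lapply(seq_len(spec$dim), function(j) {
    k <- matrix(0, C + 1L, nk)
    k[1, ] <- stats::runif(nk, 0, spec$path_span)
    if (C >= 1L) k[2, ] <- stats::rnorm(nk, 0, spec$knot_speed)
    if (C >= 2L) for (dd in 2:C)
      k[dd + 1L, ] <- stats::rnorm(nk, 0, spec$knot_speed * 4^(dd - 1L))
    k
  })
  coefs <- vector("list", spec$n_segments)
  P <- matrix(0, length(tt), spec$dim)
  for (i in seq_len(spec$n_segments)) {
    d <- edges[i + 1] - edges[i]
    S <- spec$order[i]
    cf <- matrix(0, S + 1L, spec$dim)
    for (j in seq_len(spec$dim))
      cf[, j] <- segment_coefficients(S, d, C, knot[[j]][, i],
                                      knot[[j]][, i + 1L],
                                      spec$coefficient_scale)
    coefs[[i]] <- cf
    sel <- if (i < spec$n_segments) tt >= edges[i] & tt < edges[i + 1]
           else tt >= edges[i]
    u <- tt[sel] - edges[i]
    P[sel, ] <- outer(u, 0:S, `^`) %*% cf
  }
  clean <- trajectory(tt, P, sample_rate = spec$sample_rate)
  noisy <- P + matrix(stats::rnorm(length(P), 0, spec$noise_sd),
                      nrow(P), ncol(P))
  structure(list(trajectory = trajectory(tt, noisy,
                                         sample_rate = spec$sample_rate),
                 clean = clean, boundaries = br, coefficients = coefs),
            class = "piecewise_poly_trajectory")
}
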