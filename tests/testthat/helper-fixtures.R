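## Analytic trajectory fixtures used across the test files.

## planar circle of given radius (cm), angular rate (rad/s)
circle_traj <- function(radius = 5, omega = 2 * pi, duration = 1,
                        rate = 240, noise_sd = 0) {
  tt <- seq(0, duration, by = 1 / rate)
  P <- cbind(radius * cos(omega * tt), radius * sin(omega * tt), 0 * tt)
  if (noise_sd > 0) P <- P + matrix(rnorm(length(P), 0, noise_sd),
                                    nrow(P), ncol(P))
  trajectory(tt, P, sample_rate = rate)
}

## helix (r cos t, r sin t, c t): curvature r / (r^2 + c^2)
helix_traj <- function(r = 2, cc = 1, duration = 3, rate = 240) {
  tt <- seq(0, duration, by = 1 / rate)
  trajectory(tt, cbind(r * cos(tt), r * sin(tt), cc * tt),
             sample_rate = rate)
}

line_traj <- function(slope = 3, duration = 1, rate = 240) {
  tt <- seq(0, duration, by = 1 / rate)
  trajectory(tt, cbind(slope * tt, 0 * tt, 0 * tt), sample_rate = rate)
}

## a kinematic_profile built directly from given speed/curvature vectors
fake_profile <- function(speed, curvature, rate = 240) {
  structure(list(times = seq_along(speed) / rate, speed = speed,
                 curvature = curvature,
                 valid = rep(TRUE, length(speed)), sample_rate = rate),
            class = "kinematic_profile")
}

## brute-force enumeration of Eq.-11-style configuration sums for a given
## evidence table: the independent oracle for the sum-product recursions
enum_log_p <- function(E, M) {
  T <- nrow(E)
  configs <- if (M == 0) matrix(nrow = 1, ncol = 0) else t(combn(T - 1, M))
  vals <- apply(configs, 1, function(q) {
    b <- c(0, q, T)
    sum(E[cbind(b[-length(b)] + 1, b[-1])])
  })
  bbseg:::logsumexp(vals) + boundary_prior_log(T, M)
}

## per-edge boundary probability by enumeration
enum_density <- function(E, M) {
  T <- nrow(E)
  stopifnot(M >= 1)
  configs <- t(combn(T - 1, M))
  w <- apply(configs, 1, function(q) {
    b <- c(0, q, T)
    exp(sum(E[cbind(b[-length(b)] + 1, b[-1])]))
  })
  dens <- numeric(T - 1)
  for (r in seq_len(nrow(configs)))
    dens[configs[r, ]] <- dens[configs[r, ]] + w[r]
  dens / sum(w)
}

## expected trajectory by enumeration: weighted average over configurations
## of the per-segment conjugate posterior means
enum_expected <- function(times, X, E, prior, M, t_min, dt) {
  T <- nrow(E)
  configs <- if (M == 0) matrix(nrow = 1, ncol = 0) else t(combn(T - 1, M))
  bins <- bbseg:::bin_index(times, t_min, dt, T)
  lw <- apply(configs, 1, function(q) {
    b <- c(0, q, T)
    sum(E[cbind(b[-length(b)] + 1, b[-1])])
  })
  w <- exp(lw - bbseg:::logsumexp(lw))
  out <- matrix(0, nrow(X), ncol(X))
  for (r in seq_len(nrow(configs))) {
    b <- c(0, configs[r, ], T)
    for (m in seq_len(length(b) - 1)) {
      sel <- bins > b[m] & bins <= b[m + 1]
      if (!any(sel)) next
      post <- segment_posterior(times[sel], X[sel, , drop = FALSE], prior,
                                t_start = t_min + b[m] * dt,
                                t_end = t_min + b[m + 1] * dt)
      out[sel, ] <- out[sel, ] + w[r] *
        posterior_mean_trajectory(post, times[sel])
    }
  }
  out
}

## 2D/3D numerical quadrature oracle for the L = 1 segment evidence:
## integrates the likelihood against the prior densities directly.
## Wishart(nu, V) for L = 1 is Gamma(shape nu/2, rate 1/(2V)).
quadrature_evidence_1d <- function(x, phi, b, nu, V, a0 = NULL) {
  S1 <- ncol(phi)
  if (is.null(a0)) a0 <- rep(0, S1)
  dprior_p <- function(p) stats::dgamma(p, shape = nu / 2, rate = 1 / (2 * V))
  lik <- function(coef, p) prod(stats::dnorm(x, phi %*% coef, 1 / sqrt(p)))
  if (S1 == 1) {
    inner <- function(p) vapply(p, function(pp) {
      stats::integrate(function(mu)
        vapply(mu, function(m)
          stats::dnorm(m, a0, 1 / sqrt(b * pp)) * lik(m, pp), numeric(1)),
        -Inf, Inf, rel.tol = 1e-10)$value * dprior_p(pp)
    }, numeric(1))
    stats::integrate(inner, 0, Inf, rel.tol = 1e-8)$value
  } else {
    ## S1 == 2: integrate over (a0, a1, p)
    inner2 <- function(a1v, pp)
      vapply(a1v, function(a1) {
        stats::integrate(function(a0v)
          vapply(a0v, function(av)
            stats::dnorm(av, a0[1], 1 / sqrt(b * pp)) *
              stats::dnorm(a1, a0[2], 1 / sqrt(b * pp)) *
              lik(c(av, a1), pp), numeric(1)),
          -Inf, Inf, rel.tol = 1e-9)$value
      }, numeric(1))
    inner <- function(pv) vapply(pv, function(pp) {
      stats::integrate(function(a1) inner2(a1, pp),
                       -Inf, Inf, rel.tol = 1e-8)$value * dprior_p(pp)
    }, numeric(1))
    stats::integrate(inner, 0, Inf, rel.tol = 1e-7)$value
  }
}
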