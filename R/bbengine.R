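## Bayesian binning engine: exact posterior inference over segmentations of
## a discretized time axis. The time interval is cut into T bins; a model
## with M boundaries has M+1 contiguous segments with inclusive upper
## boundaries. All configuration sums are evaluated by the sum-product
## (forward/backward) recursion in O(M T^2), in log space throughout.

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log prior of a boundary configuration
#'
#' With M ordered interior boundaries distributed over T-1 admissible edges,
#' every configuration has prior probability `1 / choose(T-1, M)`. Computed
#' via log-gamma. Although flat over configurations, this prior decreases
#' steeply in M and is the complexity control of the method.
#'
#' @param T Number of time bins.
#' @param M Number of segment boundaries, `0 <= M <= T-1`.
#' @return Log prior probability (nats).
#' @export
boundary_prior_log <- function(T, M) {
  if (M < 0 || M > T - 1)
    stop("M must be between 0 and T-1", call. = FALSE)
  -(lgamma(T) - lgamma(M + 1) - lgamma(T - M))
}

#' Log prior over the number of boundaries
#'
#' Uniform over the admissible values `M = 0, ..., T-1`: every M has log
#' prior `-log(T)`.
#'
#' @param T Number of time bins.
#' @return Scalar `-log(T)`.
#' @export
model_prior_log <- function(T) -log(T)

## Bin index of each sample: bins are [t_min + (j-1) dt, t_min + j dt),
## the last bin right-closed. The 1e-9-bin epsilon keeps samples lying
## exactly on an edge in the right-hand bin irrespective of floating-point
## jitter (e.g. under a common time translation).
bin_index <- function(times, t_min, dt, T) {
  j <- floor((times - t_min) / dt + 1e-9) + 1L
  pmin(pmax(as.integer(j), 1L), T)
}

#' Table of per-segment log evidences
#'
#' Entry `(i, j)` (upper triangle, `i <= j`) is the log marginal likelihood
#' of all samples whose bin index lies in `i..j`, under the observation
#' model prior, with the polynomial basis anchored at the segment's left
#' edge and elapsed time rescaled by the segment duration. Each entry is a
#' pure function of its data slice. Empty slices have log evidence 0.
#'
#' @param times Sample times (sorted ascending).
#' @param X Observations (n x L).
#' @param prior An [obs_prior()].
#' @param t_min Left edge of the binned interval.
#' @param dt Bin width (seconds).
#' @param T Number of bins.
#' @param use_cpp Use the compiled kernel (default) or the reference R
#'   implementation.
#' @return A `T x T` matrix, `NA` below the diagonal.
#' @export
evidence_table <- function(times, X, prior, t_min, dt, T, use_cpp = TRUE) {
  X <- as.matrix(X)
  ord <- order(times)
  times <- times[ord]
  X <- X[ord, , drop = FALSE]
  bins <- bin_index(times, t_min, dt, T)
  if (use_cpp) {
    return(evidence_table_cpp(times, X, bins, as.integer(T),
                              as.integer(prior$order), prior$coeff_bias,
                              prior$coeff_concentration,
                              prior$wishart_inv_scale, prior$wishart_dof,
                              t_min, dt,
                              legendre_coef_matrix(prior$order)))
  }
  E <- matrix(NA_real_, T, T)
  for (i in seq_len(T)) {
    for (j in i:T) {
      sel <- bins >= i & bins <= j
      E[i, j] <- segment_log_evidence(times[sel], X[sel, , drop = FALSE],
                                      prior,
                                      t_start = t_min + (i - 1) * dt,
                                      t_end = t_min + j * dt)
    }
  }
  E
}

## Forward/backward configuration sums.
## G[m+1, b+1] = log sum over ways to cover bins 1..b with m segments.
## H[m+1, b+1] = log sum over ways to cover bins b+1..T with m segments.
bb_forward <- function(E, M_max) {
  T <- nrow(E)
  G <- matrix(-Inf, M_max + 2L, T + 1L)
  G[1L, 1L] <- 0
  for (m in seq_len(M_max + 1L)) {
    for (b in m:T) {
      bp <- (m - 1L):(b - 1L)
      G[m + 1L, b + 1L] <- logsumexp(G[m, bp + 1L] + E[cbind(bp + 1L, b)])
    }
  }
  G
}

bb_backward <- function(E, M_max) {
  T <- nrow(E)
  H <- matrix(-Inf, M_max + 2L, T + 1L)
  H[1L, T + 1L] <- 0
  for (m in seq_len(M_max + 1L)) {
    for (b in 0:(T - m)) {
      bpp <- (b + 1L):(T - m + 1L)
      H[m + 1L, b + 1L] <- logsumexp(E[cbind(b + 1L, bpp)] +
                                       H[m, bpp + 1L])
    }
  }
  H
}

#' Log marginal likelihood of the data for each number of boundaries
#'
#' For each `M = 0, ..., M_max`, the log of the sum over all boundary
#' configurations of the product of segment evidences, multiplied by the
#' flat configuration prior [boundary_prior_log()]. Evaluated by the
#' forward sum-product recursion in `O(M_max T^2)`.
#'
#' @param E Evidence table from [evidence_table()].
#' @param M_max Largest number of boundaries to evaluate.
#' @return Numeric vector of length `M_max + 1` (entries for M = 0..M_max).
#' @export
log_p_data_given_M <- function(E, M_max) {
  T <- nrow(E)
  stopifnot(M_max <= T - 1)
  G <- bb_forward(E, M_max)
  vapply(0:M_max, function(M) G[M + 2L, T + 1L] + boundary_prior_log(T, M),
         numeric(1))
}

#' Posterior over the number of boundaries
#'
#' Softmax of the per-M log marginals; the uniform prior over M cancels.
#' Ties in the maximum are broken toward the smaller M (parsimony).
#'
#' @param log_p_by_M Output of [log_p_data_given_M()].
#' @return List with `posterior` (simplex vector over M = 0..M_max) and
#'   `M_opt` (argmax, an integer).
#' @export
posterior_over_M <- function(log_p_by_M) {
  z <- logsumexp(log_p_by_M)
  post <- exp(log_p_by_M - z)
  list(posterior = post, M_opt = which.max(log_p_by_M) - 1L)
}

#' Posterior boundary probability per bin edge (segmentation density)
#'
#' For a fixed number of boundaries M, the posterior probability that some
#' segment boundary sits at interior edge `e` (between bins e and e+1),
#' for `e = 1..T-1`. The masses sum to M.
#'
#' @param E Evidence table from [evidence_table()].
#' @param M Number of boundaries.
#' @return Numeric vector of length `T-1` of per-edge probability masses.
#' @export
segmentation_density <- function(E, M) {
  T <- nrow(E)
  if (M == 0) return(numeric(T - 1L))
  G <- bb_forward(E, M)
  H <- bb_backward(E, M)
  logZ <- G[M + 2L, T + 1L]
  dens <- numeric(T - 1L)
  for (e in seq_len(T - 1L)) {
    m <- seq_len(M)
    dens[e] <- sum(exp(G[m + 1L, e + 1L] + H[M + 1L - m + 1L, e + 1L] - logZ))
  }
  dens
}

## Posterior probability that bins i..j form one segment, for all (i, j).
segment_weight_matrix <- function(E, M) {
  T <- nrow(E)
  G <- bb_forward(E, M)
  H <- bb_backward(E, M)
  logZ <- G[M + 2L, T + 1L]
  W <- matrix(0, T, T)
  Em <- E
  Em[is.na(Em)] <- -Inf
  for (ml in 0:M) {
    gv <- G[ml + 1L, 1:T]            # left part covers bins 1..(i-1)
    hv <- H[M - ml + 1L, 2:(T + 1L)] # right part covers bins (j+1)..T
    lw <- outer(gv, hv, `+`) + Em - logZ
    W <- W + exp(lw)
  }
  W
}

#' Posterior expected trajectory
#'
#' For each sample, the posterior-weighted average (over all segments
#' containing it, weighted by their posterior probability given M) of the
#' segment's posterior-mean polynomial.
#'
#' @param times Sample times.
#' @param X Observations (n x L), as passed to [evidence_table()].
#' @param E Evidence table.
#' @param prior The [obs_prior()] used to build the table.
#' @param M Number of boundaries to condition on.
#' @param t_min,dt Bin geometry used to build the table.
#' @param weight_threshold Segments with posterior probability below this
#'   are skipped (their total mass is renormalized away).
#' @return Matrix (n x L) of expected positions.
#' @export
expected_trajectory <- function(times, X, E, prior, M, t_min, dt,
                                weight_threshold = 1e-12) {
  X <- as.matrix(X)
  T <- nrow(E)
  ord <- order(times)
  W <- segment_weight_matrix(E, M)
  bins <- bin_index(times[ord], t_min, dt, T)
  pred <- expected_trajectory_cpp(times[ord], X[ord, , drop = FALSE], bins,
                                  as.integer(T), as.integer(prior$order),
                                  prior$coeff_bias,
                                  prior$coeff_concentration, W, t_min, dt,
                                  weight_threshold,
                                  legendre_coef_matrix(prior$order))
  out <- matrix(0, nrow(X), ncol(X))
  out[ord, ] <- pred
  out
}

#' Predicted segmentation points from a segmentation density
#'
#' The `M_opt` highest-mass edges after non-maximum suppression within one
#' bin (no two returned edges may be adjacent), converted to seconds at the
#' edge positions and sorted. Ties prefer the earlier edge.
#'
#' @param density Per-edge masses from [segmentation_density()].
#' @param M_opt Number of points to return.
#' @param t_min Left edge of the binned interval (seconds).
#' @param dt Bin width (seconds).
#' @return Sorted numeric vector of boundary times (length `M_opt`, or
#'   fewer, with a warning, if the density has fewer usable peaks).
#' @export
predicted_segmentation_points <- function(density, M_opt, t_min, dt) {
  if (M_opt == 0L) return(numeric(0))
  Tm1 <- length(density)
  ord <- order(-density, seq_len(Tm1))
  chosen <- integer(0)
  for (e in ord) {
    if (length(chosen) >= M_opt) break
    if (density[e] <= 0) break
    if (any(abs(chosen - e) <= 1L)) next
    chosen <- c(chosen, e)
  }
  if (length(chosen) < M_opt)
    warning("only ", length(chosen), " density peaks available for M_opt = ",
            M_opt)
  sort(t_min + chosen * dt)
}

#' Bayesian binning segmentation of a trajectory
#'
#' Runs the full pipeline for one polynomial order: bins the time axis into
#' `n_bins` intervals, computes the per-segment evidence table under the
#' conjugate polynomial-mean Gaussian observation model, evaluates the
#' marginal likelihood for every number of boundaries `M` up to
#' `max_boundaries` by the sum-product recursion, and extracts the
#' posterior over M, the segmentation density at the most probable M, the
#' predicted segmentation points, and (optionally) the posterior expected
#' trajectory.
#'
#' @param traj A [trajectory()].
#' @param order Polynomial order of the segment means (default 3, the
#'   minimum-acceleration order).
#' @param n_bins Number of time bins T (default 100).
#' @param prior An [obs_prior()]; by default [default_obs_prior()]
#'   calibrated on the (centered) data.
#' @param max_boundaries Cap on M (default `min(n_bins - 1, 30)`; the cap
#'   keeps the M scan inexpensive and is far above the number of movement
#'   primitives expected in a single sign-scale movement).
#' @param compute_expected Compute the posterior expected trajectory
#'   (default TRUE).
#' @param use_cpp Use the compiled evidence kernel (default TRUE).
#' @return An object of class `bb_result` with elements
#'   `log_evidence_by_M` (Eq.-level log marginals, M = 0..max),
#'   `posterior_M`, `M_opt`, `segmentation_density` (per interior edge,
#'   given `M_opt`), `edge_times`, `psp` (predicted segmentation points,
#'   seconds), `expected` (a [trajectory()] of posterior mean positions, or
#'   NULL), and the model geometry (`n_bins`, `bin_width`, `t_min`,
#'   `order`).
#' @details Positions are centered (per-coordinate mean subtracted) before
#'   inference, matching the zero coefficient bias of the default prior;
#'   the offset is restored in the expected trajectory.
#' @export
bb_segment <- function(traj, order = 3L, n_bins = 100L, prior = NULL,
                       max_boundaries = NULL, compute_expected = TRUE,
                       use_cpp = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  T <- as.integer(n_bins)
  stopifnot(T >= 2L)
  if (is.null(max_boundaries)) max_boundaries <- min(T - 1L, 30L)
  max_boundaries <- as.integer(min(max_boundaries, T - 1L))
  times <- traj$times
  ctr <- colMeans(traj$positions)
  X <- sweep(traj$positions, 2L, ctr)
  if (is.null(prior)) prior <- default_obs_prior(X, order)
  t_min <- times[1]
  dt <- (times[length(times)] - t_min) / T
  E <- evidence_table(times, X, prior, t_min, dt, T, use_cpp = use_cpp)
  lpm <- log_p_data_given_M(E, max_boundaries)
  pm <- posterior_over_M(lpm)
  dens <- segmentation_density(E, pm$M_opt)
  psp <- predicted_segmentation_points(dens, pm$M_opt, t_min, dt)
  expected <- NULL
  if (compute_expected) {
    pred <- expected_trajectory(times, X, E, prior, pm$M_opt, t_min, dt)
    expected <- trajectory(times, sweep(pred, 2L, -ctr),
                           sample_rate = traj$sample_rate)
  }
  structure(list(log_evidence_by_M = lpm, posterior_M = pm$posterior,
                 M_opt = pm$M_opt, segmentation_density = dens,
                 edge_times = t_min + seq_len(T - 1L) * dt, psp = psp,
                 expected = expected, evidence = E,
                 n_bins = T, bin_width = dt, t_min = t_min,
                 order = as.integer(order), prior = prior, center = ctr),
            class = "bb_result")
}

#' @export
print.bb_result <- function(x, ...) {
  cat(sprintf(paste0("bb_result: order %d, T = %d bins of %.4g s; ",
                     "M_opt = %d (posterior %.3f)\n"),
              x$order, x$n_bins, x$bin_width, x$M_opt,
              x$posterior_M[x$M_opt + 1]))
  if (length(x$psp))
    cat("  predicted segmentation points (s):",
        paste(sprintf("%.3f", x$psp), collapse = ", "), "\n")
  invisible(x)
}

#' Scan polynomial orders and compute their posterior
#'
#' Runs [bb_segment()] for each order and combines the per-order marginal
#' likelihoods `log P(D | order) = logsumexp_M [log P(D | M, order) +
#' log P(M)]` under a uniform prior over the tested orders into a posterior
#' over orders.
#'
#' @param traj A [trajectory()].
#' @param orders Integer vector of polynomial orders (default `0:7`).
#' @param ... Passed to [bb_segment()] (`n_bins`, `max_boundaries`, ...).
#' @param compute_expected Compute expected trajectories per order
#'   (default FALSE; they are rarely needed for a whole scan).
#' @return An object of class `bb_order_scan`: list with `orders`,
#'   `log_p_order` (log marginal per order), `posterior_order` (simplex),
#'   `order_opt`, and `fits` (list of `bb_result`, one per order).
#' @export
bb_order_scan <- function(traj, orders = 0:7, ...,
                          compute_expected = FALSE) {
  fits <- lapply(orders, function(s)
    bb_segment(traj, order = s, compute_expected = compute_expected, ...))
  lpo <- vapply(fits, function(f)
    logsumexp(f$log_evidence_by_M + model_prior_log(f$n_bins)), numeric(1))
  post <- exp(lpo - logsumexp(lpo))
  structure(list(orders = orders, log_p_order = lpo,
                 posterior_order = post,
                 order_opt = orders[which.max(lpo)], fits = fits),
            class = "bb_order_scan")
}

#' @export
print.bb_order_scan <- function(x, ...) {
  cat("bb_order_scan over orders", paste(x$orders, collapse = ", "), "\n")
  cat("  posterior:", paste(sprintf("%d:%.3f", x$orders, x$posterior_order),
                            collapse = " "), "\n")
  cat("  most probable order:", x$order_opt, "\n")
  invisible(x)
}

#' Serialize a segmentation result to JSON
#' @param result A `bb_result`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
bb_result_to_json <- function(result, path = NULL) {
  x <- list(order = result$order, n_bins = result$n_bins,
            bin_width = result$bin_width, t_min = result$t_min,
            log_evidence_by_M = result$log_evidence_by_M,
            posterior_M = result$posterior_M, M_opt = result$M_opt,
            segmentation_density = result$segmentation_density,
            edge_times = result$edge_times, psp = result$psp)
  js <- jsonlite::toJSON(x, digits = 12, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
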