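#' Match predicted to ground-truth segmentation points
#'
#' Greedy matching protocol: predicted points are visited in ascending time
#' order; each one matches the nearest still-unmatched truth point within
#' the accuracy window (ties prefer the earlier truth point). Unmatched
#' predicted points are false positives; unmatched truth points are misses.
#'
#' @param predicted Numeric vector of predicted boundary times (seconds).
#' @param truth Numeric vector of ground-truth boundary times.
#' @param window Accuracy window in seconds (default 0.090).
#' @param duration Duration of the analyzed trajectory in seconds, used as
#'   the denominator of false positives per second.
#' @param optimal Use optimal bipartite matching instead of the greedy rule
#'   (sensitivity analysis only; default FALSE).
#' @return An object of class `match_result`: `hits`, `misses`,
#'   `false_positives`, `hit_rate` (`= hits / (hits + misses)`, `NA` with
#'   no truth points), `fp_per_second`, `duration`, `window`.
#' @export
match_points <- function(predicted, truth, window = 0.090, duration = NULL,
                         optimal = FALSE) {
  stopifnot(window > 0)
  predicted <- sort(as.numeric(predicted))
  truth <- sort(as.numeric(truth))
  if (is.null(duration))
    duration <- max(c(predicted, truth, 1)) - min(c(predicted, truth, 0))
  matched <- rep(FALSE, length(truth))
  hits <- 0L
  if (!optimal) {
    for (p in predicted) {
      if (!length(truth)) break
      d <- abs(truth - p)
      d[matched] <- Inf
      i <- which.min(d)   # ties: earlier truth point
      if (is.finite(d[i]) && d[i] <= window) {
        matched[i] <- TRUE
        hits <- hits + 1L
      }
    }
  } else if (length(predicted) && length(truth)) {
    ## maximum-cardinality matching on the bipartite window graph, by
    ## exhaustive assignment over truth subsets (both sets are tiny here)
    ok <- outer(predicted, truth, function(p, q) abs(p - q) <= window)
    hits <- bipartite_max_matching(ok)
    matched <- rep(TRUE, hits)
    matched <- c(matched, rep(FALSE, length(truth) - hits))
  }
  misses <- length(truth) - hits
  fp <- length(predicted) - hits
  structure(list(hits = hits, misses = misses, false_positives = fp,
                 hit_rate = if (length(truth)) hits / length(truth) else NA_real_,
                 fp_per_second = fp / duration,
                 duration = duration, window = window),
            class = "match_result")
}

## Hungarian-free maximum matching via augmenting paths (Kuhn's algorithm).
bipartite_max_matching <- function(ok) {
  np <- nrow(ok); nt <- ncol(ok)
  match_t <- rep(0L, nt)
  try_kuhn <- function(p, seen) {
    for (q in which(ok[p, ])) {
      if (seen[q]) next
      seen[q] <- TRUE
      if (match_t[q] == 0L || Recall(match_t[q], seen)) {
        match_t[q] <<- p
        return(TRUE)
      }
    }
    FALSE
  }
  hits <- 0L
  for (p in seq_len(np))
    if (try_kuhn(p, rep(FALSE, nt))) hits <- hits + 1L
  hits
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("match_result: %d hits, %d misses, %d false positives",
                     " | hit rate %.3f, %.3f fp/s (window %g ms)\n"),
              x$hits, x$misses, x$false_positives, x$hit_rate,
              x$fp_per_second, 1000 * x$window))
  invisible(x)
}

#' Hit rate per false positives per second
#'
#' The scalar summary `HPFPPS = hit_rate / fp_per_second`; the larger, the
#' fewer false positives are incurred per hit. With zero false positives
#' (and a positive hit rate) the ratio is undefined and reported as `+Inf`
#' with the attribute `zero_fp = TRUE`; such values are excluded from
#' batch averages by [aggregate_matches()].
#'
#' @param match A [match_points()] result.
#' @return HPFPPS (dimensionless times seconds), possibly `+Inf`.
#' @export
hpfpps <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (match$fp_per_second == 0) {
    out <- if (isTRUE(match$hit_rate > 0)) Inf else 0
    attr(out, "zero_fp") <- TRUE
    return(out)
  }
  match$hit_rate / match$fp_per_second
}

#' Aggregate match results over a batch of trajectories
#'
#' Rates are computed per trajectory and then averaged (mean and standard
#' error of the mean). The batch HPFPPS is the ratio of the mean hit rate
#' to the mean false-positive rate (`+Inf` when the batch incurs no false
#' positives at all); the mean of the finite per-trajectory HPFPPS values
#' is also reported, with the count of excluded infinite values.
#'
#' @param matches List of [match_points()] results.
#' @return List with `hit_rate` (mean), `hit_rate_sem`, `fp_per_second`,
#'   `fp_per_second_sem`, `hpfpps` (ratio of means), `hpfpps_mean_finite`,
#'   `n_zero_fp`, `n`.
#' @export
aggregate_matches <- function(matches) {
  hr <- vapply(matches, `[[`, numeric(1), "hit_rate")
  fps <- vapply(matches, `[[`, numeric(1), "fp_per_second")
  hp <- vapply(matches, function(m) as.numeric(hpfpps(m)), numeric(1))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  mh <- mean(hr, na.rm = TRUE)
  mf <- mean(fps)
  list(hit_rate = mh, hit_rate_sem = sem(hr[!is.na(hr)]),
       fp_per_second = mf, fp_per_second_sem = sem(fps),
       hpfpps = if (mf > 0) mh / mf else Inf,
       hpfpps_mean_finite = if (any(is.finite(hp))) mean(hp[is.finite(hp)])
                            else Inf,
       n_zero_fp = sum(!is.finite(hp)), n = length(matches))
}

#' Line of no discrimination for the hit-rate analysis
#'
#' Simulates an uninformative segmenter: a homogeneous Poisson process with
#' rate `lambda` generates candidate segmentation events on `[0, duration]`,
#' which are matched against the truth points. Each rate yields one
#' (fp/s, hit rate) point; informative models must lie above the resulting
#' curve.
#'
#' @param truth Ground-truth boundary times (seconds).
#' @param duration Trajectory duration (seconds).
#' @param lambdas Poisson rates to simulate (events per second).
#' @param reps Monte-Carlo repetitions per rate (default 200).
#' @param window Accuracy window (seconds, default 0.090).
#' @param seed Optional RNG seed.
#' @return An object of class `no_discrimination_curve`: data frame with
#'   `lambda`, `hit_rate`, `hit_rate_sem`, `fp_per_second`,
#'   `fp_per_second_sem`.
#' @export
no_discrimination_curve <- function(truth, duration,
                                    lambdas = c(0.1, 0.2, 0.5, 1, 2, 5, 10,
                                                20, 50),
                                    reps = 200L, window = 0.090,
                                    seed = NULL) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(lambdas, function(lam) {
    hr <- numeric(reps)
    fp <- numeric(reps)
    for (r in seq_len(reps)) {
      k <- stats::rpois(1L, lam * duration)
      ev <- sort(stats::runif(k, 0, duration))
      m <- match_points(ev, truth, window = window, duration = duration)
      hr[r] <- m$hit_rate
      fp[r] <- m$fp_per_second
    }
    data.frame(lambda = lam, hit_rate = mean(hr), hit_rate_sem = sem(hr),
               fp_per_second = mean(fp), fp_per_second_sem = sem(fp))
  })
  structure(do.call(rbind, rows),
            class = c("no_discrimination_curve", "data.frame"))
}

#' Hit rate of the no-discrimination curve at given false-positive rates
#'
#' Linear interpolation of the simulated curve in fp/s; below the smallest
#' simulated point the curve is extended through the origin, above the
#' largest it is held constant.
#'
#' @param curve A [no_discrimination_curve()].
#' @param fp_per_second Query false-positive rates (1/s).
#' @return Interpolated chance hit rates.
#' @export
chance_hit_rate <- function(curve, fp_per_second) {
  x <- c(0, curve$fp_per_second)
  y <- c(0, curve$hit_rate)
  stats::approx(x, y, xout = fp_per_second, rule = 2, ties = "ordered")$y
}

#' Explained variance of a fitted trajectory
#'
#' `1 - SSE / SST` pooled across coordinates, with the total sum of squares
#' taken about the per-coordinate means of the original trajectory.
#'
#' @param original,fitted Two [trajectory()] objects of equal length (or
#'   plain position matrices of equal shape).
#' @return Fraction of variance explained (dimensionless, `<= 1`).
#' @export
explained_variance <- function(original, fitted) {
  P <- if (inherits(original, "trajectory")) original$positions
       else as.matrix(original)
  Q <- if (inherits(fitted, "trajectory")) fitted$positions
       else as.matrix(fitted)
  if (!all(dim(P) == dim(Q)))
    stop("original and fitted must have the same dimensions", call. = FALSE)
  sse <- sum((P - Q)^2)
  sst <- sum(sweep(P, 2L, colMeans(P))^2)
  if (sst == 0) stop("explained variance undefined: constant original",
                     call. = FALSE)
  1 - sse / sst
}
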