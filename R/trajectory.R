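#' Construct a trajectory object
#'
#' A `trajectory` is the universal data currency of the package: a uniformly
#' sampled 3D path (wrist positions in cm) with time stamps in seconds. The
#' sampling grid must be strictly increasing and uniform; the nominal
#' recording rate for the motion-capture data this package emulates is 240 Hz.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step.
#' @param positions Numeric matrix with one row per sample and 3 columns
#'   (x, y, z in cm). A vector is accepted for 1-column (univariate) use in
#'   tests and is promoted to a 1-column matrix.
#' @param sample_rate Sampling rate in Hz. Defaults to the reciprocal of the
#'   median time step.
#'
#' @return An object of class `trajectory`: a list with elements `times`,
#'   `positions` and `sample_rate`.
#'
#' @details At least 4 samples are required (curvature needs second
#'   derivatives); all coordinates must be finite, and the time step must
#'   equal `1/sample_rate` to within `1e-9` relative tolerance.
#'
#' @examples
#' tt <- seq(0, 1, by = 1 / 240)
#' tr <- trajectory(tt, cbind(cos(2 * pi * tt), sin(2 * pi * tt), 0 * tt))
#' tr
#' @export
trajectory <- function(times, positions, sample_rate = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(positions))) positions <- matrix(as.numeric(positions), ncol = 1L)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- length(times)
  if (n < 4L)
    stop("a trajectory needs at least 4 samples (got ", n,
         "); curvature requires second derivatives", call. = FALSE)
  if (nrow(positions) != n)
    stop("positions must have one row per time stamp", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(positions)))
    stop("times and positions must be finite", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 1e-9 * max(step, 1))
    stop("sampling must be uniform (max step deviation ",
         format(max(abs(dt - step))), " s)", call. = FALSE)
  if (is.null(sample_rate)) sample_rate <- 1 / step
  if (abs(step - 1 / sample_rate) > 1e-9 * step)
    stop("time step does not match 1/sample_rate", call. = FALSE)
  structure(list(times = times, positions = positions,
                 sample_rate = sample_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("trajectory: %d samples, %d coordinate(s), %.6g s at %.6g Hz\n",
              n, ncol(x$positions), x$times[n] - x$times[1], x$sample_rate))
  invisible(x)
}

#' Number of samples in a trajectory
#' @param traj A [trajectory()].
#' @return Integer sample count.
#' @export
n_samples <- function(traj) length(traj$times)

#' Total duration of a trajectory
#' @param traj A [trajectory()].
#' @return Duration in seconds (last minus first time stamp).
#' @export
duration <- function(traj) traj$times[length(traj$times)] - traj$times[1]

#' Extract a contiguous sample range as a new trajectory
#' @param traj A [trajectory()].
#' @param from,to First and last sample index (1-based, inclusive).
#' @return A [trajectory()] over the selected samples.
#' @export
subset_trajectory <- function(traj, from, to) {
  stopifnot(from >= 1L, to <= n_samples(traj), to - from + 1L >= 4L)
  trajectory(traj$times[from:to], traj$positions[from:to, , drop = FALSE],
             sample_rate = traj$sample_rate)
}

#' Read a trajectory from CSV
#'
#' The on-disk format is a plain CSV with header `t,x,y,z` (`t` in seconds,
#' coordinates in cm); lines starting with `#` are comments. Uniform sampling
#' is validated on read.
#'
#' @param path Path to the CSV file.
#' @return A [trajectory()].
#' @seealso [write_trajectory_csv()]
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns t,x,y,z (got: ",
         paste(names(df), collapse = ","), ")", call. = FALSE)
  if (nrow(df) == 0L) stop("empty trajectory file: ", path, call. = FALSE)
  trajectory(df$t, as.matrix(df[, c("x", "y", "z")]))
}

#' Write a trajectory to CSV
#' @param traj A [trajectory()] with 3 coordinates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  if (ncol(p) != 3L) stop("CSV export requires 3 coordinates", call. = FALSE)
  df <- data.frame(t = traj$times, x = p[, 1], y = p[, 2], z = p[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
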