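test_that("trajectory constructor enforces its invariants and CSV round-trips", {
  expect_error(trajectory(c(0, 0.1, 0.2), matrix(0, 3, 3)), "4 samples")
  expect_error(trajectory(c(0, 0.1, 0.15, 0.2), matrix(0, 4, 3)), "uniform")
  expect_error(trajectory(c(0, 0.1, 0.2, 0.3), matrix(c(1, NA, rep(0, 10)), 4, 3)),
               "finite")
  tr <- circle_traj()
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tr2 <- read_trajectory_csv(f)
  expect_equal(tr2$times, tr$times, tolerance = 1e-12)
  expect_equal(tr2$positions, tr$positions, ignore_attr = TRUE,
               tolerance = 1e-12)
  unlink(f)
})

test_that("low-pass filter passes DC and low frequencies, blocks high ones", {
  tt <- seq(0, 2, by = 1 / 240)
  const <- trajectory(tt, matrix(5, length(tt), 3))
  expect_equal(lowpass_filter(const)$positions, const$positions,
               tolerance = 1e-10)
  amp_after <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    tr <- trajectory(tt, cbind(x, x, x))
    y <- lowpass_filter(tr, 6, 50)$positions[, 1]
    mid <- seq(120, length(tt) - 120)   # interior, away from edge padding
    max(abs(y[mid]))
  }
  expect_lt(amp_after(20), 0.10)          # 20 Hz sinusoid: < 10 % passes
  expect_gt(amp_after(1), 0.95)           # 1 Hz preserved within 5 %
  expect_error(lowpass_filter(circle_traj(duration = 0.1), n_taps = 50),
               "too short")
  expect_error(lowpass_filter(circle_traj(), cutoff_hz = 200), "Nyquist")
})

test_that("speed and curvature match closed forms on circle, line and helix", {
  tr <- circle_traj(radius = 5, omega = 2 * pi, duration = 1)
  interior <- 30:210
  expect_equal(compute_speed(tr)[interior], rep(10 * pi, length(interior)),
               tolerance = 1e-4)
  expect_equal(compute_curvature(tr)[interior], rep(0.2, length(interior)),
               tolerance = 1e-4)
  ln <- line_traj(slope = 3)
  expect_equal(compute_speed(ln), rep(3, n_samples(ln)), tolerance = 1e-9)
  k_line <- compute_curvature(ln)
  expect_true(all(k_line[30:200] < 1e-6))
  hx <- helix_traj(r = 2, cc = 1)
  expect_equal(compute_curvature(hx)[100:600], rep(0.4, 501),
               tolerance = 1e-4)
  ## central-difference fallback agrees on smooth data
  expect_equal(compute_speed(hx, "central")[100:600],
               compute_speed(hx, "spline")[100:600], tolerance = 1e-4)
})

test_that("stationary input is rejected as degenerate", {
  tt <- seq(0, 1, by = 1 / 240)
  still <- trajectory(tt, matrix(1, length(tt), 3))
  expect_error(kinematic_profile(still), "degenerate")
})

test_that("curvature is invariant under rigid motion; speed/curvature scale correctly", {
  set.seed(11)
  tr <- generate_base_trajectory(synth_spec(seed = 11))
  k0 <- compute_curvature(tr)
  ## random rotation (QR of a random matrix) + translation
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tr_rot <- trajectory(tr$times,
                       sweep(tr$positions %*% Q, 2, c(10, -4, 7), `+`),
                       sample_rate = tr$sample_rate)
  k1 <- compute_curvature(tr_rot)
  interior <- 60:(n_samples(tr) - 60)
  expect_lt(max(abs(k1 - k0)[interior] / k0[interior]), 1e-8)
  ## spatial scaling by c = 2: speed doubles, curvature halves
  tr_sc <- trajectory(tr$times, 2 * tr$positions, sample_rate = tr$sample_rate)
  expect_equal(compute_speed(tr_sc)[interior], 2 * compute_speed(tr)[interior],
               tolerance = 1e-10)
  expect_equal(compute_curvature(tr_sc)[interior], k0[interior] / 2,
               tolerance = 1e-10)
})

test_that("power-law regression recovers exact generative parameters", {
  kappa <- seq(0.05, 0.5, length.out = 120)
  ## exact law v = 2 kappa^(-1/3)
  pr <- fake_profile(2 * kappa^(-1 / 3), kappa)
  f <- fit_power_law(pr)
  expect_equal(f$alpha_hat, 2, tolerance = 1e-6)
  expect_equal(f$beta_hat, -1 / 3, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-6)
  ## constant speed: beta = 0, perfect fit reported as compliance 1
  pc <- fake_profile(rep(4, 120), kappa)
  fc <- fit_power_law(pc)
  expect_equal(fc$beta_hat, 0, tolerance = 1e-6)
  expect_equal(fc$r_squared, 1)
  ## grid over the (alpha, beta) box, noise free, 1e-4 recovery
  for (al in c(0.5, 2, 5)) for (be in c(-1, -0.6, -0.2, 0)) {
    ff <- fit_power_law(fake_profile(al * kappa^be, kappa))
    expect_equal(ff$alpha_hat, al, tolerance = 1e-4)
    expect_equal(ff$beta_hat, be, tolerance = 1e-4)
  }
})

test_that("power-law regression is accurate under seeded noise", {
  set.seed(42)
  kappa <- exp(seq(log(0.05), log(0.5), length.out = 200))
  v <- 2 * kappa^(-1 / 3)
  vn <- v + rnorm(200, 0, 0.02 * mean(v))
  f <- fit_power_law(fake_profile(vn, kappa))
  expect_lt(abs(f$beta_hat + 1 / 3), 0.02)
  expect_gt(f$r_squared, 0.9)
})

test_that("power-law regression rejects bad intervals", {
  kappa <- seq(0.05, 0.5, length.out = 50)
  pr <- fake_profile(2 * kappa^(-0.5), kappa)
  expect_error(fit_power_law(pr, c(1, 4)), "5 valid samples")
  kappa2 <- kappa; kappa2[10] <- -0.1
  pr2 <- fake_profile(2 * kappa^(-0.5), kappa2)
  expect_error(fit_power_law(pr2), "sample 10")
})

test_that("compliance score matches the coefficient of determination", {
  expect_equal(compliance_r2(c(1, 2, 3), c(1, 2, 2)), 0.5)
  v <- c(2, 4, 7, 3)
  expect_equal(compliance_r2(v, v), 1)
  expect_equal(compliance_r2(v, rep(mean(v), 4)), 0)
  expect_error(compliance_r2(rep(1, 5), rep(1, 5)), "constant")
  ## property: equals the one-line classic formula on random inputs
  set.seed(7)
  for (rep in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(compliance_r2(a, b),
                 1 - sum((a - b)^2) / sum((a - mean(a))^2))
  }
})

test_that("filtering reduces the noise-induced speed error below 1 %", {
  ## error decomposition on a 1 Hz circle at sensor noise (0.08 cm):
  ## the noise-induced speed error (filtered-noisy vs filtered-clean) is
  ## what the 6 Hz filter controls and stays below 1 %; the remaining
  ## systematic deviation from the true 10*pi cm/s is the filter's small
  ## passband droop at 1 Hz (a few percent, bounded below)
  set.seed(5)
  clean <- circle_traj(radius = 5, omega = 2 * pi, duration = 1.5)
  noisy <- trajectory(clean$times,
                      clean$positions +
                        matrix(rnorm(3 * n_samples(clean), 0, 0.08),
                               ncol = 3),
                      sample_rate = clean$sample_rate)
  v_clean <- compute_speed(lowpass_filter(clean, 6, 50))
  v_noisy <- compute_speed(lowpass_filter(noisy, 6, 50))
  interior <- 60:(n_samples(clean) - 60)
  err <- abs(v_noisy - v_clean)[interior] / (10 * pi)
  expect_lt(sqrt(mean(err^2)), 0.01)       # rms noise error under 1 %
  expect_lt(max(err), 0.02)                # worst sample under 2 %
  expect_lt(max(abs(v_clean[interior] - 10 * pi) / (10 * pi)), 0.05)
  ## at 0.02 cm jitter even the worst sample stays below 1 %
  set.seed(6)
  noisy2 <- trajectory(clean$times,
                       clean$positions +
                         matrix(rnorm(3 * n_samples(clean), 0, 0.02),
                                ncol = 3),
                       sample_rate = clean$sample_rate)
  v2 <- compute_speed(lowpass_filter(noisy2, 6, 50))
  expect_lt(max(abs(v2 - v_clean)[interior]) / (10 * pi), 0.01)
})
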