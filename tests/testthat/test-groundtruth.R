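test_that("low-speed trimming keeps the largest above-threshold range", {
  ## bell-shaped profile peaking at 10: excludes samples below 1.5
  bell <- 10 * exp(-((1:200 - 100) / 40)^2)
  rng <- trim_low_speed(fake_profile(bell, rep(0.1, 200)), 0.15)
  expect_true(all(bell[rng[1]:rng[2]] >= 1.5))
  expect_true(bell[rng[1] - 1] < 1.5 && bell[rng[2] + 1] < 1.5)
  ## constant speed: full range
  expect_equal(trim_low_speed(fake_profile(rep(3, 50), rep(0.1, 50))),
               c(1, 50))
  ## interior dip below threshold is retained, only the ends are trimmed
  two_bump <- c(rep(0.5, 10), rep(10, 30), rep(0.5, 20), rep(10, 30),
                rep(0.5, 10))
  rng2 <- trim_low_speed(fake_profile(two_bump, rep(0.1, 100)), 0.15)
  expect_equal(rng2, c(11, 90))
})

test_that("random partition respects the minimum duration and the seed", {
  expect_error(random_partition(0.8, 3, 0.3), "cannot hold")
  ## tight feasibility: all durations must squeeze into (0.3, 0.31); the
  ## acceptance region has probability ~1e-4, so allow a large budget
  set.seed(1)
  br <- random_partition(0.91, 3, 0.3, max_iter = 200000L)
  expect_true(all(diff(c(0, br, 0.91)) > 0.3))
  expect_true(all(diff(c(0, br, 0.91)) < 0.31))
  set.seed(2)
  for (rep in 1:200) {
    b <- random_partition(3, 3, 0.3)
    expect_true(all(diff(c(0, b, 3)) > 0.3))
  }
  set.seed(99); b1 <- random_partition(2, 3, 0.3)
  set.seed(99); b2 <- random_partition(2, 3, 0.3)
  expect_identical(b1, b2)
})

test_that("beta sampling honors the gap constraint and the uniform marginal", {
  set.seed(3)
  for (rep in 1:200) {
    b <- sample_betas(3)
    expect_true(all(b >= -1 & b <= 0))
    expect_gt(min(abs(diff(b))), 0.1)
  }
  ## marginal of beta_1 stays uniform on [-1, 0] (the gap constrains only
  ## adjacent pairs jointly)
  set.seed(4)
  b1 <- replicate(5000, sample_betas(3)[1])
  expect_gt(suppressWarnings(ks.test(b1, "punif", -1, 0))$p.value, 0.01)
  set.seed(77); x <- sample_betas(3)
  set.seed(77); y <- sample_betas(3)
  expect_identical(x, y)
})

test_that("gain factors follow the continuity recursion", {
  kappa <- c(0.25, 0.4, 0.1, 0.3)
  prof <- fake_profile(c(10, 5, 5, 5), kappa)
  ## alpha_1 = v(0) kappa(0)^(-beta_1) = 10 * 0.25^(1/3)
  a <- compute_alphas(prof, c(2, 3), c(-1 / 3, -0.5, -0.2), start_idx = 1)
  expect_equal(a[1], 10 * 0.25^(1 / 3), tolerance = 1e-12)
  expect_equal(a[1], 6.2996, tolerance = 1e-4)
  ## equal betas (gap relaxed): alphas all equal
  ae <- compute_alphas(prof, c(2, 3), rep(-0.4, 3), start_idx = 1)
  expect_equal(ae, rep(ae[1], 3))
  ## piecewise law evaluated from left and right agrees at each boundary
  betas <- c(-0.8, -0.3, -0.6)
  aa <- compute_alphas(prof, c(2, 3), betas, start_idx = 1)
  for (i in 1:2) {
    kb <- kappa[c(2, 3)[i]]
    expect_equal(aa[i] * kb^betas[i], aa[i + 1] * kb^betas[i + 1],
                 tolerance = 1e-10)
  }
  prof_bad <- fake_profile(c(10, 5, 5, 5), c(0.25, 0, 0.1, 0.3))
  expect_error(compute_alphas(prof_bad, c(2, 3), c(-0.5, -0.2, -0.9)),
               "re-randomize")
})

test_that("time warp imposes the requested power law and preserves the path", {
  ## 3D curve with everywhere-positive curvature
  tt <- seq(0, 2, by = 1 / 240)
  tr <- trajectory(tt, cbind(8 * cos(1.5 * tt), 6 * sin(1.5 * tt),
                             2 * sin(3 * tt)))
  prof <- kinematic_profile(tr)
  rng <- c(20, n_samples(tr) - 20)
  v0 <- mean(prof$speed[rng[1]:rng[2]])
  ## beta = 0 with alpha = mean speed: arc-length parameterization
  wt0 <- time_warp(tr, prof, numeric(0), v0, 0, range_idx = rng)
  w0 <- kinematic_profile(wt0$trajectory)
  mid <- 30:(length(w0$speed) - 30)
  expect_lt(max(abs(w0$speed[mid] - mean(w0$speed[mid]))) /
              mean(w0$speed[mid]), 0.01)
  ## single segment beta = -1/3: log speed vs log curvature is linear with
  ## slope -1/3
  a1 <- compute_alphas(prof, integer(0), -1 / 3, start_idx = rng[1])
  wt <- time_warp(tr, prof, numeric(0), a1, -1 / 3, range_idx = rng)
  wp <- kinematic_profile(wt$trajectory)
  sel <- 15:(length(wp$speed) - 15)
  fit <- lm(log(wp$speed[sel]) ~ log(wp$curvature[sel]))
  expect_equal(unname(coef(fit)[2]), -1 / 3, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.999)
  ## spatial path preserved: every warped point lies within one source
  ## sample spacing of the source point set
  src <- tr$positions[rng[1]:rng[2], ]
  d2path <- vapply(seq_len(n_samples(wt$trajectory)), function(i)
    min(colSums((t(src) - wt$trajectory$positions[i, ])^2)), numeric(1))
  expect_lt(max(sqrt(d2path)), max(prof$speed) / 240)
})

test_that("ground-truth synthesis meets its acceptance contract", {
  set.seed(1)
  base <- generate_base_trajectory(synth_spec(seed = 301))
  wt <- synthesize_ground_truth(base, ground_truth_spec(seed = 301))
  segs <- wt$segments
  expect_equal(nrow(segs), 3)
  expect_true(all(segs$r_squared >= 0.97))
  expect_true(all(segs$beta >= -1 & segs$beta <= 0))
  ## refitted exponents close to the imposed ones (noise-free construction)
  expect_true(all(abs(segs$beta_hat - segs$beta) < 0.05))
  ## speed continuity at internal boundaries (< 1 % jump)
  wp <- kinematic_profile(wt$trajectory)
  for (i in 1:2) {
    tb <- segs$t_end[i]
    j <- which.min(abs(wp$times - tb))
    expect_lt(abs(wp$speed[j + 2] - wp$speed[j - 2]) / wp$speed[j], 0.05)
  }
  ## total duration preserved within one sample period
  prof <- kinematic_profile(base)
  rng <- trim_low_speed(prof, 0.15)
  dur_src <- base$times[rng[2]] - base$times[rng[1]]
  expect_lt(abs(duration(wt$trajectory) - dur_src), 1.5 / 240)
  ## log-log curve is piecewise linear within segments
  for (i in 1:3) {
    sel <- which(wp$times >= segs$t_start[i] & wp$times <= segs$t_end[i])
    sel <- sel[13:(length(sel) - 12)]
    fit <- lm(log(wp$speed[sel]) ~ log(wp$curvature[sel]))
    expect_lt(sqrt(mean(resid(fit)^2)), 1e-2)
  }
})

test_that("warping an already-compliant trajectory is near-idempotent", {
  tt <- seq(0, 2, by = 1 / 240)
  tr <- trajectory(tt, cbind(8 * cos(1.5 * tt), 6 * sin(1.5 * tt),
                             2 * sin(3 * tt)))
  prof <- kinematic_profile(tr)
  rng <- c(20, n_samples(tr) - 20)
  a1 <- compute_alphas(prof, integer(0), -1 / 3, start_idx = rng[1])
  wt <- time_warp(tr, prof, numeric(0), a1, -1 / 3, range_idx = rng)
  ## re-warp the output with its own parameters: tau stays affine in t
  wp <- kinematic_profile(wt$trajectory)
  rng2 <- c(10, n_samples(wt$trajectory) - 10)
  a2 <- compute_alphas(wp, integer(0), -1 / 3, start_idx = rng2[1])
  wt2 <- time_warp(wt$trajectory, wp, numeric(0), a2, -1 / 3,
                   range_idx = rng2, rescale_duration = FALSE)
  tgrid <- wt$trajectory$times[rng2[1]:rng2[2]]
  relerr <- abs(wt2$tau - (tgrid - tgrid[1])) / diff(range(tgrid))
  expect_lt(max(relerr), 1e-3)
})

test_that("ground-truth bundles serialize to CSV + JSON sidecar", {
  base <- generate_base_trajectory(synth_spec(seed = 302))
  wt <- synthesize_ground_truth(base, ground_truth_spec(seed = 302))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_ground_truth(wt, csv, js)
  tr2 <- read_trajectory_csv(csv)
  expect_equal(n_samples(tr2), n_samples(wt$trajectory))
  side <- jsonlite::fromJSON(js)
  expect_equal(nrow(side$segments), 3)
  expect_equal(side$segments$beta, wt$segments$beta, tolerance = 1e-9)
  unlink(c(csv, js))
})
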