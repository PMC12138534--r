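test_that("window downsampling equals the brute-force tile mean", {
  A <- matrix(1:900, 30, 30)
  expect_equal(downsample_windows(A, 15), oracle_tile_means(A, 15))
  expect_equal(downsample_windows(matrix(3.5, 40, 40), 15),
               matrix(3.5, 2, 2))  # partial edge tiles dropped
  set.seed(4)
  B <- matrix(rnorm(45 * 45), 45, 45)
  expect_equal(downsample_windows(B, 15), oracle_tile_means(B, 15))
  expect_error(downsample_windows(matrix(1, 8, 8), 15), "smaller")
})

test_that("trial segmentation aligns trials and rejects incomplete ones", {
  p <- stim_protocol()  # 40 x 15 s at 50 fps
  fpt <- 15 * 50
  stack <- array(seq_len(2 * 2 * 40 * fpt), c(2, 2, 40 * fpt))
  tr <- segment_trials(stack, p, triggers = (0:39) * 15)
  expect_equal(dim(tr$data), c(2, 2, 750, 40))
  # frame 1 of trial k is frame (k-1)*750 + 1 of the recording
  expect_equal(tr$data[, , 1, 3], stack[, , 2 * 750 + 1])

  one <- segment_trials(stack[, , 1:fpt, drop = FALSE], p, triggers = 0)
  expect_equal(dim(one$data)[4], 1)

  # a trigger with only half a trial of frames left is rejected, with a log
  expect_message(
    short <- segment_trials(stack[, , 1:(fpt + 300), drop = FALSE], p,
                            triggers = c(0, 15)),
    "rejecting 1 incomplete")
  expect_equal(short$kept, 1L)
  expect_error(segment_trials(stack, p, triggers = c(0, 1e5)), "outside")
})

test_that("percent change is baseline-anchored with zero baseline mean", {
  p <- stim_protocol(baseline_s = 2, stim_s = 2, recovery_s = 11,
                     frame_rate = 50)
  course <- c(rep(100, 100), rep(120, 101), rep(100, 549))
  pc <- trial_percent_change(course, p)
  expect_equal(pc[101:201], rep(20, 101))
  expect_equal(mean(pc[1:100]), 0)

  expect_equal(trial_percent_change(rep(55, 750), p), rep(0, 750))

  # hand-computed 4-frame example at 1 fps with a 2-frame baseline
  p4 <- stim_protocol(baseline_s = 2, stim_s = 1, recovery_s = 1,
                      frame_rate = 1)
  expect_equal(trial_percent_change(c(100, 100, 110, 90), p4),
               c(0, 0, 10, -10))
  expect_error(trial_percent_change(c(0, 0, 1, 1), p4), "positive")
})

test_that("responder selection takes the ceiling fraction with fixed ties", {
  p <- stim_protocol(frame_rate = 10)
  fpt <- 150
  flat <- array(100, c(2, 2, fpt))
  sel <- select_responders(flat, p, fraction = 0.10)
  expect_length(sel, 1)  # ceiling(0.4) = 1; tie-break deterministic
  expect_identical(sel, select_responders(flat, p, fraction = 0.10))

  # zero noise: the selected set is exactly the constructed responder set
  spec <- nvc_trial_spec(noise_sigma_percent = 0, amplitude_percent = 20,
                         responders = c(5, 23, 41, 87, 88, 89, 90, 95, 96, 97))
  g <- generate_nvc_trials(spec)
  tr <- segment_trials(g$stack, g$protocol, g$triggers)
  for (k in c(1, 20, 40)) {
    trial <- array(tr$data[, , , k], dim(tr$data)[1:3])
    expect_identical(select_responders(trial, g$protocol, 0.10),
                     sort(spec$responders))
  }
})

test_that("trial averaging recovers amplitude and reduces to one trial when noiseless", {
  # identical noiseless trials: mean course equals any single trial course
  spec <- nvc_trial_spec(noise_sigma_percent = 0, amplitude_percent = 20)
  g <- generate_nvc_trials(spec)
  res <- average_response(segment_trials(g$stack, g$protocol, g$triggers))
  expect_equal(res$mean_percent_course, res$per_trial_courses[, 1])
  expect_equal(res$peak_percent, 20)
  expect_equal(res$auc_stim, 40)  # 20% plateau x 2 s

  # zero amplitude: nothing to detect
  z <- generate_nvc_trials(nvc_trial_spec(amplitude_percent = 0,
                                          noise_sigma_percent = 0))
  rz <- average_response(segment_trials(z$stack, z$protocol, z$triggers))
  expect_equal(rz$peak_percent, 0)
  expect_equal(rz$auc_stim, 0)

  # 15% amplitude, 2% noise, 40 trials: peak within 1%
  n <- generate_nvc_trials(nvc_trial_spec(seed = 11))
  rn <- average_response(segment_trials(n$stack, n$protocol, n$triggers))
  expect_equal(rn$peak_percent, 15, tolerance = 1 / 15)
})

test_that("every per-trial percent course has zero baseline mean", {
  g <- generate_nvc_trials(nvc_trial_spec(
    protocol = stim_protocol(n_trials = 8), noise_sigma_percent = 5,
    seed = 3))
  res <- average_response(segment_trials(g$stack, g$protocol, g$triggers))
  bi <- seq_len(2 * 50)  # 2-s baseline at 50 fps
  for (tr in seq_len(ncol(res$per_trial_courses)))
    expect_lt(abs(mean(res$per_trial_courses[bi, tr])), 1e-10)
})

test_that("percent and absolute responses agree on a uniform baseline", {
  b <- 80
  g <- generate_nvc_trials(nvc_trial_spec(
    baseline_level = b, amplitude_percent = 12, noise_sigma_percent = 0,
    shape = "gamma", protocol = stim_protocol(n_trials = 4)))
  res <- average_response(segment_trials(g$stack, g$protocol, g$triggers))
  expect_equal(res$delta_cbf_course, b / 100 * res$mean_percent_course,
               tolerance = 1e-12)
})

test_that("recovered peak grows with true amplitude and tracks it within 10%", {
  peaks <- vapply(c(5, 10, 15, 20), function(amp) {
    g <- generate_nvc_trials(nvc_trial_spec(amplitude_percent = amp,
                                            seed = 100 + amp))
    average_response(segment_trials(g$stack, g$protocol,
                                    g$triggers))$peak_percent
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(abs(peaks / c(5, 10, 15, 20) - 1) < 0.10))
})

test_that("course metrics integrate the stimulation window only", {
  p <- stim_protocol(frame_rate = 50)
  t <- (seq_len(750) - 1) / 50
  # 20% plateau across the closed stimulation window
  plateau <- ifelse(t >= 2 & t <= 4, 20, 0)
  m <- nvc_metrics(plateau, p)
  expect_equal(m$peak_percent, 20)
  expect_equal(m$auc_stim, 40)

  z <- nvc_metrics(rep(0, 750), p)
  expect_equal(z$peak_percent, 0)
  expect_equal(z$auc_stim, 0)

  # triangle rising 0 -> 10% across the 2-s stim window, then back down:
  # trapezoid area over the window is 10 %.s (hand computation)
  tri <- pmax(0, pmin((t - 2) * 5, 10 - (t - 4) * 5))
  tri[t < 2] <- 0
  mt <- nvc_metrics(tri, p)
  expect_equal(mt$auc_stim, 10, tolerance = 1e-9)
  expect_equal(mt$time_to_peak_s, 2)
})
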