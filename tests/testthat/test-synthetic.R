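test_that("K = 2 with zero diagonal forces strict alternation", {
  P <- rbind(c(0, 1), c(1, 0))
  gt <- tiny_gt(K = 2, C = 6, transition = P, fs = 500)
  seg <- sample_label_stream(gt, 20, seed = 81)
  cls <- attr(seg, "true_segments")$class
  expect_true(all(diff(cls) != 0))
})

test_that("segment transition frequencies converge to the generator matrix", {
  P <- rbind(c(0, 0.5, 0.3, 0.2),
             c(0.4, 0, 0.4, 0.2),
             c(0.25, 0.25, 0, 0.5),
             c(0.1, 0.3, 0.6, 0))
  gt <- tiny_gt(transition = P, fs = 500, mean_dwell = 60)
  # ~8,000 segments is enough for a 0.05 unit check; the 50k-segment 0.02
  # bound is exercised in the acceptance suite
  seg <- sample_label_stream(gt, 8000 * 0.06, seed = 82, single_epoch = TRUE)
  ts <- attr(seg, "true_segments")
  est <- params_from_segments_test(ts$class, 4)
  expect_lt(max(abs(est - P)), 0.05)
})

test_that("empirical mean dwell matches the requested per-class mean", {
  gt <- tiny_gt(fs = 500, mean_dwell = c(80, 100, 60, 120))
  seg <- sample_label_stream(gt, 600, seed = 83, single_epoch = TRUE)
  ts <- attr(seg, "true_segments")
  for (k in 1:4) {
    m <- mean(ts$length[ts$class == k]) / gt$fs * 1000
    expect_lt(abs(m - gt$mean_dwell[k]) / gt$mean_dwell[k], 0.05)
  }
})

test_that("identical seeds give bit-identical recordings", {
  gt <- tiny_gt(snr = 2, fs = 500)
  r1 <- simulate(gt, seed = 84, duration_s = 5)[[1]]
  r2 <- simulate(gt, seed = 84, duration_s = 5)[[1]]
  expect_identical(r1$data, r2$data)
  r3 <- simulate(gt, seed = 85, duration_s = 5)[[1]]
  expect_false(identical(r1$data, r3$data))
})

test_that("ground truth validates its invariants", {
  P <- rbind(c(0.2, 0.8), c(1, 0))
  expect_error(tiny_gt(K = 2, C = 6, transition = P), "diagonal")
  P2 <- rbind(c(0, 0.7), c(1, 0))
  expect_error(tiny_gt(K = 2, C = 6, transition = P2), "sum to 1")
  expect_error(tiny_gt(mean_dwell = -5), "positive")
  expect_error(tiny_gt(carrier_freq = 45), "carrier")
  # near-duplicate templates rejected
  m <- orthogonal_maps(8, 2)
  dup <- cbind(m[, 1], m[, 1] + 1e-3 * m[, 2])
  expect_error(ms_ground_truth(template_set(dup), mean_dwell = 80),
               "distinguishable")
})

test_that("rendering validates inputs and honours the snr contract", {
  gt <- tiny_gt(snr = Inf, fs = 500)
  gt_alias <- tiny_gt(fs = 500)
  gt_alias$carrier_freq <- 300
  seg <- sample_label_stream(tiny_gt(fs = 500), 10, seed = 86)
  expect_error(render_eeg(seg, gt_alias), "aliasing")

  # noiseless: topography at every envelope peak correlates |r| = 1 with its
  # generating template
  seg0 <- sample_label_stream(gt, 10, seed = 87)
  rec <- render_eeg(seg0, gt)
  g <- find_gfp_peaks(gfp(rec))
  pk <- g$peak_indices
  r <- abs(diag(cor(rec$data[, pk + 1], gt$templates$maps[, seg0$labels[pk + 1]])))
  expect_true(all(r > 1 - 1e-9))
  # GFP peaks sit at envelope extrema: spacing = half carrier period
  half <- gt$fs / (2 * gt$carrier_freq)
  expect_true(all(abs(diff(pk) - half) <= 1))
})

test_that("snr = 1 backfit of true templates recovers >= 90% of samples", {
  gt <- tiny_gt(snr = 1, fs = 500)
  seg <- sample_label_stream(gt, 60, seed = 88)
  rec <- render_eeg(seg, gt)
  bf <- backfit(bandpass(rec, 2, 20), gt$templates)
  expect_gte(mean(bf$labels == seg$labels, na.rm = TRUE), 0.90)
})

test_that("cohort simulation emits n_low + n_high recordings and demographics", {
  gt <- tiny_gt(snr = 1, fs = 500)
  co <- simulate_cohort(group_spec(3), group_spec(4), gt, duration_s = 10,
                        seed = 89, render = "labels")
  expect_length(co$subjects, 7)
  expect_equal(nrow(co$demographics), 7)
  expect_equal(sum(co$demographics$group == "low"), 3)
  expect_true(all(co$demographics$parent_edu_1 %in% 1:5))
  expect_true(all(co$demographics$parent_occ_1 %in% 1:10))
  # per-subject transition matrices stay row-stochastic after deltas+jitter
  for (s in co$subjects) {
    expect_equal(rowSums(s$gt$transition), rep(1, 4), tolerance = 1e-12)
    expect_true(all(diag(s$gt$transition) == 0))
  }
  expect_error(group_spec(1), "n_subjects")
})

test_that("the SES effect preset shifts A-dynamics in the programmed direction", {
  pre <- ses_effect_preset(0.3)
  gt <- tiny_gt(snr = 1, fs = 500)
  gt_low <- mseeg:::apply_deltas(gt, pre$dwell_delta, pre$transition_delta)
  expect_equal(gt_low$mean_dwell[1], 80 * 1.3)
  expect_gt(gt_low$transition[2, 1], gt$transition[2, 1])  # B -> A boosted
  expect_lt(gt_low$transition[2, 3], gt$transition[2, 3])  # B -> C damped
  expect_equal(rowSums(gt_low$transition), rep(1, 4), tolerance = 1e-12)
})
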