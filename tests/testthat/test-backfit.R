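test_that("peaks take the best-correlating template label, polarity ignored", {
  tpl <- template_set(orthogonal_maps(8, 4), labels = LETTERS[1:4])
  expect_equal(assign_peaks(tpl$maps[, 2, drop = FALSE], tpl), 2L,
               ignore_attr = TRUE)
  expect_equal(assign_peaks(-tpl$maps[, 2, drop = FALSE], tpl), 2L,
               ignore_attr = TRUE)
  # noisy copies still agree >= 95% with their generators at snr ~ 10
  set.seed(31)
  idx <- sample(1:4, 400, replace = TRUE)
  V <- tpl$maps[, idx] + matrix(rnorm(8 * 400, sd = sqrt(1 / (8 * 10))), 8)
  lab <- assign_peaks(V, tpl)
  expect_gte(mean(lab == idx), 0.95)
})

test_that("flat peak maps are left unassigned with a warning", {
  tpl <- template_set(orthogonal_maps(8, 2))
  V <- cbind(tpl$maps[, 1], 0)
  expect_warning(lab <- assign_peaks(V, tpl), "flat")
  expect_equal(lab[1], 1L, ignore_attr = TRUE)
  expect_true(is.na(lab[2]))
})

test_that("label expansion follows the nearest-peak rule with earlier-peak ties", {
  # the midpoint sample 20 is equidistant from peaks 10 and 30 -> earlier
  seg <- interpolate_labels(c(1L, 2L), c(10L, 30L),
                            cbind(start = 0L, end = 40L), 40, fs = 100)
  expect_equal(seg$labels, c(rep(1L, 21), rep(2L, 19)))

  # single peak labels its whole epoch
  seg1 <- interpolate_labels(2L, 5L, cbind(start = 0L, end = 30L), 30,
                             fs = 100)
  expect_equal(seg1$labels, rep(2L, 30))

  # alternating equally-spaced peaks -> 4 segments
  seg2 <- interpolate_labels(c(1L, 2L, 1L, 2L), c(10L, 30L, 50L, 70L),
                             cbind(start = 0L, end = 80L), 80, fs = 100,
                             K = 2)
  expect_equal(nrow(seg2$segments), 4)

  # epoch without a peak stays unassigned
  seg3 <- interpolate_labels(1L, 5L,
                             rbind(c(start = 0L, end = 20L),
                                   c(start = 20L, end = 40L)), 40, fs = 100)
  expect_true(all(is.na(seg3$labels[21:40])))
  expect_true(all(seg3$labels[1:20] == 1L))
})

test_that("every labeled sample matches its nearest peak (direct scan)", {
  set.seed(37)
  n <- 400
  epochs <- rbind(c(start = 0L, end = 200L), c(start = 200L, end = 400L))
  pk <- sort(sample(0:(n - 1), 30))
  lab <- sample(1:4, 30, replace = TRUE)
  seg <- interpolate_labels(lab, pk, epochs, n, fs = 100, K = 4)
  for (s in 0:(n - 1)) {
    e <- if (s < 200) 1 else 2
    inside <- pk >= epochs[e, "start"] & pk < epochs[e, "end"]
    if (!any(inside)) next
    d <- abs(pk[inside] - s)
    nearest <- which(d == min(d))[1]  # earlier peak on ties
    expect_identical(seg$labels[s + 1], lab[inside][nearest])
  }
})

test_that("segment list tiles epochs with truncation flags and no repeats", {
  labels <- c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1)
  seg <- segmentation(labels, fs = 10, epochs = rbind(c(start = 0L, end = 5L),
                                                      c(start = 5L, end = 10L)),
                      K = 3)
  s <- seg$segments
  expect_equal(sum(s$length), 10)
  expect_equal(nrow(s), 5)
  # runs never cross the epoch boundary: 2,2,2 | 1 ... are separate
  expect_equal(s$class, c(1, 2, 1, 3, 1))
  expect_equal(s$truncated_left, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(s$truncated_right, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # segment count identity: label changes + epochs with >= 1 peak
  changes <- sum(diff(labels) != 0) - 1  # one "change" is the epoch cut
  expect_equal(nrow(s), changes + nrow(seg$epochs))
})

test_that("backfitting true templates at infinite snr reproduces the stream", {
  gt <- tiny_gt(snr = Inf, fs = 500)
  seg <- sample_label_stream(gt, 30, seed = 41)
  rec <- render_eeg(seg, gt)
  bf <- backfit(bandpass(rec, 2, 20), gt$templates)
  agree <- mean(bf$labels == seg$labels, na.rm = TRUE)
  expect_gte(agree, 0.95)
  # disagreements live within half a carrier period of a switch
  half <- gt$fs / (2 * gt$carrier_freq)
  bad <- which(bf$labels != seg$labels)
  if (length(bad)) {
    switches <- which(diff(seg$labels) != 0)
    mind <- vapply(bad, function(b) min(abs(b - switches)), numeric(1))
    expect_lte(max(mind), half)
  }
})
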