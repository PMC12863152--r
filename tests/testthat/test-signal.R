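test_that("band-pass keeps in-band tones, rejects out-of-band and DC", {
  fs <- 1000
  t <- (0:1999) / fs
  two_ch <- function(x) recording(rbind(x, -x), fs)
  core <- 300:1700  # avoid filter edge transients

  in_band <- bandpass(two_ch(sin(2 * pi * 10 * t)), 2, 20)
  gain <- sqrt(mean(in_band$data[1, core]^2)) / sqrt(0.5)
  expect_lt(abs(gain - 1), 0.01)

  out_band <- bandpass(two_ch(sin(2 * pi * 50 * t)), 2, 20)
  atten <- sqrt(mean(out_band$data[1, core]^2)) / sqrt(0.5)
  expect_lt(20 * log10(atten), -20)

  dc <- bandpass(recording(rbind(rep(3, 2000), rep(-1, 2000)), fs), 2, 20)
  expect_lt(abs(mean(dc$data[1, core])), 0.05)
})

test_that("band-pass validates edges and warns on too-short epochs", {
  fs <- 250
  rec <- recording(matrix(rnorm(2 * 500), 2), fs,
                   epochs = rbind(c(0, 10), c(10, 500)))
  expect_warning(bandpass(rec, 2, 20), "unfiltered")
  expect_error(bandpass(recording(matrix(rnorm(200), 2), fs), 20, 2))
  expect_error(bandpass(recording(matrix(rnorm(200), 2), fs), 2, 200))
})

test_that("average referencing is the zero-mean projection", {
  expect_equal(average_reference(c(3, 1)), c(1, -1))
  x <- matrix(rnorm(50), 5)
  once <- average_reference(x)
  expect_equal(colMeans(once), rep(0, 10), tolerance = 1e-12)
  expect_equal(average_reference(once), once)  # idempotent
})

test_that("GFP equals the spatial standard deviation (divisor C)", {
  expect_equal(gfp(matrix(c(1, -1), 2, 1))$values, 1)
  expect_equal(gfp(matrix(c(5, 5, 5), 3, 1))$values, 0)
  expect_equal(gfp(matrix(c(2, 0, 0, -2), 4, 1))$values, sqrt(2))
  # constant channel offset at a sample is removed by the internal centering
  v <- rnorm(6)
  expect_equal(unname(gfp(cbind(v))$values), unname(gfp(cbind(v + 7))$values))
  # linear in amplitude; invariant to channel permutation and sign flip
  m <- matrix(rnorm(40), 5)
  expect_equal(gfp(3 * m)$values, 3 * gfp(m)$values)
  expect_equal(gfp(m[sample(5), ])$values, gfp(m)$values)
  expect_equal(gfp(-m)$values, gfp(m)$values)
})

test_that("GFP peaks are strict interior local maxima with plateau rule", {
  g <- structure(list(values = c(0, 1, 0, 2, 0), peak_indices = NULL,
                      fs = NA_real_, epochs = cbind(start = 0L, end = 5L)),
                 class = "ms_gfp")
  expect_equal(find_gfp_peaks(g)$peak_indices, c(1L, 3L))

  mono <- structure(list(values = 1:6, peak_indices = NULL, fs = NA_real_,
                         epochs = cbind(start = 0L, end = 6L)),
                    class = "ms_gfp")
  expect_equal(find_gfp_peaks(mono)$peak_indices, integer(0))

  # plateau counts once, at its first sample
  plat <- structure(list(values = c(0, 2, 2, 2, 0, 1, 0),
                         peak_indices = NULL, fs = NA_real_,
                         epochs = cbind(start = 0L, end = 7L)),
                    class = "ms_gfp")
  expect_equal(find_gfp_peaks(plat)$peak_indices, c(1L, 5L))

  # epoch boundaries are never peaks even if locally maximal
  two <- structure(list(values = c(0, 1, 2, 2, 1, 0), peak_indices = NULL,
                        fs = NA_real_,
                        epochs = rbind(c(start = 0L, end = 3L),
                                       c(start = 3L, end = 6L))),
                   class = "ms_gfp")
  expect_equal(find_gfp_peaks(two)$peak_indices, integer(0))
})

test_that("a 10 Hz rectified envelope at 1 kHz yields ~20 GFP peaks per second", {
  fs <- 1000
  t <- (0:(fs - 1)) / fs
  maps <- orthogonal_maps(6, 2)
  rec <- recording(maps[, 1] %o% sin(2 * pi * 10 * t), fs)
  g <- find_gfp_peaks(gfp(rec))
  expect_equal(length(g$peak_indices), 20, tolerance = 0.05)
})

test_that("GFP and peak locations survive channel permutation and sign flip", {
  set.seed(42)
  fs <- 250
  rec <- recording(matrix(rnorm(8 * 500), 8), fs)
  g0 <- find_gfp_peaks(gfp(rec))
  flip <- recording(-rec$data, fs)
  perm <- recording(rec$data[sample(8), ], fs)
  expect_equal(find_gfp_peaks(gfp(flip))$peak_indices, g0$peak_indices)
  expect_equal(find_gfp_peaks(gfp(perm))$peak_indices, g0$peak_indices)
})
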