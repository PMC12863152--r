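test_that("spatial correlation matches hand-computed Pearson values", {
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation(a, b), 0)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), 1)
  expect_equal(spatial_correlation(a, -a, polarity_invariant = FALSE), -1)
  # centering matters: correlation of raw vectors vs stats::cor
  x <- c(2, 4, 1, 7); y <- c(1, 0, 2, 5)
  expect_equal(spatial_correlation(x, y, polarity_invariant = FALSE),
               cor(x, y))
  expect_error(spatial_correlation(c(1, 1, 1), c(1, 2, 3)), "flat")
  expect_error(spatial_correlation(c(1, 2), c(1, 2, 3)), "channel")
})

test_that("AAHC recovers exact copies of orthogonal templates with GEV 1", {
  tpl <- orthogonal_maps(8, 2)
  V <- tpl[, c(1, 2, 1, 2, 1, 2)]
  fit <- aahc(V, weights = rep(1, 6), K = 2)
  expect_equal(fit$gev_total, 1, tolerance = 1e-12)
  expect_equal(fit$assignment[c(1, 3, 5)], rep(fit$assignment[1], 3))
  expect_equal(fit$assignment[c(2, 4, 6)], rep(fit$assignment[2], 3))
  for (k in 1:2) {
    r <- max(abs(crossprod(fit$templates$maps[, k], tpl)))
    expect_equal(r, 1, tolerance = 1e-9)
  }
})

test_that("K equal to the number of maps gives GEV 1", {
  set.seed(5)
  V <- matrix(rnorm(8 * 5), 8, 5)
  fit <- aahc(V, K = 5)
  expect_equal(fit$gev_total, 1, tolerance = 1e-9)
})

test_that("AAHC recovers generating templates from noisy copies", {
  set.seed(11)
  tpl <- orthogonal_maps(12, 4)
  idx <- rep(1:4, each = 10)
  noise <- matrix(rnorm(12 * 40), 12, 40) / sqrt(10)  # snr ~ 10
  V <- tpl[, idx] + noise * sqrt(colSums(tpl[, idx]^2)) / sqrt(12)
  fit <- aahc(V, K = 4)
  R <- abs(corr_matrix_test(fit$templates$maps, tpl))
  expect_true(all(apply(R, 2, max) >= 0.99))
})

test_that("AAHC ties the exhaustive assignment optimum on separable fixtures", {
  # separable = well-clustered maps with near-uniform GFP weights; wildly
  # uneven weights can make the greedy victim rule atomize a good cluster,
  # which is inherent to AAHC, not an implementation defect
  set.seed(3)
  for (case in 1:3) {
    tpl <- orthogonal_maps(6, 2)
    V <- tpl[, c(1, 1, 1, 2, 2, 2)] +
      matrix(rnorm(6 * 6, sd = 0.05), 6, 6)
    w <- runif(6, 0.9, 1.1)
    fit <- aahc(V, weights = w, K = 2)
    best <- best_gev_exhaustive(V, w, 2)
    expect_gte(fit$gev_total, best - 1e-9)
  }
})

test_that("GEV matches its defining formula", {
  tpl <- template_set(orthogonal_maps(6, 2))
  # 3 peaks with GFP (1,1,2) and |r| = (1,0,1): gev = (1+0+4)/(1+1+4)
  V <- cbind(tpl$maps[, 1], tpl$maps[, 2], tpl$maps[, 1])
  g <- gev(V, weights = c(1, 1, 2), tpl, assignment = c(1L, 1L, 1L))
  expect_equal(g$gev_total, 5 / 6, tolerance = 1e-12)
  expect_equal(sum(g$gev_per_class), g$gev_total, tolerance = 1e-12)
  # perfect assignment -> 1; orthogonal assignment -> 0
  g1 <- gev(tpl$maps, c(1, 1), tpl, c(1L, 2L))
  expect_equal(g1$gev_total, 1, tolerance = 1e-12)
  g0 <- gev(tpl$maps, c(1, 1), tpl, c(2L, 1L))
  expect_equal(g0$gev_total, 0, tolerance = 1e-12)
})

test_that("clustering is invariant to map sign flips and channel permutation", {
  set.seed(21)
  tpl <- orthogonal_maps(10, 3)
  V <- tpl[, rep(1:3, each = 8)] + matrix(rnorm(10 * 24, sd = 0.1), 10, 24)
  w <- runif(24, 0.5, 2)
  base <- aahc(V, w, K = 3)

  flips <- sample(c(-1, 1), 24, replace = TRUE)
  f1 <- aahc(sweep(V, 2, flips, "*"), w, K = 3)
  expect_equal(f1$assignment, base$assignment)
  expect_equal(f1$gev_total, base$gev_total, tolerance = 1e-9)

  pm <- sample(10)
  f2 <- aahc(V[pm, ], w, K = 3)
  expect_equal(f2$assignment, base$assignment)
  expect_equal(f2$gev_total, base$gev_total, tolerance = 1e-9)
  expect_equal(abs(f2$templates$maps), abs(base$templates$maps[pm, ]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("group templates pool and re-cluster individual maps", {
  tpl <- template_set(orthogonal_maps(8, 3))
  fits <- list(tpl, tpl, tpl)
  g <- group_templates(fits, K = 3)
  R <- abs(corr_matrix_test(g$maps, tpl$maps))
  expect_true(all(apply(R, 2, max) > 1 - 1e-9))
  expect_equal(g$level, "group")

  # sign-flipped copies give the same group maps (polarity invariance)
  flipped <- template_set(-tpl$maps)
  g2 <- group_templates(list(tpl, flipped), K = 3)
  R2 <- abs(corr_matrix_test(g2$maps, tpl$maps))
  expect_true(all(apply(R2, 2, max) > 1 - 1e-9))

  bad <- template_set(orthogonal_maps(9, 3))
  expect_error(group_templates(list(tpl, bad)), "montage mismatch")
})

test_that("AAHC requires enough maps and rejects flat ones", {
  V <- orthogonal_maps(6, 2)
  expect_error(aahc(V, K = 4), "at least")
  V2 <- cbind(V, 0, V)
  expect_error(aahc(V2, K = 2), "flat")
})
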