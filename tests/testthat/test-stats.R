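test_that("SES composite matches the two-point hand computation", {
  d <- data.frame(parent_edu_1 = c(2, 4), parent_edu_2 = c(2, 4),
                  parent_occ_1 = c(3, 5), parent_occ_2 = c(3, 5))
  z <- ses_score(d)$ses_z
  expect_equal(z, c(-sqrt(2), sqrt(2)), tolerance = 1e-12)
  # shift invariance of either component
  d2 <- transform(d, parent_occ_1 = parent_occ_1 + 3,
                  parent_occ_2 = parent_occ_2 + 3)
  expect_equal(ses_score(d2)$ses_z, z, tolerance = 1e-12)
  # affine rescaling invariance
  d3 <- transform(d, parent_edu_1 = 1 + 0.5 * (parent_edu_1 - 1),
                  parent_edu_2 = 1 + 0.5 * (parent_edu_2 - 1))
  expect_equal(ses_score(d3)$ses_z, z, tolerance = 1e-12)
  # degenerate: identical families
  dd <- data.frame(parent_edu_1 = c(3, 3), parent_edu_2 = c(3, 3),
                   parent_occ_1 = c(4, 4), parent_occ_2 = c(4, 4))
  expect_error(ses_score(dd), "variance")
})

test_that("extreme-group split yields ceil(fraction x n) per tail", {
  d <- ses_score(simulate_ses_sample(107, seed = 61))
  g <- extreme_group_split(d, 0.27)
  expect_equal(as.vector(table(g$group)), c(29, 49, 29))

  d10 <- ses_score(simulate_ses_sample(10, seed = 62))
  expect_equal(sum(extreme_group_split(d10, 0.27)$group == "low"), 3)

  d8 <- ses_score(simulate_ses_sample(8, seed = 63))
  g8 <- extreme_group_split(d8, 0.5)
  expect_equal(sum(g8$group == "middle"), 0)
  expect_error(extreme_group_split(d8, 0.6), "overlap")

  # grouping respects the ranking
  expect_true(max(g$ses_z[g$group == "low"]) <=
                min(g$ses_z[g$group == "high"]))
})

test_that("correlation wrapper reproduces the definitional formula", {
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 9)
  res <- ms_correlate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(ms_correlate(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(ms_correlate(x, rep(1, 4)), "variance")
})

test_that("mixed ANCOVA has the SPSS univariate df pattern", {
  set.seed(67)
  n <- 58; K <- 4
  pt <- expand.grid(subject = sprintf("S%02d", 1:n), class = LETTERS[1:K])
  pt$group <- rep(rep(c("low", "high"), each = n / 2), K)
  pt$age <- rep(sample(18:23, n, TRUE), K)
  pt$gender <- rep(sample(c("F", "M"), n, TRUE), K)
  pt$value <- rnorm(n * K, 80, 10)
  out <- mixed_ancova(pt)
  expect_equal(out$df1, c(1, 3, 3))
  expect_equal(out$df2, c(54, 162, 162))
  expect_true(all(out$partial_eta2 >= 0 & out$partial_eta2 <= 1))
})

test_that("mixed ANCOVA F matches a direct projection-matrix oracle", {
  set.seed(71)
  n <- 12; K <- 3
  subj <- sprintf("S%02d", 1:n)
  group <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 20, 2)
  gender <- sample(c("F", "M"), n, TRUE)
  Y <- matrix(rnorm(n * K, 100, 15), n, K)
  Y[group == "b", 1] <- Y[group == "b", 1] + 10
  pt <- data.frame(subject = rep(subj, K),
                   class = rep(paste0("c", 1:K), each = n),
                   group = rep(group, K), age = rep(age, K),
                   gender = rep(gender, K), value = as.vector(Y))
  out <- mixed_ancova(pt)

  # oracle: univariate repeated-measures decomposition from projections.
  # Type III SS depend on the coding of the other terms, so the oracle uses
  # the same columns the model matrix has: sum-coded group, raw age,
  # 0/1 gender.
  g <- ifelse(group == "a", 1, -1)
  sx <- ifelse(gender == "F", 0, 1)
  X <- cbind(1, g, age, sx)
  rss <- function(X, y) sum(lm.fit(X, y)$residuals^2)
  # between stratum on subject means (times K restores the SS scale)
  m <- rowMeans(Y)
  ss_group <- K * (rss(X[, -2], m) - rss(X, m))
  ss_err_b <- K * rss(X, m)
  F_group <- (ss_group / 1) / (ss_err_b / (n - 4))
  expect_equal(out$F[out$effect == "group"], F_group, tolerance = 1e-8)

  # within stratum: orthonormal contrasts, stacked design
  Ct <- qr.Q(qr(cbind(1, diag(K))))[, 2:K]
  Z <- Y %*% Ct
  y <- as.vector(Z)
  XW <- kronecker(diag(K - 1), X)
  drop_block <- function(col) XW[, -(seq(col, ncol(XW), by = 4))]
  ss_class <- rss(drop_block(1), y) - rss(XW, y)
  ss_gxc <- rss(drop_block(2), y) - rss(XW, y)
  ss_err_w <- rss(XW, y)
  dfe <- (K - 1) * (n - 4)
  expect_equal(out$F[out$effect == "class"],
               (ss_class / (K - 1)) / (ss_err_w / dfe), tolerance = 1e-8)
  expect_equal(out$F[out$effect == "group:class"],
               (ss_gxc / (K - 1)) / (ss_err_w / dfe), tolerance = 1e-8)
  expect_equal(out$partial_eta2[out$effect == "group:class"],
               ss_gxc / (ss_gxc + ss_err_w), tolerance = 1e-8)
})

test_that("post hoc contrasts multiply p by K and cap at 1", {
  set.seed(73)
  n <- 20; K <- 4
  pt <- expand.grid(subject = sprintf("S%02d", 1:n), class = LETTERS[1:K])
  pt$group <- rep(rep(c("low", "high"), each = n / 2), K)
  pt$age <- rep(rnorm(n, 20), K)
  pt$gender <- rep(sample(c("F", "M"), n, TRUE), K)
  pt$value <- rnorm(n * K)
  pt$value[pt$class == "A" & pt$group == "low"] <-
    pt$value[pt$class == "A" & pt$group == "low"] + 5
  out <- posthoc_bonferroni(pt)
  expect_equal(out$p_adj, pmin(1, out$p * K), tolerance = 1e-12)
  expect_lt(out$p_adj[out$class == "A"], 0.05)
  expect_equal(out$df, rep(n - 4, K))  # intercept + group + 2 covariates
})

test_that("transition t-tests equal the pooled-variance formula on a toy table", {
  arr <- array(0, c(2, 2, 6))
  x <- c(0.60, 0.55, 0.70); y <- c(0.40, 0.45, 0.35)
  arr[1, 2, ] <- c(x, y); arr[2, 1, ] <- 1 - c(x, y)
  res <- transition_ttests(arr, rep(c("g1", "g2"), each = 3))
  row <- res[res$from == 1 & res$to == 2, ]
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$df, 4)
  expect_equal(row$cohens_d, (mean(x) - mean(y)) / sqrt(sp2),
               tolerance = 1e-12)
  # 12 ordered pairs for K = 4
  arr4 <- array(runif(4 * 4 * 6), c(4, 4, 6))
  res4 <- transition_ttests(arr4, rep(c("g1", "g2"), each = 3))
  expect_equal(nrow(res4), 12)
  # zero variance in both groups -> flagged NA, not an error
  arrc <- array(0.5, c(2, 2, 6))
  resc <- transition_ttests(arrc, rep(c("g1", "g2"), each = 3))
  expect_true(all(resc$degenerate))
  expect_true(all(is.na(resc$t)))
})
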