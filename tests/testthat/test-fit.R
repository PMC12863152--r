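test_that("the fitted model object exposes the standard methods", {
  gt <- tiny_gt(snr = 4, fs = 500)
  rec <- simulate(gt, seed = 101, duration_s = 10)[[1]]
  atlas <- template_set(gt$templates$maps, labels = LETTERS[1:4])
  fit <- microstate(rec, K = 4, sort_against = atlas)

  expect_s3_class(fit, "ms_fit")
  expect_output(print(fit), "GEV")
  expect_output(print(summary(fit)), "Temporal parameters")
  expect_equal(dim(coef(fit)), c(12, 4))
  expect_equal(colnames(coef(fit)), LETTERS[1:4])

  res <- residuals(fit)
  expect_length(res, length(fit$peaks))
  expect_true(all(res >= -1e-12 & res <= 1 + 1e-12))

  # predict backfits new data from the same generator
  rec2 <- simulate(gt, seed = 102, duration_s = 5)[[1]]
  seg <- predict(fit, rec2)
  expect_s3_class(seg, "ms_segmentation")
  expect_equal(length(seg$labels), ncol(rec2$data))

  # the fitted maps recover the generating templates
  R <- abs(corr_matrix_test(coef(fit), gt$templates$maps))
  expect_true(all(diag(R) > 0.95))
})

test_that("fitting without a reference leaves maps unsorted, no segmentation", {
  gt <- tiny_gt(snr = 4, fs = 500)
  rec <- simulate(gt, seed = 103, duration_s = 6)[[1]]
  fit <- microstate(rec, K = 4)
  expect_null(fit$segmentation)
  expect_equal(fit$templates$labels, as.character(1:4))
})

test_that("the two-level cohort pipeline recovers groups, templates, parameters", {
  gt <- tiny_gt(snr = 2, fs = 500)
  recs <- simulate(gt, seed = 104, duration_s = 12, nsim = 6)
  atlas <- template_set(gt$templates$maps, labels = LETTERS[1:4])
  co <- microstate_cohort(recs, groups = rep(c("low", "high"), each = 3),
                          K = 4, atlas = atlas)
  expect_s3_class(co, "ms_cohort")
  expect_length(co$group_templates, 2)
  expect_equal(nrow(co$params), 6 * 4)
  expect_equal(dim(co$transitions), c(4, 4, 6))
  expect_true(all(co$gev > 0.5))
  for (g in co$group_templates) {
    R <- abs(corr_matrix_test(g$maps, gt$templates$maps))
    expect_true(all(diag(R) > 0.9))
  }
  # recordings passed as a generator function give identical results
  co2 <- microstate_cohort(function(i) recs[[i]], n_subjects = 6,
                           groups = rep(c("low", "high"), each = 3),
                           K = 4, atlas = atlas)
  expect_equal(co2$params, co$params)
})

test_that("the pipeline driver is deterministic and validates its config", {
  gt <- tiny_gt(snr = 2, fs = 500)
  dir <- file.path(tempdir(), "pipe")
  dir.create(dir, showWarnings = FALSE)
  set.seed(105)
  n <- 8
  paths <- character(n)
  for (i in seq_len(n)) {
    rec <- simulate(gt, duration_s = 10)[[1]]
    paths[i] <- file.path(dir, sprintf("s%02d.tsv", i))
    write_recording(rec, paths[i])
  }
  demo <- simulate_ses_sample(n, seed = 106)
  demo_path <- file.path(dir, "demo.tsv")
  write.table(demo, demo_path, sep = "\t", row.names = FALSE, quote = FALSE)

  cfg <- list(recordings = paths, demographics = demo_path,
              split_fraction = 0.27, K = 4)
  out1 <- run_microstate_pipeline(cfg, file.path(dir, "out1"))
  out2 <- run_microstate_pipeline(cfg, file.path(dir, "out2"))
  expect_equal(out1$cohort$params, out2$cohort$params)
  t1 <- readLines(file.path(dir, "out1", "parameters.tsv"))
  t2 <- readLines(file.path(dir, "out2", "parameters.tsv"))
  expect_identical(t1, t2)
  expect_equal(sum(out1$demographics$group == "low"), 3)  # ceil(0.27 * 8)
  expect_true(file.exists(file.path(dir, "out1", "config_resolved.json")))

  expect_error(run_microstate_pipeline(c(cfg, list(bogus = 1)),
                                       file.path(dir, "out3")),
               "unknown config")
  expect_error(run_microstate_pipeline(list(recordings = character(0),
                                            demographics = demo_path),
                                       file.path(dir, "out4")),
               "empty subject list")
  unlink(dir, recursive = TRUE)
})
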