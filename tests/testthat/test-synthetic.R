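test_that("the default design yields a 288-volume 12-minute run", {
  spec <- synthetic_spec()
  expect_equal(spec$paradigm$n_volumes, 288L)
  expect_equal(spec$paradigm$run_length / 60, 12)
  b <- make_subject_run(tiny_spec(seed = 1))
  expect_equal(dim(b$run$data), c(14, 14, 10, 288))
  expect_equal(b$run$tr, 2.5)
})

test_that("simulation is bit-identical for a fixed seed and differs across seeds", {
  s <- tiny_spec(seed = 99)
  b1 <- make_subject_run(s)
  b2 <- make_subject_run(s)
  expect_identical(b1$run$data, b2$run$data)
  expect_identical(b1$truth$amplitudes, b2$truth$amplitudes)
  b3 <- make_subject_run(tiny_spec(seed = 100))
  expect_false(identical(b1$run$data, b3$run$data))
})

test_that("ground truth reconstructs the noiseless percent-signal field", {
  s <- tiny_spec(noise_sd = 0, drift_amplitude = 0, seed = 13)
  b <- make_subject_run(s)
  tr <- b$truth
  inside <- b$mask$inside
  # rebuild signal at one in-brain voxel from the stored components
  v <- which(inside)[50]
  pct <- numeric(288)
  for (k in seq_along(tr$amplitudes))
    pct <- pct + tr$amplitudes[k] * tr$trial_patterns[[k]][v] * tr$regressors[, k]
  expected <- s$baseline_brain * (1 + pct / 100)
  expect_equal(as.vector(b$run$data)[v + prod(dim(inside)) * (0:287)],
               expected, tolerance = 1e-10)
})

test_that("noiseless fully consistent trials give near-identical within-task FC maps", {
  s <- tiny_spec(pattern_consistency = 1, amplitude_sd = 0, noise_sd = 0,
                 drift_amplitude = 0, seed = 17)
  b <- make_subject_run(s)
  fb <- fc_maps_for_run(b$run, b$mask, s$paradigm)
  blk <- pairwise_blocks(fb$maps, fb$mask, task_levels = c("WR", "PV", "FT"))
  within <- blk$summary[grepl("within", blk$summary$block_kind), ]
  # the haemodynamic response outlasts the 30 s window, so each trial window
  # carries a small tail of the preceding (different-task) trial; the first
  # trial of the run has no predecessor, which keeps R just below 1
  expect_true(all(within$min > 0.995))
  expect_true(all(within$max <= 1 + 1e-12))
  expect_equal(within$n_pairs, rep(28L, 3))
})

test_that("AR(1) noise autocorrelation is recovered", {
  s <- tiny_spec(task_patterns = "none", drift_amplitude = 0,
                 ar1_coef = 0.4, seed = 19)
  b <- make_subject_run(s)
  flat <- matrix(b$run$data, ncol = 288)
  idx <- which(b$mask$inside)
  ac1 <- vapply(idx[seq(1, length(idx), by = 7)], function(v) {
    x <- flat[v, ]
    cor(x[-1], x[-288])
  }, numeric(1))
  expect_lt(abs(mean(ac1) - 0.4), 0.05)
})

test_that("cohorts share structure across subjects and lose it as deviation grows", {
  d <- c(12, 12, 8)
  base <- function(dev, seed)
    synthetic_spec(grid_shape = d, subject_deviation_sd = dev,
                   noise_sd = 0, amplitude_sd = 0, drift_amplitude = 0,
                   pattern_consistency = 1, seed = seed)

  # no deviation, no noise: cross-subject within-category R = 1
  co <- make_cohort(base(0, 23), n_subjects = 3)
  expect_equal(names(co), c("S1", "S2", "S3"))
  gm <- intersect_masks(lapply(co, `[[`, "mask"))
  tm <- lapply(co, function(b) {
    fb <- fc_maps_for_run(b$run, b$mask, default_paradigm())
    out <- list()
    for (l in c("WR", "PV", "FT"))
      out[[l]] <- task_mean_map(fb$maps[fb$windows$task_label == l])
    out
  })
  blocks0 <- cross_subject_blocks(tm, gm)
  expect_equal(blocks0$mean[grepl("within", blocks0$block_kind)], rep(1, 3),
               tolerance = 1e-9)

  # growing subject deviation monotonically erodes cross-subject similarity
  mean_within <- vapply(c(0, 0.5, 2), function(dev) {
    vals <- vapply(c(31, 32), function(seed) {
      co <- make_cohort(base(dev, seed), n_subjects = 3)
      gm <- intersect_masks(lapply(co, `[[`, "mask"))
      tm <- lapply(co, function(b) {
        fb <- fc_maps_for_run(b$run, b$mask, default_paradigm())
        out <- list()
        for (l in c("WR", "PV", "FT"))
          out[[l]] <- task_mean_map(fb$maps[fb$windows$task_label == l])
        out
      })
      blocks <- cross_subject_blocks(tm, gm)
      mean(blocks$mean[grepl("within", blocks$block_kind)])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_within) < 0))
})

test_that("within-category similarity and identification improve with pattern consistency", {
  d <- c(12, 12, 8)
  res <- vapply(c(0.2, 0.5, 0.9), function(cons) {
    vals <- vapply(c(51, 52, 53), function(seed) {
      s <- synthetic_spec(grid_shape = d, pattern_consistency = cons,
                          noise_sd = 1.5, drift_amplitude = 0, seed = seed)
      b <- make_subject_run(s)
      fb <- fc_maps_for_run(b$run, b$mask, s$paradigm)
      blk <- pairwise_blocks(fb$maps, fb$mask, task_levels = c("WR", "PV", "FT"))
      id <- run_identification(blk$sc, task_levels = c("WR", "PV", "FT"))
      c(mean(blk$summary$mean[grepl("within", blk$summary$block_kind)]),
        mean(id$correct_rate))
    }, numeric(2))
    rowMeans(vals)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))   # mean within R increases
  expect_true(all(diff(res[2, ]) >= 0))  # correct rate never decreases
})
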