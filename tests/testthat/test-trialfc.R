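test_that("trial segmentation covers the run with non-overlapping 12-volume windows", {
  w <- segment_trials(default_paradigm())
  expect_equal(nrow(w), 24)
  expect_true(all(w$n_volumes == 12))
  expect_equal(sum(w$n_volumes), 288)
  expect_equal(w$start_volume, seq(0, by = 12, length.out = 24))
  expect_equal(w$trial_index[w$task_label == "FT"], 1:8)

  w3 <- segment_trials(make_paradigm(c(0, 30, 60), c("A", "B", "A"),
                                     tr = 2.5, run_length = 90))
  expect_equal(w3$start_volume, c(0L, 12L, 24L))
  w1 <- segment_trials(make_paradigm(0, "A", tr = 2.5, run_length = 30))
  expect_equal(w1$start_volume, 0L)
  expect_equal(w1$n_volumes, 12L)
})

test_that("temporal correlation map reproduces exact and hand-computed Pearson values", {
  d <- c(3, 2, 1, 12)
  p1 <- make_paradigm(0, "WR", tr = 2.5, run_length = 30)
  tmpl <- ideal_response(p1)$samples
  a <- array(0, dim = d)
  a[1, 1, 1, ] <- tmpl                              # r = 1
  a[2, 1, 1, ] <- -tmpl + 5                         # r = -1
  a[3, 1, 1, ] <- c(1, 3, 2, 5, 4, 6, 7, 5, 8, 7, 9, 10)  # worked example
  a[1, 2, 1, ] <- rnorm(12)
  a[2, 2, 1, ] <- 3                                 # zero variance
  a[3, 2, 1, ] <- rnorm(12)
  run <- bold_run(a, 3.5, 2.5)
  mask <- brain_mask(array(TRUE, dim = d[1:3]))
  w <- list(start_volume = 0L, n_volumes = 12L, task_label = "WR", trial_index = 1L)
  fc <- temporal_correlation_map(run, mask, w, tmpl)
  expect_equal(fc$r[1, 1, 1], 1)
  expect_equal(fc$r[2, 1, 1], -1)
  expect_equal(fc$r[3, 1, 1],
               pearson_oracle(c(1, 3, 2, 5, 4, 6, 7, 5, 8, 7, 9, 10), tmpl),
               tolerance = 1e-12)
  expect_true(is.na(fc$r[2, 2, 1]))
  expect_equal(fc$n_zero_variance, 1L)
  expect_equal(fc$n_samples, 12L)
  expect_error(temporal_correlation_map(run, mask, w, rep(1, 12)), "constant")
  expect_error(temporal_correlation_map(run, mask, w, tmpl[1:6]), "length")
})

test_that("temporal correlation is affine-invariant in each voxel series", {
  with_seed(9, {
    tmpl <- sin(seq_len(12))
    for (i in 1:20) {
      x <- rnorm(12)
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      expect_equal(pearson_oracle(a * x + b, tmpl), pearson_oracle(x, tmpl),
                   tolerance = 1e-10)
      expect_equal(pearson_oracle(-a * x + b, tmpl), -pearson_oracle(x, tmpl),
                   tolerance = 1e-10)
    }
  })
})

test_that("critical r matches the t-distribution inversion", {
  expect_equal(round(critical_r(12, 0.05), 2), 0.58)
  expect_equal(round(critical_r(12, 0.05), 3), 0.576)
  # independent check: numerically invert the t CDF at df = 10
  tq <- qt(0.975, 10)
  expect_equal(critical_r(12, 0.05), tq / sqrt(tq^2 + 10), tolerance = 1e-12)
  # alpha -> 1 sends the threshold to zero
  expect_lt(critical_r(12, 0.9999), 0.001)
  expect_error(critical_r(2, 0.05), "n")
})

test_that("display thresholding keeps only |r| above the threshold and never the data map", {
  d <- c(4, 1, 1)
  vals <- array(c(-0.7, -0.3, 0.2, 0.6), dim = d)
  mask <- brain_mask(array(TRUE, dim = d))
  fc <- fake_map(vals, mask)
  th <- threshold_map(fc, 0.58)
  expect_equal(which(!is.na(th$r)), c(1L, 4L))
  expect_equal(sum(!is.na(threshold_map(fc, 1)$r)), 0L)
  expect_equal(sum(!is.na(threshold_map(fc, 0)$r)), 4L)
  # original untouched
  expect_equal(sum(!is.na(fc$r)), 4L)
})

test_that("a full run yields 8 FC maps per task category over a common mask", {
  b <- make_subject_run(tiny_spec(seed = 21))
  pp <- preprocess_run(b$run)
  fb <- fc_maps_for_run(pp$run, pp$mask, default_paradigm())
  expect_length(fb$maps, 24)
  labs <- vapply(fb$maps, function(m) m$window$task_label, character(1))
  expect_equal(unname(table(labs)[c("WR", "PV", "FT")]), rep(8L, 3),
               ignore_attr = TRUE)
  rs <- lapply(fb$maps, function(m) m$r[fb$mask$inside])
  expect_true(all(vapply(rs, function(v) all(is.finite(v)) && all(abs(v) <= 1),
                         logical(1))))
})
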