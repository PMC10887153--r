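make_run <- function(data, voxel = 3.5, tr = 2.5) bold_run(data, voxel, tr)

test_that("gaussian smoothing: identity at fwhm 0, constants preserved, impulse width correct", {
  with_seed(1, {
    a <- array(rnorm(10 * 10 * 8 * 5), dim = c(10, 10, 8, 5))
  })
  run <- make_run(a)
  expect_identical(gaussian_smooth(run, 0)$data, a)
  expect_error(gaussian_smooth(run, -1), "fwhm")

  const <- make_run(array(7, dim = c(8, 8, 8, 4)))
  expect_equal(gaussian_smooth(const, 4)$data, const$data, tolerance = 1e-12)

  # impulse response: measured FWHM ~ 4 mm within one voxel (3.5 mm)
  imp <- array(0, dim = c(15, 15, 15, 4))
  imp[8, 8, 8, ] <- 1
  sm <- gaussian_smooth(make_run(imp), 4)$data[, 8, 8, 1]
  half <- max(sm) / 2
  # linear interpolation of the half-maximum crossings along x
  above <- which(sm >= half)
  lo <- min(above); hi <- max(above)
  xlo <- lo - 1 + (sm[lo - 1] - half) / (sm[lo - 1] - sm[lo])
  xhi <- hi + (sm[hi] - half) / (sm[hi] - sm[hi + 1])
  fwhm_mm <- (xhi - xlo) * 3.5
  expect_lt(abs(fwhm_mm - 4), 3.5)
})

test_that("bandpass removes DC, keeps in-band bins, zeroes out-of-band bins", {
  tr <- 2.5; n <- 288
  tt <- (0:(n - 1)) * tr
  expect_equal(bandpass(rep(5, n), tr), rep(0, n), tolerance = 1e-12)

  # bin-aligned in-band frequency (29 cycles / 720 s ~ 0.0403 Hz)
  x <- sin(2 * pi * 29 / (n * tr) * tt + 0.3)
  expect_equal(bandpass(x, tr), x - mean(x), tolerance = 1e-9)

  # bin-aligned out-of-band frequency (0.15 Hz)
  y <- sin(2 * pi * 0.15 * tt)
  expect_lt(max(abs(bandpass(y, tr))), 1e-9)

  expect_error(bandpass(x, tr, band = c(0.009, 0.25)), "Nyquist")
  expect_error(bandpass(x, tr, band = c(0.08, 0.009)), "low < high")
})

test_that("bandpass agrees with a direct DFT oracle and is an idempotent linear projection", {
  tr <- 2; band <- c(0.02, 0.1)
  with_seed(42, {
    x <- rnorm(32); y <- rnorm(32)
  })
  expect_equal(bandpass(x, tr, band), dft_bandpass_oracle(x, tr, band),
               tolerance = 1e-10)
  bx <- bandpass(x, tr, band)
  expect_equal(bandpass(bx, tr, band), bx, tolerance = 1e-12)
  expect_equal(bandpass(2 * x - 3 * y, tr, band),
               2 * bx - 3 * bandpass(y, tr, band), tolerance = 1e-12)
})

test_that("smoothing and bandpass commute", {
  with_seed(7, {
    a <- array(rnorm(8 * 8 * 6 * 16), dim = c(8, 8, 6, 16))
  })
  run <- make_run(a, tr = 2)
  ab <- bandpass(gaussian_smooth(run, 4), band = c(0.02, 0.1))$data
  ba <- gaussian_smooth(bandpass(run, band = c(0.02, 0.1)), 4)$data
  expect_equal(ab, ba, tolerance = 1e-10)
})

test_that("percent signal change scales by the baseline and preserves correlations", {
  a <- array(2, dim = c(2, 2, 2, 4))
  run <- make_run(a)
  base100 <- array(100, dim = c(2, 2, 2))
  expect_equal(percent_signal_change(run, base100)$data[1, 1, 1, 1], 2.0)
  expect_equal(percent_signal_change(run, 2 * base100)$data,
               percent_signal_change(run, base100)$data / 2)

  # Pearson r is invariant under positive per-voxel scaling
  with_seed(11, {
    d <- c(4, 4, 3, 12)
    raw <- array(rnorm(prod(d)), dim = d)
    base <- array(runif(prod(d[1:3]), 50, 150), dim = d[1:3])
  })
  run2 <- make_run(raw)
  psc <- percent_signal_change(run2, base)
  mask <- brain_mask(array(TRUE, dim = d[1:3]))
  w <- list(start_volume = 0L, n_volumes = 12L, task_label = "WR", trial_index = 1L)
  tmpl <- sin(seq_len(12))
  r_raw <- temporal_correlation_map(run2, mask, w, tmpl)$r
  r_psc <- temporal_correlation_map(psc, mask, w, tmpl)$r
  expect_equal(r_psc, r_raw, tolerance = 1e-12)

  # non-positive baselines are flagged
  base_bad <- base; base_bad[1, 1, 1] <- 0
  flagged <- attr(percent_signal_change(run2, base_bad), "nonpositive_baseline")
  expect_identical(which(flagged), 1L)
})

test_that("brain mask construction thresholds and keeps the largest component", {
  u <- array(10, dim = c(6, 6, 6))
  expect_equal(make_brain_mask(u, 0.5)$n_voxels, 216L)

  two <- array(0, dim = c(20, 8, 8))
  two[2:7, 2:7, 2:7] <- 10    # 216 voxels
  two[14:17, 2:5, 2:5] <- 10  # 64 voxels
  m <- make_brain_mask(two, 0.5)
  expect_equal(m$n_voxels, 216L)
  expect_true(all(m$inside[2:7, 2:7, 2:7]))
  expect_false(any(m$inside[14:17, , ]))

  expect_error(make_brain_mask(u, 1.5), "fraction")
})

test_that("mask recovered from a synthetic head phantom matches the true brain volume", {
  b <- make_subject_run(tiny_spec(noise_sd = 0.5, seed = 3))
  mean_vol <- apply(b$run$data, 1:3, mean)
  m <- make_brain_mask(mean_vol, fraction = 0.3)
  expect_lt(abs(m$n_voxels - b$mask$n_voxels) / b$mask$n_voxels, 0.02)
})

test_that("the preprocessing chain is deterministic", {
  b <- make_subject_run(tiny_spec(seed = 5))
  p1 <- preprocess_run(b$run)
  p2 <- preprocess_run(b$run)
  expect_identical(p1$run$data, p2$run$data)
  expect_identical(p1$mask$inside, p2$mask$inside)
})
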