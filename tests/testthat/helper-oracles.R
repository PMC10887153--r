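# Independent oracles and small fixture builders used across the test files.

# textbook Pearson correlation by explicit elementwise sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2
    sxy <- sxy + x[i] * y[i]
  }
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  num / den
}

# brick-wall bandpass by direct O(n^2) discrete Fourier sums
dft_bandpass_oracle <- function(x, tr, band) {
  n <- length(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr)
  keep <- freq >= band[1] & freq <= band[2]
  ft <- complex(n)
  for (j in seq_len(n)) {
    ft[j] <- sum(x * exp(-2i * pi * (j - 1) * (seq_len(n) - 1) / n))
  }
  ft[!keep] <- 0
  out <- numeric(n)
  for (t in seq_len(n)) {
    out[t] <- Re(sum(ft * exp(2i * pi * (t - 1) * (seq_len(n) - 1) / n))) / n
  }
  out
}

# explicit double-loop discrete convolution of boxcar and kernel on a dt grid
convolution_oracle <- function(box, kern, dt) {
  n <- length(box)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_len(min(t, length(kern)))) {
      out[t] <- out[t] + box[t - k + 1] * kern[k] * dt
    }
  }
  out
}

# minimal fc_map fixture from a value array
fake_map <- function(values, mask, label = "WR", idx = 1L) {
  structure(list(r = values, mask = mask,
                 window = list(task_label = label, trial_index = as.integer(idx)),
                 n_samples = 12L, n_zero_variance = 0L),
            class = "fc_map")
}

# all-TRUE mask over an n x 1 x 1 (or full 3D) grid
full_mask <- function(dims) {
  if (length(dims) == 1L) dims <- c(dims, 1L, 1L)
  trialfc::brain_mask(array(TRUE, dim = dims))
}

# a full set of 24 toy maps (3 tasks x 8 trials) from per-task prototypes
toy_trial_maps <- function(protos, mask, noise_sd = 0, seed = 1) {
  trialfc::with_seed(seed, {
    maps <- list()
    d <- dim(protos[[1]])
    for (t in seq_along(protos)) {
      for (i in 1:8) {
        v <- protos[[t]] + array(rnorm(prod(d), 0, noise_sd), dim = d)
        maps[[length(maps) + 1L]] <-
          fake_map(v, mask, label = names(protos)[t], idx = i)
      }
    }
    maps
  })
}

# small, fast simulator spec for unit tests
tiny_spec <- function(...) {
  trialfc::synthetic_spec(grid_shape = c(14, 14, 10), ...)
}
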