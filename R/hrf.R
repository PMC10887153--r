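#' Canonical double-gamma haemodynamic response model
#'
#' Parameterizes the haemodynamic response function (HRF) as the difference of
#' two gamma densities: a positive lobe peaking at `peak_delay` seconds and a
#' post-stimulus undershoot peaking at `undershoot_delay` seconds, weighted by
#' `undershoot_ratio`. Gamma shapes are chosen so the mode of each lobe falls
#' exactly at its stated delay.
#'
#' @param peak_delay time to peak of the positive lobe, seconds.
#' @param undershoot_delay time to peak of the undershoot, seconds.
#' @param peak_dispersion width (gamma scale) of the positive lobe, seconds.
#' @param undershoot_dispersion width of the undershoot, seconds.
#' @param undershoot_ratio weight of the undershoot relative to the peak
#'   (dimensionless; 0 disables the undershoot).
#' @param kernel_length support of the sampled kernel, seconds.
#' @param dt internal sampling step, seconds; must not exceed the TR it will
#'   be used with.
#' @return an object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay = 6, undershoot_delay = 16,
                      peak_dispersion = 1, undershoot_dispersion = 1,
                      undershoot_ratio = 1 / 6,
                      kernel_length = 32, dt = 0.1) {
  for (nm in c("peak_delay", "undershoot_delay", "peak_dispersion",
               "undershoot_dispersion", "kernel_length", "dt"))
    stop_if_not_scalar_num(get(nm), nm, positive = TRUE)
  stop_if_not_scalar_num(undershoot_ratio, "undershoot_ratio")
  if (undershoot_ratio < 0) stop("undershoot_ratio must be >= 0", call. = FALSE)
  if (kernel_length < undershoot_delay)
    stop("kernel_length must be at least undershoot_delay", call. = FALSE)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length, dt = dt),
            class = "hrf_model")
}

# two-gamma density difference evaluated at times t (seconds), unnormalized
.hrf_raw <- function(t, m) {
  shape1 <- m$peak_delay / m$peak_dispersion + 1
  shape2 <- m$undershoot_delay / m$undershoot_dispersion + 1
  stats::dgamma(t, shape = shape1, rate = 1 / m$peak_dispersion) -
    m$undershoot_ratio *
      stats::dgamma(t, shape = shape2, rate = 1 / m$undershoot_dispersion)
}

#' Sample the HRF kernel
#'
#' Evaluates the double-gamma response on the grid `seq(0, kernel_length, dt)`
#' and rescales so the peak amplitude is 1.
#'
#' @param model an [hrf_model()].
#' @return numeric vector of kernel amplitudes, with attributes `t` (sample
#'   times, seconds) and `dt`.
#' @export
hrf_kernel <- function(model = hrf_model()) {
  stopifnot(inherits(model, "hrf_model"))
  t <- seq(0, model$kernel_length, by = model$dt)
  h <- .hrf_raw(t, model)
  h <- h / max(h)
  structure(h, t = t, dt = model$dt)
}

#' Task-evoked ideal BOLD response
#'
#' Convolves the paradigm's task on/off boxcar with the HRF kernel on the fine
#' `dt` grid, samples the result at volume times `k * TR` (k = 0, ...,
#' n_volumes - 1), and normalizes the peak absolute amplitude to 1. This is
#' the template time signal a task-driven voxel is expected to follow.
#'
#' @param paradigm a [make_paradigm()] object.
#' @param model an [hrf_model()]; `dt` must not exceed the paradigm TR.
#' @param band optional length-2 frequency band (Hz); when supplied, the
#'   sampled template is bandpass-filtered exactly like the data (off by
#'   default — the correlation is scale-free, and filtering the template is a
#'   methodological choice, not a requirement).
#' @return an object of class `ideal_response` with fields `samples`, `tr`,
#'   `n_volumes`.
#' @export
ideal_response <- function(paradigm, model = hrf_model(), band = NULL) {
  stopifnot(inherits(paradigm, "paradigm"), inherits(model, "hrf_model"))
  if (model$dt > paradigm$tr + 1e-12)
    stop("model dt must not exceed the paradigm TR", call. = FALSE)
  dt <- model$dt
  nt <- as.integer(round(paradigm$run_length / dt))
  box <- numeric(nt)
  tfine <- (seq_len(nt) - 1L) * dt
  for (k in seq_along(paradigm$onsets)) {
    on <- paradigm$onsets[k]
    box[tfine >= on - 1e-9 & tfine < on + paradigm$task_duration - 1e-9] <- 1
  }
  kern <- as.numeric(hrf_kernel(model))
  conv <- if (any(box != 0)) {
    full <- stats::convolve(box, rev(kern), type = "open")
    full[seq_len(nt)] * dt
  } else numeric(nt)
  idx <- as.integer(round((seq_len(paradigm$n_volumes) - 1L) * paradigm$tr / dt)) + 1L
  samples <- conv[idx]
  if (!is.null(band)) samples <- bandpass(samples, tr = paradigm$tr, band = band)
  m <- max(abs(samples))
  if (m > 0) samples <- samples / m
  structure(list(samples = samples, tr = paradigm$tr,
                 n_volumes = paradigm$n_volumes),
            class = "ideal_response")
}

#' Extract a per-trial template from the full-run ideal response
#'
#' Returns the `n_volumes` consecutive samples of the ideal response starting
#' at the volume nearest `trial_onset / TR`. Taking the segment of the
#' full-run regressor (rather than an isolated single-trial convolution)
#' respects any residual carryover from preceding trials.
#'
#' @param ideal an [ideal_response()].
#' @param trial_onset trial onset in seconds.
#' @param n_volumes window length in volumes.
#' @return numeric amplitude vector of length `n_volumes`.
#' @export
trial_template <- function(ideal, trial_onset, n_volumes) {
  stopifnot(inherits(ideal, "ideal_response"))
  start <- as.integer(round(trial_onset / ideal$tr))
  if (start < 0L || start + n_volumes > ideal$n_volumes)
    stop("trial window exceeds the run", call. = FALSE)
  ideal$samples[seq.int(start + 1L, start + n_volumes)]
}

#' @export
print.ideal_response <- function(x, ...) {
  cat(sprintf("ideal_response: %d volumes at TR %g s, peak |amplitude| %g\n",
              x$n_volumes, x$tr, max(abs(x$samples))))
  invisible(x)
}
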