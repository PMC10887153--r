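#' Construct a 4D BOLD run
#'
#' @param data 4D numeric array (x, y, z, volume).
#' @param voxel_size voxel edge length(s) in mm; scalar or length 3.
#' @param tr repetition time in seconds.
#' @param provenance character vector logging the processing applied so far.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, voxel_size, tr, provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, volume)", call. = FALSE)
  if (dim(data)[4L] <= 3L)
    stop("a run must have more than 3 volumes", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 1 or 3 positive values (mm)", call. = FALSE)
  stop_if_not_scalar_num(tr, "tr", positive = TRUE)
  if (any(!is.finite(data)))
    stop("run contains non-finite values", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 n_volumes = dim(data)[4L], provenance = provenance),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %d x %d x %d voxels (%s mm), %d volumes at TR %g s\n",
              d[1], d[2], d[3], paste(format(x$voxel_size), collapse = " x "),
              x$n_volumes, x$tr))
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

.gauss_weights <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}

# row-stochastic 1D smoothing operator with nearest-edge replication
.smooth_operator <- function(n, sigma_vox) {
  w <- .gauss_weights(sigma_vox)
  r <- (length(w) - 1L) / 2L
  S <- matrix(0, n, n)
  for (k in seq_along(w)) {
    j <- pmin(pmax(seq_len(n) + (k - r - 1L), 1L), n)
    S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + w[k]
  }
  S
}

# smooth an array along one axis by operator multiplication
.smooth_axis <- function(a, axis, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  d <- dim(a)
  S <- .smooth_operator(d[axis], sigma_vox)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  out <- array(S %*% m, dim = d[perm])
  aperm(out, order(perm))
}

# isotropic Gaussian smoothing of a 3D or 4D array, FWHM in mm
smooth_gaussian_mm <- function(a, voxel_size, fwhm) {
  if (fwhm == 0) return(a)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) a <- .smooth_axis(a, ax, sigma_mm / voxel_size[ax])
  a
}

#' Spatial Gaussian smoothing of a BOLD run
#'
#' Convolves every volume with an isotropic Gaussian of the stated full width
#' at half maximum (mm), converted per axis using the voxel size. Boundaries
#' use nearest-edge replication.
#'
#' @param run a [bold_run()].
#' @param fwhm full width at half maximum in mm; 0 is the identity.
#' @return the smoothed `bold_run`.
#' @export
gaussian_smooth <- function(run, fwhm) {
  stopifnot(inherits(run, "bold_run"))
  stop_if_not_scalar_num(fwhm, "fwhm")
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm == 0) return(run)
  run$data <- smooth_gaussian_mm(run$data, run$voxel_size, fwhm)
  run$provenance <- c(run$provenance, sprintf("gaussian_smooth fwhm=%g mm", fwhm))
  run
}

.validate_band <- function(band, tr) {
  band <- as.numeric(band)
  if (length(band) != 2L || any(!is.finite(band)))
    stop("'band' must be two finite frequencies (Hz)", call. = FALSE)
  nyq <- 1 / (2 * tr)
  if (band[1] < 0 || band[1] >= band[2])
    stop("band must satisfy 0 <= low < high", call. = FALSE)
  if (band[2] >= nyq)
    stop(sprintf("band high (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 band[2], nyq), call. = FALSE)
  band
}

# brick-wall DFT bandpass of a time x series matrix
.bandpass_matrix <- function(m, tr, band) {
  n <- nrow(m)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) / (n * tr)
  keep <- freq >= band[1] & freq <= band[2]
  ft <- stats::mvfft(m)
  ft[!keep, ] <- 0 + 0i
  Re(stats::mvfft(ft, inverse = TRUE)) / n
}

#' Temporal bandpass filter
#'
#' Brick-wall filtering in the discrete Fourier domain: frequency bins outside
#' `[low, high]` Hz are set to zero along the time axis. The 0 Hz (mean)
#' component is always removed since `low > 0`. This ideal-filter projection
#' is exactly idempotent and linear.
#'
#' @param x a [bold_run()], a numeric matrix (time in rows), or a vector.
#' @param tr sampling interval in seconds (taken from the run if `x` is one).
#' @param band length-2 numeric, `c(low, high)` in Hz; `high` must be below
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @return object of the same shape as `x`.
#' @export
bandpass <- function(x, tr = NULL, band = c(0.009, 0.08)) {
  if (inherits(x, "bold_run")) {
    band <- .validate_band(band, x$tr)
    d <- dim(x$data)
    m <- t(matrix(x$data, nrow = prod(d[1:3]), ncol = d[4]))
    x$data <- array(t(.bandpass_matrix(m, x$tr, band)), dim = d)
    x$provenance <- c(x$provenance, sprintf("bandpass %g-%g Hz", band[1], band[2]))
    return(x)
  }
  stop_if_not_scalar_num(tr, "tr", positive = TRUE)
  band <- .validate_band(band, tr)
  if (is.matrix(x)) return(.bandpass_matrix(x, tr, band))
  as.numeric(.bandpass_matrix(matrix(x, ncol = 1L), tr, band))
}

#' Percent signal change
#'
#' Rescales each voxel's (typically bandpassed) time course to percent units
#' relative to that voxel's baseline: `100 * series / baseline`. Voxels whose
#' baseline is not strictly positive cannot be expressed as percent change;
#' they are flagged in the `nonpositive_baseline` attribute so callers can
#' drop them from the analysis mask.
#'
#' @param run a [bold_run()] (bandpassed signal).
#' @param baseline 3D array of per-voxel baseline amplitude — the per-voxel
#'   mean of the raw (pre-bandpass) time course, i.e. the mean volume image.
#' @return a `bold_run` in percent-signal-change units with attribute
#'   `nonpositive_baseline` (3D logical).
#' @export
percent_signal_change <- function(run, baseline) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  if (!is.array(baseline) || !identical(dim(baseline), d[1:3]))
    stop("'baseline' must be a 3D array matching the run grid", call. = FALSE)
  bad <- !(baseline > 0)
  safe <- ifelse(bad, 1, baseline)
  run$data <- 100 * run$data / as.vector(safe)
  run$data[as.vector(bad)] <- 0  # flagged voxels carry no signal
  run$provenance <- c(run$provenance, "percent_signal_change")
  attr(run, "nonpositive_baseline") <- bad
  run
}

#' Full in-scope preprocessing chain
#'
#' Gaussian spatial smoothing, mean-volume computation, temporal bandpass and
#' percent signal change, in that order. Voxels with non-positive baseline are
#' removed from the mask. Despiking, slice-timing and motion correction are
#' assumed to have been applied upstream for real data.
#'
#' @param run a raw [bold_run()].
#' @param mask optional [brain_mask()]; built from the mean smoothed volume
#'   with [make_brain_mask()] when omitted.
#' @param fwhm spatial smoothing FWHM, mm.
#' @param band temporal passband in Hz.
#' @param mask_fraction threshold fraction for [make_brain_mask()] when the
#'   mask is built here.
#' @return list with elements `run` (percent-signal-change `bold_run`),
#'   `mask` (possibly refined), and `baseline` (mean volume, 3D array).
#' @export
preprocess_run <- function(run, mask = NULL, fwhm = 4, band = c(0.009, 0.08),
                           mask_fraction = 0.3) {
  stopifnot(inherits(run, "bold_run"))
  sm <- gaussian_smooth(run, fwhm)
  baseline <- apply(sm$data, 1:3, mean)
  if (is.null(mask)) mask <- make_brain_mask(baseline, fraction = mask_fraction)
  bp <- bandpass(sm, band = band)
  psc <- percent_signal_change(bp, baseline)
  bad <- attr(psc, "nonpositive_baseline")
  n_bad <- sum(bad & mask$inside)
  if (n_bad > 0) {
    mask$inside <- mask$inside & !bad
    mask$n_voxels <- sum(mask$inside)
    psc$provenance <- c(psc$provenance,
                        sprintf("excluded %d non-positive-baseline voxels from mask",
                                n_bad))
  }
  list(run = psc, mask = mask, baseline = baseline)
}
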