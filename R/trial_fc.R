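#' Segment a run into per-trial volume windows
#'
#' One window per trial, starting at the volume nearest each onset and
#' spanning `(task_duration + rest_duration) / TR` volumes (12 for the 6 s
#' task / 24 s rest design at TR 2.5 s).
#'
#' @param paradigm a [make_paradigm()] object.
#' @return data frame with columns `task_label`, `trial_index` (1-based within
#'   its category), `start_volume` (0-based), `n_volumes`, `onset`.
#' @export
segment_trials <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm"))
  nvol_trial <- (paradigm$task_duration + paradigm$rest_duration) / paradigm$tr
  if (abs(nvol_trial - round(nvol_trial)) > 1e-9)
    stop("trial length (task + rest) must be an integer number of TRs", call. = FALSE)
  nvol_trial <- as.integer(round(nvol_trial))
  start <- as.integer(round(paradigm$onsets / paradigm$tr))
  if (any(start + nvol_trial > paradigm$n_volumes))
    stop("a trial window exceeds the run", call. = FALSE)
  if (any(diff(start) < nvol_trial))
    stop("trial windows overlap", call. = FALSE)
  trial_index <- stats::ave(seq_along(paradigm$labels), paradigm$labels,
                            FUN = seq_along)
  data.frame(task_label = paradigm$labels,
             trial_index = as.integer(trial_index),
             start_volume = start,
             n_volumes = nvol_trial,
             onset = paradigm$onsets,
             stringsAsFactors = FALSE)
}

#' Critical Pearson correlation threshold
#'
#' Two-tailed critical value of the Pearson correlation coefficient for `n`
#' independent samples at significance level `alpha`, via inversion of the t
#' distribution: `r* = t* / sqrt(t*^2 + n - 2)` with `t*` the `1 - alpha/2`
#' quantile on `n - 2` degrees of freedom. Note this assumes temporally
#' independent samples (no autocorrelation correction).
#'
#' @param n number of paired samples (>= 3).
#' @param alpha two-sided significance level.
#' @return the critical |r|.
#' @examples
#' round(critical_r(12, 0.05), 2)  # 0.58
#' @export
critical_r <- function(n, alpha = 0.05) {
  stop_if_not_scalar_num(n, "n")
  stop_if_not_scalar_num(alpha, "alpha")
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Per-trial whole-brain temporal-correlation (FC) map
#'
#' For every in-mask voxel, the Pearson correlation between the voxel's time
#' course within the trial window and the ideal-response template. The
#' resulting 3D r map characterizes the whole brain's functional co-activity
#' for that trial.
#'
#' @param run a (preprocessed) [bold_run()].
#' @param mask a [brain_mask()] on the run grid.
#' @param window one row of [segment_trials()] output (or an equivalent list
#'   with `start_volume`, `n_volumes`, and optionally `task_label`,
#'   `trial_index`).
#' @param template numeric template of length `window$n_volumes` with nonzero
#'   variance.
#' @return an object of class `fc_map`: 3D array `r` (NA outside the mask and
#'   at zero-variance voxels), plus `mask`, `window`, `n_samples` and the
#'   count of excluded zero-variance voxels.
#' @export
temporal_correlation_map <- function(run, mask, window, template) {
  stopifnot(inherits(run, "bold_run"), inherits(mask, "brain_mask"))
  d <- dim(run$data)
  if (!identical(dim(mask$inside), d[1:3]))
    stop("mask grid does not match the run", call. = FALSE)
  nv <- as.integer(window$n_volumes)
  s0 <- as.integer(window$start_volume)
  if (length(template) != nv)
    stop("template length must equal the window length", call. = FALSE)
  if (stats::sd(template) == 0)
    stop("template is constant; correlation undefined", call. = FALSE)
  if (s0 < 0L || s0 + nv > d[4L])
    stop("window exceeds the run", call. = FALSE)
  flat <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4L])
  X <- flat[as.vector(mask$inside), seq.int(s0 + 1L, s0 + nv), drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(t(X), template)))
  n_zero_var <- sum(is.na(r))
  out <- array(NA_real_, dim = d[1:3])
  out[mask$inside] <- r
  structure(list(r = out, mask = mask, window = as.list(window),
                 n_samples = nv, n_zero_variance = n_zero_var),
            class = "fc_map")
}

#' All per-trial FC maps of one run
#'
#' Builds the full-run ideal response, extracts each trial's template segment
#' and computes every trial's FC map. Voxels with zero variance in any trial
#' window are removed from a subject-level intersection mask so that all
#' spatial correlations for the subject are computed over identical voxels.
#'
#' @param run a preprocessed [bold_run()].
#' @param mask a [brain_mask()].
#' @param paradigm the run's [make_paradigm()].
#' @param model an [hrf_model()].
#' @param band optional band passed to [ideal_response()] for template
#'   filtering (default: no filtering).
#' @return list with `maps` (list of `fc_map`, in paradigm trial order),
#'   `mask` (the refined subject-level mask), `windows` (the
#'   [segment_trials()] table) and `ideal` (the full-run [ideal_response()]).
#' @export
fc_maps_for_run <- function(run, mask, paradigm, model = hrf_model(),
                            band = NULL) {
  windows <- segment_trials(paradigm)
  ideal <- ideal_response(paradigm, model, band = band)
  maps <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    tmpl <- trial_template(ideal, w$onset, w$n_volumes)
    temporal_correlation_map(run, mask, w, tmpl)
  })
  # subject-level intersection: drop voxels undefined in any trial
  ok <- Reduce(`&`, lapply(maps, function(m) !is.na(m$r) )) & mask$inside
  if (sum(ok) < mask$n_voxels) {
    mask <- brain_mask(ok)
    maps <- lapply(maps, function(m) {
      m$r[!ok] <- NA_real_
      m$mask <- mask
      m
    })
  }
  list(maps = maps, mask = mask, windows = windows, ideal = ideal)
}

#' Threshold an FC map for display
#'
#' Returns a display copy with |r| at or below the threshold set to NA. The
#' unthresholded map should always be used for similarity computations;
#' thresholding is for illustration only.
#'
#' @param fc an `fc_map`.
#' @param r_crit threshold in `[0, 1]`, e.g. [critical_r()].
#' @return a thresholded `fc_map` copy.
#' @export
threshold_map <- function(fc, r_crit) {
  stopifnot(inherits(fc, "fc_map"))
  stop_if_not_scalar_num(r_crit, "r_crit")
  if (r_crit < 0 || r_crit > 1) stop("r_crit must be in [0, 1]", call. = FALSE)
  fc$r[!is.na(fc$r) & abs(fc$r) <= r_crit] <- NA_real_
  fc$display_threshold <- r_crit
  fc
}

#' @export
print.fc_map <- function(x, ...) {
  w <- x$window
  cat(sprintf("fc_map: trial %s #%s, %d samples, r in [%.3f, %.3f] over %d voxels\n",
              w$task_label %||% "?", w$trial_index %||% "?",
              x$n_samples, min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE),
              sum(!is.na(x$r))))
  invisible(x)
}
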