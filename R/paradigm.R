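#' Construct a task stimulus paradigm
#'
#' A paradigm describes an interleaved block/event design: trial onsets with
#' task labels, a common task (stimulus-on) duration and rest duration, the
#' volume sampling interval TR, and the run length.
#'
#' @param onsets numeric vector of trial onsets in seconds, strictly increasing.
#' @param labels character vector of task labels, one per trial.
#' @param task_duration stimulus-on duration per trial, seconds.
#' @param rest_duration rest duration following each task period, seconds.
#' @param tr repetition time (volume sampling interval), seconds.
#' @param run_length total run duration in seconds; must be an integer number
#'   of TRs and long enough to contain every trial.
#' @param task_levels label order used for reporting and deterministic
#'   tie-breaking; defaults to the labels' order of first appearance.
#' @return an object of class `paradigm`.
#' @examples
#' p <- default_paradigm()
#' p$n_volumes  # 288
#' @export
make_paradigm <- function(onsets, labels, task_duration = 6, rest_duration = 24,
                          tr = 2.5, run_length = NULL, task_levels = NULL) {
  stop_if_not_scalar_num(task_duration, "task_duration")
  stop_if_not_scalar_num(rest_duration, "rest_duration")
  stop_if_not_scalar_num(tr, "tr", positive = TRUE)
  if (task_duration < 0 || rest_duration < 0)
    stop("task_duration and rest_duration must be >= 0", call. = FALSE)
  onsets <- as.numeric(onsets)
  labels <- as.character(labels)
  if (length(onsets) != length(labels) || length(onsets) < 1L)
    stop("'onsets' and 'labels' must be non-empty and of equal length", call. = FALSE)
  if (any(diff(onsets) <= 0))
    stop("trial onsets must be strictly increasing", call. = FALSE)
  trial_len <- task_duration + rest_duration
  gaps <- c(diff(onsets))
  if (any(gaps < trial_len - 1e-9))
    stop("trials overlap: onset + task_duration + rest_duration exceeds the next onset",
         call. = FALSE)
  run_length <- run_length %||% (onsets[length(onsets)] + trial_len)
  stop_if_not_scalar_num(run_length, "run_length", positive = TRUE)
  if (onsets[length(onsets)] + trial_len > run_length + 1e-9)
    stop("run too short to contain all trials", call. = FALSE)
  n_volumes <- run_length / tr
  if (abs(n_volumes - round(n_volumes)) > 1e-9)
    stop("run_length must be an integer number of TRs", call. = FALSE)
  levs <- task_levels %||% unique(labels)
  if (!all(labels %in% levs))
    stop("all labels must be among task_levels", call. = FALSE)
  structure(list(
    onsets = onsets, labels = labels,
    task_duration = task_duration, rest_duration = rest_duration,
    tr = tr, run_length = run_length, n_volumes = as.integer(round(n_volumes)),
    task_levels = levs
  ), class = "paradigm")
}

#' Default interleaved three-task paradigm
#'
#' Twenty-four trials — three task types (WR word reading, PV pattern viewing,
#' FT finger tapping analogues) presented eight times each in an interleaved
#' WR, PV, FT cycle. Each trial is a 6 s task period followed by 24 s of rest
#' (12 volumes at TR 2.5 s), for a 12-minute run of 288 volumes.
#'
#' @param tr repetition time in seconds.
#' @return a `paradigm` object.
#' @export
default_paradigm <- function(tr = 2.5) {
  labels <- rep(TASK_LEVELS, times = 8)
  onsets <- seq(0, by = 30, length.out = length(labels))
  make_paradigm(onsets, labels, task_duration = 6, rest_duration = 24,
                tr = tr, run_length = 720, task_levels = TASK_LEVELS)
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("paradigm: %d trials (%s), %g s task + %g s rest, TR %g s, %g s run (%d volumes)\n",
              length(x$onsets), paste(x$task_levels, collapse = "/"),
              x$task_duration, x$rest_duration, x$tr, x$run_length, x$n_volumes))
  invisible(x)
}

#' Write a paradigm to a plain-text file
#'
#' Key-value header (tr, run_length, task_duration, rest_duration, task_levels)
#' followed by one `onset<TAB>label` line per trial.
#'
#' @param paradigm a `paradigm` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paradigm <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "paradigm"))
  header <- c(
    sprintf("tr: %.10g", paradigm$tr),
    sprintf("run_length: %.10g", paradigm$run_length),
    sprintf("task_duration: %.10g", paradigm$task_duration),
    sprintf("rest_duration: %.10g", paradigm$rest_duration),
    sprintf("task_levels: %s", paste(paradigm$task_levels, collapse = ",")),
    "trials:"
  )
  body <- sprintf("%.10g\t%s", paradigm$onsets, paradigm$labels)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a paradigm from a plain-text file
#'
#' @param path file written by [write_paradigm()].
#' @return a `paradigm` object.
#' @export
read_paradigm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sep <- match("trials:", lines)
  if (is.na(sep)) stop("malformed paradigm file: no 'trials:' section", call. = FALSE)
  kv <- lines[seq_len(sep - 1L)]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  names(vals) <- keys
  trial_lines <- lines[seq.int(sep + 1L, length(lines))]
  parts <- strsplit(trial_lines, "\t", fixed = TRUE)
  onsets <- vapply(parts, function(p) as.numeric(p[[1L]]), numeric(1))
  labels <- vapply(parts, function(p) p[[2L]], character(1))
  make_paradigm(onsets, labels,
                task_duration = as.numeric(vals[["task_duration"]]),
                rest_duration = as.numeric(vals[["rest_duration"]]),
                tr = as.numeric(vals[["tr"]]),
                run_length = as.numeric(vals[["run_length"]]),
                task_levels = strsplit(vals[["task_levels"]], ",", fixed = TRUE)[[1L]])
}
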