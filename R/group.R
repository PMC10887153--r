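#' Task-mean FC map
#'
#' Voxelwise arithmetic mean of one subject's trial FC maps for a single task
#' category, representing that subject's typical whole-brain co-activity for
#' the task. Averaging substantially reduces trial-to-trial variation.
#'
#' @param maps list of `fc_map` objects of one category (8 for the standard
#'   design).
#' @param n_required expected number of maps (default 8); set `check_count =
#'   FALSE` to average any number.
#' @param check_count enforce `length(maps) == n_required`.
#' @return an object of class `task_mean_map` with fields `r`, `mask`,
#'   `task_label`, `subject_id`, `n_maps`.
#' @export
task_mean_map <- function(maps, n_required = 8L, check_count = TRUE) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, logical(1), "fc_map")))
  if (check_count && length(maps) != n_required)
    stop(sprintf("expected %d maps per category, got %d (set check_count = FALSE to override)",
                 n_required, length(maps)), call. = FALSE)
  d <- dim(maps[[1L]]$r)
  acc <- array(0, dim = d)
  for (m in maps) {
    if (!identical(dim(m$r), d)) stop("maps are not on one grid", call. = FALSE)
    acc <- acc + m$r
  }
  structure(list(r = acc / length(maps),
                 mask = maps[[1L]]$mask,
                 task_label = maps[[1L]]$window$task_label %||% NA_character_,
                 subject_id = maps[[1L]]$window$subject_id %||% NA_character_,
                 n_maps = length(maps)),
            class = "task_mean_map")
}

# treat a task_mean_map as an fc_map for correlation utilities
as_fc_map <- function(x) {
  if (inherits(x, "fc_map")) return(x)
  stopifnot(inherits(x, "task_mean_map"))
  structure(list(r = x$r, mask = x$mask,
                 window = list(task_label = x$task_label,
                               trial_index = NA_integer_,
                               subject_id = x$subject_id),
                 n_samples = NA_integer_, n_zero_variance = 0L),
            class = "fc_map")
}

# flatten cohort task-mean maps into voxels x (subject, category) matrix
.group_stack <- function(task_mean_maps, mask) {
  subjects <- names(task_mean_maps)
  cats <- names(task_mean_maps[[1L]])
  cols <- list()
  for (s in subjects) {
    if (!identical(names(task_mean_maps[[s]]), cats))
      stop("all subjects must provide the same task categories", call. = FALSE)
    for (cc in cats) {
      m <- task_mean_maps[[s]][[cc]]
      if (!identical(dim(m$r), dim(mask$inside)))
        stop("task-mean maps are not on one grid", call. = FALSE)
      cols[[paste(s, cc, sep = ".")]] <- m$r[mask$inside]
    }
  }
  M <- do.call(cbind, cols)
  if (any(!is.finite(M)))
    stop("undefined values inside the group mask; intersect subject masks first",
         call. = FALSE)
  list(M = M, subjects = subjects, cats = cats,
       subject_of = rep(subjects, each = length(cats)),
       cat_of = rep(cats, times = length(subjects)))
}

#' Cross-subject similarity blocks of task-mean maps
#'
#' For each task category, the spatial correlation between every pair of
#' subjects' task-mean maps (C(n_subjects, 2) pairs) quantifies the
#' commonality of task-evoked activity across subjects; between-category
#' blocks pair the task-mean maps of two different categories across all
#' subject pairs (including a subject with itself, since the two maps are
#' distinct).
#'
#' @param task_mean_maps named list (by subject) of named lists (by category)
#'   of `task_mean_map` objects, all on one grid.
#' @param mask the group [brain_mask()] (intersection of subject masks).
#' @return data frame of block summaries as in [summarize_block()].
#' @export
cross_subject_blocks <- function(task_mean_maps, mask) {
  if (length(task_mean_maps) < 2L) stop("need at least 2 subjects", call. = FALSE)
  st <- .group_stack(task_mean_maps, mask)
  C <- stats::cor(st$M)
  cats <- st$cats
  rows <- list()
  for (cc in cats) {
    i <- which(st$cat_of == cc)
    vals <- C[i, i][upper.tri(diag(length(i)))]
    rows[[length(rows) + 1L]] <- summarize_block(vals, sprintf("within %s", cc))
  }
  for (a in seq_along(cats)[-length(cats)]) for (b in seq.int(a + 1L, length(cats))) {
    i <- which(st$cat_of == cats[a]); j <- which(st$cat_of == cats[b])
    vals <- as.vector(C[i, j])
    rows[[length(rows) + 1L]] <-
      summarize_block(vals, sprintf("between %s-%s", cats[a], cats[b]))
  }
  do.call(rbind, rows)
}

#' Cross-subject task identification
#'
#' Uses each subject's three task-mean maps in turn as the task markers and
#' classifies every other subject's task-mean maps by largest spatial
#' correlation, pooling correct rates per category over all reference
#' subjects (for a 9-subject cohort: 8 x 3 = 24 test maps per reference).
#'
#' @inheritParams cross_subject_blocks
#' @return list with `correct_rate` (named percent vector), `n_correct`,
#'   `n_total`, `n_tests_per_reference`.
#' @export
cross_subject_identification <- function(task_mean_maps, mask) {
  if (length(task_mean_maps) < 2L) stop("need at least 2 subjects", call. = FALSE)
  st <- .group_stack(task_mean_maps, mask)
  C <- stats::cor(st$M)
  cats <- st$cats
  k <- length(cats)
  subjects <- st$subjects
  correct <- total <- stats::setNames(numeric(k), cats)
  for (s in subjects) {
    marker_cols <- which(st$subject_of == s)          # in category order
    test_cols <- which(st$subject_of != s)
    sub <- C[test_cols, marker_cols, drop = FALSE]
    pred <- max.col(sub, ties.method = "first")
    tc <- match(st$cat_of[test_cols], cats)
    for (ci in seq_len(k)) {
      sel <- tc == ci
      total[ci] <- total[ci] + sum(sel)
      correct[ci] <- correct[ci] + sum(pred[sel] == ci)
    }
  }
  list(correct_rate = 100 * correct / total,
       n_correct = correct, n_total = total,
       n_tests_per_reference = (length(subjects) - 1L) * k)
}
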