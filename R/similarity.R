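# flatten a list of fc_maps to a voxels x maps matrix over a common mask
# (fixed voxel order: array linear order, x fastest)
fc_stack <- function(maps, mask = NULL) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, logical(1), "fc_map")))
  mask <- mask %||% maps[[1L]]$mask
  d <- dim(maps[[1L]]$r)
  for (m in maps)
    if (!identical(dim(m$r), d))
      stop("FC maps are not on a common grid", call. = FALSE)
  inside <- mask$inside
  M <- vapply(maps, function(m) m$r[inside], numeric(sum(inside)))
  if (any(!is.finite(M)))
    stop("FC maps contain undefined values inside the common mask; intersect masks first",
         call. = FALSE)
  M
}

#' Spatial correlation between two FC maps
#'
#' Pearson correlation of the two maps' r values over the in-mask voxels,
#' flattened in a fixed voxel order. This is the similarity measure between
#' two trials' whole-brain co-activity patterns.
#'
#' @param a,b `fc_map` objects on one grid.
#' @param mask optional [brain_mask()]; defaults to the first map's mask.
#' @return the spatial correlation R.
#' @export
spatial_correlation <- function(a, b, mask = NULL) {
  M <- fc_stack(list(a, b), mask)
  if (nrow(M) < 3L) stop("mask must contain at least 3 voxels", call. = FALSE)
  if (stats::sd(M[, 1]) == 0 || stats::sd(M[, 2]) == 0)
    stop("an FC map is constant over the mask; correlation undefined", call. = FALSE)
  stats::cor(M[, 1], M[, 2])
}

#' All-pairs spatial-correlation matrix
#'
#' Builds the symmetric trials-by-trials matrix of spatial correlations R
#' between FC maps. Columns are centred and normalized once and the matrix is
#' formed by a single cross-product, so it is exactly symmetric with unit
#' diagonal.
#'
#' @param maps list of `fc_map` objects (one subject's trials, in paradigm
#'   order).
#' @param mask optional common [brain_mask()].
#' @param subject_id optional label stored with the result.
#' @return an object of class `sc_matrix`: fields `R` (matrix with trial
#'   labels as dimnames), `trial_meta` (data frame of `task_label`,
#'   `trial_index`), `subject_id`.
#' @export
sc_matrix <- function(maps, mask = NULL, subject_id = NULL) {
  M <- fc_stack(maps, mask)
  Z <- sweep(M, 2, colMeans(M))
  nrm <- sqrt(colSums(Z^2))
  if (any(nrm == 0))
    stop("an FC map is constant over the mask; correlation undefined", call. = FALSE)
  Z <- sweep(Z, 2, nrm, "/")
  R <- crossprod(Z)
  diag(R) <- 1
  meta <- data.frame(
    task_label = vapply(maps, function(m) as.character(m$window$task_label %||% NA),
                        character(1)),
    trial_index = vapply(maps, function(m) as.integer(m$window$trial_index %||% NA),
                         integer(1)),
    stringsAsFactors = FALSE)
  nm <- sprintf("%s_%02d", meta$task_label, meta$trial_index)
  dimnames(R) <- list(nm, nm)
  structure(list(R = R, trial_meta = meta, subject_id = subject_id),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("sc_matrix: %d trials%s, R in [%.3f, %.3f]\n",
              nrow(x$R),
              if (!is.null(x$subject_id)) paste0(" (subject ", x$subject_id, ")") else "",
              min(x$R[lower.tri(x$R)]), max(x$R[lower.tri(x$R)])))
  invisible(x)
}

#' Summarize a block of spatial correlations
#'
#' Sample minimum, maximum, mean and standard deviation (n - 1 denominator) of
#' a set of pairwise R values. A single value yields sd 0 with
#' `degenerate = TRUE`.
#'
#' @param values numeric vector of R values (non-empty).
#' @param block_kind optional label (e.g. `"within WR"`).
#' @return one-row data frame with columns `block_kind`, `n_pairs`, `min`,
#'   `max`, `mean`, `sd`, `degenerate`.
#' @export
summarize_block <- function(values, block_kind = NA_character_) {
  if (length(values) == 0L) stop("empty block", call. = FALSE)
  s <- sd1(values)
  data.frame(block_kind = block_kind, n_pairs = length(values),
             min = min(values), max = max(values), mean = mean(values),
             sd = as.numeric(s),
             degenerate = isTRUE(attr(s, "degenerate")),
             stringsAsFactors = FALSE)
}

#' Within/between-category similarity blocks
#'
#' Assembles the all-pairs SC matrix and summarizes its within-category blocks
#' (all unordered pairs of same-task trials; C(8,2) = 28 pairs per category
#' for the 8-trial design) and between-category blocks (all cross pairs of two
#' tasks; 8 x 8 = 64 pairs), mirroring the per-subject similarity table.
#'
#' @param maps list of one subject's `fc_map` objects, or an `sc_matrix`.
#' @param mask optional common mask (ignored when `maps` is an `sc_matrix`).
#' @param subject_id optional label.
#' @param task_levels category order for reporting; defaults to the order of
#'   first appearance in the trial metadata.
#' @return list with `sc` (the [sc_matrix()]) and `summary` (data frame of the
#'   within- and between-category block summaries).
#' @export
pairwise_blocks <- function(maps, mask = NULL, subject_id = NULL,
                            task_levels = NULL) {
  sc <- if (inherits(maps, "sc_matrix")) maps
        else sc_matrix(maps, mask, subject_id = subject_id)
  labs <- sc$trial_meta$task_label
  levs <- task_levels %||% unique(labs)
  idx <- lapply(levs, function(l) which(labs == l))
  names(idx) <- levs
  if (any(lengths(idx) == 0L)) stop("missing trials for some task category", call. = FALSE)
  rows <- list()
  for (l in levs) {
    i <- idx[[l]]
    if (length(i) < 2L) stop(sprintf("category %s has fewer than 2 trials", l), call. = FALSE)
    vals <- sc$R[i, i][upper.tri(diag(length(i)))]
    rows[[length(rows) + 1L]] <- summarize_block(vals, sprintf("within %s", l))
  }
  if (length(levs) >= 2L) {
    for (a in seq_along(levs)[-length(levs)]) for (b in seq.int(a + 1L, length(levs))) {
      vals <- as.vector(sc$R[idx[[levs[a]]], idx[[levs[b]]]])
      rows[[length(rows) + 1L]] <-
        summarize_block(vals, sprintf("between %s-%s", levs[a], levs[b]))
    }
  }
  list(sc = sc, summary = do.call(rbind, rows))
}
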