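#' Chance-level correct rate
#'
#' @param n_categories number of task categories (>= 2).
#' @return chance correct rate in percent, `100 / n_categories`.
#' @export
chance_rate <- function(n_categories) {
  stop_if_not_scalar_num(n_categories, "n_categories")
  if (n_categories < 2) stop("n_categories must be >= 2", call. = FALSE)
  100 / n_categories
}

#' Classify one trial by nearest marker
#'
#' Predicts the task label of a test FC map as the label of the marker map
#' with the largest spatial correlation. Ties are broken deterministically by
#' canonical label order (the order of `markers`) and flagged.
#'
#' @param test_map an `fc_map`.
#' @param markers named list of marker `fc_map`s, one per category, in
#'   canonical label order.
#' @param mask optional common [brain_mask()].
#' @return the predicted label, with attributes `R` (named spatial
#'   correlations) and `tie` (logical).
#' @export
classify_trial <- function(test_map, markers, mask = NULL) {
  stopifnot(length(markers) >= 2L, !is.null(names(markers)))
  R <- vapply(markers, function(m) spatial_correlation(test_map, m, mask),
              numeric(1))
  best <- which.max(R)  # first maximum = canonical-order tie-break
  tie <- sum(R == R[best]) > 1L
  structure(names(markers)[best], R = R, tie = tie)
}

#' Exhaustive marker-based task identification for one subject
#'
#' Enumerates every combination of one marker trial per task category (8^3 =
#' 512 for the 8-trial, 3-task design). For each combination the remaining 21
#' trials are classified by the largest spatial correlation to the three
#' markers, and correct rates are pooled per true category over all
#' combinations (micro-average; under this balanced design it coincides with
#' the per-combination average).
#'
#' @param maps list of one subject's `fc_map` objects, or a precomputed
#'   [sc_matrix()].
#' @param mask optional common mask.
#' @param task_levels canonical category order for tie-breaking and reporting;
#'   defaults to order of first appearance.
#' @return an object of class `identification_result`: `n_combinations`,
#'   `n_tests`, `correct_rate` (named percent vector), `n_correct`, `n_total`
#'   (per category), `n_ties`, `confusion` (true x predicted counts).
#' @export
run_identification <- function(maps, mask = NULL, task_levels = NULL) {
  sc <- if (inherits(maps, "sc_matrix")) maps else sc_matrix(maps, mask)
  labs <- sc$trial_meta$task_label
  levs <- task_levels %||% unique(labs)
  if (!all(labs %in% levs)) stop("trial labels outside task_levels", call. = FALSE)
  idx <- lapply(levs, function(l) which(labs == l))
  names(idx) <- levs
  if (any(lengths(idx) == 0L)) stop("missing maps for some task category", call. = FALSE)
  combos <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  n_comb <- nrow(combos)
  k <- length(levs)
  n_trials <- length(labs)
  true_cat <- match(labs, levs)
  confusion <- matrix(0, k, k, dimnames = list(true = levs, predicted = levs))
  n_ties <- 0L
  R <- sc$R
  for (i in seq_len(n_comb)) {
    m <- combos[i, ]
    tests <- seq_len(n_trials)[-m]
    sub <- R[tests, m, drop = FALSE]
    pred <- max.col(sub, ties.method = "first")
    rowmax <- sub[cbind(seq_along(tests), pred)]
    n_ties <- n_ties + sum(rowSums(sub == rowmax) > 1L)
    tc <- true_cat[tests]
    confusion <- confusion + matrix(tabulate(tc + k * (pred - 1L), nbins = k * k), k, k)
  }
  correct <- stats::setNames(diag(confusion), levs)
  total <- stats::setNames(rowSums(confusion), levs)
  structure(list(n_combinations = n_comb,
                 n_tests = as.integer(n_comb * (n_trials - k)),
                 correct_rate = 100 * correct / total,
                 n_correct = correct, n_total = total,
                 n_ties = n_ties, confusion = confusion,
                 task_levels = levs),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("task identification: %d marker combinations, %d tests\n",
              x$n_combinations, x$n_tests))
  print(round(x$correct_rate, 1))
  invisible(x)
}

#' Test per-subject correct rates against chance
#'
#' One-sample t test of the per-subject rates against the chance level, with a
#' one-sided (greater) alternative. Pairing each subject's rate with the
#' constant chance level reduces to this one-sample test on differences.
#'
#' @param rates numeric vector, one correct rate (percent) per subject.
#' @param chance chance level in percent, e.g. [chance_rate()].
#' @return list with `statistic`, `df`, `p_value`, `mean_rate`.
#' @export
test_vs_chance <- function(rates, chance = chance_rate(3)) {
  if (length(rates) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (stats::sd(rates) == 0)
    stop("zero variance across subjects; t test undefined", call. = FALSE)
  tt <- stats::t.test(rates, mu = chance, alternative = "greater")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_rate = mean(rates))
}

#' Association between within-category similarity and correct rate
#'
#' Pearson correlation (two-sided test) between the mean within-category
#' spatial correlation R and the identification correct rate, pooled over
#' subjects and categories.
#'
#' @param mean_R numeric vector of mean within-category R values.
#' @param correct_rate numeric vector of correct rates (percent), same length.
#' @return list with `r`, `p_value`, `n`.
#' @export
associate_similarity_rate <- function(mean_R, correct_rate) {
  if (length(mean_R) != length(correct_rate))
    stop("inputs must have equal length", call. = FALSE)
  if (length(mean_R) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(mean_R) == 0 || stats::sd(correct_rate) == 0)
    stop("constant input; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(mean_R, correct_rate, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(mean_R))
}
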