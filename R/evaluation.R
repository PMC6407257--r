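# Repeated stratified cross-validation with class-weighted F1 scoring.
# Per repetition, held-out-fold predictions are concatenated over the whole
# dataset before scoring, per-class F1 is averaged over repetitions, and
# the overall score is the class-size-weighted average of per-class F1
# within each repetition, averaged over repetitions.

#' Per-class F1 scores
#'
#' `F1_a = 2 P_a R_a / (P_a + R_a)` from the one-vs-rest confusion counts
#' of class `a`. A class with neither predicted nor actual positives (so
#' precision and recall are both undefined) scores 0 — the conservative
#' convention.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class order for the result; defaults to the sorted union
#'   of observed labels.
#' @return Named numeric vector of F1 scores in `[0, 1]`, one per class.
#' @export
f1_per_class <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_gtmap("`y_true` and `y_pred` must have equal length.",
               "gtmap_shape_error")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  vapply(classes, function(a) {
    tp <- sum(y_true == a & y_pred == a)
    fp <- sum(y_true != a & y_pred == a)
    fn <- sum(y_true == a & y_pred != a)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Class-size-weighted overall F1
#'
#' @param per_class Numeric vector of per-class F1 scores.
#' @param class_sizes Positive class sizes (numbers of individuals), same
#'   length and order.
#' @return `sum(F1_a * N_a) / N_total`.
#' @export
weighted_f1 <- function(per_class, class_sizes) {
  if (length(per_class) != length(class_sizes)) {
    stop_gtmap("`per_class` and `class_sizes` must have equal length.",
               "gtmap_shape_error")
  }
  if (any(class_sizes <= 0)) {
    stop_gtmap("Class sizes must be positive.", "gtmap_parameter_error")
  }
  sum(per_class * class_sizes) / sum(class_sizes)
}

# Stratified fold assignment: within each class, members are shuffled and
# dealt round-robin into `folds` folds.
stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < folds)) {
    small <- names(counts)[which(counts < folds)[1L]]
    stop_gtmap(sprintf("Class '%s' has %d member(s); %d-fold stratification needs at least %d.",
                       small, counts[[small]], folds, folds),
               "gtmap_stratification_error")
  }
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `n_repeats` repetitions of stratified `folds`-fold cross-validation.
#' Repetition `j` draws a fresh fold assignment seeded with
#' `base_seed + j`, fits the classifier on each training fold (all model
#' fitting — PCA, GTM, node-class map, k-NN — happens inside the
#' classifier, so held-out rows never influence a fitted transform), and
#' concatenates held-out predictions over the whole dataset before scoring.
#'
#' @param x Feature matrix (individuals x variables), typically imputed
#'   allele counts.
#' @param y Class labels, one per row of `x`.
#' @param classifier A classifier factory: `function(x_train, y_train)`
#'   returning a prediction function `function(x_test) -> labels`. See
#'   [classifier_gtm()], [classifier_knn()], [classifier_svm()].
#' @param n_repeats Number of repetitions J (default 10).
#' @param folds Number of folds (default 5).
#' @param base_seed Base seed; repetition `j` uses `base_seed + j`.
#' @return Object of class `cv_result`: `per_class_f1` (A x J matrix),
#'   `per_class_mean`, `overall_f1_mean`, `overall_dispersion` (1.96 x
#'   SD/sqrt(J), a 95% interval half-width), `overall_by_repetition`,
#'   `class_sizes`, `seeds`.
#' @export
repeated_cv <- function(x, y, classifier, n_repeats = 10, folds = 5,
                        base_seed = 42) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  check_number(n_repeats, "n_repeats", min = 1, integerish = TRUE)
  check_number(folds, "folds", min = 2, integerish = TRUE)
  classes <- sort(unique(y))
  sizes <- as.numeric(table(factor(y, classes)))
  seeds <- base_seed + seq_len(n_repeats)
  per_class <- matrix(NA_real_, length(classes), n_repeats,
                      dimnames = list(classes, NULL))
  overall <- numeric(n_repeats)
  for (j in seq_len(n_repeats)) {
    fold_of <- stratified_folds(y, folds, seeds[j])
    pred <- character(length(y))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      fitted <- classifier(x[!test, , drop = FALSE], y[!test])
      pred[test] <- fitted(x[test, , drop = FALSE])
    }
    f1 <- f1_per_class(y, pred, classes)
    per_class[, j] <- f1
    overall[j] <- weighted_f1(f1, sizes)
  }
  structure(
    list(per_class_f1 = per_class,
         per_class_mean = rowMeans(per_class),
         overall_by_repetition = overall,
         overall_f1_mean = mean(overall),
         overall_dispersion = dispersion_95(overall),
         class_sizes = stats::setNames(sizes, classes),
         n_repeats = as.integer(n_repeats), folds = as.integer(folds),
         seeds = seeds),
    class = "cv_result")
}

# half-width of a normal 95% interval for the mean across repetitions
dispersion_95 <- function(v) {
  if (length(v) < 2L) return(0)
  1.96 * sd(v) / sqrt(length(v))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d x %d-fold CV over %d classes\n",
              x$n_repeats, x$folds, nrow(x$per_class_f1)))
  cat(sprintf("  overall weighted F1: %.2f ± %.2f\n",
              x$overall_f1_mean, x$overall_dispersion))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    class = rownames(x$per_class_f1),
    n = as.numeric(x$class_sizes),
    f1_mean = as.numeric(x$per_class_mean),
    f1_dispersion = apply(x$per_class_f1, 1L, dispersion_95))
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(overall_f1 = x$overall_f1_mean,
                 dispersion = x$overall_dispersion,
                 n_repeats = x$n_repeats, folds = x$folds)
}

#' Hyperparameter grid search by repeated cross-validation
#'
#' Evaluates [repeated_cv()] at every grid point and returns the point with
#' the largest overall weighted F1; ties go to the earlier grid point, so
#' list simpler parameter settings first.
#'
#' @param x,y Features and labels as in [repeated_cv()].
#' @param factory Function taking one grid row's parameters (as arguments)
#'   and returning a classifier factory, e.g. `classifier_knn`.
#' @param grid Data frame of hyperparameter combinations (one column per
#'   argument of `factory`).
#' @param ... Passed to [repeated_cv()] (`n_repeats`, `folds`, `base_seed`).
#' @return List with `best_params` (one-row tibble), `best_result` (its
#'   `cv_result`) and `results` (tibble of all grid points with scores).
#' @export
grid_search <- function(x, y, factory, grid, ...) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) {
    stop_gtmap("Empty hyperparameter grid.", "gtmap_parameter_error")
  }
  fits <- purrr::map(seq_len(nrow(grid)), function(i) {
    clf <- do.call(factory, as.list(grid[i, ]))
    repeated_cv(x, y, clf, ...)
  })
  scores <- purrr::map_dbl(fits, "overall_f1_mean")
  best <- which.max(scores)  # first maximum on ties
  list(best_params = grid[best, ],
       best_result = fits[[best]],
       results = dplyr::bind_cols(grid,
                                  tibble::tibble(
                                    overall_f1 = scores,
                                    dispersion = purrr::map_dbl(fits, "overall_dispersion"))))
}

#' Principal-component sweep
#'
#' Re-runs the full cross-validated GTM classification pipeline at each
#' candidate number of principal components and reports the overall
#' weighted F1 curve together with the cumulative variance explained at
#' each point (from a PCA on the full matrix; the per-fold PCAs used for
#' classification are refit inside the folds).
#'
#' @param x,y Features and labels as in [repeated_cv()].
#' @param pc_list Integer vector of PC counts to evaluate.
#' @param gtm_args Named list of extra arguments for [classifier_gtm()].
#' @param ... Passed to [repeated_cv()] (`n_repeats`, `folds`, `base_seed`).
#' @return Tibble with `n_pcs`, `overall_f1`, `dispersion`,
#'   `cumulative_variance`.
#' @export
pc_sweep <- function(x, y, pc_list, gtm_args = list(), ...) {
  x <- as.matrix(x)
  max_f <- min(nrow(x) - 1L, ncol(x))
  if (max(pc_list) > max_f) {
    stop_gtmap(sprintf("pc_list maximum %d exceeds min(N-1, D) = %d.",
                       max(pc_list), max_f),
               "gtmap_parameter_error")
  }
  full <- fit_pca(x, n_pcs = max(pc_list))
  cum_var <- cumsum(full$explained_variance_ratio)
  rows <- purrr::map(pc_list, function(f) {
    clf <- do.call(classifier_gtm, c(list(n_pcs = f), gtm_args))
    cv <- repeated_cv(x, y, clf, ...)
    tibble::tibble(n_pcs = as.integer(f),
                   overall_f1 = cv$overall_f1_mean,
                   dispersion = cv$overall_dispersion,
                   cumulative_variance = cum_var[f])
  })
  dplyr::bind_rows(rows)
}
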