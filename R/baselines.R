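# Comparison classifiers: k-nearest neighbours on the 2D PCA plot (the
# "visual" baseline) and a thin delegating hook to a linear SVM.

#' k-nearest-neighbour classifier on a 2D PCA plot
#'
#' Models the classical PCA-plot workflow: train individuals are points in
#' the first two principal components, a test individual is projected into
#' the same coordinates and assigned the predominant ancestry among its `k`
#' nearest training neighbours (Euclidean distance). Restricted to 2D by
#' design — it is the PCA-plot baseline, not a general k-NN.
#'
#' Distance ties at the k-th radius include all equidistant points before
#' voting. Vote ties are resolved distance-respectingly: among the tied
#' classes, the one whose nearest member is closest wins (so a 2-NN (A, B)
#' tie goes to the single nearest neighbour's label); any residual tie
#' falls back to class order.
#'
#' @param train_scores N x 2 matrix of training PC scores.
#' @param labels Length-N class labels.
#' @param k Number of neighbours, `1 <= k <= N`.
#' @return Object of class `knn_model`.
#' @export
knn_fit <- function(train_scores, labels, k) {
  train_scores <- as.matrix(train_scores)
  if (ncol(train_scores) != 2L) {
    stop_gtmap("The PCA-plot baseline uses exactly 2 score columns.",
               "gtmap_parameter_error")
  }
  check_number(k, "k", min = 1, integerish = TRUE)
  if (k > nrow(train_scores)) {
    stop_gtmap(sprintf("k = %d exceeds the %d training points.",
                       k, nrow(train_scores)),
               "gtmap_parameter_error")
  }
  if (length(labels) != nrow(train_scores)) {
    stop_gtmap("One label per training point is required.", "gtmap_shape_error")
  }
  structure(list(train_points = train_scores,
                 train_labels = as.character(labels),
                 k = as.integer(k)),
            class = "knn_model")
}

#' @rdname knn_fit
#' @param model A `knn_model`.
#' @param test_scores Matrix of test points in the same 2D PCA coordinates.
#' @return `knn_predict()` returns a character vector of predicted labels.
#' @export
knn_predict <- function(model, test_scores) {
  stopifnot(inherits(model, "knn_model"))
  test_scores <- as.matrix(test_scores)
  if (ncol(test_scores) != 2L) {
    stop_gtmap("Test scores must have 2 columns.", "gtmap_shape_error")
  }
  d2 <- sq_dists(test_scores, model$train_points)
  labs <- model$train_labels
  classes <- sort(unique(labs))
  vapply(seq_len(nrow(d2)), function(i) {
    d <- d2[i, ]
    ord <- order(d)
    radius <- d[ord[model$k]]
    in_ball <- d <= radius
    votes <- tapply(rep(1L, sum(in_ball)), labs[in_ball], sum)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # distance-respecting tie break: tied class with the closest member
    nearest <- vapply(top, function(cl) min(d[labs == cl]), numeric(1))
    winners <- top[nearest == min(nearest)]
    sort(winners)[1L]
  }, character(1))
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k = %d over %d training points, %d classes\n",
              x$k, nrow(x$train_points), length(unique(x$train_labels))))
  invisible(x)
}

# seam so tests can exercise the no-SVM path
has_e1071 <- function() requireNamespace("e1071", quietly = TRUE)

#' Linear SVM delegation hook
#'
#' Thin wrapper around an established linear support-vector implementation
#' (`e1071::svm`) so SVM predictions can be consumed by the evaluation
#' harness exactly like the other classifiers. The penalty grid
#' conventionally spans `C = 2^r` for `r` in -5..10 (see [svm_c_grid()]).
#'
#' @param train_scores N x F matrix of training PC scores.
#' @param labels Length-N class labels.
#' @param cost Penalty parameter C.
#' @return A prediction function `f(test_scores) -> character labels`.
#' @export
linear_svm_hook <- function(train_scores, labels, cost = 1) {
  if (!has_e1071()) {
    stop_gtmap(
      "No linear SVM implementation available (package 'e1071' not installed); the rest of the toolkit works without it.",
      "gtmap_capability_error")
  }
  fit <- e1071::svm(as.matrix(train_scores), factor(labels),
                    kernel = "linear", cost = cost, scale = FALSE)
  function(test_scores) {
    as.character(predict(fit, as.matrix(test_scores)))
  }
}

#' @rdname linear_svm_hook
#' @export
svm_c_grid <- function() 2^(-5:10)
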