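# Classifier factories: each returns a `function(x_train, y_train)` that
# fits the whole pipeline (PCA reduction included) on the training rows and
# returns a prediction closure, so the cross-validation harness never leaks
# held-out rows into a fitted transform.

#' GTM Bayesian ancestry classifier factory
#'
#' Pipeline per training fold: fit PCA with `n_pcs` components, fit a GTM
#' on the training scores, fit the node-level ancestry model on the
#' training responsibilities; prediction projects test individuals through
#' the same PCA and map and takes the argmax ancestry profile.
#'
#' @param n_pcs Number of principal components.
#' @param k_side,m_side,width_factor,lambda,max_iter,tol GTM
#'   hyperparameters, see [gtm_fit()].
#' @param prior_mode Class prior mode for [fit_ancestry_model()].
#' @return A classifier factory for [repeated_cv()].
#' @export
classifier_gtm <- function(n_pcs = 10, k_side = 16, m_side = 4,
                           width_factor = 0.3, lambda = 0.1,
                           max_iter = 200, tol = 1e-5,
                           prior_mode = "empirical") {
  force(n_pcs)
  function(x_train, y_train) {
    pca <- fit_pca(x_train, n_pcs = n_pcs)
    map <- gtm_fit(pca$scores, k_side = k_side, m_side = m_side,
                   width_factor = width_factor, lambda = lambda,
                   max_iter = max_iter, tol = tol)
    anc <- fit_ancestry_model(map$responsibilities, y_train,
                              prior_mode = prior_mode, grid = map$grid)
    function(x_test) {
      r <- gtm_project(map, predict(pca, x_test))
      classify_ancestry(anc, r)$predicted
    }
  }
}

#' 2D-PCA k-NN baseline factory
#'
#' Fits PCA with two components on the training fold and classifies test
#' individuals by the predominant ancestry among their `k` nearest
#' neighbours on the 2D plot.
#'
#' @param k Number of neighbours.
#' @return A classifier factory for [repeated_cv()].
#' @export
classifier_knn <- function(k = 7) {
  force(k)
  function(x_train, y_train) {
    pca <- fit_pca(x_train, n_pcs = 2)
    model <- knn_fit(pca$scores, y_train, k = k)
    function(x_test) knn_predict(model, predict(pca, x_test))
  }
}

#' Linear SVM baseline factory
#'
#' Fits PCA with `n_pcs` components and delegates to [linear_svm_hook()].
#'
#' @param n_pcs Number of principal components.
#' @param cost Penalty parameter C.
#' @return A classifier factory for [repeated_cv()].
#' @export
classifier_svm <- function(n_pcs = 10, cost = 1) {
  force(n_pcs)
  function(x_train, y_train) {
    pca <- fit_pca(x_train, n_pcs = n_pcs)
    pred <- linear_svm_hook(pca$scores, y_train, cost = cost)
    function(x_test) pred(predict(pca, x_test))
  }
}
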