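test_that("per-class F1 matches hand confusion-table arithmetic", {
  y <- c("A", "A", "A", "B", "B", "C")
  expect_equal(f1_per_class(y, y), c(A = 1, B = 1, C = 1))

  # class A: TP = 2, FP = 1, FN = 1 -> precision = recall = 2/3
  y_true <- c("A", "A", "A", "B", "B", "B")
  y_pred <- c("A", "A", "B", "A", "B", "B")
  f1 <- f1_per_class(y_true, y_pred)
  expect_equal(f1[["A"]], 2 / 3)

  # precision 0.8, recall 0.5 -> F1 = 2 * 0.4 / 1.3
  y_true2 <- c(rep("A", 8), rep("B", 8))
  y_pred2 <- c(rep("A", 4), rep("B", 4), c("A", rep("B", 7)))
  f1_2 <- f1_per_class(y_true2, y_pred2)
  expect_equal(f1_2[["A"]], 2 * 0.8 * 0.5 / 1.3)

  expect_error(f1_per_class(c("A", "B"), "A"), class = "gtmap_shape_error")
})

test_that("F1 harness agrees exactly with an independent oracle", {
  classes <- c("A", "B", "C")
  for (i in 1:100) {
    labs <- gtmap:::with_seed(1000 + i, list(
      t = sample(classes, 12, replace = TRUE),
      p = sample(classes, 12, replace = TRUE)))
    expect_identical(f1_per_class(labs$t, labs$p, classes),
                     oracle_f1(labs$t, labs$p, classes))
  }
})

test_that("weighted F1 reduces correctly in edge cases", {
  expect_equal(weighted_f1(c(0.5, 0.7), c(4, 4)), 0.6)  # plain mean
  expect_equal(weighted_f1(c(1, 0), c(3, 1)), 0.75)
  expect_equal(weighted_f1(0.42, 7), 0.42)
  expect_error(weighted_f1(c(1, 0), c(3, 0)), class = "gtmap_parameter_error")

  # all-correct is exactly 1, all-wrong on two classes exactly 0
  y <- rep(c("A", "B"), 5)
  expect_equal(weighted_f1(f1_per_class(y, y), c(5, 5)), 1)
  wrong <- ifelse(y == "A", "B", "A")
  expect_equal(weighted_f1(f1_per_class(y, wrong), c(5, 5)), 0)
})

test_that("repeated CV scores an oracle classifier perfectly", {
  blobs <- blob_data(n_per = 15, f = 3, seed = 41)
  oracle_clf <- function(x_train, y_train) {
    key <- rownames(x_train)
    function(x_test) {
      # cheat deliberately: recover labels by row identity
      all_x <- rbind(x_train)
      vapply(seq_len(nrow(x_test)), function(i) {
        d <- colSums((t(all_x) - x_test[i, ])^2)
        y_train[which.min(d)]
      }, character(1))
    }
  }
  cv <- repeated_cv(blobs$x, blobs$labels, oracle_clf, n_repeats = 3,
                    folds = 5, base_seed = 1)
  expect_equal(cv$overall_f1_mean, 1)
  expect_equal(cv$overall_dispersion, 0)
  expect_equal(unname(cv$per_class_mean), rep(1, 3))
})

test_that("a constant classifier matches a hand-computed weighted F1", {
  y <- rep(c("A", "B"), each = 10)
  x <- matrix(rnorm(40), 20, 2)
  const_clf <- function(x_train, y_train) function(x_test) {
    rep("A", nrow(x_test))
  }
  cv <- repeated_cv(x, y, const_clf, n_repeats = 2, folds = 5, base_seed = 3)
  # all predictions are A regardless of folds: F1(A) = 2*10/(2*10+10),
  # F1(B) = 0; weighted by 10/10
  f1_a <- 2 * 10 / (2 * 10 + 10)
  expect_equal(cv$overall_f1_mean, (f1_a * 10 + 0 * 10) / 20)
  expect_equal(cv$overall_dispersion, 0)
})

test_that("repeated CV is deterministic in its base seed", {
  blobs <- blob_data(n_per = 10, f = 2, seed = 44)
  clf <- classifier_knn(k = 3)
  cv1 <- repeated_cv(blobs$x, blobs$labels, clf, n_repeats = 2, folds = 5,
                     base_seed = 9)
  cv2 <- repeated_cv(blobs$x, blobs$labels, clf, n_repeats = 2, folds = 5,
                     base_seed = 9)
  expect_identical(cv1$per_class_f1, cv2$per_class_f1)
  expect_identical(cv1$overall_f1_mean, cv2$overall_f1_mean)
  expect_equal(cv1$seeds, 9 + 1:2)

  # per-class means are row means of the per-repetition matrix
  expect_equal(cv1$per_class_mean, rowMeans(cv1$per_class_f1),
               tolerance = 1e-12)
  expect_true(all(cv1$per_class_f1 >= 0 & cv1$per_class_f1 <= 1))
})

test_that("classes smaller than the fold count are rejected", {
  y <- c(rep("A", 10), rep("B", 3))
  x <- matrix(rnorm(26), 13, 2)
  expect_error(repeated_cv(x, y, classifier_knn(1), n_repeats = 1,
                           folds = 5, base_seed = 1),
               class = "gtmap_stratification_error")
})

test_that("held-out rows never influence the fitted PCA", {
  blobs <- blob_data(n_per = 15, f = 3, seed = 45)
  seen_means <- list()
  spy_clf <- function(x_train, y_train) {
    seen_means[[length(seen_means) + 1]] <<- colMeans(x_train)
    pca <- fit_pca(x_train, n_pcs = 2)
    model <- knn_fit(pca$scores, y_train, k = 3)
    function(x_test) knn_predict(model, predict(pca, x_test))
  }
  repeated_cv(blobs$x, blobs$labels, spy_clf, n_repeats = 1, folds = 5,
              base_seed = 2)
  full_means <- colMeans(blobs$x)
  for (m in seen_means) expect_gt(max(abs(m - full_means)), 0)
})

test_that("grid search picks the best point and breaks ties first-wins", {
  blobs <- blob_data(n_per = 10, f = 2, seed = 46)
  gs <- grid_search(blobs$x, blobs$labels, classifier_knn,
                    grid = data.frame(k = c(1, 3)), n_repeats = 1,
                    folds = 5, base_seed = 7)
  expect_equal(nrow(gs$results), 2)
  expect_true(gs$best_params$k %in% c(1, 3))
  expect_equal(gs$best_result$overall_f1_mean, max(gs$results$overall_f1))

  one <- grid_search(blobs$x, blobs$labels, classifier_knn,
                     grid = data.frame(k = 4), n_repeats = 1, folds = 5,
                     base_seed = 7)
  expect_equal(one$best_params$k, 4)

  # identical scores tie to the earlier grid point
  const_factory <- function(dummy) function(x_train, y_train) {
    function(x_test) rep("A", nrow(x_test))
  }
  tie <- grid_search(blobs$x, blobs$labels, const_factory,
                     grid = data.frame(dummy = c(10, 20)), n_repeats = 1,
                     folds = 5, base_seed = 7)
  expect_equal(tie$best_params$dummy, 10)

  expect_error(grid_search(blobs$x, blobs$labels, classifier_knn,
                           grid = data.frame(k = numeric(0))),
               class = "gtmap_parameter_error")
})

test_that("a single-point PC sweep yields a single coherent row", {
  blobs <- blob_data(n_per = 12, f = 4, seed = 47)
  tab <- pc_sweep(blobs$x, blobs$labels, pc_list = 3,
                  gtm_args = list(k_side = 4, m_side = 2, max_iter = 30),
                  n_repeats = 1, folds = 3, base_seed = 5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_pcs, 3L)
  expect_true(tab$overall_f1 >= 0 && tab$overall_f1 <= 1)
  expect_true(tab$cumulative_variance > 0 && tab$cumulative_variance <= 1)

  expect_error(pc_sweep(blobs$x, blobs$labels, pc_list = 40),
               class = "gtmap_parameter_error")
})
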