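# PCA reduction: the first mapping stage (genotypes -> principal-component
# scores) on which the GTM manifold is fitted.

#' Fit a PCA reduction of a genotype matrix
#'
#' Centers (and by default unit-variance scales) each variant column and
#' computes the first `n_pcs` principal components by exact singular value
#' decomposition. Scaling follows the convention common in genotype PCA
#' (EIGENSTRAT-style standardisation); zero-variance columns get scale 1 and
#' contribute nothing. Component signs are fixed so that each loading's
#' entry of largest absolute value is positive, making maps reproducible
#' across runs and platforms.
#'
#' @param m Dense numeric matrix (individuals x variants), e.g. from
#'   [impute_missing()].
#' @param n_pcs Number of principal components F to retain;
#'   `2 <= n_pcs <= min(N-1, D)` is required downstream of a GTM fit.
#' @param scale Logical; scale columns to unit variance (default `TRUE`).
#' @return An object of class `pca_reduction` with fields `center`, `scale`,
#'   `rotation` (D x F orthonormal loadings), `explained_variance_ratio`,
#'   `scores` (N x F training scores) and `n_pcs`.
#' @export
fit_pca <- function(m, n_pcs, scale = TRUE) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- ncol(m)
  if (n < 2L) {
    stop_gtmap("PCA needs at least 2 individuals.", "gtmap_parameter_error")
  }
  check_number(n_pcs, "n_pcs", min = 1, integerish = TRUE)
  max_f <- min(n - 1L, d)
  if (n_pcs > max_f) {
    stop_gtmap(sprintf("`n_pcs` = %d exceeds min(N-1, D) = %d.", n_pcs, max_f),
               "gtmap_parameter_error")
  }
  center <- colMeans(m)
  xc <- sweep(m, 2L, center)
  col_var <- colSums(xc^2) / (n - 1L)
  if (sum(col_var) == 0) {
    stop_gtmap("All columns are constant: zero total variance.",
               "gtmap_parameter_error")
  }
  if (scale) {
    scl <- sqrt(col_var)
    scl[scl == 0] <- 1
  } else {
    scl <- rep(1, d)
  }
  xs <- sweep(xc, 2L, scl, "/")
  total_var <- sum(colSums(xs^2)) / (n - 1L)
  sv <- svd(xs, nu = 0, nv = n_pcs)
  rotation <- sv$v
  # sign convention: largest-magnitude loading entry positive
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rotation <- sweep(rotation, 2L, flip, "*")
  eigvals <- sv$d[seq_len(n_pcs)]^2 / (n - 1L)
  dimnames(rotation) <- list(colnames(m), paste0("PC", seq_len(n_pcs)))
  obj <- structure(
    list(center = center, scale = scl, rotation = rotation,
         explained_variance_ratio = eigvals / total_var,
         total_variance = total_var, n_pcs = as.integer(n_pcs),
         scaled = scale),
    class = "pca_reduction")
  obj$scores <- predict(obj, m)
  obj
}

#' Project new individuals into training PCA coordinates
#'
#' Applies the training column means and scales, then projects onto the
#' stored loadings, so held-out individuals are mapped in the coordinate
#' system of the training set.
#'
#' @param object A `pca_reduction`.
#' @param newdata Dense numeric matrix with the same D columns as the
#'   training matrix.
#' @param ... Unused.
#' @return N x F score matrix.
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    stop_gtmap(sprintf("`newdata` has %d columns; the reduction was fitted on %d.",
                       ncol(newdata), length(object$center)),
               "gtmap_shape_error")
  }
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  scores <- xs %*% object$rotation
  rownames(scores) <- rownames(newdata)
  scores
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("<pca_reduction> %d components over %d variants; %.1f%% variance retained\n",
              x$n_pcs, nrow(x$rotation), 100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Variance-explained report
#'
#' @param object A `pca_reduction`.
#' @return Tibble with `component`, `ratio` (fraction of total variance) and
#'   non-decreasing `cumulative`.
#' @export
variance_report <- function(object) {
  stopifnot(inherits(object, "pca_reduction"))
  tibble::tibble(
    component = seq_len(object$n_pcs),
    ratio = as.numeric(object$explained_variance_ratio),
    cumulative = cumsum(as.numeric(object$explained_variance_ratio)))
}

#' @export
tidy.pca_reduction <- function(x, ...) variance_report(x)

#' @export
glance.pca_reduction <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs,
                 variance_retained = sum(x$explained_variance_ratio),
                 total_variance = x$total_variance)
}
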