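# Generative topographic mapping: a 2D latent grid of nodes mapped through
# an RBF network into PC space, where each node image is the center of an
# isotropic Gaussian with common inverse variance beta. W and beta are
# optimised by EM; posterior node memberships ("responsibilities") drive
# both the visualisation and the Bayesian ancestry classifier.

#' Latent node grid
#'
#' A regular `k_side` x `k_side` grid of latent nodes spanning
#' \eqn{[-1,1]^2}, symmetric about the origin (a single node at the origin
#' when `k_side = 1`).
#'
#' @param k_side Nodes per side; the map has `K = k_side^2` nodes.
#' @return Object of class `gtm_grid` with `node_coords` (K x 2) and
#'   `k_side`.
#' @export
gtm_grid <- function(k_side) {
  check_number(k_side, "k_side", min = 1, integerish = TRUE)
  s <- if (k_side == 1L) 0 else seq(-1, 1, length.out = k_side)
  coords <- as.matrix(expand.grid(x = s, y = s, KEEP.OUT.ATTRS = FALSE))
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(node_coords = coords, k_side = as.integer(k_side)),
            class = "gtm_grid")
}

#' Gaussian radial basis over the latent grid
#'
#' Places `m_side^2` RBF centers on a regular sub-grid of \eqn{[-1,1]^2} and
#' evaluates each latent node against each center,
#' \eqn{\Phi_{km} = \exp(-\|x_k - c_m\|^2 / (2\sigma^2))}, appending a
#' constant bias column. The kernel width is
#' `sigma = width_factor * spacing`, where `spacing` is the center-to-center
#' distance along one axis (defined as 2, the full latent extent, when
#' `m_side = 1`).
#'
#' @param grid A [gtm_grid()].
#' @param m_side RBF centers per side (M = `m_side^2`).
#' @param width_factor Positive multiplier of the center spacing.
#' @return Object of class `gtm_rbf` with `centers`, `sigma` and the
#'   K x (M+1) design matrix `Phi`.
#' @export
gtm_rbf_basis <- function(grid, m_side, width_factor) {
  stopifnot(inherits(grid, "gtm_grid"))
  check_number(m_side, "m_side", min = 1, integerish = TRUE)
  if (!is.numeric(width_factor) || length(width_factor) != 1L ||
      !is.finite(width_factor) || width_factor <= 0) {
    stop_gtmap("`width_factor` must be a positive number.",
               "gtmap_parameter_error")
  }
  if (m_side == 1L) {
    centers <- matrix(0, 1L, 2L)
    spacing <- 2
  } else {
    s <- seq(-1, 1, length.out = m_side)
    centers <- as.matrix(expand.grid(x = s, y = s, KEEP.OUT.ATTRS = FALSE))
    spacing <- s[2L] - s[1L]
  }
  sigma <- width_factor * spacing
  phi <- exp(-sq_dists(grid$node_coords, centers) / (2 * sigma^2))
  phi <- cbind(phi, 1)
  structure(list(centers = centers, sigma = sigma, Phi = phi,
                 m_side = as.integer(m_side), width_factor = width_factor),
            class = "gtm_rbf")
}

node_images <- function(model) model$basis$Phi %*% model$W

#' Deterministic PCA-based GTM initialisation
#'
#' Initialises the weight matrix so that the node images tile the plane of
#' the first two principal axes of `x`, scaled to the data spread, and sets
#' the initial noise variance `1/beta` to the larger of the third eigenvalue
#' of `cov(x)` (when F > 2) and the squared half distance between adjacent
#' node images. No randomness is involved, so fits are seed-free.
#'
#' @param x N x F matrix of PC scores (F >= 2, rank >= 2).
#' @param grid A [gtm_grid()].
#' @param basis A [gtm_rbf_basis()].
#' @param lambda Nonnegative ridge weight on W carried into the M-step.
#' @return An unfitted `gtm_model`.
#' @export
gtm_initialize <- function(x, grid, basis, lambda = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x)
  f <- ncol(x)
  if (f < 2L) {
    stop_gtmap("GTM needs at least 2 data dimensions.", "gtmap_parameter_error")
  }
  if (n <= f) {
    stop_gtmap("GTM needs more individuals than data dimensions.",
               "gtmap_parameter_error")
  }
  check_number(lambda, "lambda", min = 0)
  eg <- eigen(cov(x), symmetric = TRUE)
  if (eg$values[2L] <= 1e-12 * max(eg$values[1L], 1e-300)) {
    stop_gtmap("Data matrix has rank < 2; cannot spread a 2D map.",
               "gtmap_initialization_error")
  }
  # node images = data mean + grid coords stretched along the two leading
  # principal axes of X
  a <- eg$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(eg$values[1:2]), 2L)
  y_target <- grid$node_coords %*% t(a)
  y_target <- sweep(y_target, 2L, colMeans(x), "+")
  phi <- basis$Phi
  w <- solve(crossprod(phi) + 1e-10 * diag(ncol(phi)), crossprod(phi, y_target))
  model <- structure(
    list(grid = grid, basis = basis, W = w, beta = 1, lambda = lambda,
         loglik_trace = numeric(0), n_pcs = f, converged = NA,
         responsibilities = NULL),
    class = "gtm_model")
  y <- node_images(model)
  binv <- (min_internode_dist(y) / 2)^2
  if (f > 2L) binv <- max(binv, eg$values[3L])
  if (binv <= 0) {
    stop_gtmap("Degenerate initial node images; cannot set beta.",
               "gtmap_initialization_error")
  }
  model$beta <- 1 / binv
  model
}

min_internode_dist <- function(y) {
  d2 <- sq_dists(y, y)
  diag(d2) <- Inf
  sqrt(min(d2))
}

#' E-step: responsibilities and data log-likelihood
#'
#' Computes the posterior probability that each latent node generated each
#' individual (Bayes' rule over the node-centered Gaussians with uniform
#' node prior 1/K) and the total data log-likelihood, both via a
#' numerically stable log-sum-exp.
#'
#' @param model A `gtm_model`.
#' @param x N x F data matrix in the model's PC coordinates.
#' @return List with `R` (K x N responsibility matrix; columns sum to 1)
#'   and `loglik`.
#' @export
gtm_e_step <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_pcs) {
    stop_gtmap(sprintf("`x` has %d columns; model expects %d.",
                       ncol(x), model$n_pcs),
               "gtmap_shape_error")
  }
  y <- node_images(model)
  k <- nrow(y)
  f <- ncol(y)
  logw <- -(model$beta / 2) * sq_dists(y, x)
  lse <- col_logsumexp(logw)
  r <- exp(sweep(logw, 2L, lse))
  colnames(r) <- rownames(x)
  loglik <- sum(lse) + nrow(x) * ((f / 2) * log(model$beta / (2 * pi)) - log(k))
  list(R = r, loglik = loglik)
}

#' M-step: update W and beta
#'
#' Solves the ridge-regularised weighted least-squares system
#' \eqn{(\Phi^T G \Phi + (\lambda/\beta) I) W = \Phi^T R X} with
#' `G = diag(rowSums(R))`, then re-estimates
#' \eqn{\beta = NF / \sum_{kn} R_{kn} \|y_k - x_n\|^2} using the new node
#' images. beta is capped at 1e12 to guard degenerate collapse.
#'
#' @param model A `gtm_model`.
#' @param r K x N column-normalised responsibility matrix.
#' @param x N x F data matrix.
#' @return The updated `gtm_model`.
#' @export
gtm_m_step <- function(model, r, x) {
  x <- as.matrix(x)
  phi <- model$basis$Phi
  g <- rowSums(r)
  a <- crossprod(phi, phi * g) +
    (model$lambda / model$beta) * diag(ncol(phi))
  b <- crossprod(phi, r %*% x)
  w <- tryCatch(solve(a, b), error = function(e) {
    stop_gtmap(paste0("Singular M-step system: ", conditionMessage(e),
                      ". Consider setting lambda > 0."),
               "gtmap_linear_algebra_error")
  })
  model$W <- w
  y <- node_images(model)
  dist_sum <- sum(r * sq_dists(y, x))
  beta <- nrow(x) * ncol(x) / dist_sum
  if (!is.finite(beta) || beta > 1e12) {
    warn("beta hit its cap (1e12): the Gaussian components are collapsing.")
    beta <- 1e12
  }
  model$beta <- beta
  model
}

#' Fit a GTM by expectation-maximisation
#'
#' Reduces the data with the supplied PC scores and alternates
#' [gtm_e_step()] / [gtm_m_step()] from the deterministic
#' [gtm_initialize()] state until the relative log-likelihood change drops
#' below `tol` or `max_iter` iterations. Defaults are the standard map
#' configuration for ancestry data: a 16 x 16 node grid, 4 x 4 RBFs, width
#' factor 0.3 and regularisation 0.1.
#'
#' @param x N x F matrix of PC scores.
#' @param k_side,m_side,width_factor,lambda Map hyperparameters (see
#'   [gtm_grid()] and [gtm_rbf_basis()]).
#' @param max_iter Maximum EM iterations; `max_iter = 0` returns the
#'   initialisation unchanged.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param verbose Print one line per iteration (iteration, loglik, beta).
#' @return A fitted `gtm_model` with `loglik_trace`, final
#'   `responsibilities` (K x N) and `converged` flag.
#' @export
gtm_fit <- function(x, k_side = 16, m_side = 4, width_factor = 0.3,
                    lambda = 0.1, max_iter = 200, tol = 1e-5,
                    verbose = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    stop_gtmap("`x` contains non-finite values.", "gtmap_data_error")
  }
  check_number(max_iter, "max_iter", min = 0, integerish = TRUE)
  grid <- gtm_grid(k_side)
  basis <- gtm_rbf_basis(grid, m_side, width_factor)
  model <- gtm_initialize(x, grid, basis, lambda)
  if (max_iter == 0) {
    model$converged <- FALSE
    return(model)
  }
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    es <- gtm_e_step(model, x)
    model$loglik_trace <- c(model$loglik_trace, es$loglik)
    if (verbose) {
      message(sprintf("iter %3d  loglik %.6f  beta %.6g", it, es$loglik,
                      model$beta))
    }
    if (it > 1L && abs(es$loglik - prev) < tol * abs(prev)) {
      model$converged <- TRUE
      model$responsibilities <- es$R
      return(model)
    }
    prev <- es$loglik
    model <- gtm_m_step(model, es$R, x)
  }
  es <- gtm_e_step(model, x)
  model$loglik_trace <- c(model$loglik_trace, es$loglik)
  model$responsibilities <- es$R
  model$converged <- FALSE
  model
}

#' Project new individuals onto a trained map
#'
#' One E-step with frozen `(W, beta)`; the model is not modified, so new
#' cohorts can be placed on a pre-constructed map.
#'
#' @param model A fitted `gtm_model`.
#' @param x_new Matrix with F columns, already in the training PCA
#'   coordinates (use [predict.pca_reduction()]).
#' @return K x N responsibility matrix.
#' @export
gtm_project <- function(model, x_new) {
  gtm_e_step(model, x_new)$R
}

#' Mean map positions
#'
#' The expected latent position of each individual,
#' \eqn{x(g_n) = \sum_k x_k R_{kn}}: a responsibility-weighted average of
#' the node coordinates, always inside the convex hull of the grid.
#'
#' @param r K x N responsibility matrix.
#' @param grid The [gtm_grid()] the responsibilities refer to.
#' @return Tibble with `sample` (column names of `r`, or indices), `x`, `y`.
#' @export
gtm_mean_positions <- function(r, grid) {
  stopifnot(inherits(grid, "gtm_grid"))
  if (nrow(r) != nrow(grid$node_coords)) {
    stop_gtmap("Responsibility rows do not match the grid size.",
               "gtmap_shape_error")
  }
  pos <- crossprod(r, grid$node_coords)
  tibble::tibble(
    sample = colnames(r) %||% as.character(seq_len(ncol(r))),
    x = unname(pos[, 1L]), y = unname(pos[, 2L]))
}

#' @export
print.gtm_model <- function(x, ...) {
  k <- nrow(x$grid$node_coords)
  cat(sprintf("<gtm_model> %d nodes, %d RBFs, F = %d, beta = %.4g, lambda = %g\n",
              k, nrow(x$basis$centers), x$n_pcs, x$beta, x$lambda))
  if (length(x$loglik_trace)) {
    cat(sprintf("  EM: %d iterations, final loglik %.4f (%s)\n",
                length(x$loglik_trace), max(x$loglik_trace),
                if (isTRUE(x$converged)) "converged" else "not converged"))
  }
  invisible(x)
}

#' @export
tidy.gtm_model <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loglik_trace),
                 loglik = x$loglik_trace)
}

#' @export
glance.gtm_model <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$grid$node_coords),
    n_rbf = nrow(x$basis$centers),
    n_pcs = x$n_pcs,
    beta = x$beta,
    lambda = x$lambda,
    n_iter = length(x$loglik_trace),
    loglik = if (length(x$loglik_trace)) x$loglik_trace[length(x$loglik_trace)] else NA_real_,
    converged = isTRUE(x$converged))
}

#' Save and reload a GTM model
#'
#' Serialises the model to a single JSON file. Doubles are stored as
#' `%.17g` strings so the IEEE values survive the round trip bit-for-bit
#' (plain JSON numbers would be truncated); the grid and basis are rebuilt
#' from their parameters on load, which is exact because their
#' construction is deterministic. A reloaded model therefore reproduces
#' projections of the original exactly.
#'
#' @param model A `gtm_model`.
#' @param path File path for the JSON model file.
#' @return `gtm_save()` returns `path` invisibly; `gtm_load()` the model.
#' @export
gtm_save <- function(model, path) {
  stopifnot(inherits(model, "gtm_model"))
  full <- function(v) sprintf("%.17g", v)
  payload <- list(
    format = "gtmap-model-v1",
    k_side = model$grid$k_side,
    m_side = model$basis$m_side,
    width_factor = full(model$basis$width_factor),
    n_pcs = model$n_pcs,
    n_basis = nrow(model$W),
    lambda = full(model$lambda),
    beta = full(model$beta),
    W = full(as.numeric(model$W)),
    loglik_trace = full(model$loglik_trace),
    converged = isTRUE(model$converged))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gtm_save
#' @export
gtm_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "gtmap-model-v1")) {
    stop_gtmap("Not a gtmap model file.", "gtmap_format_error")
  }
  grid <- gtm_grid(payload$k_side)
  basis <- gtm_rbf_basis(grid, payload$m_side,
                         as.numeric(payload$width_factor))
  structure(
    list(grid = grid, basis = basis,
         W = matrix(as.numeric(payload$W), nrow = payload$n_basis),
         beta = as.numeric(payload$beta),
         lambda = as.numeric(payload$lambda),
         loglik_trace = as.numeric(payload$loglik_trace),
         n_pcs = as.integer(payload$n_pcs),
         converged = payload$converged, responsibilities = NULL),
    class = "gtm_model")
}
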