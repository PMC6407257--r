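# Bayesian ancestry classification on GTM responsibilities. Each map node
# gets a per-class likelihood (the average responsibility it receives from
# members of that class) and, via Bayes' rule with empirical or uniform
# class priors, a posterior over ancestries. Individual profiles are
# responsibility-weighted averages of the node posteriors.

#' Fit the node-level ancestry model
#'
#' For each ancestry class `a`, the likelihood of node `k` is the class
#' average of the training responsibilities,
#' \eqn{P(x_k | a) = \sum_{n \in a} R_{kn} / N_a} (a distribution over
#' nodes), and the node posterior follows by Bayes' rule,
#' \eqn{P(a | x_k) \propto P(x_k | a) P(a)}. Nodes receiving no
#' responsibility mass from any class ("empty nodes") are flagged and given
#' the maximally uncertain uniform posterior `1/A`, so projected
#' individuals landing there still get a defined profile. No smoothing is
#' applied to the likelihoods; the empty-node rule is the only
#' regularisation.
#'
#' @param r_train K x N training responsibility matrix (columns sum to 1).
#' @param labels Length-N vector of class labels (character or factor; the
#'   class order is the factor level order, or sorted unique values).
#' @param prior_mode `"empirical"` (class frequencies `N_a / N`, the
#'   default) or `"uniform"`.
#' @param grid Optional [gtm_grid()] carried along for plotting/export.
#' @return Object of class `ancestry_model` with `classes`,
#'   `node_likelihood` (K x A), `node_posterior` (K x A), `priors` and
#'   `empty_nodes`.
#' @export
fit_ancestry_model <- function(r_train, labels,
                               prior_mode = c("empirical", "uniform"),
                               grid = NULL) {
  prior_mode <- match.arg(prior_mode)
  labels <- as.factor(labels)
  if (anyNA(labels)) {
    stop_gtmap("`labels` contains missing values.", "gtmap_label_error")
  }
  if (length(labels) != ncol(r_train)) {
    stop_gtmap("One label per responsibility column is required.",
               "gtmap_shape_error")
  }
  classes <- levels(labels)
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop_gtmap(sprintf("Class '%s' has no training members.",
                       classes[which(counts == 0L)[1L]]),
               "gtmap_class_error")
  }
  lik <- vapply(classes, function(a) {
    rowMeans(r_train[, labels == a, drop = FALSE])
  }, numeric(nrow(r_train)))
  priors <- switch(prior_mode,
    empirical = as.numeric(counts) / length(labels),
    uniform = rep(1 / length(classes), length(classes)))
  names(priors) <- classes
  unnorm <- sweep(lik, 2L, priors, "*")
  rs <- rowSums(unnorm)
  empty <- rs == 0
  post <- unnorm
  post[!empty, ] <- unnorm[!empty, , drop = FALSE] / rs[!empty]
  post[empty, ] <- 1 / length(classes)
  structure(
    list(classes = classes, node_likelihood = lik, node_posterior = post,
         priors = priors, empty_nodes = empty, prior_mode = prior_mode,
         grid = grid),
    class = "ancestry_model")
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat(sprintf("<ancestry_model> %d nodes x %d classes (%s priors), %d empty node(s)\n",
              nrow(x$node_posterior), length(x$classes), x$prior_mode,
              sum(x$empty_nodes)))
  invisible(x)
}

#' Ancestry profiles for individuals
#'
#' The ancestry profile of individual `i` is the responsibility-weighted
#' average of the node posteriors,
#' \eqn{P(a | g_i) = \sum_k P(a | x_k) R_{ki}}; rows sum to 1. The
#' predicted class is the argmax, with ties broken by class order (and
#' reported via a message).
#'
#' @param model An [fit_ancestry_model()] fit.
#' @param r_new K x N responsibility matrix for the individuals to
#'   classify, on the same map (same K).
#' @return Tibble with `sample`, one probability column per class, and
#'   `predicted`.
#' @export
classify_ancestry <- function(model, r_new) {
  stopifnot(inherits(model, "ancestry_model"))
  if (nrow(r_new) != nrow(model$node_posterior)) {
    stop_gtmap(sprintf("`r_new` has %d nodes; the model has %d.",
                       nrow(r_new), nrow(model$node_posterior)),
               "gtmap_shape_error")
  }
  probs <- crossprod(r_new, model$node_posterior)
  best <- max.col(probs, ties.method = "first")
  row_max <- probs[cbind(seq_len(nrow(probs)), best)]
  n_tied <- rowSums(probs == row_max)
  if (any(n_tied > 1L)) {
    inform(sprintf("%d individual(s) had tied top classes; ties broken by class order.",
                   sum(n_tied > 1L)))
  }
  out <- tibble::as_tibble(as.data.frame(probs))
  names(out) <- model$classes
  dplyr::bind_cols(
    tibble::tibble(sample = colnames(r_new) %||% as.character(seq_len(ncol(r_new)))),
    out,
    tibble::tibble(predicted = model$classes[best]))
}

#' Ancestry profile of a whole population
#'
#' Averages the responsibility columns of the member individuals into an
#' overall population responsibility
#' \eqn{R_{kp} = \sum_{i \in pop} R_{ki} / N_{pop}} — the population's
#' averaged distribution on the map — and pushes it through the node
#' posteriors to get \eqn{P(a | pop)}. These probabilities are a similarity
#' measure between the population and the classes used to build the map,
#' not an absolute admixture estimate.
#'
#' @param model An [fit_ancestry_model()] fit.
#' @param r_new K x N responsibility matrix.
#' @param members Indices (or column names) of the population's individuals.
#' @return Object of class `population_profile` with `pop_responsibility`
#'   (K-vector summing to 1) and `probabilities` (named A-vector summing
#'   to 1).
#' @export
population_profile <- function(model, r_new, members = seq_len(ncol(r_new))) {
  stopifnot(inherits(model, "ancestry_model"))
  sub <- r_new[, members, drop = FALSE]
  if (ncol(sub) == 0L) {
    stop_gtmap("Population member set is empty.", "gtmap_parameter_error")
  }
  rkp <- rowMeans(sub)
  probs <- drop(crossprod(model$node_posterior, rkp))
  names(probs) <- model$classes
  structure(list(pop_responsibility = rkp, probabilities = probs,
                 n_members = ncol(sub)),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf("<population_profile> %d member(s)\n", x$n_members))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' @export
tidy.population_profile <- function(x, ...) {
  tibble::tibble(class = names(x$probabilities),
                 probability = as.numeric(x$probabilities))
}

#' Most-probable-ancestry node map
#'
#' Labels every node with its most probable ancestry
#' \eqn{a_{max} = \arg\max_a P(a | x_k)} and that posterior probability —
#' the colouring used to draw classified maps. Empty nodes get the reserved
#' label `"empty"`.
#'
#' @param model An [fit_ancestry_model()] fit.
#' @return Tibble with `node`, grid coordinates `x`/`y` when the model
#'   carries a grid, `a_max`, `probability` and `empty`.
#' @export
node_color_map <- function(model) {
  stopifnot(inherits(model, "ancestry_model"))
  post <- model$node_posterior
  best <- max.col(post, ties.method = "first")
  out <- tibble::tibble(
    node = seq_len(nrow(post)),
    a_max = ifelse(model$empty_nodes, "empty", model$classes[best]),
    probability = post[cbind(seq_len(nrow(post)), best)],
    empty = model$empty_nodes)
  if (!is.null(model$grid)) {
    out <- dplyr::mutate(out,
                         x = model$grid$node_coords[, 1L],
                         y = model$grid$node_coords[, 2L],
                         .after = "node")
  }
  out
}

#' @export
tidy.ancestry_model <- function(x, ...) node_color_map(x)

#' @export
glance.ancestry_model <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$node_posterior),
                 n_classes = length(x$classes),
                 n_empty_nodes = sum(x$empty_nodes),
                 prior_mode = x$prior_mode)
}
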