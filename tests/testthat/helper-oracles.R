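# Independent oracles and small fixture builders used across the suite.
# Each oracle is coded from the defining formula, without reusing the
# package's computational path.

# Brute-force responsibilities: explicit Gaussian densities at every node
# image, explicit normalisation with uniform node prior, no log-sum-exp.
oracle_responsibilities <- function(y, x, beta) {
  k <- nrow(y)
  n <- nrow(x)
  f <- ncol(y)
  dens <- matrix(0, k, n)
  for (kk in seq_len(k)) {
    for (nn in seq_len(n)) {
      dens[kk, nn] <- (beta / (2 * pi))^(f / 2) *
        exp(-beta / 2 * sum((y[kk, ] - x[nn, ])^2))
    }
  }
  r <- sweep(dens, 2, colSums(dens), "/")
  loglik <- sum(log(colMeans(dens)))
  list(R = r, loglik = loglik)
}

# Confusion-matrix F1: counts come from a full cross-tabulation (a path
# independent of the package's logical-vector sums); the harmonic mean
# 2PR/(P+R) is evaluated in its integer-count form 2TP/(2TP+FP+FN) so
# agreement can be asserted exactly, not to a tolerance.
oracle_f1 <- function(y_true, y_pred, classes) {
  tab <- table(factor(y_true, classes), factor(y_pred, classes))
  vapply(classes, function(a) {
    tp <- tab[a, a]
    fp <- sum(tab[, a]) - tp
    fn <- sum(tab[a, ]) - tp
    if (tp + fp + fn == 0) return(0)  # no predicted and no true positives
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

# Hudson-style pairwise F_ST from two genotype blocks (allele counts 0/1/2),
# ratio-of-averages form.
oracle_hudson_fst <- function(geno1, geno2) {
  n1 <- nrow(geno1)
  n2 <- nrow(geno2)
  p1 <- colMeans(geno1) / 2
  p2 <- colMeans(geno2) / 2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  mean(num[keep]) / mean(den[keep])
}

# A small labelled genotype matrix built by hand.
toy_genotype <- function() {
  genotype_matrix(
    matrix(c(0L, 1L, 2L,
             1L, NA, 0L), nrow = 2, byrow = TRUE),
    sample_ids = c("S1", "S2"),
    variant_ids = c("v1_A", "v2_G", "v3_T"))
}

# Three well-separated Gaussian blobs in F dimensions (deterministic seed).
blob_data <- function(n_per = 50, f = 2, sep = 8, seed = 1) {
  centers <- diag(sep, 3, f)
  gtmap:::with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(i) {
      matrix(stats::rnorm(n_per * f), n_per, f) +
        matrix(centers[i, ], n_per, f, byrow = TRUE)
    }))
  })
  list(x = x, labels = rep(c("A", "B", "C"), each = n_per))
}

# The worked two-node classifier toy: class A holds individuals with
# responsibility columns (1, 0) and (0.5, 0.5); class B one with (0, 1).
toy_bayes_fixture <- function() {
  r_train <- matrix(c(1, 0,
                      0.5, 0.5,
                      0, 1), nrow = 2)
  list(r_train = r_train, labels = c("A", "A", "B"))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
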