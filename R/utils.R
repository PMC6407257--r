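# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. The generator kinds are pinned so seeded output is identical
# across platforms and R sessions.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Squared Euclidean distances between the rows of A (n x f) and B (m x f),
# via the expanded-norm identity; clipped at zero to absorb rounding.
sq_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) -
    2 * tcrossprod(a, b) +
    outer(rep(1, nrow(a)), rowSums(b^2))
  d2[d2 < 0] <- 0
  d2
}

# Column-wise log-sum-exp of a matrix of log-weights.
col_logsumexp <- function(logw) {
  m <- apply(logw, 2, max)
  m + log(colSums(exp(sweep(logw, 2, m))))
}

stop_gtmap <- function(message, class) {
  abort(message, class = c(class, "gtmap_error"))
}

check_number <- function(x, name, min = -Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_gtmap(sprintf("`%s` must be a single finite number.", name),
               "gtmap_parameter_error")
  }
  if (x < min) {
    stop_gtmap(sprintf("`%s` must be >= %s.", name, format(min)),
               "gtmap_parameter_error")
  }
  if (integerish && x != round(x)) {
    stop_gtmap(sprintf("`%s` must be a whole number.", name),
               "gtmap_parameter_error")
  }
  invisible(x)
}
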