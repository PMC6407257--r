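test_that("latent grids are square, symmetric and correctly sized", {
  g16 <- gtm_grid(16)
  expect_equal(nrow(g16$node_coords), 256L)
  expect_equal(colMeans(g16$node_coords), c(x = 0, y = 0))
  expect_equal(nrow(unique(as.data.frame(g16$node_coords))), 256L)

  g1 <- gtm_grid(1)
  expect_equal(unname(g1$node_coords), matrix(0, 1, 2))

  g2 <- gtm_grid(2)
  expect_setequal(apply(g2$node_coords, 1, paste, collapse = ","),
                  c("-1,-1", "1,-1", "-1,1", "1,1"))

  expect_error(gtm_grid(0), class = "gtmap_parameter_error")
})

test_that("RBF basis evaluates the Gaussian kernel exactly", {
  grid <- gtm_grid(16)
  basis <- gtm_rbf_basis(grid, m_side = 4, width_factor = 0.3)
  expect_equal(dim(basis$Phi), c(256L, 17L))
  expect_true(all(basis$Phi[, 17] == 1))
  expect_true(all(basis$Phi[, 1:16] > 0 & basis$Phi[, 1:16] <= 1))

  # a node coincident with a center scores exactly 1
  g2 <- gtm_grid(2)
  b2 <- gtm_rbf_basis(g2, m_side = 2, width_factor = 0.5)
  expect_equal(diag(b2$Phi[, 1:4][match(
    apply(b2$centers, 1, paste, collapse = ","),
    apply(g2$node_coords, 1, paste, collapse = ",")), ]),
    rep(1, 4))

  # a node at distance sigma from a center scores exp(-1/2)
  g1 <- gtm_grid(1)
  b1 <- gtm_rbf_basis(g1, m_side = 2, width_factor = 0.5)
  sigma <- b1$sigma
  d <- sqrt(sum((g1$node_coords[1, ] - b1$centers[1, ])^2))
  expect_equal(b1$Phi[1, 1], exp(-d^2 / (2 * sigma^2)), tolerance = 1e-12)

  expect_error(gtm_rbf_basis(grid, 4, width_factor = 0),
               class = "gtmap_parameter_error")
})

test_that("initialisation is deterministic and sets beta from the spectrum", {
  x <- blob_data(n_per = 40, f = 3, seed = 2)$x
  grid <- gtm_grid(8)
  basis <- gtm_rbf_basis(grid, 3, 0.3)
  m1 <- gtm_initialize(x, grid, basis)
  m2 <- gtm_initialize(x, grid, basis)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$beta, m2$beta)

  # isotropic standard Gaussian: 1/beta matches the third eigenvalue
  iso <- gtmap:::with_seed(9, matrix(rnorm(500 * 3), 500, 3))
  m_iso <- gtm_initialize(iso, grid, basis)
  ev3 <- eigen(cov(iso), symmetric = TRUE)$values[3]
  expect_equal(1 / m_iso$beta, ev3, tolerance = 1e-10)
  expect_equal(ev3, 1, tolerance = 0.2)  # sampling error at n = 500

  rank1 <- cbind(1:30, 2 * (1:30), 3 * (1:30))
  expect_error(gtm_initialize(rank1, grid, basis),
               class = "gtmap_initialization_error")
})

test_that("e-step matches the brute-force Bayes oracle", {
  # tiny instance: 5 individuals, 2x2 grid, single RBF (fixed weights: a
  # lone centred RBF cannot spread the four corner nodes, so W is set by
  # hand rather than by the PCA initialiser)
  x <- matrix(c(0.3, -1.2, 0.5, 2.0, -0.7,
                1.1, 0.4, -0.2, 0.8, -1.5), ncol = 2)
  grid <- gtm_grid(2)
  basis <- gtm_rbf_basis(grid, 1, 0.3)
  model <- structure(list(grid = grid, basis = basis,
                          W = matrix(c(0.8, -0.4, 0.3, 0.6), 2, 2),
                          beta = 1.7, lambda = 0.1,
                          loglik_trace = numeric(0), n_pcs = 2L),
                     class = "gtm_model")
  es <- gtm_e_step(model, x)
  oracle <- oracle_responsibilities(basis$Phi %*% model$W, x, model$beta)
  expect_equal(es$R, oracle$R, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(es$loglik, oracle$loglik, tolerance = 1e-10)

  # Eq-3 mean positions against a hand-weighted average
  pos <- gtm_mean_positions(es$R, grid)
  manual <- t(sapply(seq_len(ncol(es$R)), function(n) {
    colSums(grid$node_coords * es$R[, n])
  }))
  expect_equal(as.matrix(pos[, c("x", "y")]), manual,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("e-step degenerate cases normalise correctly", {
  # single node: responsibility is identically 1
  grid1 <- gtm_grid(1)
  basis1 <- gtm_rbf_basis(grid1, 1, 0.3)
  model1 <- structure(list(grid = grid1, basis = basis1,
                           W = matrix(0, 2, 2), beta = 1, lambda = 0.1,
                           loglik_trace = numeric(0), n_pcs = 2L),
                      class = "gtm_model")
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(unname(gtm_e_step(model1, x)$R), matrix(1, 1, 5))

  # identical node images: symmetric split
  grid2 <- structure(list(node_coords = rbind(c(-1, 0), c(1, 0)),
                          k_side = 2L), class = "gtm_grid")
  model2 <- structure(list(grid = grid2,
                           basis = list(Phi = matrix(c(1, 1), 2, 1)),
                           W = matrix(c(0.5, -0.3), 1, 2), beta = 2,
                           lambda = 0, loglik_trace = numeric(0),
                           n_pcs = 2L), class = "gtm_model")
  r2 <- gtm_e_step(model2, x)$R
  expect_equal(unname(r2), matrix(0.5, 2, 5))

  # hand-computed two-node case in one dimension embedded in 2D:
  # images at 0 and 2 on the first axis, beta = 1, point at the origin
  model3 <- model2
  model3$W <- matrix(c(1, 0), 1, 2)
  model3$beta <- 1
  model3$basis <- list(Phi = matrix(c(0, 2), 2, 1))
  r3 <- gtm_e_step(model3, matrix(0, 1, 2))$R
  expect_equal(r3[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)

  # a point far from every node image still yields a unit column
  far <- matrix(1e6, 1, 2)
  r_far <- gtm_e_step(model3, far)$R
  expect_equal(colSums(r_far), 1, ignore_attr = TRUE)
  expect_true(all(is.finite(r_far)))
})

test_that("EM log-likelihood is non-decreasing on seeded random data", {
  for (seed in 1:8) {
    x <- gtmap:::with_seed(seed, matrix(rnorm(60 * 3), 60, 3))
    fit <- gtm_fit(x, k_side = 6, m_side = 2, max_iter = 40)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8),
                info = sprintf("seed %d", seed))
  }
})

test_that("large lambda shrinks kernel weights monotonically", {
  x <- blob_data(n_per = 30, f = 2, seed = 5)$x
  grid <- gtm_grid(6)
  basis <- gtm_rbf_basis(grid, 2, 0.3)
  model <- gtm_initialize(x, grid, basis)
  r <- gtm_e_step(model, x)$R
  norms <- vapply(c(0.1, 1e3, 1e6), function(lambda) {
    m <- model
    m$lambda <- lambda
    up <- gtm_m_step(m, r, x)
    sqrt(sum(up$W[-nrow(up$W), ]^2))  # kernel rows only (bias last)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 1e-3 * norms[1])
})

test_that("beta collapse is capped with a warning", {
  # one data point equal to every node image
  grid1 <- gtm_grid(1)
  model <- structure(list(grid = grid1,
                          basis = list(Phi = matrix(1, 1, 1)),
                          W = matrix(0, 1, 2), beta = 1, lambda = 0,
                          loglik_trace = numeric(0), n_pcs = 2L),
                     class = "gtm_model")
  x0 <- matrix(0, 1, 2)
  r <- matrix(1, 1, 1)
  expect_warning(up <- gtm_m_step(model, r, x0), "cap")
  expect_equal(up$beta, 1e12)
})

test_that("fitting respects max_iter and reaches a fixed point", {
  x <- blob_data(n_per = 50, f = 2, seed = 6)$x
  init <- gtm_fit(x, k_side = 6, m_side = 2, max_iter = 0)
  ref <- gtm_initialize(x, gtm_grid(6), gtm_rbf_basis(gtm_grid(6), 2, 0.3))
  expect_identical(init$W, ref$W)
  expect_identical(init$beta, ref$beta)
  expect_length(init$loglik_trace, 0)

  fit <- gtm_fit(x, k_side = 6, m_side = 2)
  expect_gte(fit$loglik_trace[length(fit$loglik_trace)],
             fit$loglik_trace[1])
  # responsibilities at convergence equal a fresh e-step
  expect_equal(fit$responsibilities, gtm_e_step(fit, x)$R,
               tolerance = 1e-12)

  expect_error(gtm_fit(cbind(c(1, NA, 3), 1:3)), class = "gtmap_data_error")
})

test_that("projection is frozen, deterministic and consistent", {
  x <- blob_data(n_per = 40, f = 3, seed = 8)$x
  fit <- gtm_fit(x, k_side = 8, m_side = 3)
  expect_equal(gtm_project(fit, x), fit$responsibilities, tolerance = 1e-12)

  dup <- x[c(3, 3), ]
  r <- gtm_project(fit, dup)
  expect_identical(r[, 1], r[, 2])

  expect_error(gtm_project(fit, x[, 1:2]), class = "gtmap_shape_error")
})

test_that("responsibility columns always sum to one", {
  for (seed in 1:5) {
    x <- gtmap:::with_seed(seed, matrix(rnorm(30 * 2, sd = 3), 30, 2))
    fit <- gtm_fit(x, k_side = 5, m_side = 2, max_iter = 25)
    expect_equal(colSums(fit$responsibilities), rep(1, 30),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(fit$responsibilities >= 0))
  }
})

test_that("beta scales as c^-2 when the data are rescaled by c", {
  x <- blob_data(n_per = 40, f = 2, seed = 12)$x
  c_fac <- 3.7
  # pin the iteration count: the stopping rule is not scale-invariant
  # (the log-likelihood shifts by an additive constant under rescaling)
  f1 <- gtm_fit(x, k_side = 6, m_side = 2, lambda = 0.1,
                max_iter = 60, tol = 1e-14)
  f2 <- gtm_fit(x * c_fac, k_side = 6, m_side = 2,
                lambda = 0.1 / c_fac^2, max_iter = 60, tol = 1e-14)
  expect_equal(f2$beta, f1$beta / c_fac^2, tolerance = 1e-4)
})

test_that("mean positions obey delta, uniform and hand-weighted cases", {
  grid <- gtm_grid(3)
  k <- nrow(grid$node_coords)
  r_delta <- matrix(0, k, 1)
  r_delta[4, 1] <- 1
  pos <- gtm_mean_positions(r_delta, grid)
  expect_equal(c(pos$x, pos$y), unname(grid$node_coords[4, ]))

  r_unif <- matrix(1 / k, k, 2)
  pos_u <- gtm_mean_positions(r_unif, grid)
  expect_equal(unlist(pos_u[, c("x", "y")]), rep(0, 4), ignore_attr = TRUE)

  grid2 <- structure(list(node_coords = rbind(c(-1, -1), c(1, 1)),
                          k_side = 2L), class = "gtm_grid")
  pos2 <- gtm_mean_positions(matrix(c(0.25, 0.75), 2, 1), grid2)
  expect_equal(c(pos2$x, pos2$y), c(0.5, 0.5))

  # positions stay inside the grid's convex hull
  x <- blob_data(n_per = 30, f = 2, seed = 4)$x
  fit <- gtm_fit(x, k_side = 5, m_side = 2, max_iter = 20)
  pos3 <- gtm_mean_positions(fit$responsibilities, fit$grid)
  expect_true(all(abs(pos3$x) <= 1 + 1e-12 & abs(pos3$y) <= 1 + 1e-12))
})

test_that("a saved model reloads to identical projections", {
  x <- blob_data(n_per = 40, f = 3, seed = 10)$x
  fit <- gtm_fit(x, k_side = 6, m_side = 2)
  path <- tempfile(fileext = ".json")
  gtm_save(fit, path)
  back <- gtm_load(path)
  expect_equal(back$W, fit$W, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$beta, fit$beta, tolerance = 1e-15)
  expect_equal(gtm_project(back, x), gtm_project(fit, x),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$loglik_trace, fit$loglik_trace, tolerance = 1e-15)
})
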