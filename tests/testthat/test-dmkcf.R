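test_that("base kernels match hand-evaluated values", {
  expect_equal(base_kernel(kernel_spec("linear"), rbind(c(1, 2)), rbind(c(3, 4)))[1, 1], 11)
  expect_equal(base_kernel(kernel_spec("rbf", bandwidth = 1.3),
                           rbind(c(0.4, -2)), rbind(c(0.4, -2)))[1, 1], 1)
  expect_equal(base_kernel(kernel_spec("polynomial", degree = 2, coef0 = 0),
                           rbind(c(1, 0)), rbind(c(1, 0)))[1, 1], 1)
  expect_error(base_kernel(kernel_spec("linear"), rbind(c(1, 2)), rbind(c(1, 2, 3))),
               class = "skr_input_error")
})

test_that("composite kernel is the beta-weighted sum of base kernels", {
  A <- matrix(rnorm(12), 4, 3)
  specs <- list(kernel_spec("linear"), kernel_spec("rbf", bandwidth = 1))
  expect_equal(composite_kernel_matrix(composite_kernel(specs, c(1, 0)), A),
               base_kernel(specs[[1]], A))
  same <- composite_kernel(list(kernel_spec("linear"), kernel_spec("linear")),
                           c(0.5, 0.5))
  expect_equal(composite_kernel_matrix(same, A), base_kernel(kernel_spec("linear"), A))
  x <- rbind(c(1, 2))
  mixed <- composite_kernel(specs, c(0.5, 0.5))
  expect_equal(composite_kernel_matrix(mixed, x, x)[1, 1], 0.5 * 5 + 0.5 * 1)
  expect_error(composite_kernel(specs, c(0.7, 0.7)), class = "skr_config_error")
})

test_that("composite Gram matrices are positive semidefinite for random simplex weights", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    b <- runif(3); b <- b / sum(b)
    ck <- composite_kernel(list(kernel_spec("linear"),
                                kernel_spec("polynomial", degree = 3, coef0 = 1),
                                kernel_spec("rbf", bandwidth = runif(1, 0.5, 3))), b)
    G <- composite_kernel_matrix(ck, X)
    expect_gte(min(eigen((G + t(G)) / 2, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("partitioning covers all samples with balanced, stratified blocks", {
  y <- rep(c("a", "b"), each = 50)
  parts <- partition_nodes(y, dmkcf_config(P = 4, landmark_seed = 1))
  expect_equal(sort(unlist(parts)), 1:100)
  expect_equal(vapply(parts, length, integer(1)), rep(25L, 4))
  for (p in parts) {
    expect_lte(abs(sum(y[p] == "a") - 12.5), 1)  # class split within one sample
  }
  expect_equal(partition_nodes(y, dmkcf_config(P = 1)), list(1:100))
  y10 <- rep(c("a", "b"), 5)
  sizes <- sort(vapply(partition_nodes(y10, dmkcf_config(P = 3)), length, integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(4L, 3L, 3L))
  expect_error(partition_nodes(y10, dmkcf_config(P = 11)), class = "skr_config_error")
})

test_that("local kernel blocks live on the shared landmark basis", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  ds <- tiny_dataset(X, rep(c("a", "b"), 10))
  ck <- composite_kernel(list(kernel_spec("rbf", bandwidth = 1)))
  K <- local_kernel_matrix(ck, ds, 1:5, X[1:5, , drop = FALSE])
  expect_equal(dim(K), c(5L, 5L))
  expect_equal(diag(K), rep(1, 5))   # node == landmarks: unit self-similarity
  expect_true(all(K > 0 & K <= 1))
  full <- local_kernel_matrix(ck, ds, 1:20, X)
  expect_equal(full, t(full))        # P = 1 with all landmarks: symmetric Gram
  expect_error(local_kernel_matrix(ck, ds, integer(0), X), class = "skr_input_error")
})

test_that("the node update solves the proximal ridge-hinge subproblem", {
  set.seed(21)
  n <- 25; L <- 10
  K <- matrix(rnorm(n * L), n, L)
  yv <- rep(c(-1, 1), length.out = n)
  z <- rnorm(L + 1, sd = 0.1)
  # proximal dominance: huge rho pins alpha to the center
  a_pin <- local_admm_update(K, yv, z, list(C = 1, rho = 1e6))
  expect_equal(a_pin, z, tolerance = 1e-3)
  # no loss, no proximal pull: ridge minimum at zero
  expect_equal(local_admm_update(K, yv, z, list(C = 0, rho = 0)),
               numeric(L + 1))
  # first-order optimality: every directional derivative is nonnegative
  cfg <- list(C = 2, rho = 0.7)
  a <- local_admm_update(K, yv, z, cfg)
  Phi <- cbind(K, 1)
  for (d in 1:20) {
    dir <- rnorm(L + 1); dir <- dir / sqrt(sum(dir^2))
    margins <- 1 - yv * as.numeric(Phi %*% a)
    slopes <- -yv * as.numeric(Phi %*% dir)
    # margins active at the optimum are zero only up to solver tolerance
    hinge_dd <- sum(ifelse(margins > 1e-6, slopes,
                           ifelse(margins >= -1e-6, pmax(slopes, 0), 0)))
    quad_dd <- sum(a[-(L + 1)] * dir[-(L + 1)]) +
      2 * cfg$rho * sum((a - z) * dir)
    expect_gte(quad_dd + cfg$C * hinge_dd, -1e-5)
  }
})

test_that("consensus update averages node coefficients", {
  expect_equal(consensus_update(list(c(1), c(3))), c(2))
  expect_equal(consensus_update(list(c(1, 2))), c(1, 2))
  same <- list(c(1, 2), c(1, 2), c(1, 2))
  z <- consensus_update(same)
  expect_equal(z, c(1, 2))
  expect_equal(max(vapply(same, function(a) sqrt(sum((a - z)^2)), numeric(1))), 0)
  expect_error(consensus_update(list()), class = "skr_input_error")
})

test_that("kernel-weight update favors the label-aligned kernel and stays on the simplex", {
  expect_equal(update_kernel_weights(
    composite_kernel(list(kernel_spec("linear"))),
    matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5)), 1)
  two_same <- update_kernel_weights(
    composite_kernel(list(kernel_spec("linear"), kernel_spec("linear"))),
    matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  expect_equal(two_same, c(0.5, 0.5))
  set.seed(13)
  y <- rep(c("a", "b"), each = 20)
  X <- cbind(ifelse(y == "a", -2, 2) + rnorm(40, sd = 0.2), rnorm(40, sd = 3))
  aligned <- kernel_spec("rbf", bandwidth = 2)
  # noise kernel: rbf on the label-independent coordinate only is emulated by
  # a very wide bandwidth that flattens class structure
  noise <- kernel_spec("rbf", bandwidth = 1e4)
  beta <- update_kernel_weights(composite_kernel(list(aligned, noise)), X, y)
  expect_gt(beta[1], beta[2])
  expect_equal(sum(beta), 1, tolerance = 1e-9)
  expect_true(all(beta >= 0))
})

test_that("training on separable blobs converges with the residual below tolerance", {
  ds <- blob_dataset(n = 120, seed = 3)
  for (P in c(2L, 3L)) {
    m <- dmkcf_fit(ds, linear_rbf_kernel(), dmkcf_config(P = P, max_iter = 600))
    expect_true(m$converged)
    res <- max(vapply(m$per_node_alpha, function(a) sqrt(sum((a - m$z)^2)), numeric(1)))
    expect_lte(res, m$config$epsilon)
    last <- m$history[[m$n_iter]]
    expect_lt(last$dz, m$config$epsilon)
    expect_gte(mean(predict(m, ds) == ds$y), 0.95)
  }
})

test_that("a huge tolerance converges after one iteration", {
  ds <- blob_dataset(n = 60, seed = 3)
  m <- dmkcf_fit(ds, linear_kernel(), dmkcf_config(P = 2, epsilon = 1e3))
  expect_true(m$converged)
  expect_equal(m$n_iter, 1L)
})

test_that("P=1 with all landmarks matches the centralized QP solve", {
  ds <- blob_dataset(n = 120, seed = 3)
  m <- dmkcf_fit(ds, linear_kernel(),
                 dmkcf_config(P = 1, n_landmarks = 120, epsilon = 1e-6,
                              max_iter = 500))
  expect_true(m$converged)
  K <- composite_kernel_matrix(m$kernel, m$landmarks, m$landmarks)
  oracle <- centralized_oracle(K, m$train_yv, m$config$C)
  L <- nrow(K)
  o_admm <- hinge_ridge_objective(K, m$train_yv, m$config$C, m$z[1:L], m$z[L + 1])
  expect_lte(abs(o_admm - oracle$objective) / abs(oracle$objective), 1e-3)
  te <- blob_dataset(n = 200, seed = 77)
  pred_admm <- predict(m, te$X)
  sc_qp <- composite_kernel_matrix(m$kernel, te$X, m$landmarks) %*% oracle$aL + oracle$b
  pred_qp <- factor(ifelse(sc_qp >= 0, "pos", "neg"), levels = c("neg", "pos"))
  expect_gte(mean(pred_admm == pred_qp), 0.98)
})

test_that("accuracy is robust to the node count", {
  tr <- blob_dataset(n = 200, seed = 3)
  te <- blob_dataset(n = 200, seed = 31)
  acc <- vapply(c(1L, 4L), function(P) {
    m <- suppressWarnings(dmkcf_fit(tr, linear_rbf_kernel(),
                                    dmkcf_config(P = P, max_iter = 400)))
    mean(predict(m, te) == te$y)
  }, numeric(1))
  expect_lte(abs(acc[1] - acc[2]), 0.05)
})

test_that("prediction is invariant to training sample order", {
  ds <- blob_dataset(n = 80, seed = 8)
  perm <- sample(80)
  ds_perm <- skr_dataset(ds$X[perm, ], ds$y[perm], preprocessed = TRUE)
  cfg <- dmkcf_config(P = 2, max_iter = 400)
  m1 <- dmkcf_fit(ds, linear_rbf_kernel(), cfg)
  m2 <- dmkcf_fit(ds_perm, linear_rbf_kernel(), cfg)
  te <- blob_dataset(n = 50, seed = 99)
  expect_equal(decision_function(m1, te$X), decision_function(m2, te$X),
               tolerance = 1e-10)
})

test_that("decision function honors the null-model and antisymmetry contracts", {
  ds <- blob_dataset(n = 40, seed = 3)
  m <- dmkcf_fit(ds, linear_kernel(), dmkcf_config(P = 1, max_iter = 200))
  null_m <- m
  null_m$z <- numeric(length(m$z))
  Xnew <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_function(null_m, Xnew), rep(0, 5))
  expect_equal(as.character(predict(null_m, Xnew)), rep("pos", 5))  # zero maps positive
  neg_m <- m
  neg_m$z <- -m$z
  expect_equal(decision_function(neg_m, Xnew), -decision_function(m, Xnew))
  # class centroids sit on opposite sides of the decision surface
  cen_neg <- colMeans(ds$X[ds$y == "neg", ])
  cen_pos <- colMeans(ds$X[ds$y == "pos", ])
  s <- decision_function(m, rbind(cen_neg, cen_pos))
  expect_lt(s[1], 0)
  expect_gt(s[2], 0)
  expect_error(decision_function(m, matrix(0, 2, 5)), class = "skr_input_error")
})

test_that("model serialization round-trips predictions exactly", {
  ds <- blob_dataset(n = 60, seed = 3)
  m <- dmkcf_fit(ds, linear_rbf_kernel(), dmkcf_config(P = 2, max_iter = 400))
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  Xnew <- matrix(rnorm(20), 10, 2)
  expect_equal(decision_function(back, Xnew), decision_function(m, Xnew),
               tolerance = 1e-12)
  expect_equal(back$kernel$beta, m$kernel$beta)
})
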