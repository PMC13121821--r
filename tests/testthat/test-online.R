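test_that("schedules decay at the configured rates", {
  cfg <- estimator_config("tasna", c_nu = 1, n0 = 0)
  expect_equal(step_size(1, cfg), 1)
  cfg65 <- estimator_config("tasna", gamma = 0.65, c_nu = 1, n0 = 0)
  expect_equal(step_size(100, cfg65), 100^(-0.65), tolerance = 1e-10)
  expect_equal(step_size(100, cfg65), 0.050119, tolerance = 1e-5)
  # the delay constant damps early steps
  cfg_d <- estimator_config("tasna", n0 = 20)
  expect_lt(step_size(1, cfg_d), step_size(1, cfg65))
  expect_true(all(diff(step_size(1:50, cfg_d)) < 0))

  cfgl <- estimator_config("tasna", c_lambda = 0.2, alpha_lambda = 0.49)
  expect_equal(truncation_floor(1, cfgl), 0.2 * 2^(-0.49), tolerance = 1e-10)
  expect_equal(truncation_floor(1, cfgl), 0.14240, tolerance = 1e-4)
  lam <- truncation_floor(c(1, 10, 1e3, 1e6), cfgl)
  expect_true(all(lam <= 0.25))
  expect_true(all(diff(lam) < 0))
  expect_lt(truncation_floor(1e8, cfgl), 1e-3)
  expect_error(estimator_config("tasna", c_lambda = 0.3), "1/4")
  expect_error(estimator_config("tasna", gamma = 0.4), "gamma")
  expect_error(estimator_config("tasna", alpha_lambda = 0.6), "alpha_lambda")
})

test_that("averaging sequences realize TSNA, running means, and log weighting", {
  none <- estimator_config("tsna")
  expect_identical(averaging_weight(1, none), 1)
  expect_identical(averaging_weight(500, none), 1)
  unif <- estimator_config("tasna", avg_mode = "uniform")
  # uniform tau telescopes to the arithmetic mean of beta_0, beta_1, ..., beta_m
  xs <- rnorm(25)
  bbar <- 0  # beta_bar_0 = beta_0 = 0 here
  for (n in 1:25) {
    tau <- averaging_weight(n, unif)
    bbar <- (1 - tau) * bbar + tau * xs[n]
  }
  expect_equal(bbar, mean(c(0, xs)), tolerance = 1e-12)
  # log-weighted with exponent 0 is uniform
  lw0 <- estimator_config("tasna", avg_mode = "log-weighted", avg_w = 0)
  expect_equal(sapply(1:20, averaging_weight, config = lw0),
               sapply(1:20, averaging_weight, config = unif), tolerance = 1e-12)
  # log-weighted tau equals omega_n over the running omega sum
  lw2 <- estimator_config("tasna", avg_w = 2)
  expect_equal(averaging_weight(5, lw2),
               log1p(5)^2 / sum(log1p(1:5)^2), tolerance = 1e-12)
})

test_that("item gradient matches the hand-computed two-node instance", {
  t <- tiny_instance()
  beta <- t$params$items[[1]]
  post <- posterior_node_weights(t$y1, t$params, t$grid)
  g <- item_gradient(1, post, beta, t$grid)
  expect_equal(g, c(0, -0.3932239), tolerance = 1e-6)
  post0 <- posterior_node_weights(t$y0, t$params, t$grid)
  expect_equal(item_gradient(0, post0, beta, t$grid), c(0, 0.3932239), tolerance = 1e-6)
  # posterior mass on one node with zero residual gives a zero gradient
  g1 <- build_quadrature_grid(1, 1)
  b <- item_param(1, 0)
  expect_equal(item_gradient(0.5, 1, b, g1), c(0, 0), tolerance = 1e-12)
})

test_that("item curvature matches the hand-computed matrix and stays PSD", {
  t <- tiny_instance()
  beta <- t$params$items[[1]]
  post <- posterior_node_weights(t$y1, t$params, t$grid)
  Phi <- item_curvature(post, beta, t$grid, floor = 0)
  expect_equal(Phi, matrix(c(0.1966119, 0.0908577, 0.0908577, 0.1966119), 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  # an extreme item: the floor dominates everywhere
  bx <- item_param(1, 50)
  Phi_f <- item_curvature(post, bx, t$grid, floor = 0.01)
  X <- cbind(t$grid$nodes, 1)
  expect_equal(Phi_f, 0.01 * crossprod(X, X * post), tolerance = 1e-8,
               ignore_attr = TRUE)
  # symmetry and PSD on random instances
  set.seed(7)
  g <- build_quadrature_grid(7, 2)
  for (i in 1:20) {
    b <- item_param(rnorm(2), rnorm(1))
    p <- irtstream:::posterior_from_loglik(rnorm(g$M), g$weights)
    Ph <- item_curvature(p, b, g, floor = runif(1, 0, 0.25))
    expect_equal(Ph, t(Ph), tolerance = 1e-12)
    v <- rnorm(3)
    expect_gte(drop(v %*% Ph %*% v), -1e-12)
  }
})

test_that("one update from the identity Hessian reproduces the hand solve", {
  t <- tiny_instance()
  cfg <- estimator_config("tsna", c_nu = 1, n0 = 0, gamma = 1, s0 = "identity")
  st <- online_state(t$params, t$grid, cfg)
  post <- posterior_node_weights(t$y1, t$params, t$grid)
  st1 <- update_item(st$items[[1]], 1, t$grid, cfg,
                     post_for_gradient = post, post_for_hessian = post)
  expect_equal(c(st1$beta_current$loadings, st1$beta_current$intercept),
               c(1, 0.3932239), tolerance = 1e-6)
  # avg equals current when not averaging
  expect_equal(st1$beta_avg, st1$beta_current)
  # S accumulated the (floored) curvature on top of the identity
  lam <- truncation_floor(1, cfg)
  Phi <- item_curvature(post, t$params$items[[1]], t$grid, floor = lam)
  expect_equal(st1$S, diag(2) + Phi, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(st1$n, 1L)
})

test_that("accumulation preserves symmetry and only grows the spectrum", {
  t <- tiny_instance()
  cfg <- estimator_config("tasna", s0 = "identity")
  st <- online_state(t$params, t$grid, cfg)$items[[1]]
  post <- posterior_node_weights(t$y1, t$params, t$grid)
  Phi <- item_curvature(post, t$params$items[[1]], t$grid, floor = 0)
  st2 <- accumulate_hessian(st, Phi)
  expect_equal(st2$S, matrix(c(1.1966119, 0.0908577, 0.0908577, 1.1966119), 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(accumulate_hessian(st, 0 * Phi)$S, st$S)
  mineig <- function(S) min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(mineig(st2$S), mineig(st$S) - 1e-12)
})

test_that("a fully anchored item is only counted, never moved", {
  g <- build_quadrature_grid(5, 2)
  anchored <- item_param(c(1, 0), 0, free = rep(FALSE, 3))
  free_it <- item_param(c(1, 1), 0)
  params <- item_param_set(list(anchored, free_it))
  cfg <- estimator_config("tasna", Q = 2, K = 5)
  st <- online_state(params, g, cfg)
  out <- process_examinee(st, c(1, 0), g, cfg)
  a1 <- out$state$items[[1]]
  expect_equal(a1$beta_current$loadings, c(1, 0))
  expect_equal(a1$beta_current$intercept, 0)
  expect_equal(a1$n, 1L)
  # the free item moved
  expect_false(isTRUE(all.equal(out$state$items[[2]]$beta_current$intercept, 0)))
})

test_that("gradient of the per-examinee objective matches finite differences", {
  set.seed(31)
  g <- build_quadrature_grid(7, 1)
  h <- 1e-5
  for (rep in 1:25) {
    J <- sample(2:4, 1)
    items <- lapply(seq_len(J), function(j) item_param(runif(1, 0.5, 2), rnorm(1)))
    params <- item_param_set(items)
    y <- rbinom(J, 1, 0.5)
    j <- sample(J, 1)
    post <- posterior_node_weights(y, params, g)
    grad <- item_gradient(y[j], post, items[[j]], g)
    for (p in 1:2) {
      perturb <- function(delta) {
        it <- items[[j]]
        v <- c(it$loadings, it$intercept)
        v[p] <- v[p] + delta
        ps <- params
        ps$items[[j]] <- item_param(v[1], v[2])
        examinee_objective(y, ps, g)
      }
      fd <- (perturb(h) - perturb(-h)) / (2 * h)
      expect_equal(grad[p], fd, tolerance = 1e-6)
    }
  }
})

test_that("the expected gradient vanishes at the true parameters", {
  set.seed(55)
  sim <- quick_sim(4000, J = 8, seed = 55)
  g <- build_quadrature_grid(11, 1)
  j <- 3
  beta_j <- sim$params$items[[j]]
  grads <- vapply(seq_len(4000), function(i) {
    post <- posterior_node_weights(sim$responses[i, ], sim$params, g)
    item_gradient(sim$responses[i, j], post, beta_j, g)
  }, numeric(2))
  mc_se <- apply(grads, 1, sd) / sqrt(ncol(grads))
  expect_true(all(abs(rowMeans(grads)) < 4 * mc_se + 1e-3))
})

test_that("standard errors invert the accumulated Hessian with 1/sqrt(n) scaling", {
  t <- tiny_instance()
  cfg <- estimator_config("tasna", s0 = "identity")
  st <- online_state(t$params, t$grid, cfg)
  n <- 64
  st$items[[1]]$S <- n * diag(c(4, 4))
  st$items[[1]]$n <- n
  expect_equal(standard_errors(st)[, 1], c(1 / (2 * sqrt(n)), 1 / (2 * sqrt(n))),
               tolerance = 1e-12, ignore_attr = TRUE)
  st$items[[1]]$S <- diag(2)
  expect_equal(standard_errors(st)[, 1], c(1, 1), ignore_attr = TRUE)
})

test_that("smallest eigenvalue of S never falls below its initial level along a run", {
  sim <- quick_sim(150, J = 5, seed = 9)
  g <- build_quadrature_grid(5, 1)
  cfg <- estimator_config("tasna", K = 5)
  start <- default_start(5, 1)
  st <- online_state(start, g, cfg)
  mineig <- function(S) min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  base <- vapply(st$items, function(it) mineig(it$S), numeric(1))
  prev <- base
  monotone <- TRUE
  for (i in seq_len(150)) {
    st <- process_examinee(st, sim$responses[i, ], g, cfg)$state
    cur <- vapply(st$items, function(it) mineig(it$S), numeric(1))
    monotone <- monotone && all(cur >= prev - 1e-10)
    prev <- cur
  }
  expect_true(monotone)
  expect_true(all(prev >= base))
})
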