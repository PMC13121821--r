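test_that("response probability is the logistic of the linear predictor", {
  expect_equal(response_probability(item_param(1, 0), 0), 0.5)
  expect_equal(response_probability(item_param(2, -1), 1), 0.7310586, tolerance = 1e-7)
  expect_equal(response_probability(item_param(c(1, 1), 0), c(0, 0)), 0.5)
  expect_error(response_probability(item_param(c(1, 1), 0), 0), "Q = 2")
  # clipping keeps extreme probabilities inside (0, 1)
  p <- response_probability(item_param(1, 100), 0)
  expect_lt(p, 1)
  expect_gt(response_probability(item_param(1, -100), 0), 0)
})

test_that("conditional node log-likelihoods sum item terms at each node", {
  t <- tiny_instance()
  ll <- conditional_node_likelihoods(t$y1, t$params, t$grid)
  # entry k is log plogis(node_k) for a correct response to an (a=1, d=0) item
  expect_equal(ll, log(plogis(t$grid$nodes[, 1])), tolerance = 1e-12)
  kpos <- which(t$grid$nodes[, 1] > 0)
  expect_equal(ll[kpos], log(0.7310586), tolerance = 1e-6)

  # flat items: every node carries J log(1/2)
  flat <- item_param_set(lapply(1:4, function(j) item_param(0, 0)))
  g <- build_quadrature_grid(5, 1)
  expect_equal(conditional_node_likelihoods(c(1, 0, 1, 1), flat, g),
               rep(4 * log(0.5), 5))

  # duplicating an item doubles its log contribution
  one <- item_param_set(list(item_param(1.3, 0.4)))
  two <- item_param_set(list(item_param(1.3, 0.4), item_param(1.3, 0.4)))
  expect_equal(conditional_node_likelihoods(c(1, 1), two, g),
               2 * conditional_node_likelihoods(1, one, g))
})

test_that("marginal likelihood is the prior-weighted node sum", {
  t <- tiny_instance()
  expect_equal(marginal_likelihood(t$y1, t$params, t$grid), 0.5, tolerance = 1e-9)
  flat <- item_param_set(lapply(1:6, function(j) item_param(0, 0)))
  g <- build_quadrature_grid(7, 1)
  expect_equal(marginal_likelihood(rep(1, 6), flat, g), 0.5^6, tolerance = 1e-12)
  # single-node grid degenerates to the conditional likelihood at 0
  g1 <- build_quadrature_grid(1, 1)
  p <- item_param_set(list(item_param(0.8, 0.3)))
  expect_equal(marginal_likelihood(1, p, g1), plogis(0.3), tolerance = 1e-12)
  expect_equal(examinee_objective(t$y1, t$params, t$grid), log(2), tolerance = 1e-9)
})

test_that("posterior node weights normalize the prior-times-likelihood", {
  t <- tiny_instance()
  post <- posterior_node_weights(t$y1, t$params, t$grid)
  kpos <- which(t$grid$nodes[, 1] > 0)
  expect_equal(post[kpos], 0.7310586, tolerance = 1e-6)
  expect_equal(sum(post), 1, tolerance = 1e-10)
  # mirrored response mirrors the posterior
  post0 <- posterior_node_weights(t$y0, t$params, t$grid)
  expect_equal(post0[kpos], 0.2689414, tolerance = 1e-6)
  # flat items leave the prior untouched
  flat <- item_param_set(lapply(1:3, function(j) item_param(0, 0)))
  g <- build_quadrature_grid(9, 1)
  expect_equal(posterior_node_weights(c(1, 0, 1), flat, g), g$weights)
})

test_that("posterior is invariant to shifting all log-likelihoods by a constant", {
  g <- build_quadrature_grid(7, 1)
  ll <- rnorm(7)
  p1 <- irtstream:::posterior_from_loglik(ll, g$weights)
  p2 <- irtstream:::posterior_from_loglik(ll + 700, g$weights)
  p3 <- irtstream:::posterior_from_loglik(ll - 700, g$weights)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("masking an item reproduces the marginal over the remaining items", {
  set.seed(4)
  items <- lapply(1:5, function(j) item_param(runif(1, 0.5, 2), rnorm(1)))
  full <- item_param_set(items)
  g <- build_quadrature_grid(11, 1)
  y <- c(1, 0, 1, 1, 0)
  masked <- response_vector(replace(y, 3, NA), masked = TRUE)
  rest <- item_param_set(items[-3])
  expect_equal(marginal_likelihood(masked, full, g),
               marginal_likelihood(y[-3], rest, g), tolerance = 1e-12)
})

test_that("strict mode rejects missing and non-binary responses", {
  expect_error(response_vector(c(1, NA, 0)), "masked")
  expect_error(response_vector(c(1, 2, 0)), "non-binary")
  expect_silent(response_vector(c(1, NA, 0), masked = TRUE))
})

test_that("EAP grid error decays geometrically toward the fine-grid oracle", {
  sim <- quick_sim(30, J = 20, seed = 5)
  g201 <- build_quadrature_grid(201, 1)
  err_at <- function(K) {
    g <- build_quadrature_grid(K, 1)
    max(vapply(1:30, function(i) {
      abs(eap_ability(sim$responses[i, ], sim$params, g) -
          eap_ability(sim$responses[i, ], sim$params, g201))
    }, numeric(1)))
  }
  errs <- vapply(c(21, 31, 41), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  # measured against adaptive integration: ~5e-3 at K = 21, <1e-4 by K = 41
  expect_lt(errs[1], 0.01)
  expect_lt(errs[3], 1e-4)
})

test_that("EAP scores are posterior means inside the node hull", {
  t <- tiny_instance()
  expect_equal(eap_ability(t$y1, t$params, t$grid), 0.4621172, tolerance = 1e-6)
  flat <- item_param_set(lapply(1:8, function(j) item_param(0, 0)))
  g <- build_quadrature_grid(11, 1)
  expect_equal(eap_ability(rep(1, 8), flat, g), 0, tolerance = 1e-12)
  sim <- quick_sim(1, J = 20, seed = 11)
  e <- eap_ability(sim$responses[1, ], sim$params, g)
  expect_true(e >= min(g$nodes) && e <= max(g$nodes))
})
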