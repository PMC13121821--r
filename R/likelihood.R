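PROB_EPS <- 1e-12

#' Correct-response probability of a 2PL/M2PL item
#'
#' Evaluates `plogis(a . theta + d)`, clipped to `[1e-12, 1 - 1e-12]` so
#' log terms stay finite.
#'
#' @param beta An [item_param()].
#' @param point Length-`Q` ability vector (or `M x Q` matrix of points).
#' @return Probability (vector of length `nrow(point)` for a matrix input).
#' @examples
#' response_probability(item_param(2, -1), 1)  # plogis(1)
#' @export
response_probability <- function(beta, point) {
  stopifnot(inherits(beta, "item_param"))
  Q <- length(beta$loadings)
  if (is.matrix(point)) {
    if (ncol(point) != Q) stop(sprintf("ability has %d columns; item has Q = %d", ncol(point), Q))
    eta <- drop(point %*% beta$loadings) + beta$intercept
  } else {
    if (length(point) != Q) stop(sprintf("ability has length %d; item has Q = %d", length(point), Q))
    eta <- sum(beta$loadings * point) + beta$intercept
  }
  clip_prob(plogis(eta))
}

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# M x J matrix of item response probabilities at every grid node, from a
# (Q+1) x J parameter matrix. Shared by the R estimator paths and the EM
# baseline.
node_probabilities <- function(B, grid) {
  eta <- augmented_nodes(grid) %*% B
  matrix(clip_prob(plogis(eta)), nrow = grid$M)
}

#' Per-node conditional log-likelihood of a response pattern
#'
#' Entry `k` is `sum_j y_j log P_jk + (1 - y_j) log(1 - P_jk)` evaluated at
#' grid node `k`; unobserved (masked) items are skipped.
#'
#' @param y A [response_vector()] (or plain 0/1 vector).
#' @param params An [item_param_set()].
#' @param grid A [build_quadrature_grid()] grid.
#' @return Length-`M` vector of log conditional likelihoods.
#' @export
conditional_node_likelihoods <- function(y, params, grid) {
  if (!inherits(y, "response_vector")) y <- response_vector(y)
  stopifnot(inherits(params, "item_param_set"), inherits(grid, "quadrature_grid"))
  if (length(y$values) != params$J) {
    stop(sprintf("response has %d entries; parameter set has J = %d", length(y$values), params$J))
  }
  P <- node_probabilities(param_matrix(params), grid)
  obs <- y$observed
  yv <- y$values[obs]
  P <- P[, obs, drop = FALSE]
  drop(log(P) %*% yv + log1p(-P) %*% (1 - yv))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Quadrature-approximated marginal likelihood of one examinee
#'
#' `sum_k w_k exp(loglik_k)` computed through log-sum-exp.
#'
#' @inheritParams conditional_node_likelihoods
#' @param log Return the log marginal likelihood?
#' @return Scalar in `(0, 1]` (or its log).
#' @export
marginal_likelihood <- function(y, params, grid, log = FALSE) {
  ll <- conditional_node_likelihoods(y, params, grid)
  lml <- logsumexp(log(grid$weights) + ll)
  if (log) lml else exp(lml)
}

#' Discrete posterior of an examinee's ability over the grid nodes
#'
#' Normalized prior-weight times conditional-likelihood values: the
#' examinee's posterior ability distribution restricted to the quadrature
#' nodes. Computed in log space.
#'
#' @inheritParams conditional_node_likelihoods
#' @return Length-`M` probability vector.
#' @export
posterior_node_weights <- function(y, params, grid) {
  ll <- conditional_node_likelihoods(y, params, grid)
  posterior_from_loglik(ll, grid$weights)
}

posterior_from_loglik <- function(ll, weights) {
  lp <- log(weights) + ll
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Per-examinee negative log-likelihood objective
#'
#' The online estimator's per-sample objective: minus the log marginal
#' likelihood of one response pattern.
#'
#' @inheritParams conditional_node_likelihoods
#' @return Nonnegative scalar.
#' @export
examinee_objective <- function(y, params, grid) {
  -marginal_likelihood(y, params, grid, log = TRUE)
}

#' Expected a posteriori (EAP) ability estimate
#'
#' Posterior mean of the latent ability over the quadrature grid, given
#' item parameters treated as known.
#'
#' @inheritParams conditional_node_likelihoods
#' @return Length-`Q` ability vector.
#' @export
eap_ability <- function(y, params, grid) {
  post <- posterior_node_weights(y, params, grid)
  drop(crossprod(grid$nodes, post))
}
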