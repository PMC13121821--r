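#' Step-size sequence of the stochastic Newton recursion
#'
#' `nu_n = c_nu (n + n0)^(-gamma)`. The delay constant `n0` damps the first
#' updates, when the accumulated Hessian is still dominated by its initial
#' value and the iterates are poor.
#'
#' @param n Examinee index (>= 1).
#' @param config An [estimator_config()].
#' @return Scalar step size, strictly decreasing in `n`.
#' @export
step_size <- function(n, config) {
  stopifnot(all(n >= 1))
  config$c_nu * (n + config$n0)^(-config$gamma)
}

#' Decaying truncation floor for the per-sample curvature
#'
#' `lambda_n = c_lambda (n + 1)^(-alpha_lambda)`. Flooring the Bernoulli
#' curvature `P(1 - P)` at `lambda_n` keeps every per-sample curvature
#' matrix positive definite, so the accumulated Hessian stays invertible
#' along the whole run; because `P(1 - P) = 1 / (2 + 2 cosh(eta)) <= 1/4`
#' and `c_lambda <= 1/4`, the floor never exceeds the largest curvature the
#' model can produce.
#'
#' @inheritParams step_size
#' @return Scalar floor in `(0, 1/4]`, decaying to 0.
#' @export
truncation_floor <- function(n, config) {
  stopifnot(all(n >= 1))
  config$c_lambda * (n + 1)^(-config$alpha_lambda)
}

#' Averaging sequence of the TASNA iterate average
#'
#' The averaged iterate is updated as
#' `beta_bar_n = (1 - tau_n) beta_bar_{n-1} + tau_n beta_n`.
#' With `avg_mode = "none"` (TSNA) `tau_n = 1`, so the average equals the
#' current iterate; `"uniform"` gives `tau_n = 1/(n + 1)`, the running
#' arithmetic mean of `beta_0 ... beta_n`; `"log-weighted"` gives
#' `tau_n = omega_n / sum_{i <= n} omega_i` with
#' `omega_i = log(1 + i)^avg_w`, which up-weights later (better) iterates.
#'
#' @inheritParams step_size
#' @param cum_omega Optional precomputed `sum_{i <= n} omega_i` (the
#'   streaming engines keep a running sum; without it the sum is formed
#'   directly).
#' @return Scalar weight in `(0, 1]`.
#' @export
averaging_weight <- function(n, config, cum_omega = NULL) {
  stopifnot(n >= 1)
  switch(config$avg_mode,
    "none" = 1,
    "uniform" = 1 / (n + 1),
    "log-weighted" = {
      # the sum starts at i = 0 (the initial iterate's weight 0^w), so
      # with exponent 0 the sequence reduces exactly to the uniform mean
      om <- function(i) log1p(i)^config$avg_w
      if (is.null(cum_omega)) cum_omega <- sum(om(0:n))
      om(n) / cum_omega
    }
  )
}

#' Per-sample gradient of the examinee objective for one item
#'
#' Gradient of the per-examinee negative log marginal likelihood with
#' respect to the item's free parameters, with the posterior node weights
#' held at their defining parameter values:
#' `g = -sum_k post_k (y_j - P_jk) xtilde_k`, where `xtilde_k = (node_k, 1)`
#' is the augmented ability point.
#'
#' @param y_j Binary response to item `j` (`NA` for a masked item gives a
#'   zero gradient).
#' @param post Length-`M` posterior node-weight vector.
#' @param beta_j The item's [item_param()] (at which `P_jk` is evaluated).
#' @param grid Quadrature grid.
#' @return Gradient vector over the item's free entries.
#' @export
item_gradient <- function(y_j, post, beta_j, grid) {
  X <- augmented_nodes(grid)
  if (is.na(y_j)) return(numeric(sum(beta_j$free)))
  P <- response_probability(beta_j, grid$nodes)
  g <- -drop(crossprod(X, post * (y_j - P)))
  g[beta_j$free]
}

#' Truncated per-sample curvature for one item
#'
#' The Bock-Aitkin cross-information of one response, with the Bernoulli
#' curvature floored:
#' `Phi = sum_k post_k max(P_jk (1 - P_jk), floor) xtilde_k xtilde_k'`,
#' restricted to the item's free entries. Positive semidefinite always;
#' positive definite when `floor > 0` and the grid spans `Q + 1` affinely
#' independent points.
#'
#' @inheritParams item_gradient
#' @param floor Truncation floor `lambda_n` in `[0, 1/4]`.
#' @return Symmetric PSD matrix over free entries.
#' @export
item_curvature <- function(post, beta_j, grid, floor = 0) {
  stopifnot(floor >= 0, floor <= 0.25)
  X <- augmented_nodes(grid)[, beta_j$free, drop = FALSE]
  P <- response_probability(beta_j, grid$nodes)
  w <- post * pmax(P * (1 - P), floor)
  crossprod(X, X * w)
}

#' Accumulate a per-sample curvature into an item's Hessian state
#'
#' `S <- S + Phi`. The normalized Hessian estimate used by the Newton step
#' is `Hbar = S / (n + 1)`, the initial matrix `S0` counting as one
#' pseudo-observation.
#'
#' @param state_j An `online_item_state` (see [online_state()]).
#' @param Phi PSD curvature matrix over free entries.
#' @return The updated state.
#' @export
accumulate_hessian <- function(state_j, Phi) {
  stopifnot(identical(dim(state_j$S), dim(as.matrix(Phi))))
  state_j$S <- state_j$S + Phi
  state_j
}

# Expected per-examinee information at the initial parameters, integrated
# over the prior grid; the default initial value S0 of the accumulated
# Hessian (plus a small ridge guaranteeing positive definiteness).
initial_hessian <- function(beta_j, grid, s0 = c("expected_information", "identity"),
                            ridge = 1e-3) {
  s0 <- match.arg(s0)
  nf <- sum(beta_j$free)
  if (nf == 0L) return(matrix(0, 0L, 0L))
  if (s0 == "identity") return(diag(nf))
  item_curvature(grid$weights, beta_j, grid, floor = 0) + ridge * diag(nf)
}

#' Initialize the online estimation state
#'
#' Builds per-item states holding the current iterate, the averaged
#' iterate, the accumulated Hessian `S` (initialized at `S0`), and the
#' examinee counter.
#'
#' @param init_params [item_param_set()] of starting values (see
#'   [default_start()]).
#' @param grid Quadrature grid.
#' @param config An [estimator_config()].
#' @return An object of class `online_state`.
#' @export
online_state <- function(init_params, grid, config) {
  stopifnot(inherits(init_params, "item_param_set"))
  item_states <- lapply(init_params$items, function(it) {
    structure(
      list(beta_current = it, beta_avg = it,
           S = initial_hessian(it, grid, config$s0), n = 0L),
      class = "online_item_state"
    )
  })
  structure(
    list(items = item_states, item_ids = init_params$item_ids,
         J = init_params$J, Q = init_params$Q,
         n = 0L, cum_omega = log1p(0)^config$avg_w, config = config),
    class = "online_state"
  )
}

#' Default starting values: discriminations 1, intercepts 0
#'
#' @param J Item count.
#' @param Q Dimension count.
#' @param free Optional `(Q+1) x J` logical matrix of free masks (defaults
#'   to all free); columns with any `FALSE` keep those entries anchored at
#'   the values in `anchor_values`.
#' @param anchor_values Optional `(Q+1) x J` matrix supplying values for
#'   anchored entries.
#' @param item_ids Optional labels.
#' @return An [item_param_set()].
#' @export
default_start <- function(J, Q = 1L, free = NULL, anchor_values = NULL,
                          item_ids = NULL) {
  B <- rbind(matrix(1, Q, J), rep(0, J))
  if (!is.null(free)) {
    stopifnot(dim(free) == dim(B))
    if (!is.null(anchor_values)) B[!free] <- anchor_values[!free]
  } else {
    free <- matrix(TRUE, Q + 1L, J)
  }
  items <- lapply(seq_len(J), function(j) {
    item_param(B[seq_len(Q), j], B[Q + 1L, j], free = free[, j])
  })
  item_param_set(items, item_ids = item_ids)
}

# assemble item_param_set views of an online_state
state_params <- function(state, which = c("avg", "current")) {
  which <- match.arg(which)
  field <- if (which == "avg") "beta_avg" else "beta_current"
  item_param_set(lapply(state$items, `[[`, field), item_ids = state$item_ids)
}

#' One stochastic Newton update of a single item
#'
#' Applies, in order: (i) the per-sample gradient at the current iterate
#' (or averaged iterate, per `config$gradient_at`); (ii) the truncated
#' per-sample curvature at the averaged iterate; (iii) the Newton step
#' `beta <- beta - nu_n Hbar^{-1} g` with `Hbar = S/n`, the scaled
#' accumulated Hessian from before this examinee; (iv) `S <- S + Phi`;
#' (v) the averaging step. Anchored entries never move; a fully anchored
#' item only has its counter advanced.
#'
#' @param state_j An `online_item_state`.
#' @param y_j Binary response to this item.
#' @param grid Quadrature grid.
#' @param config [estimator_config()].
#' @param post_for_gradient Posterior node weights evaluated at the
#'   parameter set matching `config$gradient_at`.
#' @param post_for_hessian Posterior node weights evaluated at the averaged
#'   parameter set.
#' @param tau Averaging weight `tau_n`; computed from
#'   [averaging_weight()] when omitted.
#' @return The updated `online_item_state`.
#' @export
update_item <- function(state_j, y_j, grid, config,
                        post_for_gradient, post_for_hessian, tau = NULL) {
  n <- state_j$n + 1L
  free <- state_j$beta_current$free
  if (!any(free) || is.na(y_j)) {
    # fully anchored item, or a masked response carrying no information
    state_j$n <- n
    return(state_j)
  }
  beta_g <- if (config$gradient_at == "current") state_j$beta_current else state_j$beta_avg
  g <- item_gradient(y_j, post_for_gradient, beta_g, grid)
  Phi <- item_curvature(post_for_hessian, state_j$beta_avg, grid,
                        floor = truncation_floor(n, config))
  Hbar <- state_j$S / n
  delta <- tryCatch(solve(Hbar, g), error = function(e) {
    stop(sprintf("singular scaled Hessian for item at n = %d (min eigenvalue %.3e): %s",
                 n, min(eigen(Hbar, symmetric = TRUE, only.values = TRUE)$values),
                 conditionMessage(e)))
  })
  bc <- c(state_j$beta_current$loadings, state_j$beta_current$intercept)
  bc[free] <- bc[free] - step_size(n, config) * delta
  Q <- length(state_j$beta_current$loadings)
  state_j$beta_current <- item_param(bc[seq_len(Q)], bc[Q + 1L],
                                     free = free, id = state_j$beta_current$id)
  state_j <- accumulate_hessian(state_j, Phi)
  if (is.null(tau)) tau <- averaging_weight(n, config)
  ba <- c(state_j$beta_avg$loadings, state_j$beta_avg$intercept)
  ba[free] <- (1 - tau) * ba[free] + tau * bc[free]
  state_j$beta_avg <- item_param(ba[seq_len(Q)], ba[Q + 1L],
                                 free = free, id = state_j$beta_avg$id)
  state_j$n <- n
  state_j
}

#' Process one arriving examinee: update all items, then score the examinee
#'
#' Computes the posterior node weights twice (at the current iterates for
#' the gradient and at the averaged iterates for the curvature), applies
#' [update_item()] to every item, then scores the examinee by EAP under the
#' just-updated averaged item parameters.
#'
#' @param state An [online_state()].
#' @param y A [response_vector()] (or plain 0/1 vector) of length `J`.
#' @param grid Quadrature grid.
#' @param config [estimator_config()]; defaults to the config stored in
#'   `state`.
#' @return List with the updated `state`, the examinee's `eap` score, and a
#'   `record` (class `trajectory_record`) holding the post-update averaged
#'   parameter snapshot.
#' @export
process_examinee <- function(state, y, grid, config = state$config) {
  if (!inherits(y, "response_vector")) y <- response_vector(y, masked = TRUE)
  stopifnot(length(y$values) == state$J)
  n <- state$n + 1L
  post_cur <- posterior_node_weights(y, state_params(state, "current"), grid)
  post_avg <- posterior_node_weights(y, state_params(state, "avg"), grid)
  post_g <- if (config$gradient_at == "current") post_cur else post_avg
  if (config$avg_mode == "log-weighted") {
    state$cum_omega <- state$cum_omega + log1p(n)^config$avg_w
    tau <- averaging_weight(n, config, cum_omega = state$cum_omega)
  } else {
    tau <- averaging_weight(n, config)
  }
  state$items <- lapply(seq_len(state$J), function(j) {
    update_item(state$items[[j]], y$values[j], grid, config,
                post_for_gradient = post_g, post_for_hessian = post_avg,
                tau = tau)
  })
  state$n <- n
  avg_params <- state_params(state, "avg")
  eap <- eap_ability(y, avg_params, grid)
  record <- structure(
    list(n = n, beta_avg = param_matrix(avg_params), eap = eap,
         step = step_size(n, config), examinee_id = y$examinee_id),
    class = "trajectory_record"
  )
  list(state = state, eap = eap, record = record)
}

#' Standard errors from the inverse accumulated Hessian
#'
#' `SE_j = sqrt(diag(S_j^{-1}))` using the accumulated (unnormalized)
#' Hessian, so the `1/sqrt(n)` scale of the asymptotic normality of the
#' averaged iterates is built in.
#'
#' @param state An [online_state()] or a fitted object from [fit_online()].
#' @return `(Q+1) x J` matrix of standard errors (`NA` for anchored
#'   entries), rows ordered as (loadings, intercept).
#' @export
standard_errors <- function(state) {
  if (inherits(state, "irtstream_fit")) return(state$se)
  stopifnot(inherits(state, "online_state"))
  out <- matrix(NA_real_, state$Q + 1L, state$J,
                dimnames = list(NULL, state$item_ids))
  for (j in seq_len(state$J)) {
    st <- state$items[[j]]
    free <- st$beta_current$free
    if (!any(free)) next
    Sinv <- tryCatch(solve(st$S), error = function(e) {
      stop(sprintf("singular accumulated Hessian for item %d: %s", j,
                   conditionMessage(e)))
    })
    out[free, j] <- sqrt(diag(Sinv))
  }
  out
}
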