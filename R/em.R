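#' E-step expected counts of the Bock-Aitkin EM algorithm
#'
#' For each quadrature node `k`, accumulates the expected number of
#' examinees at the node (`nbar_k = sum_n post_nk`) and, per item, the
#' expected number of correct responses
#' (`rbar_jk = sum_n post_nk y_nj`), where `post_nk` are each examinee's
#' posterior node weights under the current parameters.
#'
#' @param data `N x J` binary response matrix (`NA` allowed; masked items
#'   are skipped in both the posterior and the counts).
#' @param params [item_param_set()].
#' @param grid Quadrature grid.
#' @return List of class `expected_counts`: `nbar` (length `M`), `rbar`
#'   (`J x M`), and `nbar_item` (`J x M` per-item effective counts, equal
#'   to `nbar` replicated when there is no missingness).
#' @export
e_step <- function(data, params, grid) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  post <- posterior_matrix(data, params, grid)
  obs <- !is.na(data)
  Y0 <- ifelse(obs, data, 0)
  rbar <- t(crossprod(post, Y0))                 # J x M
  nbar_item <- t(crossprod(post, obs * 1))       # J x M
  structure(
    list(nbar = colSums(post), rbar = rbar, nbar_item = nbar_item),
    class = "expected_counts"
  )
}

# N x M matrix of posterior node weights for every examinee
posterior_matrix <- function(data, params, grid) {
  P <- node_probabilities(param_matrix(params), grid)   # M x J
  obs <- !is.na(data)
  Y0 <- ifelse(obs, data, 0)
  # loglik N x M: sum_j y log P + (1-y) log(1-P) over observed cells
  ll <- tcrossprod(Y0, log(P)) + tcrossprod((1 - Y0) * obs, log1p(-P))
  lp <- sweep(ll, 2L, log(grid$weights), "+")
  lp <- lp - apply(lp, 1L, max)
  p <- exp(lp)
  p / rowSums(p)
}

#' M-step Newton update of one item's parameters
#'
#' Solves the expected complete-data score equation
#' `sum_k (rbar_jk - nbar_jk P_jk) xtilde_k = 0` over the item's free
#' entries by damped Newton with the weighted information matrix
#' `sum_k nbar_jk P_jk (1 - P_jk) xtilde_k xtilde_k'`. Steps are halved
#' when the expected complete-data log-likelihood would decrease or the
#' iterate leaves the finite range.
#'
#' @param counts [e_step()] output.
#' @param j Item index.
#' @param beta_j Current [item_param()] for the item.
#' @param grid Quadrature grid.
#' @param tol Convergence on the max absolute score.
#' @param max_iter Inner Newton iteration cap.
#' @return The updated `item_param`.
#' @export
m_step_item <- function(counts, j, beta_j, grid, tol = 1e-8, max_iter = 50L) {
  free <- beta_j$free
  if (!any(free)) return(beta_j)
  X <- augmented_nodes(grid)
  Xf <- X[, free, drop = FALSE]
  rb <- counts$rbar[j, ]
  nb <- counts$nbar_item[j, ]
  Q <- length(beta_j$loadings)
  b <- c(beta_j$loadings, beta_j$intercept)

  expected_ll <- function(bv) {
    P <- clip_prob(plogis(drop(X %*% bv)))
    sum(rb * log(P) + (nb - rb) * log1p(-P))
  }

  for (iter in seq_len(max_iter)) {
    P <- clip_prob(plogis(drop(X %*% b)))
    score <- drop(crossprod(Xf, rb - nb * P))
    if (max(abs(score)) < tol) break
    info <- crossprod(Xf, Xf * (nb * P * (1 - P)))
    delta <- solve(info, score)
    ll0 <- expected_ll(b)
    step <- 1
    for (h in seq_len(30L)) {
      cand <- b
      cand[free] <- b[free] + step * delta
      if (all(is.finite(cand)) && expected_ll(cand) >= ll0 - 1e-12) {
        b <- cand
        break
      }
      step <- step / 2
      if (h == 30L) stop(sprintf("M-step for item %d failed after 30 step halvings", j))
    }
  }
  item_param(b[seq_len(Q)], b[Q + 1L], free = free, id = beta_j$id)
}

#' Fixed-quadrature Bock-Aitkin EM for 2PL/M2PL
#'
#' Alternates [e_step()] and per-item [m_step_item()] until the marginal
#' log-likelihood improves by less than `tol` or `max_cycles` is reached.
#' The observed-data log-likelihood is asserted non-decreasing (within
#' `1e-8`) every cycle.
#'
#' @param data `N x J` binary response matrix.
#' @param start Starting [item_param_set()]; defaults to [default_start()].
#' @param grid Quadrature grid (defaults to `build_quadrature_grid(K, Q)`).
#' @param K,Q Grid size when `grid` is not given.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_cycles EM cycle cap.
#' @param eap Also return EAP ability scores under the final parameters?
#' @return List of class `em_fit`: `params`, `loglik` (trace), `cycles`,
#'   `converged`, and optionally `eap` (`N x Q`).
#' @examples
#' sim <- generate_dataset(sim_config(N = 300, J = 5), seed = 2)
#' fit <- em_fit(sim$responses, K = 5)
#' fit$converged
#' @export
em_fit <- function(data, start = NULL, grid = NULL, K = 11L, Q = 1L,
                   tol = 1e-6, max_cycles = 500L, eap = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  J <- ncol(data)
  if (is.null(grid)) grid <- build_quadrature_grid(K, Q)
  if (is.null(start)) start <- default_start(J, grid$Q, item_ids = colnames(data))
  stopifnot(start$J == J, start$Q == grid$Q)

  params <- start
  trace <- marginal_loglik_total(data, params, grid)
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    counts <- e_step(data, params, grid)
    items <- lapply(seq_len(J), function(j) {
      m_step_item(counts, j, params$items[[j]], grid)
    })
    params <- item_param_set(items, item_ids = params$item_ids)
    ll <- marginal_loglik_total(data, params, grid)
    if (ll < tail(trace, 1L) - 1e-8) {
      stop(sprintf("EM log-likelihood decreased at cycle %d (%.10f -> %.10f)",
                   cycle, tail(trace, 1L), ll))
    }
    improve <- ll - tail(trace, 1L)
    trace <- c(trace, ll)
    cycles <- cycle
    if (improve < tol) {
      converged <- TRUE
      break
    }
  }
  out <- structure(
    list(params = params, loglik = trace, cycles = cycles,
         converged = converged, grid = grid),
    class = "em_fit"
  )
  if (eap) {
    post <- posterior_matrix(data, params, grid)
    out$eap <- post %*% grid$nodes
  }
  out
}

# total observed-data log marginal likelihood
marginal_loglik_total <- function(data, params, grid) {
  P <- node_probabilities(param_matrix(params), grid)
  obs <- !is.na(data)
  Y0 <- ifelse(obs, data, 0)
  ll <- tcrossprod(Y0, log(P)) + tcrossprod((1 - Y0) * obs, log1p(-P))
  lp <- sweep(ll, 2L, log(grid$weights), "+")
  m <- apply(lp, 1L, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("Bock-Aitkin EM fit: %d cycles, %sconverged, final loglik %.4f\n",
              x$cycles, if (x$converged) "" else "NOT ", tail(x$loglik, 1L)))
  invisible(x)
}
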