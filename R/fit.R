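#' Fit a 2PL/M2PL model online by truncated (averaged) stochastic Newton
#'
#' Streams once over the response matrix in row (arrival) order, applying
#' the TSNA/TASNA per-item update for each examinee and scoring each
#' examinee by EAP under the just-updated averaged item parameters. The
#' default engine is compiled; `engine = "r"` runs the pure-R reference
#' path ([process_examinee()]), which produces the same trajectory to
#' numerical round-off.
#'
#' @param responses `N x J` matrix of 0/1 responses (rows = examinees in
#'   arrival order; `NA` = masked item).
#' @param config An [estimator_config()].
#' @param start Starting [item_param_set()]; defaults to [default_start()]
#'   (all discriminations 1, intercepts 0, everything free).
#' @param grid Quadrature grid; defaults to
#'   `build_quadrature_grid(config$K, config$Q)`.
#' @param checkpoints Integer vector of examinee counts at which to
#'   snapshot the averaged parameters (for real-time trajectories).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @param resume A previous `irtstream_fit` to continue from (its final
#'   state seeds the run; `responses` are then examinees
#'   `n + 1, n + 2, ...`).
#'
#' @return An object of class `irtstream_fit` with elements `params`
#'   (averaged [item_param_set()], the reported estimate), `B_avg`,
#'   `B_current` (`(Q+1) x J` matrices), `S` (per-item accumulated
#'   Hessians over free entries), `se` (from [standard_errors()]), `eap`
#'   (`N x Q` online ability scores), `n`, `checkpoints`,
#'   `checkpoint_avg` (`(Q+1) x J x n_checkpoints` array), `config`,
#'   `grid`.
#'
#' @examples
#' sim <- generate_dataset(sim_config(N = 200, J = 5), seed = 1)
#' fit <- fit_online(sim$responses, estimator_config("tasna", K = 5))
#' coef(fit)
#' @export
fit_online <- function(responses, config = estimator_config(),
                       start = NULL, grid = NULL,
                       checkpoints = integer(0),
                       engine = c("cpp", "r"),
                       resume = NULL) {
  engine <- match.arg(engine)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  bad <- !is.na(responses) & !(responses %in% c(0, 1))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary response %s at row %d, column %d",
                 format(responses[w[1L], w[2L]]), w[1L], w[2L]))
  }
  J <- ncol(responses)
  if (is.null(grid)) grid <- build_quadrature_grid(config$K, config$Q)

  if (!is.null(resume)) {
    stopifnot(inherits(resume, "irtstream_fit"))
    B_cur <- resume$B_current; B_avg <- resume$B_avg
    free <- resume$free; S0 <- resume$S
    n_start <- resume$n; cum_omega <- resume$cum_omega
    item_ids <- resume$item_ids
    template <- resume$params
  } else {
    if (is.null(start)) {
      ids <- colnames(responses)
      start <- default_start(J, config$Q, item_ids = ids)
    }
    stopifnot(inherits(start, "item_param_set"), start$J == J,
              start$Q == config$Q)
    B_cur <- B_avg <- param_matrix(start)
    free <- free_matrix(start)
    S0 <- lapply(start$items, initial_hessian, grid = grid, s0 = config$s0)
    n_start <- 0L; cum_omega <- log1p(0)^config$avg_w
    item_ids <- start$item_ids
    template <- start
  }
  checkpoints <- as.integer(sort(unique(checkpoints)))

  if (engine == "cpp") {
    res <- .stream_fit_cpp(
      responses, grid$nodes, grid$weights, B_cur, B_avg,
      matrix(as.integer(free), nrow(free), ncol(free)), S0,
      config$gamma, config$c_nu, config$n0,
      config$c_lambda, config$alpha_lambda,
      match(config$avg_mode, c("none", "uniform", "log-weighted")) - 1L,
      config$avg_w,
      match(config$gradient_at, c("current", "averaged")) - 1L,
      n_start, cum_omega, checkpoints)
  } else {
    res <- stream_fit_r(responses, grid, config, B_cur, B_avg, free, S0,
                        n_start, cum_omega, checkpoints, template)
  }

  params <- set_param_matrix(template, res$B_avg)
  fit <- structure(
    list(params = params,
         B_avg = res$B_avg, B_current = res$B_current,
         S = res$S, eap = res$eap,
         n = res$n, cum_omega = res$cum_omega,
         checkpoints = checkpoints, checkpoint_avg = res$checkpoint_avg,
         free = free, item_ids = item_ids,
         config = config, grid = grid, se = NULL),
    class = "irtstream_fit"
  )
  fit$se <- fit_standard_errors(fit)
  fit
}

# pure-R engine: drives process_examinee over the rows
stream_fit_r <- function(responses, grid, config, B_cur, B_avg, free, S0,
                         n_start, cum_omega, checkpoints, template) {
  J <- ncol(responses); Q <- grid$Q
  cur_set <- set_param_matrix(template, B_cur)
  avg_set <- set_param_matrix(template, B_avg)
  state <- online_state(cur_set, grid, config)
  for (j in seq_len(J)) {
    state$items[[j]]$beta_avg <- avg_set$items[[j]]
    state$items[[j]]$S <- S0[[j]]
    state$items[[j]]$n <- n_start
  }
  state$n <- n_start
  state$cum_omega <- cum_omega
  N <- nrow(responses)
  eap <- matrix(0, N, Q)
  cp_avg <- array(0, c(Q + 1L, J, length(checkpoints)))
  for (i in seq_len(N)) {
    out <- process_examinee(state, responses[i, ], grid, config)
    state <- out$state
    eap[i, ] <- out$eap
    hit <- match(state$n, checkpoints)
    if (!is.na(hit)) cp_avg[, , hit] <- out$record$beta_avg
  }
  list(B_current = param_matrix(state_params(state, "current")),
       B_avg = param_matrix(state_params(state, "avg")),
       S = lapply(state$items, `[[`, "S"),
       eap = eap, n = state$n, cum_omega = state$cum_omega,
       checkpoint_avg = cp_avg)
}

fit_standard_errors <- function(fit) {
  Qp1 <- nrow(fit$B_avg); J <- ncol(fit$B_avg)
  out <- matrix(NA_real_, Qp1, J, dimnames = list(NULL, fit$item_ids))
  for (j in seq_len(J)) {
    fr <- fit$free[, j]
    if (!any(fr)) next
    out[fr, j] <- sqrt(diag(solve(fit$S[[j]])))
  }
  out
}

#' @export
coef.irtstream_fit <- function(object, ...) {
  B <- object$B_avg
  Q <- nrow(B) - 1L
  rownames(B) <- c(sprintf("a%d", seq_len(Q)), "d")
  colnames(B) <- object$item_ids
  B
}

#' @export
print.irtstream_fit <- function(x, ...) {
  cat(sprintf("Online %s fit: %d examinees streamed, J = %d items, Q = %d\n",
              toupper(x$config$method), x$n, ncol(x$B_avg), nrow(x$B_avg) - 1L))
  cat("Averaged item-parameter estimates (slope-intercept form):\n")
  print(round(coef(x), 4))
  invisible(x)
}
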