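#' Configuration of a parameter-recovery simulation
#'
#' Describes one cell of the recovery design: sample size, test length,
#' latent dimensionality, the discrimination-generating uniform bounds,
#' the fitting quadrature, and the replication count.
#'
#' @param N Examinees per replication.
#' @param J Items.
#' @param Q Latent dimensions (`1` = unidimensional 2PL).
#' @param a_low,a_high Bounds of the uniform distribution generating
#'   discriminations.
#' @param K_fit Quadrature nodes per dimension used when fitting.
#' @param R Replications.
#' @param base_seed Replication `r` uses seed `base_seed + r`.
#' @param checkpoints Examinee counts at which streaming fits snapshot the
#'   averaged parameters (entries above `N` are dropped).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N, J, Q = 1L, a_low = 0.5, a_high = 2,
                       K_fit = 11L, R = 1L, base_seed = 0L,
                       checkpoints = c(500L, 1000L, 2000L, 2500L, 5000L,
                                       7500L, 10000L, 15000L, 20000L)) {
  stopifnot(N >= 1, J >= 1, Q >= 1, J > Q, a_low > 0, a_high > a_low, R >= 1)
  structure(
    list(N = as.integer(N), J = as.integer(J), Q = as.integer(Q),
         a_low = a_low, a_high = a_high, K_fit = as.integer(K_fit),
         R = as.integer(R), base_seed = as.integer(base_seed),
         checkpoints = as.integer(checkpoints[checkpoints <= N])),
    class = "sim_config"
  )
}

#' Apply anchor (identifiability) constraints to an item parameter set
#'
#' For `Q >= 2`, the first `Q` items are anchored: item `q` gets intercept
#' 0 and loading 1 on dimension `q`, 0 elsewhere, all entries fixed. This
#' resolves the rotational and translational indeterminacy of the M2PL
#' model. For `Q = 1` nothing is anchored: the standard-normal ability
#' prior already fixes the scale of the 2PL.
#'
#' @param params [item_param_set()].
#' @param Q Latent dimension count (defaults to `params$Q`).
#' @return The constrained `item_param_set`.
#' @export
apply_identifiability <- function(params, Q = params$Q) {
  stopifnot(inherits(params, "item_param_set"), params$Q == Q)
  if (Q == 1L) return(params)
  if (params$J < Q) stop("need at least Q items to anchor")
  items <- params$items
  for (q in seq_len(Q)) {
    e_q <- as.numeric(seq_len(Q) == q)
    items[[q]] <- item_param(e_q, 0, free = rep(FALSE, Q + 1L),
                             id = items[[q]]$id)
  }
  item_param_set(items, item_ids = params$item_ids)
}

#' Generate synthetic 2PL/M2PL response data
#'
#' Abilities are drawn i.i.d. standard (multivariate) normal;
#' discriminations uniform on `(a_low, a_high)`; 2PL difficulties (and
#' M2PL intercepts) standard normal. Anchor constraints are applied before
#' responses are generated, so anchored items produce data under their
#' constrained values. Responses are Bernoulli draws from the logistic
#' response probabilities.
#'
#' @param simconfig A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `theta` (`N x Q` true abilities), `params` (true
#'   [item_param_set()], anchors applied), `responses` (`N x J` 0/1
#'   matrix), and for `Q = 1` the generating `a` and `b` vectors.
#' @export
generate_dataset <- function(simconfig, seed) {
  stopifnot(inherits(simconfig, "sim_config"))
  set.seed(as.integer(seed))
  N <- simconfig$N; J <- simconfig$J; Q <- simconfig$Q
  ids <- sprintf("item%d", seq_len(J))
  if (Q == 1L) {
    a <- runif(J, simconfig$a_low, simconfig$a_high)
    b <- rnorm(J)
    items <- lapply(seq_len(J), function(j) item_2pl(a[j], b[j], id = ids[j]))
    params <- item_param_set(items, item_ids = ids)
  } else {
    A <- matrix(runif(J * Q, simconfig$a_low, simconfig$a_high), J, Q)
    d <- rnorm(J)
    items <- lapply(seq_len(J), function(j) item_param(A[j, ], d[j], id = ids[j]))
    params <- apply_identifiability(item_param_set(items, item_ids = ids), Q)
  }
  theta <- matrix(rnorm(N * Q), N, Q)
  B <- param_matrix(params)
  P <- plogis(cbind(theta, 1) %*% B)
  responses <- matrix(as.numeric(runif(N * J) < P), N, J,
                      dimnames = list(NULL, ids))
  out <- list(theta = theta, params = params, responses = responses)
  if (Q == 1L) {
    out$a <- a
    out$b <- b
  }
  out
}

#' Bias and RMSE of replicated estimates against the truth
#'
#' Per parameter: `bias = mean_r(est_r - truth)` and
#' `RMSE = sqrt(mean_r (est_r - truth)^2)` across replications; the table
#' reports the averages over the parameters of each class.
#'
#' @param estimates List (over replications) of numeric matrices/vectors of
#'   estimates, all shaped like `truth`.
#' @param truth Matrix/vector of true values.
#' @param classes Character labels, one per row of `truth` (one per
#'   element, for a vector), grouping parameters into reporting classes
#'   such as `"discrimination"`, `"difficulty"`, `"ability"`.
#' @return An object of class `bias_rmse_table`: a data.frame with columns
#'   `class`, `bias`, `rmse`, `n_parameters`, carrying the per-parameter
#'   `bias` and `rmse` matrices as attributes.
#' @export
evaluate_bias_rmse <- function(estimates, truth, classes = NULL) {
  truth <- as.matrix(truth)
  if (is.null(classes)) classes <- rep("parameter", nrow(truth))
  stopifnot(length(classes) == nrow(truth), length(estimates) >= 1L)
  errs <- lapply(estimates, function(e) {
    e <- as.matrix(e)
    if (!identical(dim(e), dim(truth))) {
      stop(sprintf("estimate has dim %s; truth has dim %s",
                   paste(dim(e), collapse = "x"), paste(dim(truth), collapse = "x")))
    }
    e - truth
  })
  R <- length(errs)
  bias <- Reduce(`+`, errs) / R
  mse <- Reduce(`+`, lapply(errs, function(e) e^2)) / R
  rmse <- sqrt(mse)
  tab <- do.call(rbind, lapply(unique(classes), function(cl) {
    rows <- classes == cl
    data.frame(class = cl,
               bias = mean(bias[rows, ]),
               rmse = mean(rmse[rows, ]),
               n_parameters = sum(rows) * ncol(truth))
  }))
  structure(tab, class = c("bias_rmse_table", "data.frame"),
            bias = bias, rmse = rmse)
}

# 2 x J matrix (discrimination, difficulty) from a slope-intercept matrix;
# the reporting scale of the unidimensional model
slope_difficulty <- function(B) {
  stopifnot(nrow(B) == 2L)
  rbind(discrimination = B[1L, ], difficulty = -B[2L, ] / B[1L, ])
}

# Pooled item-parameter RMSE of one fitted (Q+1) x J matrix vs truth, on
# the estimation (slope-intercept) scale: beta = (a, d) is the vector the
# recursion updates and the asymptotic theory addresses, and it is the
# only scale defined for every Q (the difficulty b = -d/a exists only for
# Q = 1). Class-wise tables additionally report the difficulty scale.
pooled_item_rmse <- function(B_est, B_true) {
  sqrt(mean((B_est - B_true)^2))
}

#' Run a replicated recovery study across estimators
#'
#' For each replication: generate a dataset (seed `base_seed + r`), fit
#' every requested estimator on the same data (paired design), and score
#' bias/RMSE per parameter class. Streaming estimators record averaged-
#' parameter snapshots at the configured checkpoints. A failing replicate
#' is recorded and skipped rather than aborting the study.
#'
#' @param simconfig A [sim_config()].
#' @param estimators Named list; each element an [estimator_config()] or
#'   the string `"em"`.
#' @param ability Also evaluate ability (EAP) recovery against the true
#'   abilities?
#' @return List of class `replication_study`: `results` (long data.frame:
#'   estimator, replication, class, bias, rmse, seconds),
#'   `summary` (averaged over replications), `checkpoint_rmse` (long
#'   data.frame of pooled item RMSE at each checkpoint for streaming
#'   estimators), `trajectories` (per estimator/replication checkpoint
#'   arrays), `errors` (failed replicates), and the `simconfig`.
#' @export
run_replication_study <- function(simconfig,
                                  estimators = list(tasna = estimator_config("tasna")),
                                  ability = TRUE) {
  stopifnot(inherits(simconfig, "sim_config"), length(estimators) >= 1L)
  if (is.null(names(estimators)) || any(names(estimators) == "")) {
    stop("estimators must be a named list")
  }
  results <- list()
  cp_rows <- list()
  trajectories <- list()
  errors <- list()
  classes_item <- if (simconfig$Q == 1L) {
    c("discrimination", "difficulty")
  } else {
    c(rep("discrimination", simconfig$Q), "intercept")
  }
  for (r in seq_len(simconfig$R)) {
    seed_r <- simconfig$base_seed + r
    sim <- generate_dataset(simconfig, seed = seed_r)
    B_true <- param_matrix(sim$params)
    true_rep <- if (simconfig$Q == 1L) slope_difficulty(B_true) else B_true
    for (nm in names(estimators)) {
      est <- estimators[[nm]]
      res <- tryCatch({
        t0 <- proc.time()[["elapsed"]]
        if (identical(est, "em")) {
          fit <- em_fit(sim$responses,
                        start = default_start(simconfig$J, simconfig$Q,
                                              free = free_matrix(sim$params),
                                              anchor_values = B_true,
                                              item_ids = sim$params$item_ids),
                        K = simconfig$K_fit, Q = simconfig$Q, eap = ability)
          B_est <- param_matrix(fit$params)
          eap <- if (ability) fit$eap else NULL
          cp <- NULL
        } else {
          stopifnot(inherits(est, "estimator_config"))
          fit <- fit_online(sim$responses, est,
                            start = default_start(simconfig$J, simconfig$Q,
                                                  free = free_matrix(sim$params),
                                                  anchor_values = B_true,
                                                  item_ids = sim$params$item_ids),
                            grid = build_quadrature_grid(simconfig$K_fit, simconfig$Q),
                            checkpoints = simconfig$checkpoints)
          B_est <- fit$B_avg
          eap <- if (ability) fit$eap else NULL
          cp <- fit$checkpoint_avg
        }
        secs <- proc.time()[["elapsed"]] - t0
        est_rep <- if (simconfig$Q == 1L) slope_difficulty(B_est) else B_est
        tab <- evaluate_bias_rmse(list(est_rep), true_rep, classes_item)
        if (ability && !is.null(eap)) {
          atab <- evaluate_bias_rmse(list(t(eap)), t(sim$theta),
                                     rep("ability", simconfig$Q))
          tab <- rbind(as.data.frame(tab), as.data.frame(atab))
        }
        list(tab = as.data.frame(tab), secs = secs, cp = cp)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          data.frame(estimator = nm, replication = r,
                     message = conditionMessage(res))
        next
      }
      tab <- res$tab
      tab$estimator <- nm
      tab$replication <- r
      tab$seconds <- res$secs
      results[[length(results) + 1L]] <- tab
      if (!is.null(res$cp) && length(simconfig$checkpoints)) {
        trajectories[[nm]][[r]] <- res$cp
        cp_rows[[length(cp_rows) + 1L]] <- data.frame(
          estimator = nm, replication = r, n = simconfig$checkpoints,
          rmse = vapply(seq_along(simconfig$checkpoints), function(i) {
            pooled_item_rmse(res$cp[, , i], B_true)
          }, numeric(1L)))
      }
    }
  }
  results <- do.call(rbind, results)
  summary <- stats::aggregate(cbind(bias, rmse, seconds) ~ estimator + class,
                              data = results, FUN = mean)
  checkpoint_rmse <- if (length(cp_rows)) do.call(rbind, cp_rows) else NULL
  structure(
    list(results = results, summary = summary,
         checkpoint_rmse = checkpoint_rmse, trajectories = trajectories,
         errors = if (length(errors)) do.call(rbind, errors) else NULL,
         simconfig = simconfig),
    class = "replication_study"
  )
}

#' @export
print.replication_study <- function(x, ...) {
  cat(sprintf("Replication study: N = %d, J = %d, Q = %d, R = %d\n",
              x$simconfig$N, x$simconfig$J, x$simconfig$Q, x$simconfig$R))
  print(x$summary)
  invisible(x)
}
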