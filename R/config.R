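#' Configuration of the online stochastic Newton estimator
#'
#' Collects every schedule constant of the TSNA/TASNA recursions. The step
#' sequence is `nu_n = c_nu (n + n0)^(-gamma)`; the curvature truncation
#' floor is `lambda_n = c_lambda (n + 1)^(-alpha_lambda)`; the averaging
#' sequence `tau_n` is controlled by `avg_mode` / `avg_w` (see
#' [averaging_weight()]).
#'
#' Defaults follow the recommended operating points: `gamma = 0.65` with
#' log-weighted averaging for TASNA, `gamma = 0.75` without averaging for
#' TSNA; `c_nu = 1`; a step-delay constant `n0 = 20` that damps the very
#' first updates while the accumulated Hessian is still dominated by its
#' initial value; truncation constants `c_lambda = 0.2 <= 1/4` (the largest
#' possible Bernoulli curvature, since `P(1-P) = 1/(2 + 2 cosh(eta)) <= 1/4`)
#' and `alpha_lambda = 0.49 < 1/2`.
#'
#' @param method `"tasna"` (averaged) or `"tsna"` (non-averaged). Sets the
#'   defaults of `gamma` and `avg_mode` when those are not supplied.
#' @param gamma Step exponent, in `(1/2, 1]`.
#' @param c_nu Step scale, `> 0`.
#' @param n0 Step-delay constant added to the denominator of the step
#'   sequence, `>= 0`.
#' @param c_lambda Truncation scale, in `(0, 1/4]`.
#' @param alpha_lambda Truncation exponent, in `(0, 1/2)`.
#' @param avg_mode `"none"` (TSNA), `"uniform"`, or `"log-weighted"`.
#' @param avg_w Exponent of the log-weighted averaging sequence
#'   `omega_i = log(1 + i)^avg_w`, `>= 0`.
#' @param gradient_at Evaluate the per-sample gradient at the `"current"`
#'   (non-averaged) iterate or at the `"averaged"` iterate. The per-sample
#'   curvature is always evaluated at the averaged iterate.
#' @param hessian_form Per-sample curvature form; only the Bock-Aitkin
#'   cross-information (`"cross_information"`) is implemented.
#' @param s0 Initialization of the accumulated Hessian:
#'   `"expected_information"` integrates the per-examinee information at the
#'   initial parameters over the prior grid (plus a `1e-3` ridge);
#'   `"identity"` uses the identity matrix.
#' @param K Quadrature nodes per dimension.
#' @param Q Latent dimension count.
#' @param seed Integer seed recorded with the run.
#'
#' @return An object of class `estimator_config`.
#' @examples
#' estimator_config("tasna")
#' estimator_config("tsna")$gamma  # 0.75
#' @export
estimator_config <- function(method = c("tasna", "tsna"),
                             gamma = NULL,
                             c_nu = 1,
                             n0 = 20,
                             c_lambda = 0.2,
                             alpha_lambda = 0.49,
                             avg_mode = NULL,
                             avg_w = 2,
                             gradient_at = c("current", "averaged"),
                             hessian_form = "cross_information",
                             s0 = c("expected_information", "identity"),
                             K = 11L, Q = 1L, seed = 1L) {
  method <- match.arg(method)
  gradient_at <- match.arg(gradient_at)
  s0 <- match.arg(s0)
  hessian_form <- match.arg(hessian_form)
  if (is.null(gamma)) gamma <- if (method == "tasna") 0.65 else 0.75
  if (is.null(avg_mode)) avg_mode <- if (method == "tasna") "log-weighted" else "none"
  avg_mode <- match.arg(avg_mode, c("none", "uniform", "log-weighted"))
  if (!(gamma > 0.5 && gamma <= 1)) stop("gamma must lie in (1/2, 1]")
  if (c_nu <= 0) stop("c_nu must be positive")
  if (n0 < 0) stop("n0 must be nonnegative")
  if (!(c_lambda > 0 && c_lambda <= 0.25)) {
    stop("c_lambda must lie in (0, 1/4]: the Bernoulli curvature P(1-P) never exceeds 1/4")
  }
  if (!(alpha_lambda > 0 && alpha_lambda < 0.5)) stop("alpha_lambda must lie in (0, 1/2)")
  if (avg_w < 0) stop("avg_w must be nonnegative")
  structure(
    list(method = method, gamma = gamma, c_nu = c_nu, n0 = n0,
         c_lambda = c_lambda, alpha_lambda = alpha_lambda,
         avg_mode = avg_mode, avg_w = avg_w,
         gradient_at = gradient_at, hessian_form = hessian_form, s0 = s0,
         K = as.integer(K), Q = as.integer(Q), seed = as.integer(seed)),
    class = "estimator_config"
  )
}

#' @export
print.estimator_config <- function(x, ...) {
  cat(sprintf(
    "%s config: nu_n = %g (n + %g)^-%g, lambda_n = %g (n+1)^-%g, averaging = %s (w = %g), K = %d, Q = %d\n",
    toupper(x$method), x$c_nu, x$n0, x$gamma, x$c_lambda, x$alpha_lambda,
    x$avg_mode, x$avg_w, x$K, x$Q))
  invisible(x)
}
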