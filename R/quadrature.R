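#' Tensor-product Gauss-Hermite quadrature grid for a standard normal prior
#'
#' Builds the fixed evaluation grid used to approximate integrals against a
#' standard (multivariate) normal ability prior. Per dimension, the
#' physicists' Gauss-Hermite abscissae `t` are rescaled to `x = sqrt(2) t`
#' so that the rule integrates against the N(0, 1) density; the joint grid
#' over `Q` independent dimensions is the tensor product, with node weights
#' multiplied across dimensions and renormalized to a probability vector.
#'
#' @param K Number of quadrature nodes per latent dimension (>= 1).
#' @param Q Number of latent dimensions (>= 1).
#' @param max_nodes Guard on the total grid size `K^Q`; exceeding it raises
#'   an error rather than silently allocating a huge grid.
#'
#' @return An object of class `quadrature_grid`: a list with `nodes`
#'   (`M x Q` matrix, `M = K^Q`), `weights` (length-`M` probability vector),
#'   `K`, `Q`, and `M`.
#'
#' @examples
#' g <- build_quadrature_grid(11, 1)
#' sum(g$weights)                      # 1
#' sum(g$weights * g$nodes[, 1]^2)     # ~ Var of N(0,1) = 1
#' @export
build_quadrature_grid <- function(K, Q = 1L, max_nodes = 1e6) {
  stopifnot(length(K) == 1L, length(Q) == 1L)
  K <- as.integer(K); Q <- as.integer(Q)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  if (is.na(Q) || Q < 1L) stop("Q must be a positive integer")
  M <- as.numeric(K)^Q
  if (M > max_nodes) {
    stop(sprintf("quadrature grid would have K^Q = %.0f nodes (> guard of %.0f)",
                 M, max_nodes))
  }
  if (K == 1L) {
    x1 <- 0
    w1 <- 1
  } else {
    gh <- pracma::gaussHermite(K)
    # enforce exact symmetry about 0 (gaussHermite leaves ~1e-16 residue)
    x1 <- sqrt(2) * (gh$x - rev(gh$x)) / 2
    w1 <- (gh$w + rev(gh$w)) / 2
    w1 <- w1 / sum(w1)
  }
  if (Q == 1L) {
    nodes <- matrix(x1, ncol = 1L)
    weights <- w1
  } else {
    idx <- as.matrix(expand.grid(rep(list(seq_len(K)), Q)))
    nodes <- matrix(x1[idx], ncol = Q)
    weights <- apply(matrix(w1[idx], ncol = Q), 1L, prod)
  }
  weights <- weights / sum(weights)
  structure(
    list(nodes = nodes, weights = weights, K = K, Q = Q, M = nrow(nodes)),
    class = "quadrature_grid"
  )
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("Gauss-Hermite quadrature grid: K = %d nodes/dimension, Q = %d, M = %d total\n",
              x$K, x$Q, x$M))
  invisible(x)
}

# M x (Q+1) design matrix of augmented ability points (node, 1), the
# regressor for the slope-intercept item parameterization.
augmented_nodes <- function(grid) {
  cbind(grid$nodes, 1)
}
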