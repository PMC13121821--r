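# Shared fixtures: tiny worked instances and simulation shortcuts.

# the single-item, two-node instance used in hand-computed examples:
# one item with a = 1, d = 0 on the K = 2 grid (nodes -1, +1)
tiny_instance <- function() {
  list(grid = build_quadrature_grid(2, 1),
       params = item_param_set(list(item_param(1, 0))),
       y1 = response_vector(1),
       y0 = response_vector(0))
}

# quick 2PL simulation at a given size
quick_sim <- function(N, J = 10, seed = 1, ...) {
  generate_dataset(sim_config(N = N, J = J, ...), seed = seed)
}

# pooled item-parameter RMSE on the estimation (slope-intercept) scale
pooled_rmse <- function(B_est, B_true) sqrt(mean((B_est - B_true)^2))

truth_matrix <- function(sim) {
  vapply(sim$params$items, function(it) c(it$loadings, it$intercept),
         numeric(sim$params$Q + 1L))
}
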