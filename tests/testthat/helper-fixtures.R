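# Shared fixtures: small ground-truth parameter tables and simulated
# datasets, all generated in code under fixed seeds.

# a small well-conditioned item set for recovery and scoring tests
toy_params <- function(J = 10L) {
  a <- rep(c(1.2, 2.0, 1.5, 2.5, 1.8), length.out = J)
  b1 <- seq(-1, 1, length.out = J)
  data.frame(item_id = sprintf("it%02d", seq_len(J)), a = a, b1 = b1,
             b2 = b1 + rep(c(1, 0.8, 1.2), length.out = J),
             stringsAsFactors = FALSE)
}

# theta + responses from a single-group GRM
toy_grm_data <- function(n, params = toy_params(), seed = 1L) {
  set.seed(seed)
  theta <- rnorm(n)
  list(theta = theta, resp = simulate_grm_responses(theta, params),
       params = params)
}

# minimal survey config kept small for fast end-to-end tests
small_sim_config <- function(seed = 1L, ...) {
  simulation_config(n_community = 300L, n_institutionalized = 150L,
                    seed = seed, ...)
}

# plain R tree traversal, independent of the compiled predictor
oracle_tree_predict <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- 1L
    while (tree$split_var[node] != 0L) {
      node <- if (X[i, tree$split_var[node]] <= tree$split_val[node])
        tree$left[node] else tree$right[node]
    }
    tree$pred[node]
  }, numeric(1))
}

# correlated-predictor regression fixture for the forest tests
make_forest_data <- function(n = 300, rho = 0, seed = 101) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  y <- 1.2 * x2 + rnorm(n) * 0.7
  list(X = cbind(x1 = x1, x2 = x2), y = y)
}

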