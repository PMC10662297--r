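# Shared fixtures: small random trees and independent oracles.

fixture_profiles <- hrqol_profiles()
fixture_costs <- default_cost_table()

# Random tree: depth <= max_depth, 2-4 branches per chance node, terminals
# drawing components (with replacement) from the cost table and a profile
# from the registry. Caller controls the RNG state.
random_tree <- function(max_depth = 4, p_terminal = 0.4, depth = 1) {
  if (depth > 1 && (depth >= max_depth || runif(1) < p_terminal)) {
    n_cmp <- sample(0:4, 1)
    return(terminal_state(
      paste0("t", depth, "_", sample.int(1e6, 1)),
      sample(names(fixture_costs), n_cmp, replace = TRUE),
      sample(names(fixture_profiles), 1)
    ))
  }
  k <- sample(2:4, 1)
  p <- rgamma(k, 1); p <- p / sum(p)
  chance_node(
    paste0("n", depth, "_", sample.int(1e6, 1)),
    lapply(seq_len(k), function(i) {
      branch(paste0("b", i), p[i],
             random_tree(max_depth, p_terminal, depth + 1))
    })
  )
}

# Independent oracle: expected cost/QALY by backward induction over the tree,
# never touching enumerate_paths()/path_table().
oracle_expectation <- function(node, costs, profiles) {
  if (inherits(node, "terminal_state")) {
    return(c(cost = sum(costs[node$cost_components]),
             qaly = trapezoid_qaly(profiles[[node$hrqol_profile]])))
  }
  out <- c(cost = 0, qaly = 0)
  for (b in node$branches) {
    out <- out + b$p * oracle_expectation(b$child, costs, profiles)
  }
  out
}

# Independent oracle for the bias-corrected percentile bootstrap: same
# resample stream contract as bc_bootstrap_ci (one block of n * n_boot
# uniform indices, filled column-major into an n_boot x n matrix), with the
# BC arithmetic written out from scratch.
oracle_bc_bootstrap <- function(x, n_boot, level, seed) {
  n <- length(x)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  stats_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) stats_b[b] <- sum(x[idx[b, ]]) / n
  obs <- sum(x) / n
  prop <- sum(stats_b < obs) / n_boot
  prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- qnorm(prop)
  alpha <- (1 - level) / 2
  p_lo <- pnorm(2 * z0 + qnorm(alpha))
  p_hi <- pnorm(2 * z0 + qnorm(1 - alpha))
  c(quantile(stats_b, p_lo, names = FALSE),
    quantile(stats_b, p_hi, names = FALSE))
}
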