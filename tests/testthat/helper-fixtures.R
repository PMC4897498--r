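# Construct a chain_samples object directly (for summary-module tests).
fake_samples <- function(theta_draws, alpha_draws, beta_draws) {
  structure(list(
    theta_draws = as.matrix(theta_draws),
    alpha_draws = as.matrix(alpha_draws),
    beta_draws = as.matrix(beta_draws),
    kept = nrow(as.matrix(alpha_draws)),
    config = chain_config(nrow(as.matrix(alpha_draws)) + 1L, 0L, 1L)
  ), class = "chain_samples")
}

# The published ten-item CBASE summary table shipped with the package.
published_items <- function() {
  utils::read.csv(system.file("extdata", "cbase_items_published.csv",
                              package = "gibbs2pno"))
}

# Batch-means MCSE of the second central moment of a draw sequence.
mcse_var <- function(x) mcse((x - mean(x))^2)
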