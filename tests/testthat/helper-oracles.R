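# Independent brute-force oracles and tiny fixtures shared across tests.

# Gaussian nested decomposition via stats::lm adjusted R-squared
oracle_nested_gauss <- function(y, design) {
  dd <- cbind(as.data.frame(design), y = y)
  adj <- function(form) summary(stats::lm(form, data = dd))$adj.r.squared
  a1 <- adj(y ~ condition); a2 <- adj(y ~ biological)
  a3 <- adj(y ~ preparation)
  v <- c(a1, a2 - a1, a3 - a2, 1 - a3)
  v[v < 0] <- 0
  v / sum(v)
}

# count decomposition via the closed-form Poisson group MLE (group rate =
# group count sum / group lib-size sum) and direct deviance evaluation
oracle_nested_count <- function(y, design, lib) {
  dev_for <- function(groups) {
    mu <- numeric(length(y))
    for (g in unique(groups)) {
      i <- groups == g
      mu[i] <- lib[i] * sum(y[i]) / sum(lib[i])
    }
    terms <- ifelse(y > 0, y * log(y / pmax(mu, 1e-300)), 0) - (y - mu)
    2 * sum(terms)
  }
  d0 <- dev_for(rep(1, length(y)))
  r2 <- 1 - c(dev_for(design$condition), dev_for(design$biological),
              dev_for(design$preparation)) / d0
  n <- length(y)
  adj <- 1 - (1 - r2) * (n - 1) / (n - c(2, 4, 8))
  v <- c(adj[1], adj[2] - adj[1], adj[3] - adj[2], 1 - adj[3])
  v[v < 0] <- 0
  v / sum(v)
}

# unadjusted R-squared of the three nested group-mean models
oracle_raw_r2 <- function(y, design) {
  tss <- sum((y - mean(y))^2)
  vapply(c("condition", "biological", "preparation"), function(lev) {
    fit <- stats::ave(y, design[[lev]])
    1 - sum((y - fit)^2) / tss
  }, numeric(1))
}

# small count experiment used by several normalization/DE tests
make_toy_counts <- function(seed = 5, n_genes = 400, reads = 5e4) {
  p <- sim_params(n_genes = n_genes, seq_total_reads = reads, seed = seed,
                  baseline_log_abundance = list(mean = 5, sd = 1.5))
  truth <- simulate_truth(p)
  list(params = p, truth = truth, counts = simulate_counts(truth, p),
       design = p$design)
}

# drop zero-total genes from a simulated pair so both platforms share a
# positive-intensity gene universe
filter_positive <- function(counts, arrays) {
  keep <- counts$intensity > 0
  list(counts = expression_matrix(counts$values[keep, , drop = FALSE],
                                  "counts"),
       arrays = expression_matrix(arrays$values[keep, , drop = FALSE],
                                  "logratio",
                                  intensity = arrays$intensity[keep]))
}
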