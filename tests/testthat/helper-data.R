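# Shared fixtures, built in code at test time.

# One environment with AR(1) Gaussian covariates, k positive signals of the
# given per-coordinate effect size, and exact Gaussian knockoffs.
make_knockoff_data <- function(n = 150, p = 20, k = 0, effect = 0.5,
                               rho = 0.5, seed = 1) {
  model <- gaussian_model(ar1_covariance(p, rho), rho = rho)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p) %*% chol(ar1_covariance(p, rho))
  support <- if (k > 0) sort(sample.int(p, k)) else integer(0)
  beta <- numeric(p)
  beta[support] <- effect
  y <- drop(X %*% beta) + rnorm(n)
  XXk <- create_knockoffs(X, model, seed = seed + 1)
  list(X = X, XXk = XXk, y = y, support = support, beta = beta, model = model)
}

# Exhaustive-scan oracle for the knockoff threshold: tries every candidate
# t in the positive |W| grid and takes the smallest one meeting the bound.
brute_threshold <- function(W, q, offset = 1) {
  ts <- sort(unique(abs(W[W != 0])))
  for (t in ts) {
    if ((offset + sum(W <= -t)) / max(sum(W >= t), 1) <= q) {
      return(list(threshold = t, selected = which(W >= t)))
    }
  }
  list(threshold = Inf, selected = integer(0))
}

# Random statistic vectors with zeros and ties, for equivalence sweeps.
random_W <- function(p, seed) {
  set.seed(seed)
  W <- round(rnorm(p), 1) # coarse grid induces ties
  W[sample.int(p, ceiling(p / 5))] <- 0
  W
}
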