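#' Configuration of the multi-environment synthetic experiment
#'
#' Defines the simulation design used throughout the package: every
#' environment shares the AR(1) Gaussian covariate law, while the outcome is
#' a sparse linear model whose support varies across environments. The
#' external environments share one support; the fraction of it shared with
#' the target environment's support is the `overlap` control parameter.
#' Defaults reproduce the reference design: p = 500 variables, n = 800
#' observations per environment, 3 environments, rho = 0.5, 60 signals of
#' amplitude a = 3.5 (on the `a/sqrt(n)` scale, giving per-coordinate effects
#' of about 0.12), standard Gaussian noise, and nominal FDR level q = 0.1.
#'
#' @param p number of variables.
#' @param n observations per environment.
#' @param n_env total number of environments (target + externals).
#' @param rho AR(1) correlation of the covariates.
#' @param n_signals number of nonzero effects per environment.
#' @param amplitude signal amplitude a; each nonzero effect equals
#'   `a / sqrt(n)` (or `a / n` with `amplitude_scale = "n"`).
#' @param amplitude_scale `"sqrt_n"` (default) or `"n"`.
#' @param overlap fraction of the target support shared with the external
#'   support, in \[0, 1\]; counts are rounded to the nearest integer and the
#'   realized overlap is reported.
#' @param q nominal FDR level carried into downstream filters.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param random_signs if `TRUE`, nonzero effects get independent random signs
#'   (constant across environments); default `FALSE` (all positive).
#' @param theta_grid,gamma_grid tuning grids carried to the harness methods.
#' @param cv_folds,nlambda cross-validation folds and lambda-path length used
#'   by the harness's lasso fits.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(p = 500, n = 800, n_env = 3, rho = 0.5,
                       n_signals = 60, amplitude = 3.5,
                       amplitude_scale = c("sqrt_n", "n"),
                       overlap = 1, q = 0.1, noise_sd = 1,
                       random_signs = FALSE,
                       theta_grid = seq(0, 1, by = 0.1),
                       gamma_grid = seq(0, 1, by = 0.1),
                       cv_folds = 10, nlambda = 100) {
  amplitude_scale <- match.arg(amplitude_scale)
  stopifnot(p >= 1, n >= 2, n_env >= 1, abs(rho) < 1,
            n_signals >= 0, amplitude >= 0, noise_sd >= 0,
            overlap >= 0, overlap <= 1, q > 0, q < 1,
            all(theta_grid >= 0 & theta_grid <= 1),
            all(gamma_grid >= 0 & gamma_grid <= 1))
  if (n_signals > p) stop("`n_signals` cannot exceed `p`")
  structure(
    list(p = p, n = n, n_env = n_env, rho = rho, n_signals = n_signals,
         amplitude = amplitude, amplitude_scale = amplitude_scale,
         overlap = overlap, q = q, noise_sd = noise_sd,
         random_signs = random_signs, theta_grid = theta_grid,
         gamma_grid = gamma_grid, cv_folds = cv_folds, nlambda = nlambda),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: p =", x$p, " n =", x$n, " environments =", x$n_env,
      "\n  rho =", x$rho, " signals =", x$n_signals,
      " amplitude =", x$amplitude, paste0("(", x$amplitude_scale, ")"),
      " overlap =", x$overlap, " q =", x$q, "\n")
  invisible(x)
}

#' Generate one multi-environment dataset
#'
#' Draws the supports (external environments share one support; the target
#' shares `round(overlap * n_signals)` of its signals with them), the effect
#' vectors, and for every environment an i.i.d. Gaussian AR(1) design and a
#' linear outcome `y = X beta + noise`. Environment 0 is the target.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the dataset is a deterministic function of
#'   `(config, seed)`.
#' @return A list with `envs` (list of environments, each `list(X, y, env_id)`,
#'   target first) and `truth` (`supports` per environment, `betas`,
#'   `overlap_realized`).
#' @export
generate_environments <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p
  k <- config$n_signals
  n_shared <- as.integer(round(config$overlap * k))

  set.seed(child_seed(seed, 0L)) # supports + signs
  S_ext <- sort(sample.int(p, k))
  shared <- if (n_shared > 0) sort(sample(S_ext, n_shared)) else integer(0)
  pool <- setdiff(seq_len(p), S_ext)
  extra <- k - n_shared
  if (extra > length(pool)) stop("not enough variables for a disjoint target support")
  S_0 <- sort(c(shared, if (extra > 0) sample(pool, extra)))
  signs <- if (config$random_signs) {
    stats::setNames(sample(c(-1, 1), p, replace = TRUE), NULL)
  } else {
    rep(1, p)
  }
  amp <- config$amplitude /
    switch(config$amplitude_scale, sqrt_n = sqrt(config$n), n = config$n)

  supports <- c(list(S_0), rep(list(S_ext), config$n_env - 1))
  betas <- lapply(supports, function(S) {
    beta <- numeric(p)
    beta[S] <- amp * signs[S]
    beta
  })

  Sigma <- ar1_covariance(p, config$rho)
  R <- chol(Sigma)
  envs <- vector("list", config$n_env)
  for (e in seq_len(config$n_env)) {
    set.seed(child_seed(seed, e, 1L))
    X <- matrix(stats::rnorm(config$n * p), config$n, p) %*% R
    y <- drop(X %*% betas[[e]]) + config$noise_sd * stats::rnorm(config$n)
    envs[[e]] <- list(X = X, y = y, env_id = e - 1L)
  }
  list(
    envs = envs,
    truth = list(supports = supports, betas = betas,
                 overlap_realized = if (k > 0) n_shared / k else NA_real_)
  )
}

#' False discovery proportion and power of a selection
#'
#' @param selected integer indices of selected variables.
#' @param true_support integer indices of the true signals.
#' @return A named numeric vector `c(fdp = ..., power = ...)`: FDP is the
#'   fraction of selections outside the true support (0 for an empty
#'   selection); power is the fraction of the true support recovered.
#' @examples
#' fdp_power(c(1, 2, 3), c(1, 2)) # fdp 1/3, power 1
#' @export
fdp_power <- function(selected, true_support) {
  selected <- unique(as.integer(selected))
  true_support <- unique(as.integer(true_support))
  fdp <- length(setdiff(selected, true_support)) / max(length(selected), 1)
  power <- length(intersect(selected, true_support)) / max(length(true_support), 1)
  c(fdp = fdp, power = power)
}
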