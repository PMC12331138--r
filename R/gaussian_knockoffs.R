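#' AR(1) correlation matrix
#'
#' Covariance matrix of a stationary first-order autoregressive process with
#' unit marginal variance: entry (i, j) equals `rho^|i - j|`. This is the
#' covariate law used throughout the package's synthetic experiments.
#'
#' @param p number of variables (positive integer).
#' @param rho autocorrelation parameter, strictly inside (-1, 1).
#' @return A `p x p` symmetric positive-definite matrix with unit diagonal.
#' @examples
#' ar1_covariance(3, 0.5)
#' @export
ar1_covariance <- function(p, rho) {
  stopifnot(length(p) == 1, p >= 1, p == round(p))
  if (!is.numeric(rho) || length(rho) != 1 || abs(rho) >= 1) {
    stop("`rho` must be a single value strictly inside (-1, 1)")
  }
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

#' Equicorrelated knockoff diagonal
#'
#' Computes the equicorrelated choice of the knockoff diagonal `s` for a
#' correlation matrix Sigma: `s_j = min(1, 2 * lambda_min(Sigma))` for all j,
#' shrunk by a small multiplicative slack so that `2*Sigma - diag(s)` stays
#' positive semidefinite under floating point. Deterministic and cheap;
#' an SDP-optimised `s` can be passed to [gaussian_model()] instead.
#'
#' @param covariance symmetric positive-definite matrix with unit diagonal
#'   (standardize first otherwise).
#' @param slack multiplicative shrinkage guarding numerical PSD violations.
#' @return A length-p vector of identical positive entries.
#' @export
solve_equicorrelated_s <- function(covariance, slack = 1 - 1e-6) {
  check_covariance(covariance)
  if (max(abs(diag(covariance) - 1)) > 1e-8) {
    stop("`covariance` must have unit diagonal; standardize it first")
  }
  lam_min <- min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min <= 0) stop("`covariance` is not positive definite")
  rep(min(1, 2 * lam_min) * slack, nrow(covariance))
}

check_covariance <- function(covariance) {
  if (!is.matrix(covariance) || nrow(covariance) != ncol(covariance)) {
    stop("`covariance` must be a square matrix")
  }
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    stop("`covariance` must be symmetric")
  }
  invisible(covariance)
}

#' Gaussian design model for exact model-X knockoffs
#'
#' Bundles the covariate law N(mean, covariance) with a knockoff diagonal `s`
#' and precomputes the factors needed to sample knockoffs, so that repeated
#' sampling (e.g. one call per environment) costs only a matrix product and a
#' Gaussian draw. The conditional law of the knockoff row given the original
#' row x is N(x - (x - mean) %*% Sigma^{-1} S, 2S - S Sigma^{-1} S), whose
#' joint covariance with x is the 2p x 2p block matrix
#' [[Sigma, Sigma - S], [Sigma - S, Sigma]].
#'
#' @param covariance p x p symmetric positive-definite covariance matrix.
#' @param mean length-p mean vector (default zero).
#' @param s knockoff diagonal; defaults to [solve_equicorrelated_s()] (which
#'   requires unit diagonal). Supply your own (e.g. an SDP solution) for
#'   non-standardized covariances.
#' @param rho optional AR(1) parameter, recorded for provenance only.
#' @param max_kappa maximum accepted condition number of `covariance`;
#'   ill-conditioned inputs are refused rather than silently regularized.
#' @return An object of class `"gaussian_model"`.
#' @export
gaussian_model <- function(covariance, mean = NULL, s = NULL, rho = NULL,
                           max_kappa = 1e10) {
  check_covariance(covariance)
  p <- nrow(covariance)
  if (is.null(mean)) mean <- rep(0, p)
  stopifnot(length(mean) == p)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`covariance` is not positive definite")
  if (max(ev) / min(ev) > max_kappa) {
    stop("`covariance` condition number exceeds ", format(max_kappa),
         "; refusing to invert")
  }
  if (is.null(s)) s <- solve_equicorrelated_s(covariance)
  stopifnot(length(s) == p, all(is.finite(s)))
  if (any(s < 0) || any(s > 2 * diag(covariance) + 1e-8)) {
    stop("`s` entries must lie in [0, 2*diag(covariance)]")
  }
  S <- diag(s, p)
  # 2*Sigma - S must be PSD for the construction to be valid
  ev2 <- eigen(2 * covariance - S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) < -1e-8) {
    stop("2*covariance - diag(s) is not positive semidefinite")
  }
  Sinv_S <- solve(covariance, S)            # Sigma^{-1} S, p x p
  cond_cov <- 2 * S - S %*% Sinv_S          # 2S - S Sigma^{-1} S
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  ce <- eigen(cond_cov, symmetric = TRUE)
  half <- ce$vectors %*% (sqrt(pmax(ce$values, 0)) * t(ce$vectors))
  structure(
    list(mean = mean, covariance = covariance, s = s, rho = rho,
         cond_mat = Sinv_S, cond_half = half),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("Gaussian knockoff model: p =", length(x$s),
      if (!is.null(x$rho)) paste0("(AR(1), rho = ", x$rho, ")"), "\n")
  cat("  s range: [", format(min(x$s)), ",", format(max(x$s)), "]\n")
  invisible(x)
}

#' Sample exact Gaussian model-X knockoffs
#'
#' Draws one knockoff row per observation from the Gaussian conditional law
#' defined by `model`, independently across rows and without looking at the
#' outcome. The result is the augmented design `[X, X~]` whose columns j and
#' j + p form an original/knockoff pair.
#'
#' @param X n x p data matrix distributed (row-wise) as N(mean, covariance).
#' @param model a [gaussian_model()].
#' @param seed integer seed; the draw is deterministic given `(X, model, seed)`.
#' @return An n x 2p matrix with knockoff columns named after the originals
#'   with a `".k"` suffix and attribute `"p"` recording the pair split.
#' @examples
#' m <- gaussian_model(ar1_covariance(5, 0.5), rho = 0.5)
#' X <- matrix(rnorm(50), 10, 5)
#' XXk <- create_knockoffs(X, m, seed = 1)
#' dim(XXk)
#' @export
create_knockoffs <- function(X, model, seed = 1) {
  stopifnot(inherits(model, "gaussian_model"))
  X <- as.matrix(X)
  p <- length(model$s)
  if (ncol(X) != p) stop("`X` has ", ncol(X), " columns; model expects ", p)
  if (anyNA(X)) stop("`X` contains missing values")
  n <- nrow(X)
  mu_k <- X - sweep(X, 2, model$mean) %*% model$cond_mat
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Xk <- mu_k + Z %*% model$cond_half
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("X", seq_len(p))
  out <- cbind(X, Xk)
  colnames(out) <- c(nm, paste0(nm, ".k"))
  attr(out, "p") <- p
  out
}

#' Swap original and knockoff columns
#'
#' Exchanges columns `j` and `j + p` of an augmented design for every j in
#' `swap`. Used to verify exchangeability and the flip-sign property.
#'
#' @param XXk n x 2p augmented design.
#' @param swap integer indices in 1..p to swap with their knockoffs.
#' @return The swapped augmented design.
#' @export
swap_pairs <- function(XXk, swap) {
  p <- ncol(XXk) / 2
  stopifnot(p == round(p), all(swap >= 1), all(swap <= p))
  out <- XXk
  out[, swap] <- XXk[, swap + p]
  out[, swap + p] <- XXk[, swap]
  out
}
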