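#' @importFrom glmnet glmnet cv.glmnet
NULL

standardize_cols <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  # population (1/n) scale, matching glmnet's internal convention and making
  # standardization exactly invariant to row duplication
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sdv[sdv < 1e-12] <- 1
  scale(X, center = mu, scale = sdv)
}

make_foldid <- function(n, cv_folds, seed) {
  if (n < cv_folds) stop("need at least `cv_folds` observations (n = ", n, ")")
  set.seed(seed)
  sample(rep(seq_len(cv_folds), length.out = n))
}

# Extract length-2p coefficient vector (no intercept) at a single lambda.
coef_at <- function(fit, lambda) {
  as.numeric(stats::coef(fit, s = lambda))[-1]
}

new_knockoff_stats <- function(W, method, lambda, gamma = NA_real_, coef = NULL) {
  structure(list(W = W, method = method, lambda = lambda, gamma = gamma,
                 coef = coef),
            class = "knockoff_stats")
}

#' @export
print.knockoff_stats <- function(x, ...) {
  cat("Knockoff statistics (", x$method, "): p = ", length(x$W), "\n", sep = "")
  cat("  lambda =", format(x$lambda, digits = 4),
      if (!is.na(x$gamma)) paste(" gamma =", format(x$gamma)), "\n")
  cat("  ", sum(x$W > 0), "positive /", sum(x$W < 0), "negative /",
      sum(x$W == 0), "zero\n")
  invisible(x)
}

as_W <- function(w) {
  if (inherits(w, "knockoff_stats")) w$W else as.numeric(w)
}

check_design_outcome <- function(XXk, y) {
  XXk <- as.matrix(XXk)
  y <- as.numeric(y)
  if (nrow(XXk) != length(y)) stop("`XXk` and `y` have mismatched row counts")
  if (ncol(XXk) %% 2 != 0) stop("augmented design must have an even column count")
  if (stats::sd(y) < 1e-12) stop("outcome is constant")
  list(XXk = XXk, y = y, p = ncol(XXk) / 2)
}

#' Lasso coefficient-difference knockoff statistics
#'
#' Fits an l1-penalized (generalized) linear model of the outcome on the
#' standardized augmented design `[X, X~]` and returns the flip-sign statistics
#' `W_j = |b_j| - |b_{j+p}|`. Large positive `W_j` indicates the original
#' variable is substantially more predictive than its knockoff. The penalty is
#' chosen by cross-validation unless `lambda` is supplied (fixed tuning, as
#' required by the flip-sign contract).
#'
#' @param XXk n x 2p augmented design, e.g. from [create_knockoffs()].
#' @param y length-n outcome vector.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation.
#' @param nlambda length of the glmnet lambda path (default 100).
#' @param family `"gaussian"` (least squares, default) or `"binomial"`.
#' @return A `"knockoff_stats"` object: list with `W` (length p), the tuning
#'   actually used, and the fitted 2p coefficient vector.
#' @export
stat_lasso_coefdiff <- function(XXk, y, cv_folds = 10, seed = 1,
                                lambda = NULL, nlambda = 100,
                                family = "gaussian") {
  d <- check_design_outcome(XXk, y)
  Xs <- standardize_cols(d$XXk)
  if (is.null(lambda)) {
    foldid <- make_foldid(length(d$y), cv_folds, seed)
    cvfit <- cv.glmnet(Xs, d$y, foldid = foldid, standardize = FALSE,
                       nlambda = nlambda, family = family)
    lambda <- cvfit$lambda.min
    b <- coef_at(cvfit, lambda)
  } else {
    fit <- glmnet(Xs, d$y, lambda = lambda, standardize = FALSE,
                  family = family, thresh = 1e-12)
    b <- coef_at(fit, lambda)
  }
  W <- abs(b[seq_len(d$p)]) - abs(b[d$p + seq_len(d$p)])
  new_knockoff_stats(W, "lasso_coefdiff", lambda, coef = b)
}

#' Prior penalty weights from external coefficients
#'
#' Converts external fitted coefficients into inverse prior-importance
#' weights `phi_j = 1 / (eps + |b_j| + |b_{j+p}|)`: variables with large
#' external effects (on the original or its knockoff) get small weights,
#' hence weaker regularization in [stat_weighted_lasso()]. The weight is
#' shared by each original/knockoff pair, which preserves the flip-sign
#' property of the resulting statistics.
#'
#' @param coef_ext length-2p external coefficient vector (originals first,
#'   knockoffs second), e.g. from [pooled_coefficients()] or the `coef` field
#'   of a [stat_lasso_coefdiff()] fit on external data.
#' @param eps positive offset bounding the weights above by `1/eps`
#'   (default 0.05).
#' @param include_knockoffs if `FALSE`, use only the original-variable
#'   coefficients `phi_j = 1/(eps + |b_j|)`; `coef_ext` may then have length
#'   p or 2p.
#' @return A length-p vector of strictly positive weights.
#' @examples
#' prior_weights(rep(0, 10)) # all equal to 20
#' @export
prior_weights <- function(coef_ext, eps = 0.05, include_knockoffs = TRUE) {
  coef_ext <- as.numeric(coef_ext)
  stopifnot(all(is.finite(coef_ext)), eps > 0)
  if (include_knockoffs) {
    if (length(coef_ext) %% 2 != 0) {
      stop("`coef_ext` must have even length (originals then knockoffs)")
    }
    p <- length(coef_ext) / 2
    1 / (eps + abs(coef_ext[seq_len(p)]) + abs(coef_ext[p + seq_len(p)]))
  } else {
    if (length(coef_ext) %% 2 == 0) {
      p <- length(coef_ext) / 2
      coef_ext <- coef_ext[seq_len(p)]
    }
    1 / (eps + abs(coef_ext))
  }
}

#' Weighted-lasso knockoff statistics with prior information
#'
#' Fits lasso models on the standardized augmented design with per-feature
#' penalties `lambda_j = (1 - gamma) * lambda + gamma * phi_j`, where the
#' prior weight `phi_j` is shared by the pair (j, j + p), and tunes
#' `(lambda, gamma)` by cross-validated prediction error on the target data.
#' At `gamma = 0` (or constant `phi`) this reduces exactly to
#' [stat_lasso_coefdiff()] at the same folds. Small `phi_j` on truly
#' important variables weakens their regularization and can increase power;
#' FDR control holds for arbitrary `phi` computed from external data (or from
#' pooled data when the null variables are shared across environments).
#'
#' The two-parameter penalty family is searched as one cross-validated glmnet
#' path per `gamma` with penalty factors `(1 - gamma) + gamma * phi_j`; the
#' union of these paths over the gamma grid spans the same set of per-feature
#' penalty vectors as the affine `(lambda, gamma)` parametrization. Ties in
#' cross-validated error are broken toward smaller `gamma` (less reliance on
#' the prior), then larger `lambda` (sparser model).
#'
#' @inheritParams stat_lasso_coefdiff
#' @param phi length-p vector of strictly positive prior weights, e.g. from
#'   [prior_weights()].
#' @param gamma_grid values of the prior-mixing parameter in \[0, 1\]
#'   (default `seq(0, 1, by = 0.1)`).
#' @param lambda,gamma supplying both fixes the tuning (no cross-validation);
#'   used for flip-sign verification.
#' @return A `"knockoff_stats"` object with the selected `(lambda, gamma)`.
#' @export
stat_weighted_lasso <- function(XXk, y, phi, gamma_grid = seq(0, 1, by = 0.1),
                                cv_folds = 10, seed = 1, lambda = NULL,
                                gamma = NULL, nlambda = 100,
                                family = "gaussian") {
  d <- check_design_outcome(XXk, y)
  phi <- as.numeric(phi)
  if (length(phi) != d$p) stop("`phi` must have length p = ", d$p)
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("`phi` entries must be strictly positive and finite")
  }
  if (any(gamma_grid < 0 | gamma_grid > 1)) stop("`gamma_grid` must lie in [0, 1]")
  Xs <- standardize_cols(d$XXk)
  pf_for <- function(g) (1 - g) + g * c(phi, phi)

  if (!is.null(lambda) && !is.null(gamma)) {
    if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
    fit <- glmnet(Xs, d$y, lambda = lambda, penalty.factor = pf_for(gamma),
                  standardize = FALSE, family = family, thresh = 1e-12)
    b <- coef_at(fit, lambda)
    W <- abs(b[seq_len(d$p)]) - abs(b[d$p + seq_len(d$p)])
    return(new_knockoff_stats(W, "weighted_lasso", lambda, gamma, coef = b))
  }

  foldid <- make_foldid(length(d$y), cv_folds, seed)
  best <- NULL
  for (g in sort(unique(gamma_grid))) {
    cvfit <- cv.glmnet(Xs, d$y, foldid = foldid, standardize = FALSE,
                       nlambda = nlambda, penalty.factor = pf_for(g),
                       family = family)
    err <- min(cvfit$cvm)
    if (is.null(best) || err < best$err - 1e-12) {
      best <- list(err = err, gamma = g, fit = cvfit)
    }
  }
  lam <- best$fit$lambda.min
  b <- coef_at(best$fit, lam)
  W <- abs(b[seq_len(d$p)]) - abs(b[d$p + seq_len(d$p)])
  new_knockoff_stats(W, "weighted_lasso", lam, best$gamma, coef = b)
}

#' Pooled-data lasso coefficients
#'
#' Row-concatenates augmented designs and outcomes from several environments
#' and fits one cross-validated lasso, returning the length-2p coefficient
#' vector. Used to build pooled prior weights for the weighted-lasso
#' statistics (valid when the null variables are shared across environments)
#' and as the predictive model behind the pooling benchmark.
#'
#' @param designs list of n_e x 2p augmented design matrices sharing p.
#' @param ys list of outcome vectors matching `designs`.
#' @inheritParams stat_lasso_coefdiff
#' @return A length-2p numeric coefficient vector (standardized scale).
#' @export
pooled_coefficients <- function(designs, ys, cv_folds = 10, seed = 1,
                                lambda = NULL, nlambda = 100,
                                family = "gaussian") {
  if (length(designs) == 0) stop("`designs` must be non-empty")
  if (length(designs) != length(ys)) stop("`designs` and `ys` lengths differ")
  ncols <- vapply(designs, ncol, integer(1))
  if (length(unique(ncols)) != 1) stop("all designs must share the same p")
  XX <- do.call(rbind, lapply(designs, as.matrix))
  y <- unlist(lapply(ys, as.numeric), use.names = FALSE)
  d <- check_design_outcome(XX, y)
  Xs <- standardize_cols(d$XXk)
  if (is.null(lambda)) {
    foldid <- make_foldid(length(d$y), cv_folds, seed)
    cvfit <- cv.glmnet(Xs, d$y, foldid = foldid, standardize = FALSE,
                       nlambda = nlambda, family = family)
    coef_at(cvfit, cvfit$lambda.min)
  } else {
    fit <- glmnet(Xs, d$y, lambda = lambda, standardize = FALSE,
                  family = family, thresh = 1e-12)
    coef_at(fit, lambda)
  }
}

#' Combine prior coefficient vectors from multiple sources
#'
#' Entrywise arithmetic mean of external coefficient vectors, e.g. from
#' analyses of several related phenotypes, producing a single prior for
#' [prior_weights()].
#'
#' @param coef_list non-empty list of equal-length numeric vectors.
#' @return A numeric vector of the common length.
#' @export
combine_priors <- function(coef_list) {
  if (!is.list(coef_list) || length(coef_list) == 0) {
    stop("`coef_list` must be a non-empty list")
  }
  lens <- vapply(coef_list, length, integer(1))
  if (length(unique(lens)) != 1) stop("all prior vectors must share one length")
  Reduce(`+`, lapply(coef_list, as.numeric)) / length(coef_list)
}
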