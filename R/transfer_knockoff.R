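#' FDR-controlled variable selection with transfer learning
#'
#' One-call interface to the package: samples Gaussian model-X knockoffs for
#' the target environment (and the external ones when needed), computes
#' lasso-based flip-sign statistics, applies the requested transfer-learning
#' method, and returns the FDR-controlled selection.
#'
#' Methods:
#' \describe{
#'   \item{`"vanilla"`}{standard knockoffs on the target data alone.}
#'   \item{`"lro"`}{linearly re-ordered statistics: target signs, magnitudes
#'     mixed with the pooled external statistics at weight `theta` (fixed a
#'     priori), then the threshold filter.}
#'   \item{`"adaptive"`}{adaptive knockoff filter ordered by an iteratively
#'     refit sign-prediction model using the external statistics as the prior
#'     column.}
#'   \item{`"wlasso"`}{weighted-lasso statistics with per-feature penalties
#'     from prior weights `phi` computed on the external data
#'     (`phi_source = "external"`) or on the pooled data of all environments
#'     (`phi_source = "pooled"`, valid when the null variables are shared).}
#' }
#'
#' The covariate law must be known for exact knockoffs: pass `Sigma` (with an
#' optional knockoff diagonal `s`) or `rho` for an AR(1) law. If neither is
#' given, the correlation matrix is estimated from all environments pooled and
#' the data are standardized; the resulting knockoffs are then approximate and
#' FDR control is no longer exact.
#'
#' @param X n x p target-environment design matrix.
#' @param y length-n target outcome.
#' @param X_ext,y_ext external environments: a matrix/vector or a list of
#'   them. Required for every method except `"vanilla"`.
#' @param method one of `"adaptive"`, `"lro"`, `"wlasso"`, `"vanilla"`.
#' @param q nominal FDR level (default 0.1).
#' @param offset filter offset, 0 or 1 (default 1, provable FDR control).
#' @param Sigma optional known p x p covariate covariance.
#' @param rho optional AR(1) correlation (builds `Sigma` automatically).
#' @param s optional knockoff diagonal for `Sigma`.
#' @param theta mixing weight for `method = "lro"` (fix before seeing data).
#' @param gamma_grid prior-mixing grid for `method = "wlasso"`.
#' @param ordering_model `"logistic"` or `"fixed_linear"` for
#'   `method = "adaptive"`.
#' @param phi_source `"pooled"` or `"external"` for `method = "wlasso"`.
#' @param cv_folds,nlambda lasso cross-validation controls.
#' @param family `"gaussian"` or `"binomial"` outcome model.
#' @param seed master seed; knockoff draws and fold assignments derive from it.
#' @return An object of class `"transfer_knockoff"` with `print`, `summary`,
#'   `coef` and `plot` methods. Fields include `selected` (indices),
#'   `variables` (names of selected variables), `W` (the statistics actually
#'   filtered), `W0`, `Wext`, `phi`, and the full `selection`.
#' @examples
#' cfg <- sim_config(p = 60, n = 150, n_signals = 8, cv_folds = 5, nlambda = 50)
#' d <- generate_environments(cfg, seed = 7)
#' fit <- transfer_knockoff(d$envs[[1]]$X, d$envs[[1]]$y,
#'                          X_ext = lapply(d$envs[-1], `[[`, "X"),
#'                          y_ext = lapply(d$envs[-1], `[[`, "y"),
#'                          method = "lro", theta = 0.1, rho = 0.5, seed = 7,
#'                          cv_folds = 5, nlambda = 50)
#' print(fit)
#' @export
transfer_knockoff <- function(X, y, X_ext = NULL, y_ext = NULL,
                              method = c("adaptive", "lro", "wlasso", "vanilla"),
                              q = 0.1, offset = 1, Sigma = NULL, rho = NULL,
                              s = NULL, theta = 0.1,
                              gamma_grid = seq(0, 1, by = 0.1),
                              ordering_model = "logistic",
                              phi_source = c("pooled", "external"),
                              cv_folds = 10, nlambda = 100,
                              family = "gaussian", seed = 1) {
  method <- match.arg(method)
  phi_source <- match.arg(phi_source)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.matrix(X_ext)) X_ext <- list(X_ext)
  if (is.numeric(y_ext)) y_ext <- list(y_ext)
  n_ext <- length(X_ext)
  if (method != "vanilla" && n_ext == 0) {
    stop("method '", method, "' requires external environments")
  }
  vn <- colnames(X)
  if (is.null(vn)) vn <- paste0("X", seq_len(p))

  exact <- TRUE
  if (is.null(Sigma) && !is.null(rho)) Sigma <- ar1_covariance(p, rho)
  if (is.null(Sigma)) {
    pooledX <- do.call(rbind, c(list(X), X_ext))
    Sigma <- stats::cor(pooledX)
    X <- standardize_cols(X)
    X_ext <- lapply(X_ext, standardize_cols)
    exact <- FALSE
    message("covariate law estimated from the data; knockoffs are approximate")
  }
  model <- gaussian_model(Sigma, s = s, rho = rho)

  XXk <- create_knockoffs(X, model, seed = child_seed(seed, 2L, 1L))
  W0 <- stat_lasso_coefdiff(XXk, y, cv_folds = cv_folds,
                            seed = child_seed(seed, 3L), nlambda = nlambda,
                            family = family)

  ext <- NULL
  designs_ext <- NULL
  if (n_ext > 0 && method != "vanilla") {
    designs_ext <- lapply(seq_len(n_ext), function(e) {
      create_knockoffs(as.matrix(X_ext[[e]]), model,
                       seed = child_seed(seed, 2L, e + 1L))
    })
    ext <- stat_lasso_coefdiff(do.call(rbind, designs_ext),
                               unlist(y_ext, use.names = FALSE),
                               cv_folds = cv_folds,
                               seed = child_seed(seed, 4L), nlambda = nlambda,
                               family = family)
  }

  phi <- NULL
  W <- W0
  selection <- switch(method,
    vanilla = knockoff_threshold(W0, q = q, offset = offset),
    lro = {
      W <- linear_reorder(W0, ext$W, theta)
      knockoff_threshold(W, q = q, offset = offset)
    },
    adaptive = adaptive_filter(W0, ext$W, q = q, offset = offset,
                               model = ordering_model,
                               seed = child_seed(seed, 7L)),
    wlasso = {
      bcoef <- if (phi_source == "external") {
        ext$coef
      } else {
        pooled_coefficients(c(list(XXk), designs_ext), c(list(y), y_ext),
                            cv_folds = cv_folds, seed = child_seed(seed, 5L),
                            nlambda = nlambda, family = family)
      }
      phi <- prior_weights(bcoef)
      W <- stat_weighted_lasso(XXk, y, phi, gamma_grid = gamma_grid,
                               cv_folds = cv_folds, seed = child_seed(seed, 3L),
                               nlambda = nlambda, family = family)
      knockoff_threshold(W, q = q, offset = offset)
    }
  )

  structure(
    list(call = match.call(), method = method, q = q, offset = offset,
         exact_knockoffs = exact, W = W, W0 = W0, Wext = ext, phi = phi,
         selection = selection, selected = selection$selected,
         variables = vn[selection$selected], variable_names = vn,
         p = p, n = nrow(X), n_ext = n_ext),
    class = "transfer_knockoff"
  )
}

#' @export
print.transfer_knockoff <- function(x, ...) {
  cat("Transfer-learning knockoff selection\n")
  cat("  method:", x$method, " q =", x$q, " offset =", x$offset,
      if (!x$exact_knockoffs) " (approximate knockoffs)", "\n")
  cat("  target: n =", x$n, ", p =", x$p, "; external environments:",
      x$n_ext, "\n")
  cat("  selected", length(x$selected), "variables")
  if (length(x$selected)) {
    cat(":", paste(utils::head(x$variables, 15), collapse = " "),
        if (length(x$selected) > 15) "...")
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.transfer_knockoff <- function(object, ...) {
  W <- as_W(object$W)
  tab <- data.frame(variable = object$variable_names, W = W,
                    selected = seq_along(W) %in% object$selected)
  tab <- tab[order(-abs(tab$W)), ]
  structure(list(fit = object, table = tab),
            class = "summary.transfer_knockoff")
}

#' @export
print.summary.transfer_knockoff <- function(x, n = 10, ...) {
  print(x$fit)
  cat("\nTop statistics:\n")
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' @export
coef.transfer_knockoff <- function(object, ...) {
  b <- object$W$coef
  if (is.null(b)) b <- object$W0$coef # lro/adaptive reuse the target-model fit
  if (is.null(b)) return(NULL)
  names(b) <- c(object$variable_names, paste0(object$variable_names, ".k"))
  b
}

#' @export
plot.transfer_knockoff <- function(x, ...) {
  W <- as_W(x$W)
  col <- ifelse(seq_along(W) %in% x$selected, "firebrick", "grey40")
  graphics::plot(seq_along(W), W, col = col, pch = 16, cex = 0.6,
                 xlab = "variable index", ylab = "knockoff statistic W", ...)
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(x$selection$threshold) && is.finite(x$selection$threshold)) {
    graphics::abline(h = x$selection$threshold, lty = 2)
  }
  invisible(x)
}
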