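#' Linearly re-ordered knockoff statistics
#'
#' Combines target-environment statistics `W0` with external-environment
#' statistics `Wext` into `W_lro` keeping the target signs:
#' `sign(W_lro_j) = sign(W0_j)` and
#' `|W_lro_j| = (1 - theta) * |W0_j| + theta * |Wext_j|`
#' (zero stays zero). Because the external data only rescales magnitudes, the
#' null signs remain i.i.d. coin flips and the standard
#' [knockoff_threshold()] applied to `W_lro` controls the target-environment
#' FDR. `theta` must be fixed before looking at the data; `theta = 0` returns
#' `W0` unchanged.
#'
#' @param W0 length-p target statistics (vector or `"knockoff_stats"`).
#' @param Wext length-p external statistics.
#' @param theta mixing weight in \[0, 1\] on the external magnitudes.
#' @return A `"knockoff_stats"` object with the combined statistics.
#' @examples
#' linear_reorder(c(2, -1), c(4, 6), theta = 0.5)$W # 3, -3.5
#' @export
linear_reorder <- function(W0, Wext, theta) {
  W0 <- as_W(W0)
  Wext <- as_W(Wext)
  if (length(W0) != length(Wext)) stop("`W0` and `Wext` lengths differ")
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    stop("`theta` must be a single value in [0, 1]")
  }
  W <- sign(W0) * ((1 - theta) * abs(W0) + theta * abs(Wext))
  W[W0 == 0] <- 0
  new_knockoff_stats(W, sprintf("linear_reorder(theta=%g)", theta),
                     NA_real_, theta)
}

# Ridge-regularised logistic fit of P(sign = -1) on revealed hypotheses.
# Returns a scoring function over rows of `feats`, or NULL when the fit is
# degenerate (single class, too few points, or solver failure).
fit_sign_model <- function(feats, is_neg, ridge = 1e-4) {
  if (length(is_neg) < 2 || length(unique(is_neg)) < 2) return(NULL)
  fit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(feats, factor(is_neg, levels = c(FALSE, TRUE)),
                     family = "binomial", alpha = 0, lambda = ridge,
                     standardize = TRUE)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  beta <- as.numeric(stats::coef(fit, s = ridge))
  function(newx) drop(cbind(1, newx) %*% beta)
}

#' Adaptive knockoff filter with transfer-learning side information
#'
#' Runs the sequential knockoff filter over a data-adaptive hypothesis
#' ordering learned from side information. Starting with all hypotheses
#' unrevealed, the procedure repeatedly reveals the hypothesis currently
#' deemed most likely to carry a negative statistic, using only the
#' magnitudes `|W0|`, the prior columns, and the signs of already-revealed
#' statistics (never the unrevealed signs, which is what preserves FDR
#' control). Revealed hypotheses occupy the front of the testing sequence, so
#' likely-positive statistics accumulate at the end; the resulting ordering is
#' passed to [sequential_filter()].
#'
#' Two ordering models are shipped. `"fixed_linear"` scores hypothesis j by
#' `-((1 - theta) * |W0_j| + theta * prior_j)` (smallest combined magnitude
#' revealed first), which makes the procedure identical to the linear
#' re-ordering method at fixed `theta`. `"logistic"` refits, every `batch`
#' reveals, a ridge-regularized logistic regression of the revealed signs on
#' `(|W0|, prior columns)` and reveals the unrevealed hypothesis with the
#' highest predicted probability of a negative sign; degenerate fits (fewer
#' than `2 * batch` reveals, all revealed signs equal, or solver failure) fall
#' back to the fixed-linear score and are recorded in the trace. A custom
#' model can be plugged in as a function `(feats, is_neg) -> score function`.
#'
#' @param W0 length-p target statistics (vector or `"knockoff_stats"`).
#' @param prior length-p vector or p x K matrix of prior columns, e.g.
#'   external statistics `Wext` (one column per source).
#' @param q nominal FDR level.
#' @param offset 0 or 1 (default 1).
#' @param model `"logistic"` (default), `"fixed_linear"`, or a function
#'   `(feats, is_neg)` returning a scoring function (or NULL when degenerate).
#' @param theta weight of the first prior column in the fixed-linear score and
#'   in the pre-reveal fallback (default 0.5, the uninformed midpoint).
#' @param batch refit the sign model every `batch` reveals (default 10;
#'   `batch = 1` is fully sequential).
#' @param seed integer seed (reserved for randomized ordering models; the
#'   shipped models are deterministic).
#' @return A `"knockoff_selection"` whose `trace` data frame records, per
#'   reveal, the hypothesis revealed and the ordering model in force.
#' @export
adaptive_filter <- function(W0, prior, q = 0.1, offset = 1,
                            model = c("logistic", "fixed_linear"),
                            theta = 0.5, batch = 10, seed = 1) {
  W0 <- as_W(W0)
  p <- length(W0)
  prior <- as.matrix(prior)
  if (nrow(prior) != p) stop("`prior` must have one row (or entry) per hypothesis")
  if (batch < 1 || batch != round(batch)) stop("`batch` must be a positive integer")
  model_fun <- if (is.function(model)) model else NULL
  if (!is.function(model)) model <- match.arg(model)

  absW <- abs(W0)
  feats <- cbind(absW0 = absW, prior)
  # fixed-linear fallback: smallest combined magnitude first (index-stable ties)
  fl_score <- (1 - theta) * absW + theta * abs(feats[, 2])
  min_reveals <- 2 * batch

  revealed <- integer(0)
  unrevealed <- seq_len(p)
  scores <- NULL # predicted logit of P(sign negative), higher = reveal sooner
  label <- "init"
  trace <- data.frame(step = seq_len(p), revealed = NA_integer_,
                      model = NA_character_)
  set.seed(seed)

  for (k in seq_len(p)) {
    refit <- (length(revealed) >= min_reveals) &&
      (length(revealed) %% batch == 0 || is.null(scores))
    if (refit && (is.function(model_fun) || model == "logistic")) {
      signs_rev <- W0[revealed]
      train <- revealed[signs_rev != 0]
      fitter <- if (is.function(model_fun)) model_fun else fit_sign_model
      sf <- fitter(feats[train, , drop = FALSE], W0[train] < 0)
      if (is.null(sf)) {
        scores <- NULL
        label <- "fallback"
      } else {
        scores <- sf(feats)
        label <- if (is.function(model_fun)) "custom" else "logistic"
      }
    }
    if (!is.function(model_fun) && model == "fixed_linear") label <- "fixed_linear"
    cur <- if (is.null(scores) || label %in% c("init", "fallback", "fixed_linear")) {
      -fl_score
    } else {
      scores
    }
    pick <- unrevealed[order(-cur[unrevealed], unrevealed)[1]]
    revealed <- c(revealed, pick)
    unrevealed <- setdiff(unrevealed, pick)
    trace$revealed[k] <- pick
    trace$model[k] <- label
  }

  res <- sequential_filter(W0, revealed, q = q, offset = offset)
  res$trace <- trace
  res
}
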