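new_selection <- function(selected, threshold, fdphat_path, ordering, stop_k,
                          q, offset, W, trace = NULL) {
  structure(
    list(selected = selected, threshold = threshold,
         fdphat_path = fdphat_path, ordering = ordering, stop_k = stop_k,
         q = q, offset = offset, W = W, trace = trace),
    class = "knockoff_selection"
  )
}

#' @export
print.knockoff_selection <- function(x, ...) {
  cat("Knockoff selection: ", length(x$selected), " of ", length(x$W),
      " hypotheses rejected (q = ", x$q, ", offset = ", x$offset, ")\n",
      sep = "")
  if (!is.null(x$threshold)) {
    cat("  threshold:", format(x$threshold, digits = 4), "\n")
  } else {
    cat("  stopping step k =", x$stop_k, "\n")
  }
  if (length(x$selected)) {
    cat("  selected:", paste(utils::head(x$selected, 20), collapse = " "),
        if (length(x$selected) > 20) "...", "\n")
  }
  invisible(x)
}

#' Canonical ascending-magnitude ordering for the sequential filter
#'
#' Returns the hypothesis ordering under which [sequential_filter()]
#' reproduces [knockoff_threshold()] exactly: ascending `|W|`, and within a
#' group of tied magnitudes positive statistics first, remaining ties broken
#' by original index. Placing tied positives before tied negatives makes
#' every cut inside a tie group dominated by the cut at the group boundary,
#' so the equivalence with the threshold filter holds even when magnitudes
#' tie (as lasso statistics routinely do at zero). For distinct magnitudes
#' any tie rule gives the same result.
#'
#' @param W statistic vector (or `"knockoff_stats"` object).
#' @return A permutation of `1:length(W)`.
#' @export
threshold_ordering <- function(W) {
  W <- as_W(W)
  order(abs(W), -sign(W), seq_along(W))
}

check_filter_config <- function(q, offset) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("`q` must be strictly between 0 and 1")
  }
  if (!offset %in% c(0, 1)) stop("`offset` must be 0 or 1")
  if (offset == 0) {
    warning("offset = 0 does not theoretically control the FDR ",
            "when the number of discoveries is very small", call. = FALSE)
  }
  invisible(NULL)
}

#' Knockoff threshold filter
#'
#' Computes the data-dependent significance threshold
#' `T = min{ t : (offset + #\{j: W_j <= -t\}) / max(#\{j: W_j >= t\}, 1) <= q }`
#' over the candidate grid `t` in the positive values of `|W|`, and rejects
#' all hypotheses with `W_j >= T`. When no candidate satisfies the bound the
#' threshold is `+Inf` and nothing is rejected. Zero statistics are never
#' rejected and `t = 0` is not a candidate. With `offset = 1` this controls
#' the FDR at level `q` whenever the signs of the null statistics are i.i.d.
#' coin flips given their magnitudes.
#'
#' @param W length-p statistic vector (or a `"knockoff_stats"` object).
#' @param q nominal FDR level, strictly in (0, 1).
#' @param offset 0 or 1 (default 1; 1 gives provable FDR control).
#' @return A `"knockoff_selection"` with fields `selected` (indices),
#'   `threshold`, and `fdphat_path` (estimated FDP at each candidate t).
#' @examples
#' knockoff_threshold(c(3, -1, 2, -2, 5), q = 0.5)
#' @export
knockoff_threshold <- function(W, q = 0.1, offset = 1) {
  W <- as_W(W)
  stopifnot(all(is.finite(W)))
  check_filter_config(q, offset)
  ts <- sort(unique(abs(W[W != 0])))
  if (length(ts) == 0) {
    return(new_selection(integer(0), Inf, numeric(0), threshold_ordering(W),
                         NA_integer_, q, offset, W))
  }
  fdphat <- vapply(ts, function(t) {
    (offset + sum(W <= -t)) / max(sum(W >= t), 1)
  }, numeric(1))
  ok <- which(fdphat <= q)
  threshold <- if (length(ok)) ts[min(ok)] else Inf
  selected <- if (is.finite(threshold)) which(W >= threshold) else integer(0)
  new_selection(selected, threshold, fdphat, threshold_ordering(W),
                NA_integer_, q, offset, W)
}

#' Sequential (FDP-hat) knockoff filter
#'
#' Equivalent reformulation of the knockoff filter as a sequential procedure
#' over an ordering `pi` of the hypotheses: for k = 0, 1, ..., p-1 compute
#' `FDPhat_k = (offset + #\{j > k: W_pi_j < 0\}) / max(#\{j > k: W_pi_j > 0\}, 1)`
#' and stop at the smallest k with `FDPhat_k <= q`, rejecting every hypothesis
#' past the stopping step whose statistic is positive. With the ordering by
#' ascending `|W|` this reproduces [knockoff_threshold()] exactly; FDR control
#' extends to data-dependent orderings that never look at unrevealed signs,
#' which is what the transfer-learning methods exploit.
#'
#' @inheritParams knockoff_threshold
#' @param ordering a permutation of `1:p`; hypotheses early in the ordering
#'   are excluded from the rejection set first.
#' @return A `"knockoff_selection"` with the stopping step `stop_k` (NA if no
#'   step qualifies), the full `fdphat_path`, and the ordering used.
#' @export
sequential_filter <- function(W, ordering, q = 0.1, offset = 1) {
  W <- as_W(W)
  stopifnot(all(is.finite(W)))
  check_filter_config(q, offset)
  p <- length(W)
  if (length(ordering) != p || !setequal(ordering, seq_len(p))) {
    stop("`ordering` must be a permutation of 1:p")
  }
  Wpi <- W[ordering]
  # reverse cumulative counts: neg[k+1] = #{j > k : W_pi_j < 0}, k = 0..p-1
  neg_tail <- rev(cumsum(rev(Wpi < 0)))
  pos_tail <- rev(cumsum(rev(Wpi > 0)))
  fdphat <- (offset + neg_tail) / pmax(pos_tail, 1)
  ok <- which(fdphat <= q)
  if (length(ok) == 0) {
    return(new_selection(integer(0), NULL, fdphat, ordering, NA_integer_,
                         q, offset, W))
  }
  k <- min(ok) - 1L # fdphat[1] corresponds to k = 0
  tail_idx <- if (k < p) ordering[(k + 1L):p] else integer(0)
  selected <- sort(tail_idx[W[tail_idx] > 0])
  new_selection(selected, NULL, fdphat, ordering, k, q, offset, W)
}
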