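#' Derive a child seed from a master seed
#'
#' Deterministic counter-based splitting rule used everywhere the package
#' needs several independent random streams (one per environment, replicate,
#' or purpose). Mixing is a fixed linear-congruential fold over the id
#' sequence, so any single unit of work (e.g. one replicate of one overlap
#' level) is reproducible in isolation from `(master_seed, ids...)` alone.
#'
#' @param master integer master seed.
#' @param ... integer identifiers (replicate number, environment id, a purpose
#'   code, ...). Order matters.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(42, 3, 1) # replicate 3, purpose 1
#' @export
child_seed <- function(master, ...) {
  ids <- c(master, ...)
  stopifnot(all(is.finite(ids)))
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- 0
  for (k in ids) {
    s <- (s * 69069 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}
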