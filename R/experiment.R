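parse_method <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  name <- parts[1]
  param <- if (length(parts) > 1) parts[2] else NA_character_
  known <- c("vanilla", "pooling", "lro", "lro_oracle", "adaptive", "wlasso")
  if (!name %in% known) {
    stop("unknown method '", name, "'; expected one of ",
         paste(known, collapse = ", "))
  }
  list(spec = spec, name = name, param = param)
}

#' Run one replicate of the multi-environment experiment
#'
#' Generates one dataset from `config`, samples Gaussian knockoffs in every
#' environment (from the true covariate law), computes the shared ingredients
#' each requested method needs — target statistics `W0`, external statistics
#' `Wext` from the pooled external environments, prior weights `phi` from a
#' lasso on the pooled data of all environments — and scores every method's
#' selection against the target support `S0`.
#'
#' Method specifications are strings: `"vanilla"`, `"pooling"`,
#' `"lro:<theta>"`, `"lro_oracle"` (per-replicate theta maximizing the
#' discovery count over `config$theta_grid`; not FDR-guaranteed),
#' `"adaptive:logistic"`, `"adaptive:fixed_linear"`, `"wlasso:pooled"`,
#' `"wlasso:external"`. The pooling benchmark is deliberately scored against
#' `S0` as well: it tests whether a variable is non-null in *any* environment,
#' which is exactly why it can violate the target-environment FDR.
#'
#' @param config a [sim_config()].
#' @param methods character vector of method specifications.
#' @param seed replicate-level integer seed; all internal randomness (data,
#'   knockoffs, folds) is derived from it by [child_seed()].
#' @param offset knockoff filter offset (default 1).
#' @param model optional precomputed [gaussian_model()] for the AR(1) law
#'   (saves repeated factorizations across replicates).
#' @return A data frame with one row per method: `method`, `fdp`, `power`,
#'   `n_selected`, `fdr_guaranteed`.
#' @export
run_replicate <- function(config, methods, seed = 1, offset = 1, model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  specs <- lapply(methods, parse_method)
  if (is.null(model)) {
    model <- gaussian_model(ar1_covariance(config$p, config$rho),
                            rho = config$rho)
  }
  dat <- generate_environments(config, child_seed(seed, 1L))
  S0 <- dat$truth$supports[[1]]
  designs <- lapply(seq_along(dat$envs), function(e) {
    create_knockoffs(dat$envs[[e]]$X, model, seed = child_seed(seed, 2L, e))
  })
  ys <- lapply(dat$envs, `[[`, "y")

  names_ <- vapply(specs, `[[`, "", "name")
  needs_ext <- any(names_ %in% c("lro", "lro_oracle", "adaptive")) ||
    any(names_ == "wlasso" & vapply(specs, `[[`, "", "param") == "external")
  n_ext <- length(dat$envs) - 1
  if (needs_ext && n_ext < 1) stop("transfer methods require external environments")

  W0 <- stat_lasso_coefdiff(designs[[1]], ys[[1]],
                            cv_folds = config$cv_folds,
                            seed = child_seed(seed, 3L),
                            nlambda = config$nlambda)
  ext <- NULL
  if (needs_ext) {
    ext <- stat_lasso_coefdiff(do.call(rbind, designs[-1]),
                               unlist(ys[-1], use.names = FALSE),
                               cv_folds = config$cv_folds,
                               seed = child_seed(seed, 4L),
                               nlambda = config$nlambda)
  }
  b_pool <- NULL
  if (any(names_ == "wlasso" &
          vapply(specs, `[[`, "", "param") %in% c("pooled", NA_character_))) {
    b_pool <- pooled_coefficients(designs, ys, cv_folds = config$cv_folds,
                                  seed = child_seed(seed, 5L),
                                  nlambda = config$nlambda)
  }

  one <- function(sp) {
    sel <- switch(sp$name,
      vanilla = knockoff_threshold(W0, q = config$q, offset = offset),
      pooling = {
        Wp <- stat_lasso_coefdiff(do.call(rbind, designs),
                                  unlist(ys, use.names = FALSE),
                                  cv_folds = config$cv_folds,
                                  seed = child_seed(seed, 6L),
                                  nlambda = config$nlambda)
        knockoff_threshold(Wp, q = config$q, offset = offset)
      },
      lro = {
        theta <- as.numeric(sp$param)
        knockoff_threshold(linear_reorder(W0, ext$W, theta),
                           q = config$q, offset = offset)
      },
      lro_oracle = {
        sels <- lapply(config$theta_grid, function(th) {
          knockoff_threshold(linear_reorder(W0, ext$W, th),
                             q = config$q, offset = offset)
        })
        sels[[which.max(vapply(sels, function(s) length(s$selected), 0))]]
      },
      adaptive = {
        m <- if (is.na(sp$param)) "logistic" else sp$param
        adaptive_filter(W0, ext$W, q = config$q, offset = offset, model = m,
                        seed = child_seed(seed, 7L))
      },
      wlasso = {
        src <- if (is.na(sp$param)) "pooled" else sp$param
        bcoef <- switch(src, pooled = b_pool, external = ext$coef,
                        stop("unknown phi source '", src, "'"))
        phi <- prior_weights(bcoef)
        Wwl <- stat_weighted_lasso(designs[[1]], ys[[1]], phi,
                                   gamma_grid = config$gamma_grid,
                                   cv_folds = config$cv_folds,
                                   seed = child_seed(seed, 3L),
                                   nlambda = config$nlambda)
        knockoff_threshold(Wwl, q = config$q, offset = offset)
      }
    )
    fp <- fdp_power(sel$selected, S0)
    data.frame(method = sp$spec, fdp = fp[["fdp"]], power = fp[["power"]],
               n_selected = length(sel$selected),
               fdr_guaranteed = !(sp$name %in% c("pooling", "lro_oracle")))
  }
  do.call(rbind, lapply(specs, one))
}

#' Run the full overlap-sweep experiment
#'
#' Maps [run_replicate()] over an `(overlap, replicate)` grid with
#' deterministic child seeds, so the summary is independent of execution
#' order. A failed replicate aborts the run with its `(overlap, rep, seed)`
#' context; replicates are never silently dropped.
#'
#' @inheritParams run_replicate
#' @param overlap_grid overlap levels to sweep (default `config$overlap`).
#' @param reps replicates per overlap level.
#' @param seed master seed.
#' @param verbose print progress (default FALSE).
#' @return An object of class `"knockoff_experiment"`: list with `results`
#'   (one row per method x overlap x replicate) and `summary` (mean FDP and
#'   power with Monte-Carlo standard errors per method x overlap).
#' @export
run_experiment <- function(config, methods, overlap_grid = config$overlap,
                           reps = 10, seed = 1, offset = 1, verbose = FALSE) {
  stopifnot(reps >= 1, all(overlap_grid >= 0 & overlap_grid <= 1))
  model <- gaussian_model(ar1_covariance(config$p, config$rho),
                          rho = config$rho)
  rows <- list()
  for (ov in overlap_grid) {
    cfg <- config
    cfg$overlap <- ov
    for (r in seq_len(reps)) {
      rep_seed <- child_seed(seed, as.integer(round(1000 * ov)), r)
      res <- tryCatch(
        run_replicate(cfg, methods, seed = rep_seed, offset = offset,
                      model = model),
        error = function(e) {
          stop("replicate failed (overlap = ", ov, ", rep = ", r,
               ", seed = ", rep_seed, "): ", conditionMessage(e),
               call. = FALSE)
        }
      )
      res$overlap <- ov
      res$rep <- r
      rows[[length(rows) + 1]] <- res
      if (verbose) {
        message(sprintf("overlap %.2f rep %d/%d done", ov, r, reps))
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- function(v) {
    stats::aggregate(results[[v]],
                     by = list(method = results$method, overlap = results$overlap),
                     FUN = function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
                                         n = length(x)))
  }
  fd <- agg("fdp")
  pw <- agg("power")
  summary <- data.frame(
    method = fd$method, overlap = fd$overlap,
    fdp_mean = fd$x[, "mean"], fdp_se = fd$x[, "se"],
    power_mean = pw$x[, "mean"], power_se = pw$x[, "se"],
    reps = as.integer(fd$x[, "n"])
  )
  structure(list(results = results, summary = summary, config = config,
                 methods = methods, seed = seed, offset = offset),
            class = "knockoff_experiment")
}

#' @export
print.knockoff_experiment <- function(x, digits = 3, ...) {
  cat("Multi-environment knockoff experiment:",
      length(unique(x$results$rep)), "replicates x",
      length(unique(x$results$overlap)), "overlap level(s), q =",
      x$config$q, "\n\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.knockoff_experiment <- function(x, which = c("power", "fdp"), ...) {
  which <- match.arg(which)
  s <- x$summary
  col <- paste0(which, "_mean")
  methods <- unique(s$method)
  graphics::plot(range(s$overlap), range(c(0, s[[col]])), type = "n",
                 xlab = "support overlap", ylab = paste("mean", toupper(which)),
                 ...)
  for (i in seq_along(methods)) {
    si <- s[s$method == methods[i], ]
    si <- si[order(si$overlap), ]
    graphics::lines(si$overlap, si[[col]], col = i, type = "b", pch = i)
  }
  if (which == "fdp") graphics::abline(h = x$config$q, lty = 2)
  graphics::legend("topleft", legend = methods, col = seq_along(methods),
                   pch = seq_along(methods), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
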