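small_cfg <- function(n = 150, ...) {
  sim_config(p = 60, n = n, n_signals = 8, cv_folds = 5, nlambda = 40,
             gamma_grid = c(0, 0.5, 1), theta_grid = c(0, 0.5, 1),
             overlap = 1, ...)
}

test_that("theta = 0 re-ordering and gamma = 0 weighted lasso reduce to vanilla", {
  cfg <- small_cfg()
  cfg$gamma_grid <- 0
  res <- run_replicate(cfg, c("vanilla", "lro:0", "wlasso:pooled"), seed = 17)
  expect_equal(res$fdp[res$method == "lro:0"], res$fdp[res$method == "vanilla"])
  expect_equal(res$n_selected[res$method == "lro:0"],
               res$n_selected[res$method == "vanilla"])
  expect_equal(res$fdp[res$method == "wlasso:pooled"],
               res$fdp[res$method == "vanilla"])
  expect_equal(res$n_selected[res$method == "wlasso:pooled"],
               res$n_selected[res$method == "vanilla"])
})

test_that("as q -> 0 every method returns an empty selection", {
  cfg <- small_cfg(q = 1e-6)
  res <- run_replicate(cfg, c("vanilla", "pooling", "lro:0.3",
                              "adaptive:logistic", "wlasso:pooled"), seed = 2)
  expect_true(all(res$n_selected == 0))
  expect_true(all(res$fdp == 0))
  expect_true(all(res$power == 0))
})

test_that("benchmarks without guarantees are flagged", {
  cfg <- small_cfg()
  res <- run_replicate(cfg, c("vanilla", "pooling", "lro_oracle"), seed = 3)
  expect_identical(res$fdr_guaranteed, c(TRUE, FALSE, FALSE))
  expect_error(run_replicate(cfg, "nonsense"), "unknown method")
})

test_that("the experiment summary is deterministic and matches single replicates", {
  cfg <- small_cfg()
  exp1 <- run_experiment(cfg, c("vanilla", "lro:0.5"), overlap_grid = 0.5,
                         reps = 1, seed = 7)
  direct <- run_replicate({cfg2 <- cfg; cfg2$overlap <- 0.5; cfg2},
                          c("vanilla", "lro:0.5"),
                          seed = child_seed(7, 500L, 1L))
  expect_equal(exp1$summary$fdp_mean, direct$fdp)
  expect_equal(exp1$summary$power_mean, direct$power)
  expect_equal(exp1$summary$reps, c(1L, 1L))

  exp2 <- run_experiment(cfg, c("vanilla", "lro:0.5"), overlap_grid = 0.5,
                         reps = 1, seed = 7)
  expect_identical(exp1$results, exp2$results)
})

test_that("the one-call interface runs every method and reports its selection", {
  cfg <- small_cfg(n = 120)
  d <- generate_environments(cfg, seed = 23)
  Xe <- lapply(d$envs[-1], `[[`, "X")
  ye <- lapply(d$envs[-1], `[[`, "y")
  for (m in c("vanilla", "lro", "adaptive", "wlasso")) {
    fit <- transfer_knockoff(d$envs[[1]]$X, d$envs[[1]]$y, X_ext = Xe,
                             y_ext = ye, method = m, rho = 0.5, seed = 23,
                             cv_folds = 5, nlambda = 40,
                             gamma_grid = c(0, 0.5, 1))
    expect_s3_class(fit, "transfer_knockoff")
    expect_identical(fit$selected, fit$selection$selected)
    expect_output(print(fit), m)
    s <- summary(fit)
    expect_equal(nrow(s$table), cfg$p)
    if (m != "adaptive") {
      b <- coef(fit)
      expect_length(b, 2 * cfg$p)
    }
  }
  expect_error(transfer_knockoff(d$envs[[1]]$X, d$envs[[1]]$y, method = "lro"),
               "external")
  # unknown covariate law: estimated, flagged as approximate
  expect_message(
    fit_est <- transfer_knockoff(d$envs[[1]]$X, d$envs[[1]]$y, X_ext = Xe,
                                 y_ext = ye, method = "vanilla", seed = 23,
                                 cv_folds = 5, nlambda = 40),
    "approximate")
  expect_false(fit_est$exact_knockoffs)
})
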