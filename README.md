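# knockofftl: transfer learning with model-X knockoffs

`knockofftl` selects variables associated with an outcome in a **target
environment** — a population, study, or phenotype of interest — while
borrowing strength from **external environments**, with finite-sample false
discovery rate (FDR) control. The motivating use case is genetic association
analysis for under-represented populations: most GWAS data come from European
ancestry cohorts, and one wants to leverage that information to find the
variants relevant to a smaller minority cohort without importing the larger
cohort's false positives.

## The method

For each environment *e*, model-X knockoffs augment the design `X^e` with
synthetic copies `X~^e`, sampled from the known covariate law without looking
at the outcome, such that swapping any variable with its knockoff leaves the
joint covariate distribution unchanged. A flip-sign statistic

  `W_j = |b̂_j| − |b̂_{j+p}|`

(from a cross-validated lasso of `y` on the standardized `[X, X~]`) measures
how much more predictive each variable is than its own negative control. The
knockoff filter rejects `{j : W_j ≥ T}` at the data-dependent threshold

  `T = min{ t : (1 + #{j: W_j ≤ −t}) / max(#{j: W_j ≥ t}, 1) ≤ q }`,

which controls the FDR at level `q` because null statistics have i.i.d.
coin-flip signs. An equivalent sequential form orders the hypotheses and
stops at the first step k where the running FDP estimate drops below `q`.

Three transfer-learning strategies use external data without breaking the
coin-flip property of the target nulls:

- **Linear re-ordering** (`method = "lro"`): keep the target signs, mix the
  magnitudes, `|W_lro| = (1−θ)|W⁰| + θ|W^ext|`, with θ fixed a priori; filter
  with the standard threshold.
- **Adaptive filter** (`method = "adaptive"`): run the sequential filter over
  an ordering learned on the fly by a logistic model of the revealed
  statistic signs on `(|W⁰|, W^ext)`, refit as signs are revealed — the
  ordering never peeks at unrevealed target signs.
- **Weighted lasso** (`method = "wlasso"`): refit the target model with
  per-feature penalties `λ_j = (1−γ)λ + γφ_j`, where
  `φ_j = 1/(0.05 + |b̂_j^ext| + |b̂_{j+p}^ext|)` downweights the penalty on
  variables that external (or pooled) data flag as promising; `(λ, γ)` are
  tuned by cross-validation, so useless priors fall back to `γ ≈ 0`.

## Worked example

Simulate three environments (AR(1) covariates with ρ = 0.5, sparse linear
outcomes, fully shared support) and analyze the target with and without
transfer learning:

```r
library(knockofftl)

cfg <- sim_config(p = 150, n = 250, n_signals = 18, overlap = 1,
                  cv_folds = 5, nlambda = 50, gamma_grid = seq(0, 1, 0.25))
dat <- generate_environments(cfg, seed = 7)
target <- dat$envs[[1]]

fit <- transfer_knockoff(
  target$X, target$y,
  X_ext = lapply(dat$envs[-1], `[[`, "X"),
  y_ext = lapply(dat$envs[-1], `[[`, "y"),
  method = "wlasso", rho = 0.5, q = 0.1, seed = 7,
  cv_folds = 5, nlambda = 50, gamma_grid = seq(0, 1, 0.25))
fit
#> Transfer-learning knockoff selection
#>   method: wlasso  q = 0.1  offset = 1
#>   target: n = 250 , p = 150 ; external environments: 2
#>   selected 19 variables: X17 X25 X27 X28 X32 X33 X34 X37 X59 X66 ...

fdp_power(fit$selected, dat$truth$supports[[1]])
#>        fdp      power
#> 0.05263158 1.00000000
```

The weighted-lasso transfer analysis recovers all 18 true signals with one
false discovery (FDP 0.05, below the nominal q = 0.1). The vanilla analysis
of the target data alone, on the same replicate, finds only 12 of them:

```r
vfit <- transfer_knockoff(target$X, target$y, method = "vanilla",
                          rho = 0.5, q = 0.1, seed = 7,
                          cv_folds = 5, nlambda = 50)
fdp_power(vfit$selected, dat$truth$supports[[1]])
#>        fdp      power
#> 0.07692308 0.66666667
```

`run_experiment()` sweeps methods over a support-overlap grid and replicates,
returning mean FDP/power with Monte-Carlo standard errors (`plot()` draws the
power and FDR curves). A thin command-line wrapper over the same functions is
at `inst/cli/knockofftl.R`.

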