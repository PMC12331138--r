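---
title: "Transfer learning with model-X knockoffs: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning with model-X knockoffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knockofftl)
```

## The problem and the model

We observe data from several *environments* `e = 0, 1, ..., E`: environment
`e` has covariates `X^e` (n × p) drawn row-wise from a known law `P_X^e` and
an outcome `y^e` whose conditional law `P_{Y|X}^e` may differ across
environments. The inferential target is the set of variables that carry
signal in environment 0 only — the conditional-independence nulls
`H_j: Y^0 ⊥ X_j^0 | X_{-j}^0` — with FDR control at level `q`. The external
environments are allowed to inform the analysis, but not its error rate: a
variable that is active only in the external data must still be a controlled
null for the target.

Model-X knockoffs provide the negative controls. For Gaussian covariates
`N(μ, Σ)` with knockoff diagonal `s`, the knockoff row given the original row
`x` is drawn from

`N( x − (x − μ) Σ⁻¹ S ,  2S − S Σ⁻¹ S )`, with `S = diag(s)`,

so the joint 2p-dimensional law has covariance `[[Σ, Σ−S], [Σ−S, Σ]]` and is
invariant under swapping any subset of variables with their knockoffs. Any
statistic `W_j` built from `(X, X~, y)` with the flip-sign property then has
i.i.d. coin-flip signs at the nulls, and the knockoff filter (threshold or
sequential form) converts `W` into an FDR-controlled rejection set.

The three transfer methods in this package modify, respectively, the
*magnitudes* used to order hypotheses (linear re-ordering), the *ordering
itself* (adaptive filter), and the *statistic model* (weighted lasso), in
ways that each preserve the coin-flip property of null target signs. Their
validity is checked empirically in the test suite via aggregate binomial
tests of null signs and via FDR sweeps of the full pipeline.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `q` | filters | 0.1 | nominal FDR level (fraction, unitless) |
| `offset` | filters | 1 | numerator offset; 1 gives provable FDR control, 0 is more powerful but loses the guarantee when discoveries are few (a warning is emitted) |
| `theta` | `linear_reorder()` | — | weight of external magnitudes, in [0, 1]; must be fixed before looking at the data; θ = 0 recovers the vanilla statistics |
| `gamma_grid` | `stat_weighted_lasso()` | `seq(0, 1, 0.1)` | candidate prior-mixing values; γ is tuned by cross-validation, so a useless prior collapses to the plain lasso |
| `phi_eps` (`eps`) | `prior_weights()` | 0.05 | offset bounding prior weights above by 1/eps = 20; prevents infinite weights on variables with zero external coefficients |
| `cv_folds` | statistics | 10 | cross-validation folds; folds are drawn once per call from the seed and shared across the whole tuning grid so comparisons are paired |
| `nlambda` | statistics | 100 | length of the glmnet lambda path |
| `batch` | `adaptive_filter()` | 10 | reveals between refits of the sign model; 1 is fully sequential, larger is faster |
| `s` | `gaussian_model()` | equicorrelated | knockoff diagonal; injectable so an SDP-optimized construction can be plugged in |

Equicorrelated `s = min(1, 2λ_min(Σ))·(1 − 1e−6)` is the default because it
is deterministic, cheap, and adequate for the AR(1) designs studied here; the
multiplicative slack guards floating-point violations of the positive
semidefiniteness of `2Σ − S`. Covariance matrices with condition number above
1e10 are refused rather than silently regularized.

## The weighted-lasso tuning family

The per-feature penalty family is `λ_j = (1−γ)λ + γφ_j`, symmetric within
each original/knockoff pair. It is searched as one cross-validated glmnet
path per γ with penalty factors `(1−γ) + γφ_j`. A point on such a path
realizes per-feature penalties `t·((1−γ')λ' ... )` — i.e., the two-parameter
family `α + βφ_j` with `α, β ≥ 0` — and conversely any `(λ, γ)` of the affine
parametrization corresponds to a path point via `γ' = β/(α+β)`,
`λ' = α + β`. The two grids therefore span the same family of penalty
vectors; the multiplicative form is used because a single solver path covers
all λ at fixed mixing ratio, which is roughly tenfold cheaper than refitting
per (λ, γ) pair. At γ = 0 the reduction to the unweighted lasso is exact
(bit-identical with shared folds), which the tests assert. Ties in
cross-validated error are broken toward smaller γ, then larger λ.

The prior weights include the external knockoff coefficients,
`φ_j = 1/(0.05 + |b̂_j^ext| + |b̂_{j+p}^ext|)`, so that a previously fitted
knockoff model can be recycled as-is; `include_knockoffs = FALSE` gives the
equally valid simpler variant without the knockoff term. Pooled weights
(externals plus target) are valid when the null set is shared across
environments; this is the `phi_source = "pooled"` option and the default in
the experiment harness.

## The adaptive ordering

The sequential filter tolerates any hypothesis ordering that is a function of
the statistic magnitudes, the side information, and the signs already
revealed — never the unrevealed signs. The shipped logistic model regresses
`1{sign(W_j⁰) = −1}` on `(|W_j⁰|, W_j^ext)` over the revealed, nonzero-sign
hypotheses, with a small ridge penalty (1e−4, on standardized features) so
the fit exists under separation, and reveals next the unrevealed hypothesis
with the highest predicted probability of a negative sign. Likely-negative
statistics therefore land at the front of the testing sequence and positives
accumulate at the end, which is what gives the method its power.

Choices the theory leaves open, resolved here as package defaults: the model
is refit every `batch = 10` reveals; before `2·batch` reveals (and whenever
the fit is degenerate — all revealed signs equal, or solver failure) the
score falls back to the fixed combination `(1−θ)|W⁰| + θ|W^ext|` with
θ = 0.5, and the fallback is recorded in the returned trace. With
`model = "fixed_linear"` the procedure is exactly the linear re-ordering
method: the ordering equals the ascending ranking of the combined magnitude,
which the tests verify against `sequential_filter()` on the static ordering.
A custom ordering model can be supplied as a function; it receives only the
revealed features and signs, so the sign-invariance contract is structural.

## The synthetic data generator

`generate_environments()` emulates a multi-environment linear-Gaussian
design: all environments share the AR(1)(ρ = 0.5) covariate law; each has a
sparse effect vector with `n_signals = 60` nonzero entries (defaults
p = 500, n = 800, 3 environments); the external environments share one
support, and the fraction shared with the target support is the `overlap`
control parameter. Noise is standard Gaussian. Shared-signal counts are
rounded to the nearest integer and the realized overlap is reported.

Two generator choices deserve comment. First, nonzero effects default to
`a/√n` with a = 3.5 (per-coordinate effect ≈ 0.12 at n = 800): this puts the
vanilla analysis at intermediate power, where transfer learning has room to
help; the alternative `a/n` normalization (≈ 0.004) is available via
`amplitude_scale = "n"` but yields essentially no power at these sample
sizes. Second, effects are all positive by default; `random_signs = TRUE`
gives coin-flip signs held constant across environments.

What the generator does *not* emulate: discrete genotypes, linkage
disequilibrium block structure, population stratification, group-level
hypotheses, or environment-specific covariate laws. Passing FDR and power
checks on this design therefore says nothing about robustness to covariate
model misspecification — the Gaussian law used to sample knockoffs here is
exactly the generating law, which is the model-X assumption at its most
favorable.

## Numerical choices

- All lasso fits standardize columns to zero mean and unit population (1/n)
  variance, matching the solver's convention and making standardization
  exactly invariant to row duplication; fits use `standardize = FALSE`
  internally so fixed-tuning refits are reproducible.
- Fixed-lambda fits use a tightened convergence threshold (1e−12) so the
  flip-sign property holds to ~1e−6 in absolute terms; cross-validated fits
  use solver defaults.
- Zero statistics count as neither positive nor negative: they are never
  rejected, never candidate thresholds, and are excluded from sign-model
  training.
- Ties in |W| within an ordering break by original index, so runs are
  reproducible; the estimated-FDP path uses one reverse cumulative pass,
  tested for equality against a naive per-step recount.
- The textbook equivalence between the threshold and sequential filters
  presumes distinct magnitudes. With tied |W| (common for lasso statistics),
  an index-broken ascending ordering lets the sequential form cut inside a
  tie group and reject a strict superset — still valid, since its estimated
  FDP is controlled at every cut, but not identical. `threshold_ordering()`
  places tied positives before tied negatives, which makes every intra-group
  cut dominated by the group boundary and restores the exact equivalence;
  the tests assert both facts.
- All randomness (environment draws, knockoff sampling, fold assignment)
  derives from a master seed through a fixed counter-based splitting rule
  (`child_seed()`), so any single replicate is reproducible in isolation and
  results are independent of execution order.

## Problem sizes used in the shipped experiments

The package's own verification runs at desk scale, with the Monte-Carlo
standard-error-based tolerance `mean FDP ≤ q + 3·SE` scaling accordingly:

- acceptance script: p = 150, n = 250 per environment, 18 signals (the same
  ~12% signal fraction as the 60/500 reference design), a = 3.5, 3
  environments, 100 replicates per overlap in {0, 0.5, 1}; 5-fold CV, a
  40-value lambda path, γ grid {0, 0.25, 0.5, 0.75, 1};
- test suite: p = 100, n = 200, 14 signals, 25 replicates per overlap, plus
  property checks (flip-sign, filter equivalence, null-sign binomial tests,
  knockoff joint covariance at n = 50 000).

The full-scale design is a `sim_config()` call away, at proportionally
larger runtime (the weighted-lasso cross-validation dominates, scaling
roughly with `n·p·nlambda·cv_folds·|gamma_grid|`).

## Known limitations

- Exact FDR control needs the true covariate law. When `transfer_knockoff()`
  estimates it from the data, the knockoffs are approximate and the result is
  flagged accordingly.
- Only lasso-family statistics are provided (Gaussian and binomial losses);
  the filter accepts any flip-sign statistic vector, so other learners can be
  used by computing `W` externally.
- The pooling benchmark intentionally tests the "non-null anywhere"
  hypothesis; its FDP against the target support can far exceed q at low
  overlap (the harness reproduces this violation).
- `lro_oracle` (per-replicate best θ) is a benchmark, not a method: it is
  flagged `fdr_guaranteed = FALSE` in all outputs.
- Group-level hypotheses and knockoffs for discrete or hidden-Markov
  covariate models are out of scope.
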