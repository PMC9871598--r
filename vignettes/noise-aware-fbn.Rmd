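---
title: "Noise-aware estimation of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-aware estimation of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A functional brain network (FBN) summarises a subject's resting-state fMRI
scan as a weighted graph: nodes are atlas regions (ROIs), edge weights are
statistical dependencies between the regions' BOLD time series. Two standard
estimators dominate applied work. With `X` the `T x N` matrix of centred,
unit-norm ROI series:

* **Pearson's correlation (PC)**: `W = X'X`, the full marginal correlation —
  dense, fast, confounded by third regions.
* **Sparse representation (SR)**: each ROI is lasso-regressed on all others,
  `min ||X - XW||_F^2 + lambda1 ||W||_1` with `w_ii = 0` — an L1-stabilised
  surrogate for partial correlation.

Both treat the residual as i.i.d. over time. Acquisition noise is not:
artefacts that survive preprocessing (motion, drift, normalization errors)
are temporally correlated. This package estimates the network *jointly* with
a `T x T` temporal noise precision matrix `Omega`, shared across ROIs.

# The model

Writing the residual quadratic form with an explicit precision gives, per
ROI, a Gaussian likelihood with non-diagonal `Omega`. Two facts make the
resulting estimators practical:

1. **Whitening identity.** With `Y = Omega^{1/2} X`,
   `(x_i - X w_i)' Omega (x_i - X w_i) = ||y_i - Y w_i||^2`, so the W-step
   of the noise-aware estimators is exactly the baseline estimator applied
   to whitened data: a plug-and-play modification (`transform_data()`).
   SRAND is SR on `Y`; PCAND is PC on `Y`.
2. **Tractable `Omega` updates.** Given `W`, with `S = (X - XW)(X - XW)'`:
   the unregularized problem `min tr(Omega S) - N log|Omega|` has stationary
   point `Omega = N S^{-1}`, which is ill-posed whenever `T > N` (the usual
   fMRI regime). Two priors restore well-posedness:
   * **L1 prior** (`omega_update_l1()`): adds `lambda2 ||Omega||_1`; solved
     as a graphical lasso on `S/N` with penalty `lambda2/N`. Motivated by
     sparse temporal structure — only regularly varying noise couples
     nearby time points.
   * **Wishart prior** (`omega_update_wishart()`): conjugate
     `W(Omega | Sigma, nu)` with `Sigma = alpha^{-1} I` gives the closed
     form `Omega = (N + nu)(S + alpha I)^{-1}`, positive definite for any
     residual.

`fbn_fit(method = "srand")` alternates the two steps from `Omega = I` until
the joint objective
(`tr(R' Omega R) - N log|Omega| + lambda1||W||_1 + lambda2||Omega||_1` for
the L1 prior; `tr(Omega (S + alpha I)) - (N + nu) log|Omega| +
lambda1||W||_1` for the Wishart prior) changes by less than `tol` in
relative terms. Both steps are exact block minimisations, so the objective
trace is non-increasing — a property the test suite checks on random
instances with `1e-8` slack.

# Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda1` | sparsity of `W` (dimensionless) | 0.1 | on the un-scaled objective; any `lambda1 >= 2` gives `W = 0` on normalized data |
| `lambda2` | sparsity of `Omega` (L1 prior) | 0.1 | on the joint-objective scale; divided by `N` only inside the glasso mapping |
| `nu` | Wishart degrees of freedom | `T` | smallest value satisfying `nu > T - 1` |
| `alpha` | Wishart scale, `Sigma = alpha^{-1} I` | 1 | must be `> 0`: `S` is rank-deficient when `T > N`, so the "infinitely broad" limit `alpha -> 0` is ill-posed |
| `max_iter`, `tol` | outer loop control | 50, `1e-4` | relative change of the joint objective |
| `lasso_tol`, `lasso_max_iter` | W-step coordinate descent | `1e-6`, 10000 | convergence when the largest coefficient change falls below `lasso_tol * max(1, max|w|)` |
| `omega_rescale` | rescale `Omega` to trace `T` after each update | `FALSE` | see below |

**The `Omega` scale coupling.** The faithful updates give `Omega` an overall
scale of order `N S^{-1}` (L1) or `N + nu` (Wishart). That scale multiplies
`Y` and therefore *divides* the effective `lambda1` of the next W-step:
with the default faithful update the noise-aware fits are much denser than
the baseline at the same nominal `lambda1`. `omega_rescale = TRUE`
renormalizes `Omega` to trace `T` after every update, preserving the noise
*shape* while keeping `lambda1` comparable across methods. The default
remains the faithful update; the rescaled variant is a documented departure
useful when comparing sparsity across estimators.

**PCAND convergence.** The PC-style W-step `W = Y'Y` is a closed-form
substitution, not a descent step on any joint objective, and the alternation
typically settles into a small-amplitude period-2 cycle rather than a fixed
point (the fit then carries `converged = FALSE` and a warning after
`max_iter`). One iteration reduces exactly to PC; the Omega iterates remain
symmetric positive definite throughout. `omega_rescale = TRUE` shrinks the
cycle's amplitude substantially and is recommended for PCAND.

# Numerical choices

* The W-step is a per-column cyclic coordinate descent on the Gram matrix
  with a structural zero diagonal (never post-hoc zeroing), warm-started
  from the previous outer iteration. It is validated against an independent
  proximal-gradient (ISTA) solver in the tests.
* The graphical lasso backend is the block-coordinate (regression) scheme
  on the covariance side, convergence threshold `1e-5` relative to the mean
  absolute off-diagonal of the input, at most 1000 sweeps; the elementwise
  L1 penalty includes the diagonal, matching the classical objective. It is
  validated by KKT/subgradient conditions, objective comparisons, and the
  `lambda2 = 0` reduction to `N S^{-1}`.
* `matrix_sqrt_spd()` uses the spectral decomposition and clips eigenvalues
  in `[-1e-10, 0)` to zero; anything more negative is an error.
* Constant ROI columns are rejected at normalization (a direction-free
  column cannot be unit-normalized); series with fewer than 3 time points
  or 2 ROIs are rejected outright.
* Whitened data are deliberately *not* re-centred or re-normalized before
  the W-step: re-normalizing would break the whitening identity. This is a
  genuine modelling fork; re-normalization would change results.
* All estimator code is deterministic — no random initialisation anywhere.

# The classification pipeline

`fbn_loocv()` implements the standard diagnosis benchmark: per-subject FBN
estimation, upper-triangle edge weights as features (`N(N-1)/2` of them —
4005 for a 90-ROI cerebrum parcellation; regression-based networks are
symmetrized as `(W + W')/2` at feature extraction only, never inside the
optimisation), two-sample pooled-variance t-test selection at `p < 0.01`
(Welch behind `var_equal = FALSE`; no multiple-testing correction, by
design), a linear SVM with `C = 1` and no feature standardization, all
wrapped in leave-one-out cross-validation with an inner LOOCV grid search
over `lambda1` (default grid `0.05, 0.10, ..., 1.00`; ties broken toward
the smaller, sparser penalty). Feature selection is re-run inside every
inner fold — the stricter of the two defensible readings. When no feature
passes the threshold, the 10 smallest-p features are used so every fold
stays classifiable; features with zero variance in both groups are never
selected. Networks are estimated once per subject per candidate penalty and
cached across folds, which is mathematically identical to re-estimating
per fold because estimation never sees labels or other subjects.

A caveat worth knowing: under permuted labels a *balanced* leave-one-out
design is biased **below** chance, because the held-out subject's class is
always the training minority and a linear SVM on uninformative features
votes with the training majority. Null accuracies near 0 (not 0.5) are the
expected signature of this well-known artifact, and the package makes no
attempt to hide it (no class weighting — the pipeline stays faithful).

# The synthetic generator

`simulate_cohort()` draws, per subject, clean rows i.i.d. over time from a
zero-mean Gaussian whose sparse ROI precision has known support (off-diagonal
magnitudes 0.3–0.6 with random signs; diagonal set to absolute row sum + 1,
guaranteeing diagonal dominance and hence positive definiteness), plus
additive noise `sigma * L Z` with `L` the Cholesky factor of an AR(1)
covariance `rho^{|t-s|}` — the simplest temporal family whose precision is
sparse (tridiagonal), matching the L1 prior's rationale. Group differences
are injected on the precision (partial-correlation) scale, since the
SR family targets partial correlation, with a diagonal-boost repair if
positive definiteness is lost. Defaults mirror the resting-state shape the
package targets (`T = 170`, `N = 90`, 45 subjects per group).

What the generator does **not** emulate: hemodynamics (no HRF convolution),
scanner drift, motion spikes, global-signal structure, or any temporal
autocorrelation in the *clean* signal. Passing recovery tests therefore
demonstrate correctness of the estimators under the package's own noise
model, not performance on real fMRI.

# What the validation study shows — and what it does not

The recovery study (20 replicates; `N = 15`, `T = 120`, edge density 0.1,
AR(1) `rho = 0.6`, `sigma = 0.5`, `lambda1 = 0.3`, `lambda2 = 0.1`; scored
as F1 of the top-`|support|` edges by magnitude) is computed by
`scripts/acceptance.R` and the test suite at desk scale, chosen so the full
suite runs in minutes on one core. Its outcome is instructive: **SRAND-L1
does not beat SR at these conditions** (mean F1 roughly 0.26 vs 0.46 with
the faithful update; 0.39 vs 0.46 rescaled). Oracle experiments in the
development notes localise the cause: whitening with the *true* noise
precision gains almost nothing here (the clean signal is i.i.d. over time
and the regressors themselves are noisy — an errors-in-variables problem
that generalised-least-squares whitening does not address), while the
estimated `Omega` is a `120 x 120` precision fit from only 15 residual
columns, and its estimation noise costs more than the whitening buys. The
noise-depression machinery is mathematically verified (monotone descent,
KKT conditions, closed-form/numeric-oracle agreement, exact reduction to
the baselines); its *statistical* benefit at this sample geometry is not
demonstrated by the synthetic study, and the package reports that honestly
rather than tuning the generator until it flatters the method.

# Known limitations

* `Omega` estimation needs many ROIs relative to time points to be more
  than weak regularised smoothing; with `N << T` expect the Wishart update
  to stay close to a scaled identity and the L1 update to be nearly
  diagonal.
* PCAND lacks a joint objective and may cycle (see above).
* LOOCV accuracy under class-balanced nulls is biased below 0.5 (see
  above); interpret permutation baselines accordingly.
* No raw-image preprocessing, atlas handling, or NIfTI input: the package
  starts from parcellated ROI-by-time tables.
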