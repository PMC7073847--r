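---
title: "Testing differential edges between nonparanormal graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential edges between nonparanormal graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npndiff)
```

## The problem

Two groups of samples — say tumour subtypes — are each modelled by a
graphical model over the same p genes, and the question is which gene
pairs change their *conditional* dependence between the groups. In a
Gaussian graphical model the conditional dependence between variables
i and j given the rest is captured by the partial correlation
$\rho_{ij\cdot} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}$, where
$\Omega = (\omega_{ij})$ is the precision (inverse covariance) matrix.
An edge (i, j) is *differential* when $\rho_{ij\cdot}$ differs between
classes, and the hypotheses are
$H_{0ij}: \rho^{(1)}_{ij\cdot} = \cdots = \rho^{(K)}_{ij\cdot}$ for all
p(p−1)/2 pairs jointly, with false discovery rate (FDR) control over the
family.

Expression data are rarely Gaussian, even after variance-stabilising
transformations. The package therefore works in the *nonparanormal*
(Gaussian copula) family: each variable is assumed Gaussian only after
some unknown strictly increasing transformation $f_j$. Because partial
correlations of the latent Gaussian vector are invariant to such
marginal transformations, the differential-network question is
well-posed without ever knowing the $f_j$.

## The procedure

`dnet_test()` composes three stages.

**1. Winsorized latent-Gaussian imputation** (`npn_impute()`). The
unknown transformation is estimated through the empirical CDF, clamped
to $[\delta_n, 1-\delta_n]$ with
$\delta_n = 1/(4 n^{1/4}\sqrt{\pi \log n})$ before the normal-quantile
map, so that the largest observations do not explode to $\Phi^{-1}(1)$.
The imputed value is $x^*_{mj} = \hat\mu_j + \hat\sigma_j
\Phi^{-1}(\tilde F_j(y_{mj}))$ with $\hat\mu_j, \hat\sigma_j$ the raw
column mean and 1/n-scale standard deviation. The standardized scores
depend on the data only through ranks; `npn_impute(..., standardize =
"latent")` returns them directly. The truncation rate balances the bias
of clamping against the variance of the empirical CDF in the tails; a
`delta_n` override is accepted but rarely needed.

**2. Node-wise regression with a bias-corrected statistic**
(`fit_nodewise()`, `bias_corrected_stat()`). Each variable is regressed
on all others; the coefficients satisfy
$\beta_j = -\omega_{jj}^{-1}\Omega_{-j,j}$, so sparse regression
recovers the conditional-dependence structure. The regressions are
solved in gram form — by cyclic coordinate descent for the lasso
(compiled code) or by linear programming for the Dantzig selector — on
either the correlation matrix of the imputed data (`gram_source =
"imputed"`) or the rank-based adjusted-Spearman matrix
$2\sin(\pi\rho_S/6)$ (`"adjusted_spearman"`, the default), which is
consistent for the latent correlation under any monotone marginals.
Residual cross-products are then corrected for the first-order shrinkage
bias of the penalised fits:
$N_{ij} = r^*_{ij} + r^*_{ii}\hat B_{j,i} + r^*_{jj}\hat B_{i,j}$,
with $\hat B_{j,i}$ the coefficient of variable i in the regression of
variable j. Pairing the residual variance $r^*_{ii}$ with the
coefficient *of* variable i (rather than with the coefficient of the
partner variable from regression i) is what makes the plug-in limit come
out as exactly $-\omega_{ij}/(\omega_{ii}\omega_{jj})$; the two pairings
coincide when all $\omega_{ii}$ are equal, and only the one used here is
consistent in general. On the partial-correlation scale,
$\hat\rho_{ij} = N_{ij}/\sqrt{r^*_{ii} r^*_{jj}}$ consistently estimates
$\rho_{ij\cdot}$ (the precision-entry-scale variant is kept as `s_star`
for inspection).

**3. Multiple testing with an empirically corrected threshold**
(`two_sample_stat()`, `t_transform()`, `fdr_threshold()`). Class
differences are standardised by the plug-in variance
$(1-\hat\rho^2)^2/n_k$, where $\hat\rho$ is first hard-thresholded at
$2\sqrt{\log p / n_k}$ so that only stably-estimated partial
correlations shrink the variance. For K classes the K(K−1)/2 pairwise
statistics are combined by a sum of squares, referred to a weighted
chi-square law $\sum_i \lambda_i Z_i^2$, and mapped through
$\Phi^{-1}$ to the normal scale, where under the complete null the
$T_{ij}$ behave like standard normal draws. The rejection threshold is
the smallest t with
$1-\Phi(t) \le \alpha_0 A(t) \max\{1, \#\{T_{ij} \ge t\}\}/\tilde p$,
where $\tilde p = p(p-1)/2$ and
$A(t) = (1 + |A|\,|t|\,\phi(t)/(2(1-\Phi(t))))^{-1}$ with
$A = (P_0 - \hat P_0)/Q_0$, $P_0 = 2\Phi(1)-1$, $Q_0 = 2\phi(1)$: the
observed fraction $\hat P_0$ of $|T_{ij}| \le 1$ measures how far the
statistics are from null calibration and tightens the threshold
accordingly. The search runs over the observed statistics in
$[0, \sqrt{4\log\tilde p}]$; when no candidate qualifies, the threshold
falls back to $\sqrt{4\log\tilde p}$ and only extreme statistics are
rejected — without a fallback the procedure would be undefined exactly
when there is nothing to reject.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha0` | 0.05 | nominal FDR level (unitless, in (0,1)) |
| `method` | `"lasso"` | node-wise solver; `"dantzig"` solves the sup-norm-constrained $\ell_1$ program instead |
| `gram_source` | `"adjusted_spearman"` | rank-based gram; `"imputed"` uses Pearson correlation of the imputed values (appropriate for the oracle arm) |
| `n_lambdas` | 20 | penalty path length per node |
| `delta_n` | $1/(4 n^{1/4}\sqrt{\pi\log n})$ | eCDF truncation level |
| `weights` | unit | weights of the reference weighted-chi-square law for K > 2 |

**Penalty selection.** Each node's penalty is chosen by
$AIC = n\log(RSS/n) + 2\,df$ along a 20-point log-spaced path from
$\lambda_{\max} = \max_i |G_{i,j}|$ down to
$\max(\lambda_{\max}/100,\; \tfrac12\sqrt{\log p / n})$, with the number
of non-zero coefficients as the degrees of freedom. The clamp on the
lower endpoint matters: the bias-corrected statistic is derived under
penalties on the $\sqrt{\log p/n}$ scale, and if the candidate set is
allowed to descend far below that scale, AIC picks heavily overfitted
regressions whose residual cross-products share projection noise — at
p = 50, n = 100 the standard deviation of the null two-sample statistic
inflates to about 1.15 (1.40 on shared strong edges) and false
rejections become routine. With the clamp the null statistic has
standard deviation close to 1 and the empirical FDR tracks the nominal
level (see the numbers below). AIC ties go to the larger penalty, and
the K > 2 weighted-chi-square weights default to unit weights because
the two-class case (a single $\chi^2_1$ term) is the fully supported
path.

**Numerical choices.** Coordinate descent converges at a maximum
coefficient change below 1e−7 (10,000-sweep cap, warm starts along the
path; non-convergence is a warning, since the adjusted-Spearman gram is
not guaranteed positive semi-definite). Partial correlations are clipped
at $1 - 10^{-10}$ before any $(1-\rho^2)$ plug-in. Weighted-chi-square
probabilities use the exact scaled-chi-square closed form for equal
weights and Imhof-type numerical inversion of the characteristic
function otherwise; CDF values are clamped to $[10^{-15}, 1-10^{-15}]$
before $\Phi^{-1}$ so every statistic is finite. The Dantzig linear
program at $\lambda = 0$ is solved directly as the least-squares system,
its unique feasible point. Ties in a column are given the shared
empirical-CDF value (the count of observations at or below); the
procedure is otherwise tie-free.

## The synthetic benchmark

`band_precision()` and `er_precision()` generate the two study designs:

* **Band graph** — tridiagonal precision matrix (1 on the diagonal, 0.6
  on the first off-diagonals); a chosen number of edges flip sign in
  class 2; $\max(|\lambda_{\min}(\Omega_1)|, |\lambda_{\min}(\Omega_2)|)
  + 0.05$ is added to both diagonals to enforce positive definiteness.
* **Erdős–Rényi graph** — each pair connected with probability 5%, edge
  weights uniform on $\pm[1/4, 1/2]$ then shrunk by a factor of 5
  (magnitudes 0.05–0.1), unit diagonal; 5% of the existing edges flip
  sign. This construction is diagonally dominant with high probability;
  if a draw is not positive definite the same diagonal remedy as in the
  band design is applied. Sign flips are restricted to existing edges,
  and a graph drawn with no edges at all is redrawn.

`sample_nonparanormal()` draws latent data from $N(0, \Omega^{-1})$ and
pushes each column through a strictly increasing transform (`identity`,
`exp`, `cube`, `logistic`); identity reproduces the oracle-data arm, and
because the whole pipeline is rank-based, the transformed arms produce
identical standardized scores — the tests assert this exactly.
`evaluate_performance()` repeats the draw-and-test protocol and averages
the false discovery proportion FP/max(R, 1) and the true positive rate
over replicates for a grid of nominal levels, fitting once per
replicate and re-thresholding per level.

What the generator does *not* emulate about real expression data:
counts and zero-inflation, batch structure (that is `batch_correct()`'s
job, applied upstream), gene-gene correlation structure beyond sparse
precision models, and model misspecification where no monotone marginal
transform Gaussianises the data. Passing benchmarks therefore
demonstrates correctness of the machinery under its own assumptions,
not robustness to violations of them.

## Problem sizes and what the checks show

The packaged checks run the benchmark at p = 50 variables, n = 100
samples per class and 50 replicates — large enough for the asymptotic
calibration to bite, small enough to iterate on routinely. With seed 1
the acceptance computation reports band-graph empirical FDR 0.084 at
nominal 0.10 with power 1.00 on the ten flipped edges; under the global
null the fraction of $|T_{ij}| \le 1$ is 0.683 against the theoretical
$2\Phi(1)-1 \approx 0.6827$, and the null empirical FDR at level 0.10
is 0.08. Bias-corrected estimates on a known 3-variable model at
n = 5000 are within 0.008 of the true partial correlations.

At this scale the Erdős–Rényi design has only about three differential
edges with partial correlations below 0.1 in magnitude, which are
essentially undetectable at n = 100: its power is near zero (clearly
below the band design, the qualitative ordering one expects, since its
differential signal is much weaker), and with almost no true
discoveries available, the realised false discovery proportion among
the handful of rejections is noisy and can sit well above the nominal
level. That is a property of a powerless design rather than of the
threshold rule; at the full design size the same construction carries
more and stronger differential edges.

## Batch correction

`batch_correct()` implements the median- and variance-matching map
$g^*_{ijk} = M_i + (g_{ijk} - M_{ij})\,\hat\sigma_{g_i}/\hat\sigma_{g_{ij}}$
per gene, which aligns every batch's location (median) and scale (SD)
with the pooled ones; the same operation applied with age-group labels
removes age-group effects. The SD convention is the sample SD
(1/(n−1)) by default, configurable to 1/n. Note that the map is exactly
idempotent only in the 1/n convention and when within-batch means and
medians coincide: after one pass each batch has the pooled SD, but the
*pooled* SD of the corrected data recombines across batches, so under
1/(n−1) a second pass rescales by $\sqrt{(N-J)/(N-1)}$-type factors.
In practice the second-pass drift is far below biological noise.

## Design choices made where the design was open

* The partial-correlation-scale statistic
  $N_{ij}/\sqrt{r^*_{ii}r^*_{jj}}$ (bounded, sign-consistent with
  $\rho_{ij\cdot}$) drives the test, because the two-sample variance
  plug-in $(1-\rho^2)^2/n$ presumes that scale; the precision-entry
  scale $N_{ij}/(r^*_{ii}r^*_{jj})$ is exposed as `s_star`.
* $\hat P_0$ is computed over all upper-triangle statistics, including
  pairs whose thresholded partial correlation is zero.
* The threshold search condition reads $1-\Phi(t)$, the standard-normal
  tail; a density there would be negative-signed nonsense for small t.
* Missing values are never imputed: samples exceeding the missing
  fraction cap (1%) are dropped at ingestion and any remaining missing
  entry is an error.
* Sign flips in the generators pick among existing edges only —
  "flipping" an absent edge would create one rather than flip it.
* One master seed spawns per-replicate sub-seeds, so any replicate can
  be reproduced from the report alone.

## Known limitations

* FDR control relies on sparsity of the differential network; a
  globally rewired network breaks the $\hat P_0$ calibration logic.
* K > 2 classes are supported mechanically (sum of squared pairwise
  statistics against a unit-weight chi-square law), but the reference
  weights are a convention, not derived theory; the two-class path is
  the validated one.
* The adjusted-Spearman gram need not be positive semi-definite;
  coordinate descent then lacks a convergence guarantee (in practice it
  converges, and non-convergence is reported).
* No per-edge p-values are produced: the procedure thresholds the
  normal-scale statistics directly.

## A worked call

```{r example, eval = FALSE}
model <- band_precision(p = 50, n_flips = 10, seed = 1)
y1 <- sample_nonparanormal(model, n = 100, class_index = 1,
                           transforms = "exp", seed = 2)
y2 <- sample_nonparanormal(model, n = 100, class_index = 2,
                           transforms = "exp", seed = 3)
res <- dnet_test(list(tumor = y1$observed, normal = y2$observed),
                 alpha0 = 0.1)
glance(res)        # threshold, constants, rejection count
tidy(res)          # one row per edge, sorted by evidence
autoplot(res)      # statistics against the threshold
```
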