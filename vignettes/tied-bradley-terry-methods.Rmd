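---
title: "Bayesian Bradley-Terry models with ties: model, algorithm and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Bradley-Terry models with ties: model, algorithm and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btties)
```

## The problem

Comparative judgement surveys estimate the relative level of some
quantity — here, the prevalence of honour-based abuse across the wards
of a county — by showing participants pairs of areas and asking which
is higher, instead of asking for absolute ratings. Judges who know a
community well can answer such pairwise questions reliably even where
no administrative data exist. Two features of real surveys drive the
model in this package:

* judges often cannot separate two similar areas, so a *tie* must be a
  legitimate response (forcing a choice causes fatigue and noise);
* only a limited pool of knowledgeable judges exists, so the prior
  should share information between neighbouring areas.

## The model

Each ward $i$ carries a quality $\lambda_i \in \mathbb{R}$. In this
package's orientation, large *negative* values correspond to high
prevalence. A comparison of wards $i$ and $j$ has three outcomes:

$$\pi(i \text{ beats } j) =
  \frac{e^{\lambda_i}}{e^{\lambda_i} + e^{\lambda_j + \delta}}, \qquad
\pi(\text{tie}) =
  \frac{(e^{2\delta} - 1)\, e^{\lambda_i + \lambda_j}}
       {(e^{\lambda_i} + e^{\lambda_j + \delta})
        (e^{\lambda_i + \delta} + e^{\lambda_j})},$$

with $\delta \ge 0$ the tie parameter (the Rao–Kupper extension of
Bradley–Terry). At $\delta = 0$ ties have probability zero and the
standard model is recovered; for two equally placed wards the tie
probability is $\tanh(\delta/2)$. Writing $\psi_{ij} = \lambda_i -
\lambda_j - \delta$ and collecting ordered-pair counts $y_{ij}$ (wins)
and $t_{ij}$ (ties, symmetric), the likelihood factorises as

$$L(\lambda, \delta) =
  (e^{2\delta} - 1)^{\sum_{i<j} t_{ij}}
  \prod_{i \ne j}
  \left(\frac{e^{\psi_{ij}}}{1 + e^{\psi_{ij}}}\right)^{y_{ij}+t_{ij}}.$$

A useful identity, used throughout the package and pinned down by unit
tests, is $\pi(\text{tie}) = (e^{2\delta}-1)\,\pi_{ij}\,\pi_{ji}$: the
ordered-pair product above *equals* the per-outcome multinomial
likelihood exactly, not merely up to a constant. All probability
arithmetic is done on the log scale (`plogis(, log.p = TRUE)`,
`log(expm1(.))`), so qualities of magnitude 50 or more are handled
without overflow.

Skipped pairings carry no information under this model and are excluded
from the data format altogether. Wards that appear in no comparison stay
in the model and are informed by the prior alone — with a spatial prior
this is precisely the mechanism that lets sparse surveys cover a whole
county.

## The spatial prior

Qualities get a joint Gaussian prior $\lambda \sim N(\mu, \alpha^2
\Sigma_0)$. For a ward map, $\Sigma_0$ is built from the adjacency
matrix $A$ of the ward graph via the matrix exponential,

$$\Sigma_0 = D^{-1/2} e^A D^{-1/2}, \qquad D = \mathrm{diag}(e^A),$$

which counts weighted walks between wards and therefore gives strongly
connected pairs high prior correlation. The symmetric normalisation
makes $\Sigma_0$ unit-diagonal, so a single signal-variance parameter
$\alpha^2$ carries the scale. $\alpha^2$ can be fixed or given a
conjugate inverse-gamma hyperprior, in which case its Gibbs update is
$\mathrm{IG}(a + N/2,\; b + \tfrac12 (\lambda-\mu)^\top \Sigma_0^{-1}
(\lambda-\mu))$. The matrix exponential is computed once per fit;
$\alpha^2$ only rescales it. Disconnected graphs are permitted (the
covariance stays positive definite) but warned about, since cross-
component correlation is then negligible. Non-spatial correlated priors
are supported through any unit-diagonal covariance, e.g. the normalised
Wishart draws used by the synthetic scalability designs.

The tie parameter gets an exponential prior with rate $\chi$
(default 0.01, deliberately vague), and the default inverse-gamma
hyperparameters are 0.01/0.01, matching common practice for variance
components in small-area work.

## The Polya-Gamma Gibbs sampler

Each likelihood factor has the logistic form $(e^\psi)^a / (1 +
e^\psi)^b$, so the Polya-Gamma identity

$$\frac{(e^x)^a}{(1+e^x)^b} = 2^{-b} e^{(a - b/2)x}
  \int_0^\infty e^{-z x^2/2}\, p_{\mathrm{PG}(b,0)}(z)\, dz$$

introduces one latent $z_{ij}$ per ordered pair with positive exposure
$b_{ij} = y_{ij} + t_{ij}$, making $\lambda$ conditionally Gaussian.
The sweep per iteration is:

1. $z_{ij} \mid \lambda, \delta \sim \mathrm{PG}(y_{ij} + t_{ij},\,
   \lambda_i - \lambda_j - \delta)$;
2. $\lambda \mid z, \delta, \alpha^2 \sim N(m, S)$ with
   $S^{-1} = X^\top Z X + \Sigma^{-1}$ and
   $m = S\,(X^\top(\kappa + \delta z) + \Sigma^{-1}\mu)$, where $X$ is
   the $\pm 1$ design matrix, $Z = \mathrm{diag}(z)$ and $\kappa_{ij} =
   (y_{ij} + t_{ij})/2$; the draw uses the Cholesky factor of the
   precision, never an explicit inverse;
3. the identifiability translation (below);
4. $\delta$ by a Gaussian random-walk Metropolis step against the
   *observed-data* likelihood times the $\mathrm{Exp}(\chi)$ prior —
   the tie factor $(e^{2\delta}-1)^{\sum t}$ has no convenient
   augmentation, the stated conditional contains no $z$ terms, and
   refreshing $z$ first in each sweep keeps the marginal chain on
   $(\lambda, \delta, \alpha^2)$ exactly invariant;
5. $\alpha^2$ by its conjugate inverse-gamma draw, when inferred.

Completing the square in $\kappa_{ij}\psi_{ij} - z_{ij}\psi_{ij}^2/2$
gives the linear coefficient $\kappa + \delta z$ that appears in $m$;
the two-dimensional quadrature test in the suite pins both the mean and
the covariance of this update to numerical integration at $10^{-6}$,
which is the package's guard against sign errors in this algebra.

Negative $\delta$ proposals are rejected through zero prior density — a
plain random walk kept deliberately simple; `tune_delta_step()` adjusts
the scale to a 20–40% acceptance band by pilot runs, because no
universal proposal scale suits all data sizes. A componentwise
random-walk Metropolis sampler over $(\lambda, \delta)$ targeting the
identical posterior (`run_mh_baseline()`) serves both as an independent
correctness oracle — the acceptance suite requires posterior agreement
on all identified quantities — and as the efficiency comparator that
the augmented sampler must beat in effective samples per second.

### Identifiability

The likelihood is invariant under $\lambda \mapsto \lambda + c$, so the
average quality $\Lambda = \tfrac1N \sum_i \lambda_i$ is identified
only by the prior, under which $\Lambda \sim N(\mathbf{1}^\top\mu/N,\;
\mathbf{1}^\top\Sigma\mathbf{1}/N^2)$. Each iteration recentres the
vector and, by default, adds a fresh draw from this law; a
centring-only mode is available via `sampler_config(translation =
"center")`. Either choice leaves every identified contrast untouched.
The resampling move is *exactly* invariant whenever $\mathbf{1}$ is an
eigenvector of $\Sigma$ (vertex-transitive graphs, such as the complete
graph used in the prior-preservation test); on irregular graphs it
perturbs only the unidentified level, which is why summaries and tests
are phrased in terms of contrasts, medians and ranks.

### Exact Polya-Gamma draws

No Polya-Gamma sampler ships with this R installation, so the package
implements the exact alternating-series accept–reject scheme (the
Devroye-type sampler popularised for Bayesian logistic regression) in
compiled code, drawing $\mathrm{PG}(b, c)$ for integer $b$ as a sum of
$b$ unit-exposure draws. Exposures are per-pair comparison counts, so
$b$ is small by construction and the sum is cheap; saddlepoint
approximations for large $b$ are deliberately out of scope. All draws
go through R's RNG stream, so `set.seed()` (or the `seed` field of
`sampler_config()`) makes entire fits bit-reproducible. The test suite
validates the sampler against closed-form means and variances
($E = \tfrac{b}{2c}\tanh\tfrac{c}{2}$, $V = b(\sinh c - c)\,
\mathrm{sech}^2(c/2)/(4c^3)$, with limits $b/4$ and $b/24$ at $c = 0$),
sign symmetry, additivity in $b$, and the integral identity itself by
Monte Carlo — so the backing sampler is swappable without weakening the
contract.

## What the synthetic generator emulates — and what it does not

`simulate_study()` reproduces the study conditions end to end: wards on
a connected graph (a near-square lattice standing in for a real ward
map), qualities drawn from the matrix-exponential prior with
$\alpha^2 = 1$, about ten comparisons per ward chosen uniformly at
random over pairs, outcomes drawn from the tied model, and the tie
parameter either set directly (e.g. 0.5, the scale seen in fitted
surveys) or calibrated by monotone root-finding so the *expected* tie
fraction over uniformly chosen pairs hits a target (5–75% spans the
sensitivity designs; calibration uses the deterministic population
quantity, not a simulated rate). A familiarity-restricted pair scheme
is available to mimic judges who only compare areas they know, but the
default stays uniform, and judge-level effects are not modelled at all
— the model has no judge terms. Passing the recovery tests on these
data therefore shows the *inference machinery* is sound at realistic
sizes and tie rates; it does not validate judge behaviour, judge
misfit, order effects, or the adequacy of the spatial prior for any
particular county.

## Numerical and design choices

* **Problem sizes in the tests.** The recovery study uses 20 wards,
  200 comparisons, a ~20% tie rate, 20 replicates and 5000-iteration
  chains with a 100-iteration burn-in (the fit defaults); the
  cross-sampler check runs the baseline twenty times longer than the
  augmented sampler (100 000 vs 5000 iterations), mirroring the mixing
  gap between the two. These sizes were chosen as the smallest at
  which the statistical claims are meaningfully exercised.
* **Prior-preservation testing.** The successive-conditional check
  alternates data simulation with full transition sweeps and compares
  the marginals of $\lambda_1$, $\delta$ and $\alpha^2$ against direct
  prior draws. It uses proper moderate hyperpriors
  ($\mathrm{IG}(3,2)$, $\mathrm{Exp}(1)$): the vague fit defaults have
  no finite moments, which makes any finite-sample distributional
  comparison vacuous. This is a property of the test design, not a
  change to the fitting defaults.
* **Degenerate inputs.** Empty comparison sets make the quality update
  a pure prior draw; tables with ties reject the no-ties likelihood
  explicitly; $\delta = 0$ with observed ties yields log-likelihood
  $-\infty$ (and the chain moves away immediately); constant chains
  report `NA` effective sample size with a flag rather than infinity;
  non-finite sampler states abort with the iteration index.
* **Ordering and determinism.** Design-matrix rows are lexicographic
  in the ordered pair, ward identity is by string label everywhere in
  user-facing files, and every output (trace, summary, manifest CSV/
  JSON) round-trips exactly, so a manifest's seed reproduces a fit
  bit-for-bit on the same platform.

## Known limitations

Inference quality degrades by design at extreme tie rates — at ~75%
ties the data carry little ranking information, and the suite asserts
only the *ordering* (worse than at 20%), not an absolute level. The
random-walk baseline is not tuned per-component and is intentionally
plain; it is a comparator, not a recommended fitting route. Adaptive
MCMC, judge effects, multi-way comparisons and experimental design for
pair selection are out of scope.
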