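---
title: "Methods: genetic influences on connectome hub connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic influences on connectome hub connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

connherit asks a single question in several registers: do genetic and
molecular influences fall uniformly across the connections of a structural
brain network, or do they concentrate on the *rich club* — the densely
inter-connected set of high-degree hub regions? This vignette documents the
models behind each stage, the tunable parameters and the reasoning behind
their defaults, the numerical choices, and what the synthetic data do and do
not establish.

## Group connectome and link classes

Subject-level connectomes are symmetric nonnegative matrices (streamline
count, "SC", and a bounded (0,1) FA-like channel). The group-representative
network keeps an edge when (i) it appears in at least a fraction
`consistency_min` of subjects (default 0.30) and (ii) its cross-subject
weight statistic (default: median over the subjects in which the edge is
present; absent edges are treated as missing, not zero) ranks among the top
`round(tau * n(n-1)/2)` candidates. Ties at the density boundary are broken
by higher consistency and then by lower node-index pair, so the output is a
deterministic function of the input. When the consistency filter leaves too
few candidates the achieved density is reported with a warning rather than
silently padded.

Hubs at a threshold `k` are nodes with binary degree strictly greater than
`k`; edges are *rich* (hub–hub), *feeder* (hub–nonhub) or *peripheral*
(nonhub–nonhub). All curve code sweeps every integer `k` from the minimum
degree to the maximum degree minus one, reporting undefined points as `NA`
rather than dropping them.

## Rich-club statistics and nulls

The topological coefficient is the density of the `degree > k` subgraph,
`phi(k) = 2 E_>k / (N_>k (N_>k - 1))`, and the weighted variant divides the
subgraph's total weight by the sum of the equally many strongest weights
anywhere in the network. Because high-degree nodes are dense by
construction, `phi` is normalized by the mean over null networks:
degree-preserving rewiring (50 swap trials per edge, via igraph's compiled
double-edge-swap engine) for the binary case, and weight permutation on the
fixed topology for the weighted case, which separates the weighted from the
topological effect. Permutation p-values use the add-one rule
`(1 + #{phi_rand >= phi}) / (1 + n_null)` and can therefore never be zero.
At extreme `k` the subgraph is tiny and `phi` takes few distinct values;
ties then make the permutation test conservative, which is why calibration
checks are run at thresholds where the subgraph retains at least ~15 nodes.

Communicability sums walks of all lengths with factorial damping:
`exp(A)` for the binary mask, and `exp(S^{-1/2} W S^{-1/2})` with
`S = diag(strength)` for weights. Both are computed by eigendecomposition of
the symmetric argument, which is exact to machine precision at these sizes.
Note that the strength normalization deliberately discounts raw degree, so
hub effects are most visible in the binary variant.

Link-type comparisons use one-sided Welch t-tests of each class against all
remaining edges at each `k`, uncorrected across thresholds, mirroring
common practice for these curves; the lack of multiplicity correction
across `k` is a documented limitation, and the per-`k` p-values are
strongly dependent. Classes with fewer than two finite values are reported
with the test skipped.

## Edge-wise twin models (ACTE family)

For each edge, phenotypes over a twin-plus-sibling cohort are modelled as
family-block multivariate normals. Every member has variance
`a2 + c2 + t2 + e2`; covariances are `a2 + c2 + t2` for MZ twins,
`0.5 a2 + c2 + t2` for DZ twins, and `0.5 a2 + c2` for any twin–sibling
pair (T is twin-specific; a sibling draws an independent copy). Age and sex
enter the mean as fixed effects in raw units — one global coefficient per
edge — rather than pre-residualization, matching SEM convention. Families
with missing members contribute the marginal likelihood of their observed
block (full-information treatment).

Numerical choices:

* Nonnegativity of variance components is enforced by optimizing path
  coefficients and squaring them, avoiding boundary-constrained
  optimizers.
* The mean/covariate coefficients are concentrated out by generalized
  least squares inside every objective evaluation. This is exactly
  equivalent to joint maximum likelihood, reduces the search to at most
  four parameters, and lets the cross-products with the design matrix be
  precomputed once per edge.
* BFGS with relative tolerance 1e-12, one moment-based start (Falconer-style
  estimates from the observed MZ/DZ covariances) plus random restarts, up
  to five in total, stopping as soon as two starts agree to 1e-6 in
  log-likelihood. Fits that never converge are flagged with NaN components
  and excluded from summaries.
* Outliers are removed per edge by the strict Tukey fence
  `Q1 - 1.5 IQR < w < Q3 + 1.5 IQR` with quartiles by linear interpolation
  of order statistics (the `quantile` type-7 convention); the same
  convention is used by the test oracles.

Model selection minimizes AIC (`2p - 2 lnL`, with `p` counting variance and
mean parameters) over the converged candidates ACTE, ACE, AE, CE, E; exact
ties go to the model with fewer parameters. Heritability is the
standardized `a2` of the selected model, and the full-ACTE `a2` is reported
alongside so that selection artifacts can be checked. Note that best-model
heritability is exactly zero wherever CE or E is selected, which biases the
cohort mean of `h2` slightly downward at low true heritability — a property
of the selection procedure, not of the optimizer.

## Transcriptional coupling

Expression tables are normalized by a scaled robust sigmoid
(`1 / (1 + exp(-(x - median)/(IQR/1.35)))`, then min–max to [0, 1]), first
per sample across genes and then per gene across samples; zero-IQR features
map to a constant 0.5 and are flagged. Correlated gene expression (CGE) is
the Pearson correlation of two regions' normalized profiles
(pairwise-complete over genes). Spatial autocorrelation is removed by
fitting `r(d) = A exp(-d/n) + B` with Levenberg–Marquardt least squares,
multi-started over the length scale, and retaining residuals
`CGE - r(d)`. Geodesic cortical distances can be supplied; Euclidean
distances are the fallback and are labelled in the fit object.

The gene contribution score is `GCS_ij^a = z_i^a z_j^a - r(d_ij)`, where
`z` standardizes each *region's* profile across genes with the population
(1/N) divisor — the one convention under which the mean of GCS over genes
reproduces the residual CGE identically, which the tests enforce to 1e-10.
A single-gene table is degenerate for that convention and is z-scored
across regions instead. Per-gene rich-versus-peripheral Welch t-statistics
summarize each gene's contribution to hub–hub coupling; enrichment uses
gene score resampling (mean set score against means of equally sized random
draws, upper tail only since the score is directional, add-one p, BH
adjustment across retained sets of 5–100 genes). The resampling null
depends only on the set size, so it is computed once per distinct size.

## Microstructural profile covariance

Depth-wise intensity profiles (16 surfaces by default) are corrected for
the midsurface y-coordinate — each depth regressed on y, residuals
standardized per depth — and regions are compared by the partial
correlation of their profiles controlling the cortex-wide mean profile.
Per-depth standardization makes the mean profile identically zero; the
partialling step detects this (null mean profile) and reduces to the plain
correlation, because the standardization has already removed the
cortex-wide component. On raw profiles the partialling is active, and it is
verified against an lm-residual oracle. Non-positive correlations are
thresholded to 0 in the raw channel. Since published pipelines differ in
the exact log transform, both channels are emitted: raw thresholded `r`,
and `log(r / (1 - r))` (finite and monotone on (0, 1)) with non-positive
entries floored at the minimum transformed value so the matrix stays dense
for the curve code.

## Generative growth models

Networks grow from an empty graph by adding one edge per iteration with
probability proportional to `theta_ij = d_ij^eta * (t_ij + eps)^gamma`,
where `d` is Euclidean distance and `t` one of 13 topological terms
(degree and clustering combinations, neighbour counts, matching index),
recomputed each iteration. Genetic variants substitute or add a factor
`g_hat^lambda`, with `g_hat` the residual CGE min–max rescaled to
`[eps, 1]` over node pairs — a monotone form that respects the
`lambda in [0, 200]` range without overflow. `eps = 1e-5` prevents
zero-probability lockout at the empty start. Scores are accumulated in log
space and shifted by their maximum before exponentiation. Rules whose
scores do not depend on the current topology (sptl, S, G, SG) are grown by
one sequential weighted draw without replacement, which has exactly the
same distribution as the iterative renormalized sampling.

Default parameter bounds follow the convention that wiring cost is always
penalized — distance exponent in [-15, 0] — while the topology exponent may
take either sign in [-4, 4] and `lambda` lies in [0, 200]; all bounds are
overridable.

Fit is summarized by two-sample Kolmogorov–Smirnov statistics on degree,
clustering, betweenness (exact shortest-path betweenness via igraph) and
edge length, with the energy being the maximum (the worst-fitted
property); the *sequence* of degrees — their spatial topography — is
summarized separately by the Spearman correlation with the target, since a
model can match the degree distribution while putting its hubs in the
wrong places. The optimizer samples the parameter box uniformly in round
one and then, in each later round, picks an evaluated point with
probability proportional to the inverse rank of its objective and proposes
a new point uniformly within that point's nearest-neighbour-radius box —
an approximation of Voronoi-cell sampling that avoids the cost of exact
cell membership tests; the preferential-sampling law itself is not pinned
down by the literature this follows.

## What the synthetic data emulate — and what they do not

The generators plant exactly the structure the analyses assume: geometric
edge probability `base_prob * exp(-d/decay_scale)` with additive presence
boosts between hubs (`richclub_boost`) and on hub–nonhub pairs
(`hub_degree_boost`, default a third of the rich-club boost), plus
boost-linked weight elevation so planted hubs survive weight-ranked density
thresholding as true top-degree nodes; twin phenotypes built from shared
latent factors with the exact ACTE covariance algebra; expression drawn
from a latent region covariance equal to the target decay-plus-boost
correlation (so the implied CGE structure is exact in expectation, repaired
by minimal diagonal inflation with a warning if the implied matrix is not
positive definite); and depth profiles as block templates plus noise plus
an injected y trend. Default cohort sizes follow the emulated twin-imaging
study: 117 MZ pairs with 69 siblings, 60 DZ pairs with 48 siblings; the
default decay parameters are A = 0.64, B = -0.19, n = 90.4 mm.

They do not emulate tractography artifacts, donor- or batch-specific
expression effects, realistic cortical geometry or spatially
autocorrelated measurement noise. Passing tests therefore establish the
correctness and calibration of the machinery under its own assumptions,
not the empirical findings on real imaging, transcriptomic or histological
data.

## Problem sizes and reproducibility

The test-suite and acceptance computations run at desk scale, chosen so the
full suite completes in minutes on one core: 100–150-node connectomes,
200 nulls per rich-club curve, 200 edges per heritability level at the
emulated cohort sizes, 500-gene atlases, 10^4 resampling iterations for
enrichment calibration, 500 evaluations for generative self-recovery, and
20 optimization replicates for the TG-versus-ST comparison on 50-node
targets. Every generator draws from one seeded RNG stream per call and
records its seed; the pipeline writes a manifest with parameters, seeds and
md5 digests of all outputs, and reruns with the same configuration are
byte-identical.

## Known limitations

* Best-model heritability is shrunk toward zero at weakly genetic edges by
  the AIC selection step (see above); the full-ACTE channel is the
  unshrunk alternative.
* Uncorrected per-`k` significance flags on link-type curves inherit strong
  dependence across thresholds.
* The weighted rich-club null separates weights from topology but does not
  preserve geometry; cost-preserving nulls are out of scope.
* Enrichment resampling treats genes as exchangeable; spatially constrained
  nulls for pairwise phenotypes are an open problem and not attempted.
* The exact functional form by which transcriptional coupling should enter
  the growth models is not settled; the rescaled-power form used here is
  monotone and bounded, and alternative forms can be substituted by
  transforming the `gexp` matrix before the call.
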