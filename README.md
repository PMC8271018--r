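# connherit

Do genes shape all connections of the human structural connectome equally,
or do they concentrate on the *rich club* — the costly, densely
inter-connected core of high-degree hub regions? `connherit` is an R
toolkit for asking that question end to end: it builds group connectomes
from subject-level connectivity matrices, quantifies rich-club organization
and communicability against null models, decomposes edge-wise phenotypic
variance into genetic and environmental components with classical twin
models, measures distance-corrected transcriptional coupling and
cytoarchitectonic similarity between connected regions, and fits
generative models of network growth that trade off wiring cost, topology
and transcriptional similarity. It is written for network-neuroscience and
imaging-genetics researchers; everything runs on synthetic data with
planted structure, so the full pipeline is testable without any imaging,
transcriptomic or histological download.

## The models at the core

* **Rich club.** With hubs defined as nodes of degree > *k*, the
  topological rich-club coefficient is the hub-subgraph density
  φ(*k*) = 2*E*₍>k₎ / (*N*₍>k₎(*N*₍>k₎−1)); the weighted variant divides
  the subgraph weight by the sum of the equally many strongest weights in
  the network. Both are normalized by degree-preserving rewired (binary)
  or weight-permuted (weighted) nulls, Φ_norm(*k*) = φ/⟨φ_rand⟩, with
  add-one permutation p-values.
* **Communicability.** *C* = e^*A* for a binary mask;
  *C*ʷ = exp(*S*^−½ *W* *S*^−½) with *S* = diag(node strength).
* **Twin biometrics.** Per edge, family-block multivariate-normal
  likelihoods with var = a²+c²+t²+e², cov(MZ) = a²+c²+t²,
  cov(DZ) = ½a²+c²+t², cov(twin, sibling) = ½a²+c²; age and sex as fixed
  effects; squared-path nonnegativity; AIC selection over
  {ACTE, ACE, AE, CE, E}; heritability h² = standardized a².
* **Transcriptional coupling.** CGE = Pearson correlation of two regions'
  normalized expression profiles; spatial trend r(d) = A·e^(−d/n) + B
  removed by nonlinear least squares; per-gene contribution scores
  GCS<sub>ij</sub><sup>a</sup> = z<sub>i</sub><sup>a</sup>z<sub>j</sub><sup>a</sup> − r(d<sub>ij</sub>),
  whose mean over genes equals the residual CGE exactly; gene-score
  resampling for set enrichment.
* **Microstructural profile covariance.** Depth-wise intensity profiles
  corrected for the midsurface y-coordinate, correlated between regions
  (partialling the cortex-wide mean profile where informative), positive
  correlations log-transformed.
* **Generative growth.** Edges added one at a time with probability ∝
  θ<sub>ij</sub> = d<sub>ij</sub><sup>η</sup> (t<sub>ij</sub>+ε)<sup>γ</sup>,
  13 topological terms t, plus genetic variants (S, G, SG, TG, ST) carrying
  a rescaled residual-CGE factor ĝ<sup>λ</sup>; fit = max
  Kolmogorov–Smirnov distance over degree, clustering, betweenness and
  edge-length distributions; degree topography judged separately by the
  Spearman correlation of degree sequences.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data and write tidy tables under `results/`. A condensed session:

```r
library(connherit)

sim  <- simulate_cohort_connectomes(cohort_spec(
          n_nodes = 100, n_subjects = 40, hub_fraction = 0.12,
          richclub_boost = 0.6, seed = 2026))
conn <- build_group_connectome(lapply(sim$subjects, `[[`, "sc"),
                               consistency_min = 0.30, density_target = 0.20,
                               nodes = sim$nodes)
conn
#> <connectome> 100 nodes, 990 edges (density 0.200), channel SC

rc <- normalized_rich_club_curve(conn, n_null = 200, seed = 2027)
range(rc$k[rc$phi_norm > 1 & rc$p < 0.05])
#> [1]  8 27        # the planted rich club, detected against rewired nulls
```

The 12 planted hubs hold the top degrees (minimum hub degree 36 versus
maximum non-hub degree 28), and Φ_norm exceeds 1 with p < 0.05 across the
hub-defining range k = 8–27. Feeding twin phenotypes with higher additive
genetic variance planted on rich links (a² = 0.8 versus 0.2) through the
edge-wise screen:

```r
scr <- edgewise_heritability(tw)    # tw: simulated twin cohort on conn's edges
scr
#> <heritability_screen> 184 edges; mean h2 = 0.174
#>   best-model proportions: ACTE=1.6%, ACE=0.5%, AE=52.7%, CE=26.1%, E=19.0%
```

and the link-type comparison recovers the planted concentration: rich-link
h² = 0.78 against a network mean of 0.17 (one-sided Welch p ≤ 3.9e-32 at
the planted thresholds). The same curve logic applied to residual CGE
(hub-coupling boost 0.35) gives rich-link coupling 0.128 against a network
mean of 0.003, and to microstructural profile covariance (hubs sharing a
depth template) gives rich-link MPC 1.82 against −2.20. In the generative
stage, the degree-average cost-topology rule fits the planted-hub network
best among the classical rules (energy 0.14), and the transcriptionally
constrained TG variant beats the classical ST model on degree topography
(median degree-sequence ρ 0.28 versus 0.12 over matched optimization
replicates) — hubs end up in the right places only when the model can see
the coupling.

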