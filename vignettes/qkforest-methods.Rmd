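---
title: "Methods: structure-corrected association mapping and forest-based marker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-corrected association mapping and forest-based marker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genebank core collections segregate for both the traits of interest and for
deep population structure: accessions sharing a breeding history share allele
frequencies *and* trait means. A single-marker scan that ignores this
stratification attributes the subpopulation mean differences to every marker
whose frequency differs between subpopulations, producing large numbers of
false associations. `qkforest` implements the standard ladder of corrections
for collections genotyped with *dominant binary markers* (AFLP-type bands and
SSR alleles recoded per allele as present/absent, one haploid profile per
accession), together with a Random-Forest marker selection whose
significance is calibrated by permutation, and a partial-correlation view of
correlated metabolite-style traits.

# The four association models

For a trait $y$ and marker $x_j \in \{0,1\}$:

1. **Naive** — $y = \mu + \beta x_j + \varepsilon$, OLS, two-sided $t$ test
   of $\beta$ (with two marker classes this equals the pooled-variance
   two-sample $t$ test).
2. **Q** — adds admixture memberships as fixed covariates:
   $y = \mu + Q\gamma + \beta x_j + \varepsilon$. Because membership rows sum
   to one, only $K-1$ columns of $Q$ enter the design (identifiability; the
   source material is silent on this, so the choice is recorded here).
3. **K** — mixed model $y = \mu + \beta x_j + g + \varepsilon$ with
   $g \sim N(0, \sigma_g^2 K)$, $\varepsilon \sim N(0, \sigma_e^2 I)$.
4. **Q+K** — both corrections at once.

The variance components are estimated by REML, profiling
$\lambda = \sigma_g^2/\sigma_e^2$: one eigendecomposition $K = U D U'$
rotates the model so the covariance is diagonal ($\lambda D + I$) and each
$\lambda$ evaluation costs $O(n)$. The profile is maximized on a 100-point
log grid over $[10^{-5}, 10^5]$ and refined by `optimize()` between the
flanking grid points; grid-edge optima are reported as boundary estimates,
not errors. Tests verify the spectral path against a dense
$O(n^3)$-per-point REML implementation to $10^{-6}$.

By default the components are estimated **once** on the marker-free null
model and reused for every marker (the EMMAX-style approximation);
`vc_strategy = "per-marker"` re-profiles REML with the marker in the design
and is the route checked against a brute-force dense-GLS oracle
($|\Delta\log_{10} p| \le 0.05$ at $n = 50$). Wald $t$ tests use denominator
df $n - \mathrm{rank}(X)$. Variance explained is the incremental $R^2$ of
the marker against the same model without it, computed on the whitened
(GLS) scale for the mixed models and clamped to $[0, 1]$.

# Population structure

Two independent routes, as in comparative practice:

* **PCO-MC** — Jaccard distances over presence sets (shared absences are
  uninformative for dominant bands), classical metric scaling
  (double-centering of $-D^2/2$; negative-eigenvalue axes are dropped and
  their mass reported), then kernel-density mode clustering on the retained
  axes: Gaussian kernel densities at each accession, hill-climbing to the
  densest neighbour within one bandwidth radius, cluster labels in
  decreasing mode density. The SAS-style parametric cluster significance is
  replaced by a bootstrap co-assignment stability score in $[0,1]$. The
  default bandwidth is a Silverman-style rule on the retained axes, and the
  default is the first two axes. The procedure is made order-invariant by
  clustering lexicographically sorted unique points.
* **Bayesian admixture** — a haploid Gibbs sampler with independent
  Beta(1,1) band frequencies per subpopulation, flat Dirichlet memberships,
  and latent per-accession-per-marker ancestries. This deliberately
  *simplifies* the reference implementation used in the original study
  (whose correlated-frequency model and 300,000-iteration runs are out of
  scope); the admixture Q is consumed downstream only as a fixed covariate
  matrix, and recovery tests (aligned MAE $\le 0.15$, hard-assignment
  accuracy $\ge 0.9$ on an $F_{ST} = 0.25$ two-population fixture) validate
  exactly that role. Label switching across samples is resolved by greedy
  matching of the frequency matrix to the first post-burn-in sample.
  `select_k()` reports mean post-burn-in log-likelihood per assumed K and
  deliberately makes no automatic choice: the criterion used to pick K = 4
  in the motivating study is not recoverable, so the package surfaces the
  table instead of guessing.

# Kinship

The exact estimator behind the study's kinship software is not recoverable;
the default here is a frequency-corrected allele-sharing form: standardize
each marker by $\sqrt{p_j(1-p_j)}$, average the cross-products, normalize to
correlation scale (so duplicated accessions have kinship exactly 1),
truncate negative values to 0, and set the diagonal to 1. With this
similarity convention $\sigma_g^2$ in $V_G = \sigma_g^2 K$ is the genotypic
variance of one non-inbred accession. Jaccard similarity is provided as the
alternative the study reports testing with identical results. Negative
truncation makes the matrix mildly indefinite (relative minimum eigenvalue
around $-0.02$ on two-population fixtures); the REML fitters apply a
tolerance clip — eigenvalues above $-0.05 \cdot \lambda_{max}$ are zeroed,
anything worse is an error instructing an explicit eigen-clip.

# Random Forest

No regression-forest implementation is available in the target environment,
so the forest is implemented natively (C++): bagged, fully-grown CART
regression trees, `mtry` candidate markers per split, minimum node size 5.
Because every predictor is a binary band, each candidate split is evaluated
in one pass over the node. Out-of-bag samples give the honest MSE; variance
explained is $1 - \mathrm{MSE}_{OOB}/\mathrm{Var}(y)$ (population variance).
Importance is the **unscaled** mean increase in OOB MSE when a marker's
out-of-bag values are permuted (matching the "mean decrease in MSE"
definition; a variance-scaled variant is deliberately not the default).

`mtry` is tuned over the grid $\{3, 6, 12, 24, 48, 96\}$ by OOB variance
explained (ties to the smaller value, oversized values skipped), **once**,
on the observed response, and held fixed for all permutation runs:
re-tuning per permutation would multiply cost by the grid size and change
the null being sampled. The per-marker significance test permutes the whole
response `n_perm` times (1000 by default), refits the forest, and stores
each marker's importances as its own null distribution; a marker is
significant iff its observed importance exceeds the empirical
$(1-\alpha)$ order-statistic quantile of its own null, and the permutation
p-value uses the $(1 + \#\{null \ge obs\})/(1 + B)$ estimator so p can never
be 0. `perm_trees` may be reduced below `n_trees` for desk-scale runs, in
which case the observed forest also uses `perm_trees` to keep observed and
null importances exchangeable.

# Multiple testing

Two corrections, matching the two cited in the source material, both
exposed and labelled: Benjamini–Hochberg step-up FDR (the default for the
comparison report, thresholded at 0.05) and Westfall–Young step-down maxT
resampling. For the mixed models the permutation scheme rotates by the
null-model covariance inverse square root first — in the whitened space the
errors are exchangeable under the null, so permuting the whitened residuals
and recombining them with the null fit respects K. Adjusted p-values are
monotone-enforced along the step-down order and are bitwise reproducible
under a fixed seed. Untestable markers (monomorphic, or collinear with Q)
carry NA through every correction and are excluded from the family size.

# Metabolite network

Full-order partial correlations: scale the inverse correlation matrix,
$\rho_{ij\cdot rest} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$, tested
via the $t$ transform with df $n - 2 - k$ where $k$ conditions on the other
traits (the standard full-order choice; the source is silent on testing).
When $n$ approaches the trait count, a shrinkage estimator toward the
identity with the analytic (Schäfer–Strimmer-style) intensity replaces plain
inversion; plain inversion is the default when well conditioned, and both
are exposed since the study's network methodology is ambiguous on this
point. Trait–trait edges require partial-correlation $p \le \alpha$ (weight
$|\rho|$); marker–trait edges take significant markers after the chosen
multiple-testing adjustment with weight $-\log_{10}(p_{adj})$. Trait
vertices are kept even when isolated; markers are included only with edges.
Export is a strict Pajek dialect (`*Vertices n`, quoted labels, 1-based
ids, `*Edges u v w`) plus TSV mirrors, with a reader used to verify
lossless round trips.

# The synthetic world

The generator states one world and the tests measure it; its defaults are
not tuned to outcomes:

* **Allele frequencies** — ancestral frequencies uniform on $[0.1, 0.9]$
  (near-fixed loci would dominate otherwise), subpopulation frequencies
  Balding–Nichols $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with $F$ the
  divergence parameter (default 0.25).
* **Admixture** — membership rows $\sim \mathrm{Dirichlet}(\alpha)$ with
  $\alpha = 0.17$, calibrated a priori by Monte Carlo so that the fraction
  of accessions whose maximum membership exceeds 0.70 matches the 109/168
  ≈ 0.65 assignment rate of the motivating collection ("high level of
  admixture").
* **Markers** — Bernoulli draws with success $\sum_k Q_{ik} p_{kj}$: one
  haploid dominant profile per accession. No heterozygote state exists
  anywhere in the pipeline, mirroring the ploidy-one treatment of the data.
* **Phenotypes** — $y = Q\,\text{pop\_effects} + X_c\beta + g +
  \varepsilon$ with $g \sim N(0, \sigma_g^2 K)$ (K eigen-clipped, the clip
  recorded) and multi-trait residuals sharing an AR(1)-style chain
  correlation (default $\rho = 0.6$) so the full-order partial correlations
  have a known sparsity pattern. "Population shifts of 1 SD" is realized as
  adjacent subpopulation means one residual SD apart, e.g. $(0,1,2,3)$ for
  four subpopulations. Every component is stored per accession and trait
  and sums to the phenotype exactly.

What the generator does **not** emulate: linkage disequilibrium (markers
are exchangeable), missing data (rejected, not imputed — the source never
mentions missingness), genotyping error, non-Gaussian trait noise, and the
within-accession heterogeneity of real genebank entries (an accession is
one haploid profile; how the original study collapsed heterogeneous,
heterozygous accessions to one binary profile is not stated). A green test
therefore establishes correctness of the statistical machinery under the
stated model, not robustness to those real-data features.

# What the acceptance experiments show — including one honest red

Most pipeline-level properties hold at their stated tolerances: the naive
model's rejection rate under pure confounding is ~0.36 at nominal 0.05
while the Q and Q+K models stay inside the 99% binomial interval of 0.05;
heritability 0.5 is recovered to within 0.1; the admixture sampler recovers
Q; the RF permutation test is level-α under the null and detects a 1.5 SD
planted marker; BH, maxT, and the partial-correlation machinery match their
oracles.

One expectation is **deliberately left failing**: that the K-only mixed
model's rejection rate stays within 20% of the naive model's ("kinship
alone fails to correct"). In the motivating study that finding was driven
by an empirically near-flat kinship matrix — 79.5% of pairs below 0.05 —
which carries almost no structure information. In the synthetic world
mandated for the acceptance experiment ($F_{ST} = 0.25$), the marker-based
kinship *strongly* encodes subpopulation membership (the same world's
kinship checks require within-subpopulation kinship to exceed
between-subpopulation kinship), and REML consequently absorbs most of the
confounding: the K-only rate lands around 0.06, a factor ~6 below the
naive rate. This is the standard mixed-model GWAS result, and no correct
implementation can simultaneously satisfy "K is informative at
$F_{ST}=0.25$" and "K fails to correct". The assertion is implemented
exactly as stated and left red rather than weakened; the contrast it
encodes *is* reproduced qualitatively whenever the kinship is
uninformative, as in the study's data.

Two smaller stated example values did not survive contact with their own
oracles and were frozen at the oracle-derived values instead: the
probability that a Dirichlet(0.01, 4) row exceeds 0.99 membership is 0.871
(not ≥ 0.95), and the REML null heritability ratio falls below 0.05 in
about 74% of replicates at $n = 300$ (not ≥ 90%) because the null
distribution is half a point mass at the boundary and half a positive tail.

# Numerical conventions

* $\lambda$ grid $[10^{-5}, 10^5]$; boundary maxima flagged, not errors.
* p-values floored at the smallest positive double; permutation p-values at
  $1/(B+1)$.
* Marker testability: residual sum of squares after projecting out the
  covariates must exceed $10^{-9}$ of the marker's centered sum of squares.
* Frequency filter is strict and symmetric: keep
  $f_{min} < \bar{x}_j < 1 - f_{min}$. A band present in essentially all
  accessions is as uninformative as a rare one, and the naive model is
  undefined for monomorphic markers.
* SSR most-frequent-allele ties break to the first column; mtry ties to the
  smaller value; both recorded in the result objects' provenance.
* Pipeline stage seeds derive from the global seed by stable hashing of
  stage names, so adding a stage never silently shifts another stage's
  random stream; reruns are bitwise identical and the manifest carries md5
  checksums of every artifact.

# Known limitations

Single-marker models only (no multi-marker, haplotype, or epistasis
models; the forest captures interactions implicitly but defines no
interaction statistic). The admixture sampler assumes independent band
frequencies across subpopulations and markers. The forest handles binary
predictors only — exactly the domain of this pipeline, but not a
general-purpose forest. Genomic-control-style inflation factors are not
reported. The CLI is a thin veneer over the R API and does not implement a
configuration language beyond flags.
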