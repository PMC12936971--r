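---
title: "Models and design choices in msnbiotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in msnbiotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each stage
implements, the assumptions they make, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` do not
themselves compute.

## The problem

Clinical neurodevelopmental diagnoses collect heterogeneous presentations
under one label. The workflow here asks whether network-level deviations
from normative brain development can stratify cases into reproducible,
neurobiologically defined subgroups ("biotypes"): build an individual brain
network per subject from structural morphometry, profile each region's hub
role, score every subject's deviation from an age- and sex-expected
reference, cluster cases by their deviation profiles against the control
distribution, and validate the clusters out of sample.

## Morphometric similarity networks

For one subject, each region contributes a sample of positive gray-matter
values (standing in for within-parcel voxel values). The edge between
regions $i$ and $j$ is

$$\mathrm{KLS}(p_i, p_j) = \exp\{-[\mathrm{KL}(p_i \| p_j) +
\mathrm{KL}(p_j \| p_i)]\} \in (0, 1],$$

computed on discretized densities over a shared per-subject grid spanning
that subject's pooled value range (individualized construction). The
divergence is symmetrized by the sum of the two directed divergences, the
conventional choice that makes the exponent a symmetric dissimilarity.

**Density estimation.** `estimate_density()` defaults to a 128-bin histogram
with a probability floor of $10^{-10}$ per bin (keeping all divergences
finite). The floor interacts badly with sparse histograms: with a few
hundred samples spread over 128 bins, many bins are empty and the floored
log-ratios dominate the divergence, collapsing all similarities toward 0 and
drowning real signal in discretization noise. A Gaussian kernel estimate
evaluated at the bin midpoints (`method = "kde"`, Silverman bandwidth) fixes
this and is the *pipeline* default; the histogram remains the low-level
default and is the better choice when samples per region vastly outnumber
bins. Whether to floor empty bins at all was an open choice; the floor is
ours.

## Hub topology

Three nodal metrics on the proportionally thresholded network (top
`sparsity` fraction of off-diagonal edges by weight, default 0.3, ties at
the cutoff broken lexicographically):

* degree centrality — node strength (sum of incident weights);
* nodal efficiency — mean inverse shortest-path length to all other nodes,
  with edge length $1/w$ (the standard map for similarity weights) and
  $1/d = 0$ for unreachable pairs;
* participation coefficient — $1 - \sum_s (k_{is}/k_i)^2$ over modules $s$,
  0 for isolated nodes by convention.

The participation partition is estimated once, from the mean training-control
network, by consensus Louvain (seeded restarts, co-assignment clustering) and
then held fixed for every subject: normative modeling requires the metric to
mean the same thing across subjects. Thresholding scheme, partition source,
and weighted-vs-binary choices are exposed as configuration rather than
constants, since each is a known sensitivity in this literature.

## Normative models

Per node $\times$ metric (so $3R$ independent models), the response $y$ is
standardized and passed through a sinh-arcsinh warp
$t = \sinh(\delta\,\mathrm{asinh}(y_{std}) - \epsilon)$ (skew $\epsilon$,
tail weight $\delta > 0$; identity at $(0, 1)$), and $t$ is modeled by
Bayesian linear regression on a cubic B-spline basis of age (5 interior
knots at training-age quantiles — low enough for a few hundred subjects per
model) plus sex. Prior precision and noise precision are set by evidence
maximization (fixed-point updates); the warp parameters maximize the profile
marginal likelihood including the warp Jacobian, by bounded L-BFGS on
$(\epsilon, \log\delta)$ from the identity start, with bounds
$|\epsilon| \le 2$, $\delta \in [0.25, 4]$ to exclude degenerate warps.
Non-convergence falls back to the identity warp with a flag.

Deviations are $z = (t(y) - \mu_{pred}) / \sqrt{\sigma^2_{pred} +
\sigma^2_{noise}}$, monotone in $y$ at fixed covariates; $|z| \ge 2$ defines
an extreme deviation (about 4.55% of well-modeled controls). Ages outside
the training range are clamped for the spline basis and rejected beyond a
tolerance band of 10% of the training span on each side — wide enough that a
validation subject marginally outside the controls' observed range is still
scored, narrow enough to refuse genuine extrapolation.

**Site handling.** Site never enters as a covariate. New cohorts are handled
by transfer recalibration: the offset and scale of the z-scores are
re-estimated on $\ge 20$ adaptation controls, leaving the coefficients
untouched. This mirrors how a reference model is carried to a new scanner
and keeps a single mechanism for discovery and validation cohorts. A 2-fold
linear-SVM site-prediction check (`check_site_effects()`) screens residual
site information; balanced accuracy near 1/(number of sites) indicates
successful harmonization.

## Deviation cartography

Per-node extreme-deviation proportions per group; case minus control
difference in percentage points; two-sided add-one permutation p-values
from group-label shuffles (within site by default — the multisite design
makes site the natural exchangeability block; a flag disables it); spatial
significance from spin tests — random 3-D rotations of the spherical node
layout with one-sided nearest-neighbor reassignment (duplicates permitted),
preserving each map's value multiset and spatial autocorrelation;
Benjamini-Hochberg FDR across nodes; Cohen's $h$
($2\,\mathrm{asin}\sqrt{p_1} - 2\,\mathrm{asin}\sqrt{p_2}$) for proportion
contrasts and pooled-SD Cohen's $d$ with two-sample t for per-subject
extreme-node burdens. Between-biotype frequency contrasts use k x 2
chi-squared tests without continuity correction (expected counts under 5
trigger a warning and a Fisher fallback).

## Multimodal fusion

The three subjects x nodes deviation matrices are linked by multiset CCA
under the SSQCOR criterion (sum of squared correlations among modality
variates), solved deflationarily by alternating generalized-eigenvector
updates; the canonical variates are orthonormal per modality and the
associated maps are least-squares back-projections. Joint ICA then runs
symmetric FastICA (logcosh contrast, 20 seeded restarts keeping the best
negentropy) on the maps concatenated along the node axis; sources are
sign-fixed (largest-magnitude element positive) and split back into
per-modality blocks; subject-wise mixing coefficients are
$A_k = D_k W^{+}$. Sources whose excess kurtosis sits within two sampling
standard errors of zero are flagged — ICA cannot identify Gaussian sources.
The component count is the smallest whose cumulative reconstruction
explained variance exceeds `variance_floor` (default 0.8) in every modality.
SSQCOR-with-deflation and the logcosh contrast are our documented choices
where several equivalent conventions exist.

## HYDRA biotypes

$k$ weighted linear max-margin classifiers (faces) jointly separate controls
from cases: every control is a negative example for every face; each case is
a positive example for its assigned face only. Faces are L2-regularized
squared-hinge SVMs solved by a compiled damped-Newton method — the nested
cross-validation needs thousands of face fits, and the smooth objective
admits a solver that is both fast and exactly deterministic. Controls weigh
$1/n_{controls}$ per face and cases $1/n_{cases}$ globally, which makes the
summed objective non-increasing across uninterrupted alternating iterations
(asserted at every step); the empty-face repair rule — re-seed with the case
deepest inside the polytope — may raise it and resets the assertion.

Two design choices departed from the obvious defaults after the obvious
defaults measurably failed on planted-truth simulations:

* **Regularization.** At `C = 1` the hinge term dominates and the
  alternation tends to collapse all cases onto one face — a degenerate
  polytope that can even minimize the global objective. The default is
  `C = 0.25`: the margin term forces faces to specialize. C chiefly governs
  which basin an initialization falls into rather than whether a good
  solution is a fixed point.
* **Initialization.** The global objective does not rank solutions (the
  collapsed solution often minimizes it), so restarts cannot be selected by
  objective, and raw k-means on case features is blinded by variance shared
  across all case deviations. The biotype signal lives in each case's
  strongly *negative* deviations (extreme under-coupling), so up to three
  informed starts — k-means on the extreme-deviation mask, k-means on the
  negative feature part, and average-linkage clustering of negative-part
  correlations — anchor the restart ensemble alongside random balanced
  assignments. Final labels come from spectral consensus over the restart
  co-assignment matrix plus one final alternating refit, so the returned
  polytope is consistent with the returned labels.

The restart-stability ARI scores pairs involving an effectively single-face
(collapsed) solution as 0: two degenerate solutions agree trivially and
carry no clustering signal; without this rule the permutation null would be
dominated by mutually "stable" collapses. The permutation test's null
permutes each feature column independently across cases — destroying the
multivariate coupling that defines subgroups while preserving every node's
marginal deviation distribution. (Permuting within case rows instead, the
obvious alternative, also destroys per-node tail heterogeneity, which the
stability statistic legitimately reflects, and so makes the test
anticonservative whenever nodes differ in tail weight.) Model selection runs 10-fold nested cross-validation: per
candidate k, each fold model is fit on a seeded 70% subject resample of its
training portion and assigns the complete case set by expression scores;
per-k stability is the mean pairwise ARI between fold models' assignments,
and the chosen k maximizes it. Subject resampling is the canonical basis of
stability selection; comparing fold assignments against a single consensus
labeling instead saturates once k reaches the true count, because an
overfit extra face reproduces the same in-sample noise split in every fold.
Split-half validation and permutation testing probe the same stability from
different angles. Features are standardized with training
statistics stored in the model; expression scores $E_{ij} = w_j^T x_i + b_j$
(optionally normalized by $\|w_j\|$ — argmax assignment is invariant only
for equal-norm faces, so both variants are kept behind a flag) assign new
cases by row argmax, ties to the lowest face index.

## Spatial decoding

The three metric-wise difference maps are fused by z-scoring each across
nodes and averaging (the metrics are not commensurate; `sum` and `maxabs`
aggregations are available). Annotation decoding reports Spearman (default)
or Pearson spatial correlations with spin-test p-values — rotation
surrogates are shared across the annotation set — and BH adjustment across
annotations. Both correlation conventions are implemented because usage in
this literature is inconsistent; neither is asserted as canonical. PLS
decoding scores only the first component (weights proportional to the
standardized covariance $X^Ty$, the first PLS direction for a single
response; terms are the predictors and the fused map the response, recorded
in the output metadata): explained variance of the fused map, significance
by spin-rotating the response, and term stability by bootstrap over nodes
with per-resample sign alignment.

## The synthetic cohort generator

`generate_cohort()` draws, per subject and region, `n_samples_per_region`
positive values around a latent region mean

$$\mu_{sr} = b_{0r} + f_r(\mathrm{age}_s) + c_r\,\mathrm{sex}_s +
s_{\mathrm{site}(s)} + g_r\,a_{m(r),s} + e_{sr},$$

with logistic age curves $f_r$, additive site offsets plus per-site noise
scale multipliers, and per-subject module factors $a_m$. Regions within a
module share baseline, growth curve, loading, and sample-variance profile up
to small jitter — morphometric-similarity modules are sets of regions with
common maturational and architectonic profiles, and that shared structure is
what makes MSN edges informative. Modules are seeded k-means clusters of a
Fibonacci-lattice spherical layout (so spin nulls are well behaved and
modules are spatially contiguous).

Cases of biotype $k$ have the shared-factor term on a designated disjoint
node set replaced, with weight $\min(1, s)$ for $s =$ `effect_size` / 3, by
independent noise of standard deviation $\tau(1 + s)$: decoupled regions are
both desynchronized from their community and excessively variable. At
`effect_size = 0` cases are generatively identical to controls; at 3 the
replacement is complete with doubled idiosyncratic spread. The disruption is
a coupling change, not a mean shift, because MSN edges measure
distributional concordance — the planted effect must live in the network's
measured space. Symptom scores have biotype-ordered means (biotype 1 most
severe on both scales), truncated to [0, 1].

Defaults (300 + 300 subjects, 60 regions, 4 sites, 200 samples per region,
3 biotypes, ages 6-18 with male fractions 0.60/0.76) are the study
conditions every end-to-end test uses. What the generator does *not*
emulate: image-level artifacts, real scanner protocols or site sample sizes,
non-disjoint or nested subtype structure, symptom-network coupling, and any
spatial correspondence between module layout and real anatomy — so passing
tests demonstrate that the chain recovers the structure it assumes, not that
real ADHD cohorts contain such structure.

## Numerical and procedural choices

* Per-stage seeds derive from hashing the master seed with the stage name,
  so adding or dropping optional stages leaves other stages' streams
  untouched; every random consumer takes an explicit seed and restores the
  caller's RNG state.
* The pipeline caches each stage and recomputes a stage exactly when its
  cache is missing, the configuration hash changed (the hash covers all
  semantic parameters but not which stages were requested), or an upstream
  stage was recomputed. Stage timings are written separately from the
  manifest so manifests of identical runs are byte-identical.
* The k x 2 chi-squared statistic for [[20, 80], [5, 95]] is 10.286 (the
  closed form $n(ad-bc)^2$ over the margin products); tests assert that
  value.
* Spin tests use uniformly random rotations (QR of a Gaussian matrix,
  determinant +1); the `difference` statistic returns per-node p-values from
  rotated difference maps, the `correlation` statistic a single p.
* Test and acceptance problem sizes: calibration checks use 2000 training /
  2000 held-out controls over 20 seeds; end-to-end recovery uses the
  default study conditions over 10 seeds; null calibration uses one
  150 + 150 cohort at 40 regions (group and spin tests, 1000 permutations)
  and ten 80 + 60 cohorts at 24 regions for the HYDRA permutation test
  (39 permutations each); fusion identifiability uses 400 subjects, 100
  nodes, 15 replicates; determinism runs a 90 + 60 subject, 32-region
  pipeline twice. These sizes are the package's chosen simulation scales.

## Known limitations

* The stability permutation test detects *any* multivariate coupling among
  case deviations, not biotype structure specifically. A network pipeline
  induces benign within-subject coupling (one subject's whole similarity
  matrix is estimated from one sample of regional values, so that subject's
  deviations co-vary across nodes), and an independence-style null removes
  it; the test can therefore reject on cohorts with no planted subgroups.
  Treat a significant result as "more structure than independent noise",
  not as proof of discrete subtypes.

* The KLS floor makes histogram-based similarities sensitive to the
  samples-per-bin ratio; use the KDE estimator unless samples per region
  number in the thousands.
* HYDRA's alternation is a local search; the informed initializations target
  under-coupling biotypes (negative deviations). Planted structure expressed
  purely as positive deviations would need the symmetric inits (a one-line
  change), and real data may hold subtypes in directions none of the inits
  favor.
* The normative model assumes a single smooth age effect per node x metric
  and homoscedastic warped noise; site differences in curve *shape* (not
  offset/scale) are outside the transfer mechanism.
* mCCA+jICA identifiability requires non-Gaussian spatial sources; the
  kurtosis flag marks, but cannot rescue, near-Gaussian components.
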