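# msnbiotypes

Stratifying a pediatric clinical cohort into neurobiological subtypes
("biotypes") from structural MRI-derived brain networks. The package
implements, end to end:

1. **Morphometric similarity networks (MSN).** For each subject, the edge
   between two brain regions is the Kullback-Leibler divergence similarity
   of their gray-matter value distributions,
   `KLS(p, q) = exp(-[KL(p||q) + KL(q||p)])`, in (0, 1].
2. **Hub topology.** Three nodal hubness metrics on the proportionally
   thresholded MSN: weighted degree centrality, nodal efficiency
   (mean inverse shortest-path length, edge length `1/w`), and the
   Guimera-Amaral participation coefficient on a fixed consensus partition
   of the mean control network.
3. **Normative modeling.** Per node x metric, a warped Bayesian linear
   regression of the metric on a cubic B-spline basis of age plus sex, fit
   on controls: `t = sinh(delta * asinh(y_std) - epsilon)` is modeled by
   empirical-Bayes linear regression, with `(epsilon, delta)` chosen by the
   profile marginal likelihood. Each subject gets a deviation z-score per
   node x metric; `|z| >= 2` marks an extreme deviation.
4. **Deviation cartography.** Per-node extreme-deviation proportions,
   case-control difference maps, group-based and spatial (spin-rotation)
   permutation nulls, Benjamini-Hochberg FDR, Cohen's *h* and *d*.
5. **Multimodal fusion.** Multiset CCA (SSQCOR) plus joint ICA across the
   three metric-wise deviation matrices, yielding subject-wise mixing
   coefficients tested for group differences.
6. **Biotype discovery (HYDRA).** Semi-supervised max-margin clustering: k
   linear SVM hyperplanes form a convex polytope around the controls, each
   face defining a case biotype; nested cross-validation selects k by
   clustering stability (adjusted Rand index), with permutation and
   split-half validation.
7. **Spatial decoding.** Fused deviation maps correlated against
   receptor-like annotation maps under spin tests with FDR across the
   annotation set, and PLS regression against cognitive-term maps with
   spin-tested explained variance and bootstrap term loadings.
8. **Out-of-sample transfer.** Pretrained normative models are recalibrated
   on a validation cohort's controls (site offset and scale); validation
   cases are assigned to biotypes by maximum expression score against the
   pretrained polytope.

Because the motivating data are clinical MRI cohorts that cannot be
redistributed, the package ships a seeded synthetic-cohort generator
(`cohort_spec()` / `generate_cohort()`) that emulates the relevant
structure: multisite pediatric samples aged 6-18, nonlinear age effects,
site offsets and noise scales, module-structured regional coupling, planted
case biotypes that decouple designated node sets, and biotype-graded symptom
scores on a 0-1 scale. Every stage is exercised and tested against this
generator.

## Worked example

```r
library(msnbiotypes)

cfg <- pipeline_config(
  spec = cohort_spec(n_controls = 90, n_cases = 60, n_regions = 32,
                     n_sites = 2, n_samples_per_region = 80,
                     k_true = 2, effect_size = 3),
  master_seed = 5, k_grid = 2:3, n_restarts = 3, n_folds = 5,
  n_perm = 150, n_surrogates = 150, n_annotations = 6, n_terms = 8,
  n_boot = 80)
res <- run_pipeline(cfg, workspace = tempfile("ws"))

res$state$cv$ari
#>        k2        k3
#> 0.9468806 0.7171774
res$state$cv$chosen_k
#> [1] 2
table(res$state$hydra$case_labels,
      res$state$sim$cohort$true_biotype[res$state$sim$cohort$group == "case"])
#>      1  2
#>   1  0 30
#>   2 30  0
res$state$site_acc
#> [1] 0.52
```

The cross-validated stability peaks at the planted biotype count (k = 2),
the consensus labels recover the planted subgroups exactly, and site cannot
be predicted from the deviations much above chance (0.5 for two sites) —
the normative models have absorbed the site structure the generator
injected. Stage outputs (cohort table, topology profiles, deviation maps,
fusion components, the serialized HYDRA model, decoding tables, and a
markdown report) are written under the workspace as TSV/JSON.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` ... `07_transfer_validation.R`) at the full demo scale
(300 controls / 200 cases, 60 regions), writing under `results/`; run them
in order from the repository root.

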