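# cytomodules

Sample-level analysis of high-dimensional mass cytometry (CyTOF) studies of
the intestinal and blood immune system, aimed at the question that drives
treatment-naive IBD profiling: *which immune cell subsets co-vary as a
network, and which of those networks track mucosal inflammation?*

The package provides, as testable R building blocks:

* a **synthetic study generator** with complete ground truth — 44 designed
  immune subsets across six lineages measured by a 36/39-antibody panel,
  per-sample compositions from a logistic-normal model with latent
  co-abundance modules, two cohorts, paired tissues per subject,
  inflammation effects and replicate internal controls;
* **subset identification**: signature-based lineage assignment followed by
  per-lineage Gaussian-mixture clustering with BIC model selection;
* **differential abundance**: Welch t-tests of inflamed versus pooled
  noninflamed/control biopsies with Benjamini–Hochberg FDR control, and
  Kruskal–Wallis tests with Dunn's post-hoc comparisons;
* **correlation networks**: Spearman matrices over subset frequencies,
  module extraction by average-linkage clustering with silhouette-chosen k,
  qualification of modules as networks (membership and within-correlation
  thresholds), collective network frequencies and patient stratification;
* **label transfer**: linear discriminant analysis with class means
  \(\mu_k\), pooled covariance \(\Sigma\) and priors \(\pi_k\); posteriors
  \(p(k\mid x) \propto \pi_k \exp(-\tfrac12 (x-\mu_k)^\top \Sigma^{-1}
  (x-\mu_k))\) with a rejection option at threshold \(\tau\);
* **sample embeddings**: t-SNE and PCA of per-sample frequency profiles,
  replicate QC by silhouette, and Hotelling's two-sample
  \(T^2 = \frac{n_A n_B}{n_A+n_B} (\bar x_A - \bar x_B)^\top
  S^{-1}_{pooled} (\bar x_A - \bar x_B)\) on PCA-reduced groups.

See `vignettes/cytomodules-methods.Rmd` for the models, parameter defaults
and design rationale.

## Worked example

```r
library(cytomodules)

cfg <- defaultConfig("primary")
study <- simulateStudy(cfg, seed = 1, markers = FALSE)
freq <- trueFrequencies(study)          # samples x subsets, % of CD45+
da <- ttestInflamedVsRest(freq)         # inflamed vs noninflamed/control
mods <- extractModules(spearmanMatrix(freq), da = da)
mods
#> CorrelationModules over 44 subsets: 4 modules, 3 qualified networks
#>   module 1: 9 members, mean rho 0.66 [network] <network3>
#>   module 2: 21 members, mean rho 0.48 [network] <network2>
#>   module 3: 11 members, mean rho 0.57 [network] <network1>
#>   module 4: 3 members, mean rho 0.15
sum(da$significant & da$direction == "up_in_inflamed" &
    da$subset_id %in% networkMembers(mods, "network2"))
#> [1] 11
sum(da$significant & da$direction == "down_in_inflamed" &
    da$subset_id %in% networkMembers(mods, "network1"))
#> [1] 10
```

Three qualified networks emerge: a 21-subset module enriched in inflamed
biopsies (11 of its members individually significant at FDR < 5%), an
11-subset module depleted in inflammation (10 significant), and a 9-subset
blood-like module; a weakly-correlated trio is detected but does not
qualify. `collectiveFrequencies()` and `stratifyPatients()` then flag the
patients whose inflamed biopsies are dominated (> 50% of CD45+ cells) by
the enriched network.

For the cell-level stages:

```r
study <- simulateStudy(cfg, seed = 1, markers = "intestinal")
gated <- gateCD45(study)
labeling <- identifySubsets(gated)         # lineages + GMM/BIC clustering
length(labeling@hierarchy)                 # 44 recovered subsets
model <- fitLDA(gated, labeling)
pred <- predictWithRejection(model, gated, tau = 0.95)
```

`runPipeline(pipelineConfig(), "report/")` chains all stages and writes
tab-separated tables, a JSON summary and a log.

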