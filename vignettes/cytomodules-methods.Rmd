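---
title: "cytomodules: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytomodules: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cytomodules` implements a sample-level analysis pipeline for mass-cytometry
(CyTOF) studies of intestinal and blood immune cells: subset identification
from per-cell marker intensities, per-sample subset frequency matrices under
two denominators, differential abundance with FDR control, Spearman
co-abundance networks with module qualification, linear-discriminant label
transfer with a rejection option, and sample-level embeddings with
multivariate group statistics. Because real studies of this kind are large
and access-restricted, the package ships a first-class synthetic study
generator with complete ground truth; every stage is exercised and tested
against that generator.

# The synthetic study generator

## Designed subsets and marker phenotypes

The generator emulates a two-cohort, treatment-naive IBD study design. A
36-antibody panel (39 in the validation cohort, which adds CD66b, CD1c and
CD163) measures 44 designed immune subsets spread over six lineages: 9 CD4
T, 8 CD8 T, 7 TCR-gammadelta T, 8 ILC/NK, 5 B, and 7 myeloid/granulocyte
subsets. Each subset has a fixed arcsinh-scale mean phenotype built from a
lineage base profile plus subset-defining markers (e.g. the HLA-DR+CD38+
effector-memory CD4 T subset sets HLA-DR and CD38 to 4). Phenotypes satisfy
a separability guarantee — every pair of subsets differs by at least 1.5
arcsinh units in at least two markers — which is checked at construction
time.

Per-cell intensities are drawn from normals truncated at zero. Expressed
markers (mean >= 1) use sd 0.35; background channels sit at 0.45 with sd
0.15, i.e. three standard deviations above the truncation bound, so the
draws are near-Gaussian. This matters: heavily truncated background
channels are strongly skewed, and skew in many dimensions systematically
inflates the number of mixture components that information criteria
support. Directly simulating raw ion counts is deliberately avoided — every
analysis stage operates on transformed intensities, so the generator
produces them directly.

## The composition model

Per-sample subset compositions follow a logistic-normal model. For subset
$k$ in sample $s$ of subject $j$ (tissue $t$):

$$\log a_{sk} = b_{tk} + u_{jk} + \lambda_k f_{s,m(k)} + \varepsilon_{sk},
\qquad p_{s\cdot} = \mathrm{softmax}(\log a_{s\cdot})$$

* $b_{tk}$: tissue baseline log-abundance (ileum, colon, blood differ;
  blood is dominated by naive/central-memory subsets).
* $u_{jk} \sim N(0, \sigma_{subj}^2)$, shared across all of a subject's
  samples: induces the within-subject composition correlation seen in real
  data. Default $\sigma_{subj} = 0.4$.
* $f_{s,m}$: latent module factor, one per sample and module, shared by all
  module members — this is what creates block-structured Spearman matrices.
  Default $\sigma_{mod} = 0.7$ with loadings 1.0 (network1), 1.25
  (network2) and 1.2 (network3); the larger loadings compensate the extra
  counting noise of the rarer members of those modules. The three
  module-free subsets share only a weak residual factor (loading 0.7) and
  carry larger idiosyncratic noise, so they appear as a detected but
  unqualified residual cluster.
* $\varepsilon_{sk} \sim N(0, \sigma_{noise}^2)$, default 0.4.

Cell counts are multinomial with Poisson-distributed totals around 2,000
(ileum), 1,000 (colon) and 5,000 (blood) cells per sample — a deliberate
desk-scale reduction of the tens of thousands of cells per sample a real
study acquires; counts are configurable. Internal-control replicates (7 by
default) share one fixed blood composition and differ only by multinomial
and expression noise.

## Inflammation effects

Eleven network2 subsets carry `up_in_inflamed` and ten network1 subsets
carry `down_in_inflamed` flags; in inflamed samples their log-abundance is
shifted by $\pm\delta$ with $\delta = 1$ (about 2.7-fold), chosen so that
the flagged subsets are detected with power near 1 at the default sample
sizes while the unflagged module members stay below the FDR threshold. The
module factors themselves carry no inflammation shift by default
(`deltaFactor = 0`): a factor-level shift would propagate a detectable mean
change to *every* module member, contradicting the designed pattern in
which only the flagged members reach significance. `deltaFactor` remains a
parameter for users who want a uniformly shifted module.

Two further designed effects: a designated "high-network2" subgroup of IBD
subjects (45% by default) receives an extra `deltaHigh = 0.5` on the
flagged network2 subsets in inflamed samples, which makes the collective
network2 frequency exceed 50% of CD45+ cells in roughly half the patients;
and IBD subjects' blood receives a `deltaBloodSpike = 1.2` boost of the
HLA-DR+CD38+ EM CD4 subset, so that blood cells matched to that intestinal
phenotype are more frequent in patients than controls. The synthetic blood
cells use the same phenotypes as tissue cells; real blood/tissue phenotype
divergence (which makes most real blood cells reject against intestinal
classes at high thresholds) is not modelled.

Baseline healthy-intestine shares by module role — network1 members 2.2%,
network2 flagged 0.5%, network2 unflagged 1.3%, network3 1.2%, unassigned
4% — were chosen so that the inflammation shifts roughly conserve total
mass (the 10 depleted subsets lose about as much share as the 11 enriched
ones gain). This keeps compositional closure effects small: in a
composition, pushing one group of subsets up mechanically pushes every
other subset down, and an unbalanced design would spill "significance" onto
unshifted subsets.

# Subset identification

The interactive hierarchical embedding used to cluster cells in the
original workflow is replaced by a deterministic, testable two-level stage:

1. **Lineage assignment**: each cell is scored against six lineage
   signatures (mean of `high` markers minus mean of `low` markers) and
   assigned to the argmax, with a fixed tie-break order. On default
   synthetic data the accuracy is above 0.995.
2. **Within-lineage Gaussian mixtures**: for each lineage, diagonal-
   covariance (`"VVI"`) Gaussian mixtures are fitted over k = 1..12 and the
   component number is selected by maximum BIC. Diagonal covariance is the
   matched family for the generator (markers are drawn independently per
   subset) and keeps the parameter count identifiable at desk scale —
   full-covariance mixtures in 36 dimensions need ~700 parameters per
   component. The covariance family is an argument, so the full-covariance
   variant is available.

Numerical choices that make the k-selection reliable:

* Mixtures are fitted on a per-lineage subsample (2,000 cells) for speed;
  all cells are then assigned by maximum responsibility.
* Each candidate k is optimised from a multi-restart kmeans partition *and*
  from a warm start that splits the widest component of the k-1 solution;
  the better log-likelihood wins. Without the warm-start chain, the BIC
  curve is jagged (different k land in different-quality local optima) and
  the selected k is noisy.
* Cells whose lineage call is ambiguous (best-vs-second score margin below
  0.5) are excluded from the fitting subsample only. A handful of
  cross-lineage stragglers is otherwise enough to seed a spurious
  component, because under tight diagonal variances a far-away cell gains
  hundreds of log-likelihood units from a private component.
* Components that attract fewer than 30 cells on the full data are dropped
  and their cells reassigned — subsample artifacts at the scale where BIC
  cannot distinguish them.
* The BIC scan stops after three consecutive declines.

With these choices the modal recovered inventory on the default study is
44 subsets with an adjusted Rand index above 0.99 against ground truth;
individual seeds occasionally yield 45-46 when one lineage accepts an extra
split.

# Frequency matrices and preprocessing

Frequencies are percentages per sample, either of all labelled (CD45+)
cells or of each subset's lineage. The "standard pre-processing" applied
before sample-level embeddings is arcsine-square-root
($p \mapsto \arcsin\sqrt{p/100}$, the classical variance stabiliser for
proportions) followed by per-column z-scoring; constant columns z-score to
zeros rather than erroring. Spearman correlations are computed on raw
percentages — ranks are invariant to the arcsine-sqrt map, which the test
suite asserts. The t-tests use arcsine-sqrt values by default, with a flag
for raw percentages.

# Differential abundance

Welch two-sample t-tests compare inflamed against pooled
noninflamed-IBD/control intestinal samples (blood samples are excluded from
this contrast) per subset, with Benjamini-Hochberg control at 5% across the
44 subsets. Welch rather than Student is the default because group sizes
are unequal by design; a pooled-variance flag exists. Kruskal-Wallis tests
with Dunn's post-hoc z-comparisons (Bonferroni over pairs) serve the
multi-group views; the Dunn statistics use the standard tie-corrected
pooled-rank standard error.

# Correlation networks

The co-abundance network is the Spearman matrix over intestinal samples.
Modules come from average-linkage hierarchical clustering on distance
$1-\rho$; the cluster number is chosen by maximum mean silhouette over
k = 2..8 (the source analysis gives no cut rule; silhouette is a neutral,
standard criterion). A cluster qualifies as a *network* when it has at
least `mMin = 4` members and mean within-module pairwise $\rho \ge$
`rhoMin = 0.3`. On the default study this yields four detected clusters of
which exactly three qualify — the 21-member inflammation-enriched module,
the 11-member depletion module and the 9-member blood-like module — while
the weakly-correlated residual trio is detected but fails qualification.
When differential-abundance results are supplied, qualified modules get
semantic labels (`network1` = predominantly depleted, `network2` =
predominantly enriched, remaining by size); the labels are metadata only.

Collective network frequencies are per-sample sums of member-subset
percentages; a patient is stratified as "high network2" when any inflamed
sample exceeds the 50% cutoff.

# Label transfer

The LDA classifier is homoscedastic Gaussian: class means, one pooled
within-class covariance with a small diagonal ridge (`1e-6` times the mean
diagonal), and proportional priors. Posteriors are computed in log space
with log-sum-exp; a cell is assigned only if its maximum posterior reaches
$\tau - 10^{-6}$, where the epsilon makes $\tau = 1$ ("100% confidence")
numerically meaningful instead of demanding exact floating-point unity.
Rejection is monotone in $\tau$ by construction. An optional Mahalanobis
chi-squared cut flags genuine phenotype novelty, which posterior
normalisation alone cannot detect (a cell far from *all* classes still has
posteriors summing to one).

Cross-cohort concordance is evaluated by training on the clustered primary
cohort, predicting every validation-cohort cell, aggregating predicted
frequencies into ground-truth subset space through the maximum-overlap
(many-to-one) cluster-to-truth mapping, and correlating the flattened
sample-by-subset percentage entries (per-subset correlations are available
by flag). The many-to-one mapping makes the evaluation robust to an
occasional split cluster: both halves aggregate back to the same truth
subset.

# Sample embeddings and multivariate tests

Sample-level t-SNE runs exact (theta = 0) on the preprocessed frequency
matrix — sample counts are small, so the Barnes-Hut approximation is
unnecessary — with perplexity 15 by default for 100-200 samples and a fixed
seed. Replicate QC is the mean silhouette width of the internal-control
samples against all others. PCA provides group centroids and the score
space for Hotelling's two-sample $T^2$, computed on the pooled-sample PC
scores (default d = 2, as plotted) and referred to
$F(d,\,n_A+n_B-d-1)$. The $T^2$ implementation is validated against the
squared two-sample t in one dimension and calibrated under the null in the
test suite.

# What passing tests do and do not show

The generator reproduces the statistical *structure* the pipeline assumes:
separable subset phenotypes, logistic-normal compositions with latent
co-abundance modules, subject-level correlation, paired tissues, two
cohorts, replicate controls and designed inflammation effects. It does not
reproduce instrument artifacts (doublets, bead events, acquisition drift,
dead cells), batch shifts between cohorts (available as a knob, zero by
default, with no literature-anchored magnitude), tissue-blood phenotype
divergence, or heavy-tailed marker distributions. Passing acceptance on
synthetic data therefore demonstrates correctness of the statistical
machinery under the stated model, not performance on raw instrument data.

Problem sizes used by the test and acceptance runs: default cohorts (34 +
34 subjects, three intestinal plus one blood sample each, 7 internal
controls), ~2,000/1,000/5,000 cells per ileum/colon/blood sample; 20
simulation seeds for the recovery medians; 200 null studies for the FDR
calibration; 1,000 replicates for the Hotelling null. These sizes are the
package's chosen desk-scale study conditions.

# Known limitations

* Samples are treated as independent in the differential-abundance tests,
  matching the source analysis; a mixed-effects treatment of within-subject
  correlation is out of scope and would be the principled extension.
* The 44-subset inventory is recovered modally, not on every seed; the
  occasional extra split is the price of an automated, non-interactive
  clustering stage.
* FCS files are not read or written (no FCS library is available to the
  package); studies round-trip through per-sample CSV plus tab-separated
  metadata instead.
* The silhouette-based cluster-number choice for modules is scanned over
  k = 2..8 only, which is appropriate for tens of subsets but would need
  widening for much larger panels.
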