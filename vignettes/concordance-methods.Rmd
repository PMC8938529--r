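---
title: "Methods: cross-model transcriptomic concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-model transcriptomic concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressconcord)
```

## The scientific question

Preclinical stress models differ in their stressor — hormonal (chronic
oral corticosterone, CORT), environmental/social (chronic social defeat
stress, CSDS, under standard or enriched housing), genetic (the BDNF
Val66Met variant) — yet may converge on shared transcriptional programs
in the ventral hippocampus. `stressconcord` implements the analysis
chain used to ask that question on two experiments at once:

1. per-contrast differential expression with an empirical-Bayes
   moderated t on log-CPM;
2. stratified rank-rank hypergeometric overlap (RRHO) between signed
   gene rankings of the two models, with per-quadrant peaks and peak
   gene sets;
3. a consensus weighted co-expression network (soft-threshold
   adjacency, topological overlap, quantile-calibrated element-wise
   minimum across experiments, average-linkage clustering with branch
   cutting), eigengenes and kME;
4. module-by-DEG-set Fisher enrichment under joint BH-FDR, a
   differential-expression relevance score, cross-model *key module*
   flags, and mu-plus-sigma hub selection;
5. behavioral emotionality composites from control-referenced,
   direction-signed z-scores, a per-animal behavioral score, and
   SI-ratio phenotyping with cohort proportions.

Every stage is exercised end to end on synthetic data with planted
structure, so each claim the pipeline makes ("these modules are
enriched across both models") can be checked against ground truth.

## Differential expression

Counts are transformed to `log2 CPM` with a pseudo-count:
`log2((y + c) / (L + 2c) * 1e6)`, `c = 0.5`. Each of the four
published-style contrasts (WT VEH vs WT CORT, hMet VEH vs hMet CORT,
SH RES vs SH SUS, EE RES vs EE SUS) is fit as a two-group comparison.
The gene-wise pooled variance \(s_g^2\) (df \(d_g = n_1+n_2-2\)) is
shrunk towards a prior \(s_0^2\) with prior df \(d_0\):

\[
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0+d_g},\qquad
t_g = \frac{\bar x_{2g}-\bar x_{1g}}{\tilde s_g\sqrt{1/n_1+1/n_2}},
\]

with two-sided p-values on \(d_0+d_g\) df. The prior is estimated by
method of moments on \(\log s_g^2\), using the mean and variance of the
log scaled-F distribution (the excess of \(\mathrm{var}(\log s_g^2)\)
over \(\psi'(d_g/2)\) determines \(d_0\) via the inverse trigamma).
This closed-form estimator is deterministic and, in the test suite,
agrees with limma's empirical-Bayes fit to machine precision; the
\(d_0 = 0\) limit reproduces an independently coded pooled two-sample t
to \(10^{-10}\). Voom-style precision weights are supported but off by
default: the unweighted moderated t on log-CPM is fully specified and
is the path all defaults use.

DEGs use the uncorrected rule *p < 0.05 and fold change > 1.3*, with
strict inequalities (a gene at exactly p = 0.05 or FC = 1.3 is
excluded) and the fold-change read on the natural scale in either
direction. Rankings for RRHO use
\(-\log_{10}(p)\cdot\mathrm{sign}(\log_2 FC)\), ties broken
lexicographically by gene id so ranked lists are deterministic.

## Stratified RRHO

Both ranked lists are split at zero score into an up-stratum (taken
from the top) and a down-stratum (taken from the bottom); genes with
score exactly 0 (p = 1) go to the down-stratum. Four quadrants (UU,
DD, UD, DU) are evaluated on a threshold grid with step
`ceiling(sqrt(N))` by default (step 1 gives the exact map); each cell
stores \(-\log_{10}\) of the raw upper-tail hypergeometric p-value of
the overlap between the two threshold sets against the full background
N. A BH-corrected map over all cells is attached as an option, since
the published convention (maximum \(-\log_{10} p\) per quadrant) does
not name a correction; peaks are read off the raw map by default, with
ties resolved to the smallest i then j. Peak gene sets are the overlap
at the peak cell and are, by construction, confined to the quadrant's
direction strata. Display orientation follows the published heatmaps:
upper-left = co-down, lower-right = co-up.

## Consensus co-expression network

Signed Pearson adjacency \(a_{ij} = ((1+r_{ij})/2)^\beta\) preserves
the up/down concordance the analysis interprets; \(\beta\) is chosen as
the smallest power (candidates 1–20) whose scale-free fit \(R^2\)
(log-log regression of binned connectivity frequency, negative slope
enforced) reaches 0.8, with an argmax fallback and warning. The
topological overlap matrix

\[
TOM_{ij} = \frac{\sum_{u\neq i,j} a_{iu}a_{uj} + a_{ij}}
                {\min(k_i,k_j) + 1 - a_{ij}}
\]

is computed per experiment, the second TOM is rescaled so its 0.95
off-diagonal quantile matches the first's, and the consensus is the
element-wise minimum — co-expression is only retained where *both*
experiments support it. Modules come from average-linkage clustering
of `1 - TOM`: a static cut at 0.995 of the dendrogram height range, one
top-down refinement pass (a retained branch splits when its two
sub-branches each reach `min_size = 30` and join above 0.9 of the cut
height), a size filter to background label 0, and iterative merging of
modules whose eigengene dissimilarity — the maximum over the two
datasets of \(1-\mathrm{cor}\) — is below 0.25. The full hybrid
dynamic tree cut is intentionally out of scope; the static cut plus
one refinement pass is simpler, deterministic, and recovers planted
partitions with adjusted Rand index 0.74–0.98 in the test
configurations. Eigengenes are unit-norm first principal components of
the per-gene standardized module submatrix, sign-oriented towards the
module mean profile; kME is the gene-eigengene correlation, reported
per dataset and as their mean (the consensus kME used for hub
ranking — the combination rule is not dictated by the source analyses,
so both ingredients are kept).

## Enrichment, relevance, key modules, hubs

Each module is tested against each of the 8 directional DEG sets ("up
in group X" for each group of each contrast) with a one-sided Fisher
exact test (upper hypergeometric tail) over the network background.
BH correction is applied *jointly* across all module-by-set tests —
the conservative reading of a single FDR threshold — and significance
is adjusted p < 0.05. The relevance score of a module is the mean of
\(-\log_{10}(\text{adjusted } p)\) over the 8 sets (a raw-p variant is
a flag). A module is *key* when it is significantly enriched in at
least one DEG set from each experiment — the pattern that identified
the published cyan (CORT-up in both genotypes plus SH-SUS-up) and
yellow (hMet-VEH-up plus EE-SUS-up) modules. Hubs of a module are the
members whose consensus kME strictly exceeds the module mean plus one
*sample* standard deviation; because the published legend is ambiguous
between kME and weighted connectivity, ranking by intramodular
connectivity (`measure = "kin"`) is available behind a flag. DEG
membership is flagged per hub and intramodular TOM edges are exported
for network rendering.

## Behavioral scoring

Each variable has a direction sign making larger directional z =
more emotionality (defaults: % time in light −1, latency to light +1,
latency to dark −1, grooming time −1, grooming sessions −1, grooming
latency +1, SI-zone time −1, SI ratio −1; all overridable).
Directional z-scores are referenced to the control group's mean and sd;
the emotionality composite averages z within each behavioral test and
then across tests with equal weight. The per-animal behavioral score
for a (group, control) comparison is `1 - z/ā` after normalizing all
composite z values to the cohort minimum *by subtraction* (the
published normalization phrase is ambiguous between subtraction and
division; the subtraction reading makes the two algebraic anchors
exact — the cohort-minimum animal scores 1 and an animal at the control
mean scores 0 — and is the implemented default). ā is the mean
normalized z of the comparison's control animals; a zero ā (degenerate
control spread) is an error. SI ratio strictly above 1 is resilient;
exactly 1 is classified susceptible, closing the gap in the published
strict-inequality rule conservatively. Cohort proportions are reported
as percentages of the grand total (integer display rounding alongside
full precision) with a two-sided Fisher exact test on the 2x2
phenotype-by-housing table; the published group sizes (SH 59/14,
EE 49/32) reproduce the published 21% / 9% resilient proportions.

## The synthetic-data generator

The generator is first-class, tested code; it emulates what the
downstream statistics assume and nothing more:

* negative-binomial counts, gene-wise mean
  \(2^{b_g + \lambda_g f_{j,m(g)} + \delta_{gj}}\cdot s_j\) with
  dispersion 0.2 shared across genes; baselines
  \(b_g \sim N(5, 1.5^2)\) log2 units; log-normal library-size scales
  (sd 0.3);
* 10 planted modules of 50 genes in a 2000-gene background; module
  genes load on a per-sample latent factor with loadings drawn once
  per gene from \([0.45, 0.8]\) and *shared across the two
  experiments* — the shared-loading design is exactly what a consensus
  network assumes. With these loadings the factor explains roughly
  30–45% of a module gene's log-scale variance (kME ≈ 0.6, in the
  range reported for bulk co-expression modules) while leaving the
  planted differential expression identifiable at n = 6;
* latent factors are centered within each experimental group, so the
  planted shifts are the *only* systematic group differences and the
  serialized ground truth is exact. Without centering, random factor
  group-means of a 50-gene module are the same order as the planted
  log2FC of 0.6 and would create real, unrecorded module-level DE;
* concordant DE planted on the log2 scale before sampling: the
  susceptibility module is shifted up in WT-CORT, hMet-CORT and
  SH-SUS; the resilience module up in hMet-VEH and EE-SUS —
  reproducing the published cross-model enrichment pattern;
* behavioral tables with group mean shifts of 1.2 control-sd in the
  emotionality direction for CORT-treated / susceptible groups, and SI
  ratios drawn on the matching side of 1 so phenotype classification
  recovers the labels; experiment B uses the published cohort sizes
  (59/14/49/32) so the cohort-proportion display is reproduced from
  simulated animals as well.

What the generator does **not** emulate: batch effects, library
preparation artifacts, RNA pooling across animals (the CORT arm of the
original design pooled two animals per replicate; this is noted, not
modeled), count outliers, or mean-variance trends beyond the shared
NB dispersion. Passing tests therefore demonstrate correctness of the
statistical machinery and recoverability of planted structure — not
robustness to every artifact of real sequencing data.

## Numerical choices and degenerate inputs

* Strict inequalities at every published threshold (p, FC, SI ratio,
  mu + sigma).
* Ranked-list ties break lexicographically by gene id; RRHO peak ties
  resolve to the smallest i, then j; zero signed scores join the
  down-stratum.
* All-constant genes get t = 0, p = 1 and a flag rather than NaN;
  zero-variance genes are removed (and logged) before network
  construction; zero library sizes, empty modules, single-gene
  modules, and mismatched backgrounds raise classed errors.
* The trigamma inverse uses a Newton iteration with closed-form
  endpoints; `d0` overrides of 0 and Inf give the unshrunken and
  fully shrunken limits exactly.
* Problem sizes in the test suite: oracle equivalences run at
  N ≤ 50 (RRHO), 6–10 genes (TOM), backgrounds ≤ 200 (Fisher);
  calibration uses 200 genes x 200 null runs; module recovery and
  concordance recovery run the full default generator (2000 genes,
  two 24-sample experiments), the latter over five seeded replicates.

## Known limitations

* Per-gene DE power at the default planted effect (log2FC 0.6, n = 6,
  NB dispersion 0.2) is ~15–20%; DEG sets are honest but small, so
  single-set enrichment calls sit near the FDR boundary and the
  exact key-module pattern is recovered in roughly half of random
  replicates (the susceptibility module, supported by three DEG sets,
  is essentially always key; the resilience module depends on two
  single-set calls). The relevance-score top-2 ranking is much more
  stable (10/11 random replicates in development runs).
* The RRHO peak gene set can only approximate the planted concordant
  set when per-gene recall is high; the recovery property is
  demonstrated at a strong planted effect (log2FC 1.5), where the
  peak-set Jaccard against truth is 0.70.
* The consensus network at desk scale finds, besides the planted
  modules, additional weak background modules; they carry no planted
  signal and mainly enlarge the BH family.
* Two-group contrasts (not a factorial model) follow the published
  four pairwise comparisons; variance is pooled within each contrast
  only.
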