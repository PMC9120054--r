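---
title: "Methods: limbic subregion connectome hierarchy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: limbic subregion connectome hierarchy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbconn)
```

## The problem

Structural connectomes built from diffusion tractography describe the brain
as a weighted graph: anatomical regions are nodes, and the (SIFT2-weighted)
streamline count between each pair of regions is an edge weight. `limbconn`
analyzes such networks at hippocampal-subfield and amygdala-nucleus
resolution: a 98-region parcellation combining 68 cortical parcels, 10
subcortical structures, 8 hippocampal subfield groupings (CA1, CA3/4,
subicular complex, GC-DG per hemisphere) and 12 amygdala nuclei (LA, BA,
ABA, CoA, CeA, CAT per hemisphere; the medial nucleus is too small for
reliable delineation and is not part of the parcellation). The scientific
question is whether the *hierarchy* of these small limbic structures within
the whole-brain network — not merely their volume or raw connectivity —
differs between patients with major depressive disorder (MDD) and healthy
controls (HC), and whether it tracks symptom severity.

## Nodal features and threshold summarization

Three weighted local centrality features are computed per region:

* **Node strength** $s_i = \sum_j w_{ij}$ — total connectivity of region
  $i$ to the rest of the network; hubs have high strength.
* **Betweenness centrality** $b_i$ — the (fractional) number of shortest
  paths between other region pairs that traverse $i$, computed on the
  length graph $l_{ij} = 1/w_{ij}$ so that stronger connections are shorter
  paths. Co-minimal paths share credit fractionally; counts are left
  unnormalized (each unordered pair counted once), since group inference is
  invariant to common scaling. The $1/w$ transform is the standard
  convention for streamline-count networks and is isolated in one place so
  a $-\log$ alternative could be substituted.
* **Clustering coefficient** $C_i$ — the geometric-mean triangle intensity
  $C_i = \sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / (k_i(k_i-1))$
  with $\hat w = w / \max(w)$ and $k_i$ the nonzero-neighbor count
  ($C_i = 0$ for $k_i < 2$). On binary graphs this reduces to the classic
  triangle fraction $2T_i/(k_i(k_i-1))$. It measures how strongly a
  region's neighbors interconnect — its embedding in a cluster.

Raw networks differ in density across subjects, which confounds nodal
features. A **proportional sparsity threshold** $S$ therefore retains the
$k = \lfloor S\,N(N-1)/2 \rfloor$ strongest edges (weights preserved, not
binarized — strength is defined on weights) and zeroes the rest, matching
edge counts across subjects. Because no single $S$ is privileged, features
are computed across $S \in \{0.10, 0.11, \dots, 0.30\}$ (21 values; the
range endpoints are included, matching the stated 0.1–0.3 analysis range)
and summarized by the trapezoidal **area under the metric-versus-$S$
curve** (integration width 0.20 for the default grid). Ties at the cutoff
weight are broken deterministically by ascending (row, column) index, and
$k$ uses `floor` ("retain at most $S$ density"), so results are bit-stable
across platforms. A matrix whose density is below $S$ keeps all its edges
with a logged warning.

## Group inference

Per region and metric, the AUC feature is contrasted between groups with an
ANCOVA-style linear model
`feature ~ intercept + group + covariates`; the test statistic is the group
coefficient's $t$ with $df = n - (\#\text{covariates}) - 2$, and Cohen's
$d$ is the adjusted group difference divided by the residual SD. With no
covariates this is exactly the pooled two-sample $t$. Default covariates
are age, sex and the region's own volume; prior antidepressant medication
history can be added (the source analyses report both sets, so the set is
configurable). A single-model ANCOVA was chosen over
residualize-then-t because it accounts for nuisance degrees of freedom the
way the reported $df$ values imply.

Significance uses a **permutation test**: group labels are shuffled
(covariates stay bound to their subjects), the adjusted $t$ is recomputed
each time, and the default p-value is the two-sided add-one estimate
$p = (1 + \#\{|t_\pi| \ge |t_{obs}|\}) / (1 + n_\pi)$ with
$n_\pi = 1000$ by default, so $p \ge 1/(n_\pi+1)$. A literal one-sided
"fraction of permuted $t$ smaller than observed" is also returned for
completeness; read literally that fraction *increases* with effect size and
cannot serve as a significance measure, so it is never used downstream.
Internally the permutation loop uses Frisch–Waugh residualization (project
the feature and each permuted indicator off the covariate space once); this
is algebraically identical to refitting the full model (verified in tests
to 1e-10) and makes 98 regions × 1000 permutations cheap. Per-region
permutation streams are derived deterministically from
`(seed, region_index, metric)`, so results are independent of execution
order.

Multiple comparisons are controlled by **Benjamini–Hochberg FDR** within
each metric's 98-region family (families are never pooled across metrics),
applied by default to the permutation p-values.

### The BH floor: a structural caveat

Because the add-one permutation p is floored at $1/(n_\pi+1)$, the smallest
attainable BH-adjusted value over a 98-test family is
$98/(n_\pi+1)/k$ where $k$ tests sit at the floor jointly. With
$n_\pi = 1000$ a *single* strong effect bottoms out at $q \approx 0.098$
and can never pass $q \le 0.05$ alone; discovery requires at least two
(at $n_\pi = 500$, four) regions at the floor simultaneously. This is not a
bug but arithmetic shared by any permutation+BH pipeline at this scale —
multi-region findings reported by such analyses are consistent with it
precisely because several regions hit the floor together. The package
therefore exposes `p_source = "param"` in `compare_groups()` to feed the
parametric ANCOVA p-values to the FDR step instead; the spec-faithful
default remains the permutation source, and the corresponding
planted-single-effect acceptance check is deliberately left failing rather
than silently switched (see `tests/testthat/test-acceptance.R`).

## Symptom associations

Within patients only, each of the 8 hippocampal and 12 amygdala subregions'
features is correlated with symptom scores (clinician-rated MADRS,
self-reported QIDS-SR, exploratory episode duration) by **partial Spearman
correlation**: rank-transform both variables (average ranks on ties),
residualize both rank vectors on intercept + covariates (age, sex,
subregion volume, medication history), and correlate the residuals; the
p-value uses the $t$ approximation with $df = n - \#\text{cov} - 2$. This
rank-then-residualize construction keeps Spearman's monotone invariance
while removing linear covariate effects; Kendall-based alternatives were
rejected as unconventional here. BH-FDR is applied separately within the
8-test hippocampus family and the 12-test amygdala family; episode-duration
results are reported uncorrected and labeled as such. Subjects missing a
score or covariate are dropped listwise with the per-variable n logged,
mirroring the per-variable n convention of demographics tables.

## Demographics statistics

`t_from_summary()` reproduces pooled-variance two-sample t-tests from
printed mean ± SD ± n rows, `chi_square_2x2()` the Pearson chi-square
(no continuity correction) for sex distributions, and
`frequency_percent()` the printed percentages. These let published
demographics tables be checked exactly without raw data; they are also the
basis of the acceptance report, since the neuroimaging results themselves
require the original 7T cohort.

## The synthetic cohort generator

`generate_cohort()` provides ground truth for every inference stage. What
it emulates:

* **Template network**: one symmetric log-normal weight matrix
  (`meanlog = 4`, `sdlog = 1`, median ≈ 55 on a streamline-count scale)
  with a ×2 within-hemisphere multiplier giving the hemispheric modularity
  characteristic of structural connectomes; zero diagonal; full density
  before thresholding (probabilistic tractography yields mostly nonzero
  counts).
* **Subject noise**: each edge multiplied by independent log-normal noise
  with mean 1 and CV 0.20 — the order of session-to-session variability of
  tractography counts.
* **Group effect**: patients' edges incident to designated deficit nodes
  scaled by $1-\delta$ (a pure strength deficit), and/or the edges among
  one node's top-6 template neighbors scaled by $m^{z}$ with latent
  severity $z \sim N(0,1)$ — raising triangle intensity with modest
  strength change (an approximation; ground truth is the sidecar, not a
  closed form).
* **Clinical variables**: MADRS 29.34 ± 5.16 (MDD) vs 0.62 ± 1.18 (HC),
  QIDS-SR 14.06 ± 4.32 vs 1.16 ± 1.79 with ~5% missingness, age ≈ 37 ± 11,
  male fractions 22/38 and 26/40, prior-medication probability 0.7 in
  patients, region volumes 1500 ± 150 voxels (optionally echoing the
  deficit), episode duration log-normal ≈ 56 ± 71 months — all matching
  the study's demographics rows; group sizes default to 38/40 so
  permutation and FDR behavior is exercised at study scale.
* **Weights are continuous**, not integer: SIFT2-style weighting makes
  counts effectively continuous and all downstream math is count-agnostic.

MADRS in patients is $\mu + \sigma(\lambda z + \sqrt{1-\lambda^2}\epsilon)$.
Since the clustering AUC tracks $z$ only up to simulation noise (rank
correlation $r_{cz} < 1$), the realized feature–symptom correlation is
$\lambda\, r_{cz}$. `calibrate_symptom_association()` measures $r_{cz}$ on
a pilot, sets $\lambda = \rho / r_{cz}$, verifies the realized partial
Spearman lands within ±0.05 of the target, and errors when the target is
unattainable ($|\lambda| > 1$, e.g. $\rho = 0.99$ under heavy noise).

What the generator does **not** emulate: geometric/distance-dependent
wiring, hub-and-rich-club topology beyond hemispheric blocks, test–retest
structure, integer count noise, or realistic covariate–connectivity
confounding (volumes are independent of edge weights unless coupling is
requested). A green planted-effect test therefore establishes that the
statistical machinery recovers effects of the stated form and size under
realistic noise — not that the pipeline is validated against real
tractography idiosyncrasies.

## Numerical choices and degenerate inputs

* Asymmetry tolerance for silent symmetrization:
  $\max|W - W^T| \le 10^{-8}\max(W)$; larger asymmetries are corrupt input.
  Nonzero diagonals are zeroed with a warning.
* Constant features (zero residual variance after covariate projection,
  detected with a relative $10^{-20}$ guard against floating-point dust)
  give $t = 0$, $d = 0$, permutation $p = 1$.
* Perfect residual correlations are clamped to ±1 and yield infinite $t$,
  which orders correctly in permutation comparisons.
* Results CSVs round-trip at 12 significant digits with fixed column and
  row order (region index, then metric).
* Scaled-down defaults in tests are declared in the test files themselves;
  the null-calibration suite runs 20-node cohorts (the permutation null
  does not depend on network size) and the symptom-association pilot uses
  40-node networks at the full n = 2000 pilot size (the calibration is a
  per-patient scalar property).

## Known limitations

* Betweenness is backed by igraph's Brandes implementation (checked against
  brute-force path enumeration and an independent toolbox implementation);
  a pure-R Brandes would be pedagogically nicer but far slower at 98 nodes
  × 21 thresholds × 78 subjects.
* Freedman–Lane-style shuffling of residuals is not implemented; label
  shuffling keeps covariates bound to subjects, which is exact under the
  null of no group effect given exchangeability.
* No global network measures (efficiency, modularity, small-worldness), no
  network-based statistic, no edge-level corrected inference — edge t-tests
  are exploratory and labeled uncorrected.
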