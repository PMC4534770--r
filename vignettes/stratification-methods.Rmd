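---
title: "Topological stratification of clinicopathobiologic cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological stratification of clinicopathobiologic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortmapper)
```

## The problem

Asthma is not one disease. Cohort studies that measure both clinical
descriptors (lung function, symptom scores, treatment intensity, atopy)
and pathobiologic read-outs (T-cell subset frequencies across blood,
sputum, bronchoalveolar lavage and biopsy; cytokines; mast cell
proteases; granulocyte differentials) consistently find that patients
fall into *endotypes* — subgroups defined by combinations of mechanism
and presentation that cut across conventional severity grades.
`cohortmapper` implements, as a tested and reusable pipeline, the
analysis machinery behind one such stratification study of 62
participants characterized by 26 pathobiologic and 26 clinical
parameters: compartment-composite preprocessing, a from-scratch Mapper
(topological data analysis) stage that emits a node–edge network and
Kolmogorov–Smirnov-characterized patient clusters, a discretized
Bayesian-network stage for parameter interconnectivity, the standard
group-comparison battery, and sputum inflammatory-subtype reporting.

Because the study's per-subject data were never deposited, the package
ships a first-class synthetic cohort generator that plants the published
cluster phenotypes; every downstream stage is exercised and tested
against cohorts whose ground truth is known.

## Preprocessing: scale, imputation, compositing, normalization

Each measurement column is screened with the Shapiro–Wilk test
(`decide_scale()`, default alpha 0.05): columns rejecting normality are
carried as `log10(x + c)`, with offset `c` equal to half the smallest
positive observed value when zeros are present (zero medians do occur
for low-abundance mediators). Binary flags are never transformed, and a
constant column — for which the test is undefined — is treated as
normal.

Missing entries are imputed by the mean of the observed values of the
same measurement among subjects with the same severity label
(`impute_subgroup_mean()`); tissue specificity is inherent to the
measurement column, which is compartment-resolved. Only subgroup means
are used — no model-based or multiple imputation.

The order of operations is: scale decision, imputation on the analysis
scale, compartment compositing, variance normalization. The ordering is
a design choice: imputing after the log transform prevents subgroup
means from being dominated by the skew of raw concentrations.

`composite_average()` collapses each parameter to one column by a
weighted average over the compartments in which it was measured
(mediators: sputum/BAL/serum; cell counts: blood/sputum/BAL/biopsy).
The weighting of the original analysis is unpublished; the default is
equal weights over the measured compartments, renormalized per
parameter, and overridable through `composite_spec()`.

`variance_normalize()` centers and scales every column to unit standard
deviation, so Euclidean distance on the result *is* the
variance-normalized Euclidean metric used downstream. The sample
(`n − 1`) denominator is the default and the `n` convention is a
switch, since the original software's convention is unknown and the
choice perturbs the metric slightly. Constant columns carry no metric
information (their contribution would be 0/0) and are dropped with a
warning.

## The Mapper stage

`compute_lenses()` projects subjects onto the first two right singular
vectors of the normalized matrix — classical principal-component
scores. For a variance-normalized Euclidean metric this coincides with
the "metric SVD" lenses of the commercial implementation the field has
used. Sign is fixed by making each singular vector's largest-magnitude
loading positive, so runs are bit-reproducible. A rank-1 matrix
degrades to a zero secondary lens with a warning rather than failing.

`build_cover()` tiles the 2-D lens space with `resolution` base
intervals per axis (default 32), each dilated about its center by the
per-axis `gain` (defaults 4.0 and 3.5; overlap fraction `1 − 1/gain`).
With `equalize = TRUE` (default) base intervals hold equal numbers of
subjects, and — a deliberate design decision — the dilation is applied
in occupancy (quantile) space before mapping back to lens units.
Dilating quantile intervals in raw lens units lets a cell that happens
to sit in a sparse stretch of the lens swallow a third of the cohort,
which in testing welded several planted profiles into one node; in
occupancy space every cell holds at most about `gain/resolution` of the
cohort per axis. Non-equalized covers dilate in lens units.

`cluster_preimage()` runs single-linkage clustering inside each cell
under the variance-normalized metric and cuts the dendrogram at the
first empty bin of the 10-bin histogram of merge heights (with the cell
diameter appended) — the classical Mapper gap heuristic. Two boundary
cases needed decisions. A two-subject cell has a single merge height,
so the histogram is vacuous, and the canonical outcome (one cluster) can
weld two distant structures through one spurious pair; similarly when
every bin is occupied. Inside `mapper_run()` such cells are therefore
re-cut at the Tukey upper fence (Q3 + 1.5 IQR) of the merge heights
pooled over all cells: only joins that are outliers of the cover-wide
merge-height distribution are severed, ordinary pairs are kept. Nodes
need at least 2 subjects; singletons are reported as unassigned, never
silently dropped.

`build_graph()` deduplicates identical subject sets and connects two
nodes exactly when they share a subject. `extract_clusters()` takes
connected components as candidate subgroups (components more than half
contained in a larger one are absorbed; subjects claimed by several
components go to the one holding them in more nodes), screens every
composite parameter with two-sample Kolmogorov–Smirnov tests of members
against the rest, adjusts with Benjamini–Hochberg by default
(Bonferroni optional), and promotes candidates with at least one
significant parameter to clusters, with those parameters as defining
features signed by the member-versus-rest median difference.

## The Bayesian-network stage

`discretize()` bins each composite column: two bins for binary columns,
otherwise quantile bins with the count set by Sturges' rule clamped to
5–9 (7 bins at n = 62). `learn_structure()` is a BIC hill-climber over
add/delete/reverse arc moves with at most 3 parents per node and random
restarts, deterministic under its seed; acyclicity is verified on every
accepted move via an explicit reachability check. The search algorithm
of the original desktop software is unpublished; BIC hill climbing is
the standard desk-scale choice. Nodes left without arcs are reported
separately as `isolated` — the published network likewise left five
parameters outside the graph.

Arc strength is mutual information in bits between the endpoints'
discretized values (`edge_strength()`); the figure legend's literal
"Euclidean distance" is not a meaningful dependence measure between
discrete variables, so the lens-loading Euclidean distance is exported
alongside for anyone wanting that quantity. `classify_edge_sign()`
labels an arc positive or negative when |Spearman rho| of the continuous
values reaches 0.3, and nonlinear otherwise, with a permutation test of
the discretized mutual information recording whether the nonlinear
dependence is itself significant.

## The statistical battery

`mann_whitney()`, `kruskal_dunn()` (tie-corrected H; Dunn z versus the
reference group only, matching how the original figures report post hoc
results, with all-pairs behind a flag and Bonferroni over the
comparisons made), `anova_bonferroni()`, `linear_trend_contrast()`
(equally spaced zero-sum coefficients, pooled variance),
`jonckheere_terpstra()` and `ks_two_sample()` follow the two-sided,
alpha = 0.05 conventions throughout. The Jonckheere–Terpstra p-value is
permutation-based with the observed statistic included in the null set,
switching to exhaustive enumeration whenever the number of distinct
group assignments is at most 10^6 — the normal approximation is poor at
these group sizes with ties. Wrappers delegate to `stats` wherever a
base routine exists (`wilcox.test`, `kruskal.test`, `ks.test`,
`shapiro.test`, `p.adjust`); the Dunn post hoc, trend contrast, JT
permutation and the Mapper/BN machinery are implemented here because no
installed package provides them.

## The synthetic cohort generator

`generate_cohort()` draws a 62 × 101 measurement table (101 =
parameters expanded over their compartments) from seven planted
phenotype profiles: one healthy archetype and six asthma clusters with
ordinal fidelity to the published descriptions — a mild atopic
TH2-cell-high but mediator-low paucigranulocytic cluster; a
well-controlled cluster whose only signal is eosinophilia with low Treg
and TC1 frequencies; a moderate type-2-high cluster with the top IL-5,
IL-13, reversibility and eNO values; a small later-onset nonatopic
cluster with nasal polyposis, salicylate sensitivity and low IL-17; an
older obese high-treatment cluster with mast cell proteases and TC2
cells up and Tregs down; and a predominantly female, obese, nonatopic,
corticosteroid-dependent severe cluster with profound MAIT deficiency
and the highest carboxypeptidase A3 and tryptase levels.

Distributional choices: concentrations are log-normal on their natural
scale (log10 SD 1.5 at unit `noise_scale`, i.e. 0.3 at the default
0.2 — wide enough that raw margins reject Shapiro–Wilk normality at
n = 62 while log margins do not, matching the pipeline's
log-transform-on-rejection contract); percentages are logit-normal
scaled to [0, 100]; scores are truncated normal; counts are rounded
truncated normals so `noise_scale` controls them too; binary flags are
Bernoulli. Binary probabilities are archetypal (near 0 or 1 per
profile, sex excepted): a mid-range probability makes within-profile
flag discordance common, and after variance normalization a single
discordant low-frequency flag contributes as much squared distance as a
several-SD continuous shift, which destroys any clustering structure
one tries to plant. Missingness is completely at random within
biological compartments (the minimal assumption consistent with
"missing data were imputed"), default rate 0.05; the severity group
sizes default to the enrolled 24/15/23/22 rescaled to 62 by largest
remainder (18/11/17/16), and profiles are allocated within severity
groups by largest-remainder rounding of their severity weights, so
generation is a pure function of (config, panel, seed).

What the generator does *not* emulate: correlated within-profile noise,
informative missingness, batch effects, or the real cohort's printed
medians and IQRs (ordinal fidelity only — the raw data are not
available). Passing recovery tests therefore demonstrates that the
pipeline recovers structure of the planted kind at realistic size and
noise, not that it would recover the original study's clusters from the
original measurements.

The published parameter list itself sits in an inaccessible repository
table; the default panel reconstructs it from parameters named in the
study narrative, padded with standard clinical descriptors to the
stated 26 + 26 shape, and is flagged as a reconstruction in its
documentation.

## Numerical and reproducibility choices

Sample SD (`n − 1`) throughout, switchable to `n`; log offsets as half
the minimum positive value; deterministic SVD signs; stable node
ordering; every stochastic step seeded, with per-stage streams derived
from the master seed by stage name so skipping a stage never perturbs
another stage's draws. Problem sizes in the test-suite simulations (20
cohorts of 62 subjects for end-to-end recovery; 2,000 replicates for
null calibration; 50 seeds at n = 1,000 for network structure checks)
were chosen to estimate the relevant proportions tightly while keeping
the default suite runnable on a laptop.

## Known limitations

- Cluster segmentation by connected components is the closest
  deterministic analog of the original visual subgroup identification;
  it cannot split a component that is genuinely bridged by dense data.
- The Tukey-fence fallback cut is a package refinement of the canonical
  gap heuristic; standalone `cluster_preimage()` calls keep the
  canonical behavior unless a fallback is passed.
- The plug-in mutual information is biased upward by roughly
  `(r−1)(c−1)/(2n ln 2)`; at 7 × 7 bins and n = 62 the bias is
  appreciable, so strengths should be compared within a network, not
  across discretizations.
- Whether the original gains "4.0/3.5×" were per-axis settings or a
  range explored is ambiguous; both axes are independently
  configurable, and the per-axis reading is the default.

## A short worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "out")
res$mapper$report      # clusters and their KS defining features
res$bayesnet           # arcs with strength and sign class
head(res$stats)        # severity battery, one row per parameter
res$subtype$table      # sputum granulocytic subtype frequencies
```
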