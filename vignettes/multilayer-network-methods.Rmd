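---
title: "Methods: differential co-expression networks and patient-similarity fusion"
author: "DCNfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression networks and patient-similarity fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

DCNfuse implements a multi-layer network analysis for small immuno-oncology
cohorts profiled with two data types: a targeted tumour gene-expression
panel (a few hundred genes, tens of patients) and circulating immune
phenotyping (percentages of immune-cell subsets in blood, measured before
and after the start of therapy). The pipeline asks two questions: which
gene-gene and immune-immune relationships differ between therapy responders
and non-responders, and whether combining the two data types separates
patients into clinically meaningful prognostic groups.

# Correlation networks

All association is measured with Spearman's rank correlation: expression
counts are heavily skewed and immune percentages are bounded, so only the
monotone part of a relationship is trusted. P-values use the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom; at the cohort sizes this package targets (roughly 18-44 samples
per group) the approximation is accurate, and an exact seeded permutation
option exists for smaller groups. Benjamini-Hochberg correction is applied
over the unordered pairs of each network family separately — one family
per group-and-timepoint network — because each network is interpreted and
thresholded on its own. A pooled family across networks would couple the
four immune networks' thresholds for no inferential gain.

An edge requires both a large effect and significance: $|\rho| > 0.55$ and
FDR $< 0.05$ for the immune layer, $|\rho| > 0.7$ and FDR $< 0.05$ for
gene co-expression. These thresholds are defaults of
`pipelineParams()`, not constants. Variables that are constant in a group
stay in the network as isolated nodes, so the node universe is identical
across the four immune networks and degree distributions are comparable.

# The differential co-expression network

Group-wise co-expression networks are built first; the differential test
is then applied to the union of their edge sets (`pair_universe =
"union_of_networks"`). The alternative of testing all pairs is available,
but the default mirrors the construction order of the analysis this
package operationalises and keeps the candidate family interpretable: a
pair must be convincingly co-expressed in at least one group before its
difference is worth testing.

For a candidate pair the correlation difference is tested with the Fisher
z-statistic
$$Z = \frac{\operatorname{atanh}\rho_A - \operatorname{atanh}\rho_B}
{\sqrt{1/(n_A-3) + 1/(n_B-3)}},$$
and edges with $|Z| > 2$ are retained, with no further multiple-testing
correction — the raw threshold is deliberate fidelity to the method being
implemented. The $1/(n-3)$ variance is the bivariate-normal value even
though the correlations are Spearman; the Fieller-Hartley-Pearson
inflation ($1.06/(n-3)$) is exposed as `variance_inflation = 1.06` for
users who prefer it. Two consequences of this design are worth stating
plainly, because the package's own calibration tests quantify them:

* Under an equal-correlation null at $n_A = 20$, $n_B = 18$, the
  fraction of pairs with $|Z| > 2$ sits near 0.05 (the acceptance suite
  asserts the band $[0.03, 0.07]$). Strongly but *equally* co-expressed
  pairs that enter the candidate set therefore appear as edges at about
  that rate. In a panel where hundreds of genes share co-regulation in
  both groups, these matched-pair false edges are numerous in absolute
  terms; they are thinly spread, so they inflate low degrees rather than
  create spurious hubs.
* A fully differential pair (population $\rho_A = 0.8$, $\rho_B = 0$) is
  detected with probability near 0.82 at these group sizes — high, but
  not near-certain; exact-sampling simulation fixed this value before the
  test bounds were frozen.

Perfect sample correlations make $\operatorname{atanh}$ infinite; such
pairs are excluded from the differential test with a warning rather than
clipped, since a sample correlation of exactly 1 at these sizes almost
always indicates duplicated or degenerate variables.

# Hubs and communities

Node degree in the DCN counts how many co-expression changes a gene
participates in. Hubs are the right tail of the degree distribution:
the threshold is the 95th percentile (linear interpolation) of the
degrees of nodes with at least one edge, and hubs are the nodes strictly
above it, with ties at the smallest included degree also admitted. Zero-
degree nodes are excluded from the percentile so that the threshold
reflects the connected part of the network. The percentile is a
parameter; `percentileSensitivity()` rescans \{75, 90, 95, 98, 99\} and
reports hub counts, partition stability (ARI against the 95th-percentile
reference) and cluster accuracy, flagging percentiles whose hub set is
empty instead of aborting.

Mesoscale structure uses the Louvain algorithm via igraph, unweighted by
default (an edge either marks a correlation change or it does not);
$|Z|$-weighted detection is a flag. Determinism comes from a fixed seed
controlling the scan order. Modularity is reported for the final
partition.

# Enrichment

Hub neighbourhoods (a hub with its first neighbours, optionally split by
edge sign) and communities are tested for over-representation against a
user-supplied GMT collection with the one-sided hypergeometric upper
tail, $P(X \ge k)$. The background is the gene panel itself, never the
whole genome: a curated panel is already enriched for cancer and immune
biology, and a transcriptome background would make almost any panel
subset look significant. Terms with fewer than three background genes or
zero overlap are dropped before BH correction, one family per query. The
strict-inequality convention $P(X > k)$ is exposed as an option because
published composition p-values are sometimes computed that way; the two
conventions differ by the point mass at $k$ and neither is treated as a
ground-truth test value here.

# Patient-similarity fusion

Each data layer becomes a patient-affinity matrix: variables are z-scored
(so count-scale genes and percentage-scale immune subsets contribute
comparably), Euclidean distances are computed, and the scaled-exponential
kernel $W_{ij} = \exp(-d^2_{ij} / (\mu\,\varepsilon_{ij}))$ is applied
with $\varepsilon_{ij}$ the mean of the two patients' K-nearest-neighbour
distances and their own distance. The bandwidth term is kept on the
squared-distance scale, following the reference SNF implementation; on
the linear scale the kernel argument grows with the absolute distance
scale and the affinity matrix degenerates towards the identity for
high-dimensional standardized data. The gene-expression layer uses
log1p-transformed counts of the hub genes only — feature selection is the
point of the hub analysis — while the immune layer uses all variables at
the pre-therapy timepoint by default (the patient-similarity network is
meant as a baseline stratifier; the post-therapy layer is a flag).

Fusion follows the standard nonlinear cross-diffusion: each layer is
normalised into a full transition kernel (half the mass on the diagonal)
and a sparse K-NN kernel, and each iteration diffuses the average of the
other layers' kernels through the local one, renormalising every step
(the maximum row-sum deviation after renormalisation is recorded and
asserted below $10^{-8}$ in the tests). Defaults $K = 20$ (capped at
$N-1$), $\mu = 0.5$, $t = 20$ follow the conventions of the cited
method's software, since the source analysis does not print them; all are
configurable and echoed in the run manifest.

The number of clusters is chosen by the eigengap of the symmetric
normalised Laplacian over $k \in \{2,\dots,5\}$, and spectral clustering
embeds patients in the bottom-$k$ eigenvectors, row-normalises, and runs
k-means with seeded k-means++ restarts (best inertia kept, ties broken by
the lexicographically smallest label vector, so the output is a pure
function of the seed).

# Survival and cluster characterisation

Cluster survival uses the Kaplan-Meier product-limit estimator with the
conventional median (first time the curve reaches 0.5, no interpolation),
the two-group log-rank test, and Cox proportional-hazards models through
the survival package with Efron tie handling — survival times recorded in
months tie frequently, and Efron's approximation is the accurate standard
choice. The cluster effect is reported both univariate and adjusted for
age, smoking history, histology, PD-L1 category and ECOG performance
status, with Wald 95% intervals. Non-convergence and separation are
flagged, never silently reported. Cluster composition against response
uses the hypergeometric tail; two-cluster accuracy maps clusters to
labels by the better of the two possible assignments (hence never below
0.5); per-variable cluster differences use the Mann-Whitney test, exact
by enumeration when both groups have at most ten untied observations,
BH-corrected per layer; baseline balance uses Fisher's exact test for
categorical covariates and the Wilcoxon rank-sum test for continuous
ones.

# Internal validation

`loocv()` removes one patient at a time and reruns the entire chain —
differential network, hub selection, both affinity layers, fusion,
spectral clustering with $k = 2$ — on the remaining patients. The
held-out patient is not assigned a cluster: concordance with response and
log-rank separation are evaluated on the retained patients, which is the
refit-stability reading of leave-one-out for an unsupervised pipeline (a
nearest-centroid assignment of the held-out patient would test a
different, supervised claim). Per-iteration seeds derive deterministically
from the base seed and the left-out patient id, so iterations are
independent yet reproducible, and a failed iteration is recorded as
failed rather than dropped.

# The synthetic-cohort generator

No raw data are distributed with the analysis this package
operationalises, so `generateCohort()` exists as a first-class module
that emulates the *statistical structure* the pipeline assumes, with
ground truth for parameter-recovery testing. Defaults mirror the study
geometry: 438 panel genes, 44 expression patients, 38 patients common to
both layers (20 responders, 18 non-responders), 31 immune variables, 23
planted hubs. The responder split of the six expression-only patients is
not printed in the source analysis, so it is a configuration field
(default 23 responders of 44).

The expression model is a latent-program Gaussian on the log scale,
exponentiated and rounded to counts. Each planted hub anchors its own
co-regulated program: a backbone cohort of panel genes follows the hub's
latent activity in responders with pairwise correlation
`rho_within_module` (default 0.8), while in non-responders the same
cohort follows a ghost copy of the program and the hub itself is
decoupled. Two properties motivate this over a single global factor.
First, it makes exactly the hub-touching pairs differentially
co-expressed — the ground truth is unambiguous. Second, a single global
factor couples the sampling noise of tens of thousands of pair
correlations through one latent draw, which makes whole-cohort summary
statistics swing wildly between seeds; independent programs keep the
Monte-Carlo behaviour stable. The backbone covers the whole panel by
default because hub selection is a percentile of the nonzero-degree
distribution: hubs can only occupy the top 5% if essentially the whole
panel participates in the differential network, which is also what the
published network's edge and hub counts imply about the real panel.

A known limitation follows directly from the calibration numbers above:
with 23 hubs among 438 genes, every covered non-hub gene has roughly
eight times more backbone partners than hub partners, and matched
backbone pairs produce false edges at the ~5% null rate of the $|Z|>2$
rule. The planted-pair precision of the DCN edge set therefore plateaus
near 0.55-0.65 at the study geometry regardless of how the structure is
arranged; the acceptance suite states the stricter published bound and
the corresponding check is expected to fail, documenting the phenomenon
rather than hiding it. Hub recovery is unaffected (the false edges are
spread thin) and averages about 0.9.

Immune profiles use a Gaussian copula: block-correlated latents (a
myeloid block, an NK block, a T-cell block; an NK-myeloid bridge present
only in responders before therapy, echoing the connectivity difference
the immune networks are meant to detect) pushed through a logistic map
onto (0, 100). Patient stratification signal enters as latent mean
shifts: the latent prognostic cluster raises NK subsets in cluster 1 and
myeloid subsets in cluster 2 (`immune_cluster_shift`, default 1.6 latent
SD), and raises hub-gene expression in cluster 1
(`gep_cluster_shift`, default 0.8 log-units). These defaults were fixed
once by pre-build simulation so that fused clustering recovers the
latent cluster clearly (ARI well above 0.6) while accuracy against
response stays around 0.8 — bounded by design, because the latent cluster
disagrees with the response label with probability `flip_prob` (default
0.2, chosen to mimic the imperfect cluster-response concordance reported
for the real cohort).

Survival is exponential: the good-prognosis cluster has median 32 months
(`median_survival_good`), the poor cluster's hazard is `hazard_ratio`
(default 4.5) times larger, and censoring is independent uniform on
$(0, u)$ with $u$ solved numerically so the expected censored fraction
equals `censoring_rate` (default 0.2). Baseline covariates (age, sex,
smoking, histology, PD-L1 category, ECOG) are drawn independently of the
cluster, so balance tests are null by construction.

What the generator does not emulate: probe-level measurement chemistry,
flow-cytometry gating artefacts, batch effects, compositional coupling
between immune percentages, non-proportional hazards, and any
correlation between clinical covariates and biology. Passing recovery
tests on these cohorts therefore demonstrates that the pipeline detects
the structure it claims to detect at realistic sizes and noise — not that
real data contain such structure.

# Numerical choices and problem sizes

Seeded stochastic steps (generation, k-means restarts, Louvain order,
permutation p-values) all run under locally scoped RNG so library calls
do not perturb user state; derived seeds stay below $2^{31}$. Constant
variables are dropped from affinity features with a warning but retained
as isolated network nodes. Degenerate inputs (empty hub sets, fewer than
four samples, non-positive times, perfect correlations) raise typed
errors or flagged rows as documented per function.

The test suite and acceptance script run on one CPU in a few minutes:
recovery checks use ten default-size cohorts; the null calibration uses
5,000 simulated pairs; log-rank uniformity uses 500 simulated cohorts of
38; Cox coverage uses 50 replicates at n = 200; pipeline-level unit
tests use a reduced cohort (80 genes, 30 patients) so that the full
LOOCV loop stays fast. These sizes were chosen as the smallest that make
the Monte-Carlo bounds sharp.
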