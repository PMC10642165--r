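---
title: "Quantifying the tumour immune microenvironment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the tumour immune microenvironment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmectx)
```

## The problem

Solid tumours such as oesophageal adenocarcinoma differ enormously in how
immune cells occupy them. Three recurring contextures matter clinically:
*immune-inflamed* tumours with intra-tumoural cytotoxic infiltration,
*immune-excluded* tumours where immune cells accumulate in the
peri-tumoural stroma but not the epithelium, and *immune-desert* tumours
with little infiltration anywhere. tmectx quantifies these contextures
from two complementary data modalities — segmented multiplex-IHC cell
tables over labelled tissue masks, and bulk immune gene-expression panels
— and links them to patient outcome with survival models. A synthetic
cohort generator reproduces the statistical structure of such a study so
that every stage of the analysis can be validated without access to
patient data.

## Spatial contexture

**Compartments and densities.** A region mask labels each pixel
background, tumour, stroma or normal epithelium, with a physical scale in
µm/pixel. The density of phenotype $p$ in compartment $c$ is
$\hat\lambda_{pc} = n_{pc}/A_c$ with $A_c$ the compartment pixel count
times the squared pixel size (mm²). Densities are exactly count over
area; a zero-area compartment yields a missing (never zero) row.

**The infiltrative border.** The border is the set of tumour pixels
8-adjacent to a non-tumour label. Tumour touching only the field edge is
excluded: a biopsy cut is not an infiltrative front, and a tumour filling
the whole field therefore has an empty border. Depth of an intra-tumoural
cell is its distance to the nearest border point, computed by an exact
Euclidean distance transform on the pixel grid (EBImage) and converted to
µm; cells map to pixels by `floor(coordinate / µm_per_pixel)`. Against an
exhaustive nearest-border-point scan this grid read-off is accurate to
half a pixel diagonal, which the test suite enforces on randomized masks.
Note one discretization subtlety: border pixel *centres* sit half a pixel
inside the continuous tumour boundary, so analytic expectations must be
stated against pixel centres.

**Tumour core and margin.** At threshold $d \in \{50, 100, 150\}$ µm, a
cell is margin (TM) when depth $< d$ and core (TC) when depth $\ge d$.
The strict inequalities of the field's usual definition leave depth
exactly $d$ unassigned; we close the core side so the zones always
partition the tumour — a measure-zero choice under continuous
coordinates, but one that keeps counts additive. Cells outside the tumour
never enter TC/TM statistics: the profile measures infiltration from the
border *toward the tumour centre*, so stromal cells near the border are
deliberately excluded.

**Proportion conventions.** "Proportion of the cell type of interest to
total cell number at a given distance" admits two readings, and both are
implemented and labelled rather than silently picking one:

* `zone` (default): cells of the phenotype in the zone over **all cells
  in that zone** — the zone's composition;
* `phenotype`: cells of the phenotype in the zone over **all
  intra-tumoural cells of that phenotype** — so $p_{TM} + p_{TC} = 1$ and
  $p_{TM}$ is non-decreasing in $d$.

Every output row records the convention used.

**Ratios and PD-L1.** The anti/pro-tumour balance is a density ratio
(e.g. CD8/CD163), dichotomized at 1; $a/0$ with $a>0$ is `Inf` (high),
$0/0$ is missing. PD-L1 is an area statistic — the percentage of
compartment pixels staining positive — dichotomized at 1%.

## Expression profiling

**Normalization.** Counts are rescaled per sample so the geometric mean
of housekeeping genes matches the grand housekeeping geometric mean, then
transformed to $\log_2(\text{count} + 1)$. Housekeeping genes with a zero
count anywhere are dropped from the factor with a warning (a single zero
would annihilate the geometric mean).

**Scores.** A cell-type or pathway score is the mean log2 expression of
the set's member genes; relative quantities (B cells versus total TILs,
CD8 versus exhausted CD8) are score *differences*, which on the log scale
correspond to abundance ratios. Scoring is linear: adding $c$ to all
member genes shifts the score by exactly $c$.

**Clustering.** Scores are z-scored across samples and clustered by
Ward-linkage (`ward.D2`) agglomerative clustering on Euclidean distance,
cut at $k = 3$. Neither linkage nor scaling is canonical in the
literature; Ward/Euclidean/z-score is the standard recipe behind score
heatmaps and is recorded in the output. Cluster naming is a codified
approximation of the descriptive convention: the cluster with the highest
mean anti-tumour centroid (T/CD8/B/NK/Th1 sets) is `inflamed`; of the
remainder, the higher myeloid/Treg centroid (macrophage, neutrophil, Treg
sets) is `myeloid_treg`; the last is `desert`. Centroids are returned so
users can audit or rename. The procedure involves no randomness.

**Differential expression.** Per gene, Welch's two-sample *t*-test on
log2 values; the fold change is the difference of group means;
Benjamini–Hochberg adjustment across all tested genes with no
pre-filtering. A gene is significant when $|\log_2 FC| > 1.5$ *and*
adjusted $p < 0.05$. Welch's test is the simplest defensible choice for
normalized log-scale panel data; its type-I calibration (empirical
$\alpha \in [0.03, 0.07]$ at nominal 0.05 over 770-gene null panels) is
verified by simulation in the acceptance suite. One caveat of the BH
invariants: the step-up is *not* idempotent — re-adjusting an adjusted
vector inflates it again — so only the constant-vector fixed point holds.

## Survival inference

**Estimators.** Kaplan–Meier product-limit curves, the $(O-E)^2/V$
log-rank test, and univariate Cox partial-likelihood fits with Breslow
tie handling (Newton–Raphson, tolerance $10^{-9}$, ≤ 50 iterations) are
computed via the survival package behind the package's interfaces.
Monotone likelihoods (perfect separation) are flagged non-converged with
the drift sign rather than reported as finite estimates.

**Maximally selected rank statistics.** To dichotomize a continuous
immune covariate against outcome without a pre-specified cutoff, the
package scans all candidate cutpoints — midpoints between consecutive
distinct covariate values whose low/high split keeps both groups within
$[\text{minprop}, \text{maxprop}] = [0.1, 0.9]$ (conventional bounds; the
source literature does not state them) — and computes at each the
standardized linear rank statistic in log-rank (Savage) scores
$a_i = \delta_i - \hat\Lambda(t_i)$:
$$Z(\mu) = \frac{S(\mu) - m\,\bar a}{\sqrt{\tfrac{m(n-m)}{n(n-1)}\sum_i (a_i - \bar a)^2}},$$
where $S(\mu)$ sums scores in the low group of size $m$. The selected
cutpoint maximizes $|Z|$, taking the smallest maximizer on ties for
determinism. Because the maximum is selected, its p-value must account
for multiplicity; two methods are provided and always labelled:

* **permutation** (default, 9999 permutations of the covariate): exact
  under exchangeability, assumption-light, and validated for null
  uniformity by a Kolmogorov–Smirnov check in the acceptance suite;
* **approx**: the Brownian-bridge crossing approximation of
  Miller–Siegmund/Lausen–Schumacher type over the admissible proportion
  window — much faster, slightly conservative near the window edges, used
  where thousands of scans are needed.

**Other tests.** Wilcoxon rank-sum (exact for small untied samples)
serves independent two-group comparisons and the signed-rank variant
paired pre/post comparisons — chosen by pairing metadata, since the two
are often conflated in methods text; Kruskal–Wallis covers ≥ 3 groups and
chi-square (no continuity correction) contingency tables. Fully tied
inputs return statistic 0 with $p = 1$. The long-/short-term survivor
split at 24 months counts event-free follow-up ≥ 24 months as long-term;
patients censored earlier are excluded as unknown (with the count
reported) rather than misclassified — the immortal-time-safe reading.

**Mock subtraction.** Antigen-stimulation assays report the percentage of
cytokine-positive CD8⁺ cells after subtracting the unstimulated (mock)
background, floored at zero.

## The synthetic cohort generator

The generator's defaults are the study conditions the analysis is
validated under.

* **Clinical composition** (`cohort_spec`): 107 patients, arm fractions
  0.505/0.495 (nCRT/nCT), three equal archetype fractions; MPR
  probability 0.55/0.15/0.17 by archetype (inflamed/myeloid-Treg/desert,
  giving ≈ 29% overall and the observed association of response with the
  inflamed contexture), N0 probability 0.75/0.45/0.45 (≈ 55% overall),
  and residual post-treatment tumour availability 0.59.
* **Tissue** (`tissue_spec`): cells follow an inhomogeneous Poisson
  process — per-pixel Poisson counts with uniform jitter inside the
  pixel, which is exact for piecewise-constant intensity. Stromal
  intensity is constant; intra-tumoural intensity is the tumour density
  times the exclusion gradient
  $g(\text{depth}) = 0.1 + 0.9\,e^{-\text{depth}/\text{scale}}$ (scale
  50 µm by default; $g \equiv 1$ when the scale is 0). The 0.1 floor
  guarantees non-empty cores so TC statistics stay defined. Default
  densities (cells/mm²) encode the orderings the contextures imply —
  stroma denser than tumour for every immune phenotype, CD8-rich inflamed
  tumours, CD163/FoxP3-rich myeloid-Treg tumours, sparse deserts; the
  magnitudes are chosen once as plausible multiplex-IHC values, since no
  per-archetype reference densities exist. A clustered parent–child
  process is deliberately *not* the default: the homogeneous Poisson
  process is the simplest model with controllable density and gradient.
* **Expression** (`expression_spec`): log2 values are baseline (7) plus
  additive archetype effects on marker-set member genes (a gene in
  several affected sets sums their effects) plus Gaussian noise (SD 0.5),
  plus a per-sample library offset (SD 0.5 log2) applied to *all* genes
  so normalization is genuinely exercised; values are exponentiated to
  counts. Gaussian-on-log2 is used instead of a negative-binomial count
  model because the pipeline consumes normalized log2 values and additive
  effects keep recovery checks interpretable.
* **Survival** (`survival_spec`): exponential proportional hazards,
  $h(x) = \tfrac{\ln 2}{\text{median}}\,e^{\beta^\top x}$ with baseline
  median 25 months, administrative censoring at 89 months and light
  random censoring (rate 0.008/month); the closed-form median makes
  acceptance checks exact. The planted protective effect used throughout
  validation is $\beta = \ln 0.45$.
* **Seeds**: one master seed; every stage and patient draws from a
  sub-stream derived by a stable polynomial hash (`derive_seed`), so
  adding a patient never perturbs another patient's data.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: segmentation and phenotyping error, staining
variability, spatial clustering of cells beyond the radial exclusion
gradient, irregular infiltrative fronts (geometries are discs, annuli and
lobed blobs), count-level overdispersion, informative censoring, and
correlation between modalities beyond the shared archetype label.

## Validation sizes and numerical choices

The test and acceptance suites run at deliberately modest sizes chosen to
make each check statistically decisive: Poisson intensity checks over 200
fields; Cox recovery at $n = 1000$ with 100-replicate CI coverage;
end-to-end (density → maxstat → Cox) recovery at $n = 500$ over
50 replicates against the $[0.30, 0.65]$ HR window; maxstat null
calibration over 200 simulations × 999 permutations; DGE calibration over
100 null panels of 770 genes; clustering recovery over 100 seeds. Ties in
the maxstat scan break to the smallest cutpoint; Cox convergence is
$|\Delta\beta| < 10^{-9}$; proportions of empty zones, scores of absent
sets and ratios $0/0$ are always missing, never zero.

## Known limitations

Single-covariate survival models only (no multivariable Cox, competing
risks or proportional-hazards diagnostics); no probe-level QC or batch
correction; mean-marker scoring rather than deconvolution; masks are
treated as ground truth; the shipped marker catalog is a synthetic
stand-in assembled from canonical lineage markers, not a licensed curated
panel — users with access to a curated catalog can supply it as JSON.
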