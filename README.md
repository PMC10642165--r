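# tmectx — tumour immune microenvironment contexture analysis

tmectx is an R package for quantifying the immune contexture of solid
tumours and linking it to patient outcome. It is aimed at translational
researchers working with segmented multiplex-immunohistochemistry data
(per-cell tables plus labelled tissue masks) and immune gene-expression
panels, in settings such as neoadjuvant-treated oesophageal
adenocarcinoma where the balance of anti-tumour (CD8⁺) and pro-tumour
(CD163⁺ M2-macrophage, FoxP3⁺ Treg) infiltration stratifies survival.

The package covers four connected analyses:

* **Spatial contexture** — compartment cell densities λ = n/A
  (cells/mm²), anti/pro-tumour density ratios (dichotomized at 1), PD-L1
  area positivity (% of compartment area, dichotomized at 1%), and
  tumour-core/tumour-margin profiles: each intra-tumoural cell's depth is
  its Euclidean distance to the *infiltrative border* (tumour pixels
  8-adjacent to non-tumour, excluding the field edge), and cells are
  split at d ∈ {50, 100, 150} µm into margin (depth < d) and core
  (depth ≥ d).
* **Expression profiling** — housekeeping geometric-mean normalization to
  log₂(count + 1); cell-type/pathway scores as mean log₂ expression of
  marker sets; Ward/Euclidean hierarchical clustering of z-scored scores
  into immune phenotypes (inflamed / myeloid-Treg / desert); per-gene
  Welch *t* differential expression with the rule |log₂FC| > 1.5 and
  Benjamini–Hochberg adjusted p < 0.05.
* **Survival inference** — Kaplan–Meier, log-rank, univariate Cox
  (Breslow ties), and cutpoint selection by **maximally selected rank
  statistics**: over all admissible cutpoints µ (low-group proportion in
  [0.1, 0.9]), the standardized log-rank-score statistic

      Z(µ) = (S(µ) − m·ā) / sqrt[ m(n−m)/(n(n−1)) · Σ(aᵢ − ā)² ]

  is scanned and M = max|Z| selected, with a permutation p-value
  (default) or a Brownian-bridge crossing approximation, always labelled.
* **Synthetic cohorts** — generators for clinical tables, tissue fields
  (inhomogeneous Poisson cells with a radial immune-exclusion gradient
  g(depth) = 0.1 + 0.9·e^(−depth/50 µm)), expression panels with additive
  archetype effects, and exponential proportional-hazards outcomes — so
  the whole pipeline is testable end to end.

## Worked example

Spatial profile of one simulated inflamed field, then survival
dichotomization of a measured CD8 density against outcomes carrying a
planted protective effect (true HR 0.45):

```r
library(tmectx)

ts <- tissue_spec(field_width_um = 1500, field_height_um = 1500,
                  um_per_pixel = 10,
                  tumour_geometry = list(shape = "disc", radius_um = 500))
tis <- generate_tissue(ts, "inflamed", seed = 3)
border <- extract_infiltrative_border(tis$mask)
depths <- distance_to_border(tis$cells, border, tis$mask)
subset(margin_profile(tis$cells, depths, denominator = "phenotype"),
       phenotype == "CD8")
#>  phenotype d_um zone count denominator_n proportion convention
#>        CD8   50   TM    35            60  0.5833333  phenotype
#>        CD8   50   TC    25            60  0.4166667  phenotype
#>        CD8  100   TM    46            60  0.7666667  phenotype
#>        CD8  100   TC    14            60  0.2333333  phenotype
#>        CD8  150   TM    49            60  0.8166667  phenotype
#>        CD8  150   TC    11            60  0.1833333  phenotype
```

Under the `phenotype` convention the TM/TC proportions of each cell type
sum to 1 per band; here 58% of intra-tumoural CD8⁺ cells sit within 50 µm
of the border — the exclusion gradient at work. Densities show the
stroma-dominant pattern of an immune-excluded epithelium, and the
intra-tumoural CD8/CD163 ratio dichotomizes "high" at the conventional
cutoff of 1:

```r
dens <- compute_density(tis$cells, tis$mask)
#>  compartment phenotype count area_mm2 density_cells_per_mm2
#>       tumour       CD8    60    0.786                 76.34
#>       tumour     CD163    39    0.786                 49.62
#>       stroma       CD8   670    1.464                457.65
#>       stroma     CD163   374    1.464                255.46
# tumour CD8/CD163 ratio: 1.54 -> high
```

```r
covs <- data.frame(patient_id = 1:300, cd8_high = rep(0:1, 150))
sv <- generate_survival(
  survival_spec(covariate_log_hazards = c(cd8_high = log(0.45))),
  covs, seed = 9)
set.seed(9)
density_meas <- 80 + 90 * covs$cd8_high + rnorm(300, 0, 25)
dic <- maxstat_dichotomize(sv$time_months, sv$event, density_meas,
                           p_method = "permutation", n_perm = 1999)
dic
#> Maximally selected rank statistic: cutpoint = 109.6, max |Z| = 5.612, p = 0.0005 (permutation)
#>   n = 300; low-group proportion window [0.10, 0.90]
cox_univariate(sv$time_months, sv$event, as.numeric(dic$labels == "high"))
#> Cox PH: HR = 0.438 (95% CI 0.331-0.579), p = 6.559e-09, n = 300 (205 events)
```

The scan places the cutpoint at 109.6 cells/mm² — between the two planted
density modes — and the Cox fit on the resulting high/low groups recovers
the planted hazard ratio (0.438 vs true 0.45).

An end-to-end run (simulate → spatial → expression → survival → report)
is one call, writing per-stage CSVs plus a provenance manifest:

```r
run_pipeline(list(out_dir = "demo_run", seed = 11,
                  cohort = list(n_patients = 24)))
```

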