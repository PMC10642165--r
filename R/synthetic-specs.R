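#' Cohort specification
#'
#' Defines the clinical composition of a synthetic cohort: treatment-arm
#' and immune-archetype mixtures, plus archetype-conditional rates for the
#' clinicopathological flags carried by the clinical table. Defaults mirror
#' a neoadjuvant oesophageal adenocarcinoma cohort: roughly half of
#' patients per arm, about 29% major pathological response (MPR) overall —
#' most likely in inflamed tumours — 55% node-negative, and residual
#' post-treatment tumour available for 59%.
#'
#' @param n_patients number of patients (>= 2).
#' @param arm_fractions named fractions over `c("nCT", "nCRT")`, summing
#'   to 1.
#' @param archetype_fractions named fractions over
#'   `c("inflamed", "myeloid_treg", "desert")`, summing to 1.
#' @param mpr_prob archetype-conditional probability of MPR.
#' @param n0_prob archetype-conditional probability of node-negative (N0)
#'   status.
#' @param post_sample_prob probability that a residual-tumour
#'   post-treatment sample exists.
#' @param seed integer seed for [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 107,
                        arm_fractions = c(nCT = 0.495, nCRT = 0.505),
                        archetype_fractions = c(inflamed = 1 / 3,
                                                myeloid_treg = 1 / 3,
                                                desert = 1 / 3),
                        mpr_prob = c(inflamed = 0.55, myeloid_treg = 0.15,
                                     desert = 0.17),
                        n0_prob = c(inflamed = 0.75, myeloid_treg = 0.45,
                                    desert = 0.45),
                        post_sample_prob = 0.59,
                        seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2 || n_patients != round(n_patients)) {
    stop_spec("n_patients must be an integer >= 2")
  }
  if (!setequal(names(arm_fractions), c("nCT", "nCRT"))) {
    stop_spec("arm_fractions must be named over {nCT, nCRT}")
  }
  if (!setequal(names(archetype_fractions),
                c("inflamed", "myeloid_treg", "desert"))) {
    stop_spec("archetype_fractions must be named over {inflamed, myeloid_treg, desert}")
  }
  check_fractions(arm_fractions, "arm_fractions")
  check_fractions(archetype_fractions, "archetype_fractions")
  stopifnot(all(mpr_prob >= 0 & mpr_prob <= 1),
            all(n0_prob >= 0 & n0_prob <= 1),
            post_sample_prob >= 0, post_sample_prob <= 1)
  structure(list(
    n_patients = as.integer(n_patients),
    arm_fractions = arm_fractions,
    archetype_fractions = archetype_fractions,
    mpr_prob = mpr_prob, n0_prob = n0_prob,
    post_sample_prob = post_sample_prob,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Tissue field specification
#'
#' Parametrizes one simulated multiplex-IHC field: physical extent, pixel
#' scale, tumour geometry, and archetype x compartment x phenotype expected
#' densities for an inhomogeneous Poisson cell process. Intra-tumoural
#' intensity is attenuated with depth from the infiltrative border by
#' \deqn{g(depth) = floor + (1 - floor) e^{-depth/scale},}
#' the immune-exclusion gradient; the floor (default 0.1) keeps deep-core
#' density positive so core statistics stay defined. `exclusion_scale_um = 0`
#' switches the gradient off (`g == 1`).
#'
#' Default densities (cells/mm^2) encode the compartment and archetype
#' ordering seen in immune-excluded tumours: every immune phenotype is
#' denser in stroma than in tumour, inflamed tumours are CD8-rich,
#' myeloid/Treg tumours CD163- and FoxP3-rich with depressed CD8, and
#' desert tumours sparse throughout.
#'
#' @param field_width_um,field_height_um field extent in micrometres.
#' @param um_per_pixel mask pixel size in micrometres.
#' @param tumour_geometry list with `shape` in `{disc, blob, annulus}` and
#'   size parameters (`radius_um`; `inner_radius_um` for the annulus;
#'   `n_lobes` for the blob).
#' @param density_map nested list `archetype$compartment$phenotype` of
#'   expected densities in cells/mm^2.
#' @param exclusion_scale_um decay length of the exclusion gradient.
#' @param exclusion_floor lower bound of `g`.
#' @param pdl1_fraction per-archetype, per-compartment probability that a
#'   pixel is PD-L1 positive.
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(field_width_um = 2000, field_height_um = 2000,
                        um_per_pixel = 10,
                        tumour_geometry = list(shape = "disc", radius_um = 600),
                        density_map = default_density_map(),
                        exclusion_scale_um = 50,
                        exclusion_floor = 0.1,
                        pdl1_fraction = default_pdl1_fraction()) {
  stopifnot(field_width_um > 0, field_height_um > 0, um_per_pixel > 0,
            exclusion_scale_um >= 0,
            exclusion_floor >= 0, exclusion_floor <= 1)
  shape <- tumour_geometry$shape %||% "disc"
  if (!shape %in% c("disc", "blob", "annulus")) {
    stop_spec("tumour_geometry$shape must be disc, blob or annulus")
  }
  r <- tumour_geometry$radius_um %||% stop_spec("tumour_geometry needs radius_um")
  if (2 * r > min(field_width_um, field_height_um)) {
    stop_spec("tumour geometry does not fit inside the field")
  }
  dens <- unlist(density_map)
  if (any(dens < 0)) stop_spec("densities must be non-negative")
  structure(list(
    field_width_um = field_width_um, field_height_um = field_height_um,
    um_per_pixel = um_per_pixel, tumour_geometry = tumour_geometry,
    density_map = density_map, exclusion_scale_um = exclusion_scale_um,
    exclusion_floor = exclusion_floor, pdl1_fraction = pdl1_fraction
  ), class = "tissue_spec")
}

#' @rdname tissue_spec
#' @export
default_density_map <- function() {
  list(
    inflamed = list(
      tumour = c(CD8 = 300, FoxP3 = 60, CD163 = 150, other = 900),
      stroma = c(CD8 = 450, FoxP3 = 110, CD163 = 260, other = 1100),
      normal = c(CD8 = 60, FoxP3 = 15, CD163 = 40, other = 700)
    ),
    myeloid_treg = list(
      tumour = c(CD8 = 60, FoxP3 = 150, CD163 = 380, other = 900),
      stroma = c(CD8 = 140, FoxP3 = 260, CD163 = 560, other = 1100),
      normal = c(CD8 = 40, FoxP3 = 20, CD163 = 60, other = 700)
    ),
    desert = list(
      tumour = c(CD8 = 25, FoxP3 = 15, CD163 = 45, other = 650),
      stroma = c(CD8 = 70, FoxP3 = 35, CD163 = 90, other = 950),
      normal = c(CD8 = 25, FoxP3 = 10, CD163 = 30, other = 650)
    )
  )
}

#' @rdname tissue_spec
#' @export
default_pdl1_fraction <- function() {
  list(
    inflamed = c(tumour = 0.06, stroma = 0.05, normal = 0.002),
    myeloid_treg = c(tumour = 0.02, stroma = 0.025, normal = 0.002),
    desert = c(tumour = 0.004, stroma = 0.006, normal = 0.001)
  )
}

#' Expression panel specification
#'
#' Parametrizes the synthetic immune expression panel: a marker-gene
#' catalog (cell-type and pathway sets plus housekeeping genes), additive
#' archetype effects on the log2 scale applied to a set's member genes,
#' log-normal measurement noise, and per-sample library-scaling offsets
#' that housekeeping normalization must remove. A gene belonging to
#' several affected sets receives the sum of their effects.
#'
#' @param catalog a [gene_set_catalog()]; default loads the synthetic
#'   stand-in catalog shipped with the package.
#' @param n_genes total panel size; genes beyond the catalog are unnamed
#'   filler genes with baseline expression only.
#' @param archetype_effects list `archetype -> named numeric` of log2
#'   shifts per set name.
#' @param noise_sd per-measurement Gaussian noise SD on the log2 scale.
#' @param baseline_log2 baseline log2 expression of every gene.
#' @param offset_sd SD of the per-sample log2 library offset.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(catalog = default_gene_catalog(),
                            n_genes = 160,
                            archetype_effects = default_archetype_effects(),
                            noise_sd = 0.5,
                            baseline_log2 = 7,
                            offset_sd = 0.5) {
  if (noise_sd <= 0) stop_spec("noise_sd must be positive")
  marker_genes <- unique(unlist(c(catalog$cell_types, catalog$pathways)))
  if (length(intersect(marker_genes, catalog$housekeeping)) > 0) {
    stop_spec("marker sets must be disjoint from housekeeping genes")
  }
  n_named <- length(unique(c(marker_genes, catalog$housekeeping)))
  if (n_genes < n_named) stop_spec("n_genes smaller than the catalog")
  structure(list(
    catalog = catalog, n_genes = as.integer(n_genes),
    archetype_effects = archetype_effects,
    noise_sd = noise_sd, baseline_log2 = baseline_log2,
    offset_sd = offset_sd
  ), class = "expression_spec")
}

#' @rdname expression_spec
#' @export
default_archetype_effects <- function() {
  list(
    inflamed = c(T_cells = 1.5, CD8_T = 2, B_cells = 2, NK = 1.5,
                 Th1 = 1.5, cytotoxicity = 1.5, antigen_processing = 1.5),
    myeloid_treg = c(CD45 = 1, macrophages = 2, neutrophils = 2, Treg = 2,
                     exhausted_CD8 = 1, CD8_T = -1, B_cells = -1),
    desert = c(macrophages = -1.5, neutrophils = -1.5, exhausted_CD8 = -2,
               CD8_T = -0.5, T_cells = -0.5)
  )
}

#' Survival-process specification
#'
#' Event times follow an exponential proportional-hazards model
#' `h(x) = (log 2 / baseline_median) * exp(sum beta_j x_j)`, so a patient
#' with all covariates at zero has the stated median survival. Observed
#' time is the minimum of the event time, an administrative cutoff, and an
#' exponential random-censoring time. Defaults emulate a cohort with
#' 25-month baseline median survival followed for at most 89 months with
#' light loss to follow-up.
#'
#' @param baseline_median_months median event time at covariates zero.
#' @param covariate_log_hazards named numeric: log hazard ratio per unit
#'   of each covariate.
#' @param censor_admin_months administrative censoring time.
#' @param censor_random_rate rate of the random-censoring exponential
#'   (0 disables random censoring).
#' @return A `survival_spec` list.
#' @export
survival_spec <- function(baseline_median_months = 25,
                          covariate_log_hazards = c(),
                          censor_admin_months = 89,
                          censor_random_rate = 0.008) {
  if (baseline_median_months <= 0) stop_spec("baseline_median_months must be > 0")
  if (censor_admin_months <= 0) stop_spec("censor_admin_months must be > 0")
  if (censor_random_rate < 0) stop_spec("censor_random_rate must be >= 0")
  structure(list(
    baseline_median_months = baseline_median_months,
    covariate_log_hazards = covariate_log_hazards,
    censor_admin_months = censor_admin_months,
    censor_random_rate = censor_random_rate
  ), class = "survival_spec")
}
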