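#' Generate a synthetic clinical cohort
#'
#' Draws one patient per row: treatment arm and immune archetype are
#' independent multinomial draws with the spec fractions; MPR and nodal
#' status are Bernoulli with archetype-conditional rates; availability of
#' a residual-tumour post-treatment sample is Bernoulli with a common
#' rate. Reproducible for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with columns `patient_id, arm, archetype, mpr,
#'   n_stage, has_post_sample`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(derive_seed(spec$seed, "cohort"), {
    arm <- sample(names(spec$arm_fractions), n, replace = TRUE,
                  prob = spec$arm_fractions)
    archetype <- sample(names(spec$archetype_fractions), n, replace = TRUE,
                        prob = spec$archetype_fractions)
    mpr <- as.integer(stats::runif(n) < spec$mpr_prob[archetype])
    n_stage <- ifelse(stats::runif(n) < spec$n0_prob[archetype], "N0", "N+")
    has_post <- as.integer(stats::runif(n) < spec$post_sample_prob)
  })
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    arm = arm, archetype = archetype, mpr = mpr,
    n_stage = n_stage, has_post_sample = has_post,
    stringsAsFactors = FALSE
  )
}

# Tumour label geometry for one field, as a logical matrix.
tumour_geometry_mask <- function(spec, seed) {
  nx <- as.integer(round(spec$field_width_um / spec$um_per_pixel))
  ny <- as.integer(round(spec$field_height_um / spec$um_per_pixel))
  px <- (seq_len(nx) - 0.5) * spec$um_per_pixel
  py <- (seq_len(ny) - 0.5) * spec$um_per_pixel
  cx <- spec$field_width_um / 2
  cy <- spec$field_height_um / 2
  geo <- spec$tumour_geometry
  d2 <- outer((py - cy)^2, (px - cx)^2, `+`)
  shape <- geo$shape %||% "disc"
  if (shape == "disc") {
    tum <- d2 <= geo$radius_um^2
  } else if (shape == "annulus") {
    inner <- geo$inner_radius_um %||% (geo$radius_um / 2)
    tum <- d2 <= geo$radius_um^2 & d2 >= inner^2
  } else { # blob: union of jittered lobes around the centre
    n_lobes <- geo$n_lobes %||% 3L
    tum <- matrix(FALSE, ny, nx)
    jitter_max <- geo$radius_um * 0.45
    lobes <- with_seed(derive_seed(seed, "blob"), {
      cbind(stats::runif(n_lobes, -jitter_max, jitter_max),
            stats::runif(n_lobes, -jitter_max, jitter_max),
            stats::runif(n_lobes, 0.45, 0.8) * geo$radius_um)
    })
    for (k in seq_len(n_lobes)) {
      tum <- tum | outer((py - cy - lobes[k, 2])^2,
                         (px - cx - lobes[k, 1])^2, `+`) <= lobes[k, 3]^2
    }
  }
  tum
}

#' Generate one tissue field: mask, cells and PD-L1 positivity
#'
#' Builds a region mask (tumour geometry surrounded by stroma), then lays
#' down cells by an inhomogeneous Poisson process: per pixel, counts are
#' Poisson with mean `density x pixel area`, attenuated inside the tumour
#' by the exclusion gradient `g(depth)` of [tissue_spec()]; positions are
#' uniform within the pixel. A per-pixel Bernoulli PD-L1 positivity mask
#' is drawn with the spec's archetype/compartment fractions.
#'
#' @param spec a [tissue_spec()].
#' @param archetype one of `"inflamed"`, `"myeloid_treg"`, `"desert"`.
#' @param seed integer seed.
#' @return A list with `mask` ([region_mask()]), `cells` ([cell_table()])
#'   and `pdl1` (logical matrix, pixel-level marker positivity).
#' @export
generate_tissue <- function(spec, archetype, seed) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (!archetype %in% names(spec$density_map)) {
    stop_spec("no densities for archetype '", archetype, "'")
  }
  tum <- tumour_geometry_mask(spec, seed)
  lab <- matrix(2L, nrow(tum), ncol(tum))
  lab[tum] <- 1L
  mask <- region_mask(lab, spec$um_per_pixel)

  # exclusion gradient per tumour pixel
  g <- matrix(1, nrow(lab), ncol(lab))
  if (spec$exclusion_scale_um > 0 && any(tum)) {
    border <- extract_infiltrative_border(mask)
    if (nrow(border) > 0) {
      depth <- depth_map_um(mask, border)
      g[tum] <- spec$exclusion_floor +
        (1 - spec$exclusion_floor) * exp(-depth[tum] / spec$exclusion_scale_um)
    }
  }

  px_area_mm2 <- (spec$um_per_pixel / 1000)^2
  dens <- spec$density_map[[archetype]]
  codes <- compartment_codes()
  xs <- ys <- numeric(0)
  phen <- character(0)
  comp <- character(0)
  with_seed(derive_seed(seed, "cells"), {
    for (cn in names(dens)) {
      in_comp <- lab == codes[[cn]]
      if (!any(in_comp)) next
      idx <- which(in_comp, arr.ind = TRUE)
      gain <- if (cn == "tumour") g[in_comp] else rep(1, nrow(idx))
      for (p in names(dens[[cn]])) {
        lambda <- dens[[cn]][[p]] * px_area_mm2 * gain
        cnt <- stats::rpois(length(lambda), lambda)
        tot <- sum(cnt)
        if (tot == 0) next
        rows <- rep(idx[, 1], cnt)
        cols <- rep(idx[, 2], cnt)
        xs <- c(xs, (cols - 1 + stats::runif(tot)) * spec$um_per_pixel)
        ys <- c(ys, (rows - 1 + stats::runif(tot)) * spec$um_per_pixel)
        phen <- c(phen, rep(p, tot))
        comp <- c(comp, rep(cn, tot))
      }
    }
    pdl1_frac <- spec$pdl1_fraction[[archetype]]
    pdl1 <- matrix(FALSE, nrow(lab), ncol(lab))
    for (cn in names(pdl1_frac)) {
      in_comp <- lab == codes[[cn]]
      if (!any(in_comp)) next
      pdl1[in_comp] <- stats::runif(sum(in_comp)) < pdl1_frac[[cn]]
    }
  })
  cells <- cell_table(
    cell_id = if (length(xs)) sprintf("c%06d", seq_along(xs)) else character(0),
    x_um = xs, y_um = ys, phenotype = phen, compartment = comp
  )
  list(mask = mask, cells = cells, pdl1 = pdl1)
}

#' Generate a synthetic expression panel
#'
#' Per gene and sample, true log2 expression is
#' `baseline + (sum of archetype effects over sets containing the gene)
#' + N(0, noise_sd)`; a per-sample library offset (log2 scale) is then
#' added to every gene and the value exponentiated to a count, so
#' housekeeping normalization has real work to do.
#'
#' @param spec an [expression_spec()].
#' @param archetypes named character vector mapping sample id to
#'   archetype.
#' @param seed integer seed.
#' @return A list with `expr` (raw-count [expression_matrix()]) and
#'   `catalog` (the [gene_set_catalog()] used).
#' @export
generate_expression <- function(spec, archetypes, seed) {
  stopifnot(inherits(spec, "expression_spec"))
  if (is.null(names(archetypes))) {
    names(archetypes) <- sprintf("S%03d", seq_along(archetypes))
  }
  cat <- spec$catalog
  named <- unique(c(unlist(c(cat$cell_types, cat$pathways)), cat$housekeeping))
  n_fill <- spec$n_genes - length(named)
  genes <- c(named, if (n_fill > 0) sprintf("FILLER%03d", seq_len(n_fill)))
  all_sets <- c(cat$cell_types, cat$pathways)

  # per-gene, per-archetype additive effect
  effect <- matrix(0, length(genes), length(archetypes),
                   dimnames = list(genes, names(archetypes)))
  for (arch in unique(archetypes)) {
    eff <- spec$archetype_effects[[arch]]
    if (is.null(eff)) next
    shift <- numeric(length(genes))
    names(shift) <- genes
    for (set_name in names(eff)) {
      members <- intersect(all_sets[[set_name]], genes)
      shift[members] <- shift[members] + eff[[set_name]]
    }
    effect[, archetypes == arch] <- shift
  }

  with_seed(derive_seed(seed, "expression"), {
    offsets <- stats::rnorm(length(archetypes), 0, spec$offset_sd)
    noise <- matrix(stats::rnorm(length(genes) * length(archetypes),
                                 0, spec$noise_sd),
                    length(genes), length(archetypes))
  })
  log2_true <- spec$baseline_log2 + effect + noise
  counts <- round(2^sweep(log2_true, 2, offsets, `+`))
  list(
    expr = expression_matrix(counts, log2_scale = FALSE),
    catalog = cat
  )
}

#' Generate survival outcomes under proportional hazards
#'
#' Event times are exponential with hazard
#' `(log 2 / baseline_median) * exp(sum beta_j x_j)`; observed time is the
#' minimum of the event time, the administrative cutoff, and (when
#' enabled) an exponential random-censoring time.
#'
#' @param spec a [survival_spec()].
#' @param covariates `data.frame` with a `patient_id` column and numeric
#'   columns for every name in `spec$covariate_log_hazards`.
#' @param seed integer seed.
#' @return A `data.frame` (`survival_table`) with `patient_id,
#'   time_months, event` followed by the covariate columns.
#' @export
generate_survival <- function(spec, covariates, seed) {
  stopifnot(inherits(spec, "survival_spec"), is.data.frame(covariates))
  beta <- spec$covariate_log_hazards
  missing_cov <- setdiff(names(beta), names(covariates))
  if (length(missing_cov)) {
    stop_spec("unknown covariate(s) in covariate_log_hazards: ",
              paste(missing_cov, collapse = ", "))
  }
  n <- nrow(covariates)
  lp <- rep(0, n)
  for (nm in names(beta)) {
    x <- covariates[[nm]]
    if (!is.numeric(x)) stop_spec("covariate '", nm, "' must be numeric")
    lp <- lp + beta[[nm]] * x
  }
  h0 <- log(2) / spec$baseline_median_months
  with_seed(derive_seed(seed, "survival"), {
    t_event <- stats::rexp(n, h0 * exp(lp))
    t_cens <- if (spec$censor_random_rate > 0) {
      pmin(spec$censor_admin_months, stats::rexp(n, spec$censor_random_rate))
    } else {
      rep(spec$censor_admin_months, n)
    }
  })
  out <- data.frame(
    patient_id = covariates$patient_id %||% sprintf("P%03d", seq_len(n)),
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
  cov_cols <- setdiff(names(covariates), c("patient_id"))
  out[cov_cols] <- covariates[cov_cols]
  class(out) <- c("survival_table", "data.frame")
  out
}
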