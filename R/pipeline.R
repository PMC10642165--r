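#' Assemble a pipeline run configuration
#'
#' Fills defaults for every knob of an end-to-end run. The analysis
#' constants default to the conventional values used throughout the
#' package: distance bands 50/100/150 um, cell-ratio cutoff 1, PD-L1
#' cutoff 1%, differential-expression thresholds |log2FC| > 1.5 and
#' BH-adjusted p < 0.05, and a 24-month long-term survivor split.
#'
#' @param config named list of overrides, or a path to a YAML file with
#'   the same structure.
#' @return A `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_spec("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    out_dir = "tmectx_run",
    seed = 1L,
    cohort = list(n_patients = 20),
    tissue = list(field_width_um = 1200, field_height_um = 1200,
                  um_per_pixel = 10,
                  tumour_geometry = list(shape = "disc", radius_um = 400)),
    survival = list(baseline_median_months = 25,
                    covariate_log_hazards = c(inflamed = log(0.45))),
    thresholds = list(distance_bands = c(50, 100, 150),
                      ratio_cutoff = 1,
                      pdl1_cutoff_percent = 1,
                      dge_lfc = 1.5, dge_alpha = 0.05,
                      survivor_split_months = 24),
    denominator = "zone",
    p_method = "approx",
    n_perm = 999
  )
  cfg <- utils::modifyList(defaults, config)
  thr <- unlist(cfg$thresholds)
  if (any(thr <= 0)) stop_spec("all thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

stage_error <- function(stage, e) {
  stop_data("[", stage, "] ", conditionMessage(e))
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Stages run in order: `simulate` (cohort, tissue fields, expression
#' panel, outcomes), `spatial` (densities, margin profiles, PD-L1),
#' `expression` (normalization, scores, clustering, differential
#' expression), `survival` (maxstat dichotomization, Kaplan-Meier,
#' log-rank, Cox), `report` (cohort summary and provenance manifest).
#' Later stages read only the files earlier stages wrote, so any stage
#' can be rerun on a prior run directory. All randomness derives from
#' the config seed; rerunning with the same config reproduces every
#' output.
#'
#' @param config a [run_config()], override list, or YAML path.
#' @param stages subset of stages to run (in pipeline order).
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "spatial", "expression",
                                    "survival", "report")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in stages) {
    message("-- stage: ", stage)
    fn <- switch(stage,
                 simulate = stage_simulate, spatial = stage_spatial,
                 expression = stage_expression, survival = stage_survival,
                 report = stage_report)
    tryCatch(fn(cfg), error = function(e) stage_error(stage, e))
  }
  invisible(cfg$out_dir)
}

run_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

stage_simulate <- function(cfg) {
  cs <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  clinical <- generate_cohort(cs)
  utils::write.csv(clinical, run_path(cfg, "clinical.csv"), row.names = FALSE)

  ts <- do.call(tissue_spec, cfg$tissue)
  for (i in seq_len(nrow(clinical))) {
    pid <- clinical$patient_id[i]
    tis <- generate_tissue(ts, clinical$archetype[i],
                           derive_seed(cfg$seed, "tissue", pid))
    write_cells_csv(tis$cells, run_path(cfg, paste0("cells_", pid, ".csv")))
    write_mask_tiff(tis$mask, run_path(cfg, paste0("mask_", pid, ".tiff")))
    tiff::writeTIFF((tis$pdl1 * 1) / 255,
                    run_path(cfg, paste0("pdl1_", pid, ".tiff")),
                    bits.per.sample = 8L)
  }

  es <- do.call(expression_spec, cfg$expression %||% list())
  archetypes <- stats::setNames(clinical$archetype, clinical$patient_id)
  gen <- generate_expression(es, archetypes, derive_seed(cfg$seed, "expr"))
  write_expression_csv(gen$expr, run_path(cfg, "expression.csv"))
  write_catalog_json(gen$catalog, run_path(cfg, "catalog.json"))

  ss <- do.call(survival_spec, cfg$survival)
  covs <- data.frame(patient_id = clinical$patient_id,
                     inflamed = as.numeric(clinical$archetype == "inflamed"))
  surv <- generate_survival(ss, covs, derive_seed(cfg$seed, "surv"))
  utils::write.csv(surv, run_path(cfg, "survival.csv"), row.names = FALSE)
  invisible(cfg)
}

stage_spatial <- function(cfg) {
  clinical <- utils::read.csv(run_path(cfg, "clinical.csv"))
  bands <- cfg$thresholds$distance_bands
  dens_all <- list(); prof_all <- list(); pdl1_all <- list()
  for (pid in clinical$patient_id) {
    mask_path <- run_path(cfg, paste0("mask_", pid, ".tiff"))
    if (!file.exists(mask_path)) stop_data("missing mask file for patient ", pid)
    mask <- read_mask(mask_path)
    cells <- read_cells_csv(run_path(cfg, paste0("cells_", pid, ".csv")))
    dens <- compute_density(cells, mask)
    dens$sample <- pid
    dens_all[[pid]] <- dens
    border <- extract_infiltrative_border(mask)
    if (nrow(border) > 0 && any(cells$compartment == "tumour")) {
      depths <- distance_to_border(cells, border, mask)
      prof <- margin_profile(cells, depths, bands, cfg$denominator)
      prof$sample <- pid
      prof_all[[pid]] <- prof
    }
    pdl1_img <- round(tiff::readTIFF(run_path(cfg, paste0("pdl1_", pid, ".tiff"))) * 255) > 0
    pdl1_all[[pid]] <- data.frame(
      sample = pid,
      compartment = c("tumour", "stroma"),
      pdl1_percent = c(pdl1_area_positivity(pdl1_img, mask, "tumour"),
                       pdl1_area_positivity(pdl1_img, mask, "stroma"))
    )
  }
  utils::write.csv(do.call(rbind, dens_all), run_path(cfg, "density.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, prof_all), run_path(cfg, "margin_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, pdl1_all), run_path(cfg, "pdl1.csv"),
                   row.names = FALSE)
  invisible(cfg)
}

stage_expression <- function(cfg) {
  expr <- read_expression_csv(run_path(cfg, "expression.csv"))
  catalog <- read_catalog_json(run_path(cfg, "catalog.json"))
  clinical <- utils::read.csv(run_path(cfg, "clinical.csv"))
  norm <- normalize_expression(expr, catalog$housekeeping)
  scores <- score_cell_types(norm, catalog)
  pscores <- pathway_scores(norm, catalog)
  utils::write.csv(
    data.frame(sample = rownames(scores), scores, pscores, check.names = FALSE),
    run_path(cfg, "scores.csv"), row.names = FALSE)
  cl <- cluster_immune_phenotypes(scores, k = 3)
  utils::write.csv(
    data.frame(sample = names(cl$labels), cluster = cl$labels),
    run_path(cfg, "clusters.csv"), row.names = FALSE)
  grp_a <- clinical$patient_id[clinical$mpr == 1]
  grp_b <- clinical$patient_id[clinical$mpr == 0]
  if (length(grp_a) >= 2 && length(grp_b) >= 2) {
    dge <- differential_expression(norm, grp_a, grp_b,
                                   cfg$thresholds$dge_lfc,
                                   cfg$thresholds$dge_alpha)
    utils::write.csv(dge, run_path(cfg, "dge.csv"), row.names = FALSE)
  } else {
    message("skipping differential expression: an MPR group has < 2 samples")
  }
  invisible(cfg)
}

stage_survival <- function(cfg) {
  surv <- utils::read.csv(run_path(cfg, "survival.csv"))
  dens <- utils::read.csv(run_path(cfg, "density.csv"))
  cd8 <- dens[dens$compartment == "tumour" & dens$phenotype == "CD8", ]
  cd8_density <- stats::setNames(cd8$density_cells_per_mm2, cd8$sample)
  x <- cd8_density[surv$patient_id]
  dic <- maxstat_dichotomize(surv$time_months, surv$event, x,
                             p_method = cfg$p_method, n_perm = cfg$n_perm)
  utils::write.csv(
    data.frame(patient_id = surv$patient_id,
               covariate = "CD8_tumour_density",
               value = unname(x), label = dic$labels,
               cutpoint = dic$cutpoint, statistic = dic$statistic,
               p = dic$p, p_method = dic$p_method),
    run_path(cfg, "dichotomies.csv"), row.names = FALSE)
  fit <- cox_univariate(surv$time_months, surv$event,
                        as.numeric(dic$labels == "high"))
  utils::write.csv(
    data.frame(covariate = "CD8_tumour_density_high",
               beta = fit$beta, se = fit$se, hr = fit$hr,
               ci_low = fit$ci_low, ci_high = fit$ci_high, p = fit$p,
               converged = fit$converged, n = fit$n, n_event = fit$n_event),
    run_path(cfg, "cox.csv"), row.names = FALSE)
  lr <- logrank_test(surv$time_months, surv$event, dic$labels)
  utils::write.csv(
    data.frame(test = lr$method, statistic = lr$statistic, df = lr$df,
               p = lr$p, n = lr$n),
    run_path(cfg, "tests.csv"), row.names = FALSE)
  for (grp in c("high", "low")) {
    sel <- dic$labels == grp
    utils::write.csv(km_estimate(surv$time_months[sel], surv$event[sel]),
                     run_path(cfg, paste0("km_", grp, ".csv")),
                     row.names = FALSE)
  }
  invisible(cfg)
}

stage_report <- function(cfg) {
  clinical <- utils::read.csv(run_path(cfg, "clinical.csv"))
  surv_path <- run_path(cfg, "survival.csv")
  surv <- if (file.exists(surv_path)) utils::read.csv(surv_path) else NULL
  summ <- cohort_summary(clinical, surv)
  jsonlite::write_json(unclass(summ), run_path(cfg, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "tmectx",
    version = as.character(utils::packageVersion("tmectx")),
    generated = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    denominator_convention = cfg$denominator,
    p_method = cfg$p_method,
    thresholds = cfg$thresholds,
    config = cfg[setdiff(names(cfg), "out_dir")]
  )
  jsonlite::write_json(manifest, run_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(cfg)
}

#' Cohort summary table
#'
#' Counts and percentages for treatment arm, MPR, nodal status and
#' residual-tumour availability, plus survival medians when outcomes are
#' supplied. Percentages are rounded half-up at each field's conventional
#' printed precision: one decimal for arm splits and sample availability,
#' integers for MPR and N0 rates.
#'
#' @param clinical `data.frame` with columns `patient_id, arm, mpr,
#'   n_stage, has_post_sample`.
#' @param survival optional `data.frame` with `time_months` and `event`.
#' @return A `cohort_summary` list of named counts, percentages and
#'   medians.
#' @export
cohort_summary <- function(clinical, survival = NULL) {
  if (is.null(clinical) || nrow(clinical) == 0) stop_data("empty clinical table")
  need <- c("patient_id", "arm", "mpr", "n_stage", "has_post_sample")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop_data("clinical table lacks: ", paste(miss, collapse = ", "))
  n <- nrow(clinical)
  n_ncrt <- sum(clinical$arm == "nCRT")
  n_nct <- sum(clinical$arm == "nCT")
  n_mpr <- sum(clinical$mpr == 1)
  n_n0 <- sum(clinical$n_stage == "N0")
  n_post <- sum(clinical$has_post_sample == 1)
  post <- clinical[clinical$has_post_sample == 1, , drop = FALSE]
  out <- list(
    n_patients = n,
    n_ncrt = n_ncrt, pct_ncrt = percent_of(n_ncrt, n, 1),
    n_nct = n_nct, pct_nct = percent_of(n_nct, n, 1),
    n_mpr = n_mpr, pct_mpr = percent_of(n_mpr, n, 0),
    n_n0 = n_n0, pct_n0 = percent_of(n_n0, n, 0),
    n_post_sample = n_post, pct_post_sample = percent_of(n_post, n, 1),
    n_post_ncrt = sum(post$arm == "nCRT"),
    pct_post_ncrt = if (n_post > 0) percent_of(sum(post$arm == "nCRT"), n_post, 1) else NA,
    n_post_nct = sum(post$arm == "nCT"),
    pct_post_nct = if (n_post > 0) percent_of(sum(post$arm == "nCT"), n_post, 1) else NA
  )
  if (!is.null(survival)) {
    out$median_os_months <- km_median(survival$time_months, survival$event)
    survivors <- survival$event == 0
    out$median_followup_months <- if (any(survivors)) {
      stats::median(survival$time_months[survivors])
    } else NA_real_
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n_patients))
  cat(sprintf("  nCRT            %d/%d (%.1f%%)\n", x$n_ncrt, x$n_patients, x$pct_ncrt))
  cat(sprintf("  nCT             %d/%d (%.1f%%)\n", x$n_nct, x$n_patients, x$pct_nct))
  cat(sprintf("  MPR             %d/%d (%d%%)\n", x$n_mpr, x$n_patients, x$pct_mpr))
  cat(sprintf("  N0              %d/%d (%d%%)\n", x$n_n0, x$n_patients, x$pct_n0))
  cat(sprintf("  residual tumour %d/%d (%.1f%%)\n",
              x$n_post_sample, x$n_patients, x$pct_post_sample))
  if (!is.null(x$median_os_months)) {
    cat(sprintf("  median OS %.1f months; median follow-up (survivors) %.1f months\n",
                x$median_os_months, x$median_followup_months))
  }
  invisible(x)
}
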