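#' Expression matrix container
#'
#' A genes x samples numeric matrix tagged with whether its values are on
#' the log2 scale (normalized) or raw counts. Gene and sample ids must be
#' unique; values must be finite.
#'
#' @param x numeric matrix, genes in rows, samples in columns, both
#'   dimnames set.
#' @param log2_scale `TRUE` for normalized log2 values, `FALSE` for raw
#'   counts.
#' @return The matrix with class `expression_matrix` and a `log2_scale`
#'   attribute.
#' @export
expression_matrix <- function(x, log2_scale = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop_spec("x must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_spec("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop_spec("gene and sample ids must be unique")
  }
  if (!all(is.finite(x))) stop_spec("expression values must be finite")
  structure(x, log2_scale = isTRUE(log2_scale),
            class = c("expression_matrix", class(matrix())))
}

is_log2 <- function(x) isTRUE(attr(x, "log2_scale"))

#' Marker gene-set catalog
#'
#' Named gene lists for cell types and pathways plus the housekeeping
#' genes used for normalization. The package ships a synthetic stand-in
#' catalog built from widely used lineage markers
#' (`inst/extdata/synthetic_immune_catalog.json`); any catalog with the
#' same JSON layout (`{"cell_types": {...}, "pathways": {...},
#' "housekeeping": [...]}`) can be supplied instead.
#'
#' @param cell_types named list of character vectors.
#' @param pathways named list of character vectors.
#' @param housekeeping character vector of housekeeping gene ids.
#' @return A `gene_set_catalog` list.
#' @export
gene_set_catalog <- function(cell_types, pathways = list(), housekeeping) {
  sets <- c(cell_types, pathways)
  if (any(!nzchar(names(sets))) || is.null(names(sets))) {
    stop_spec("every gene set must be named")
  }
  if (any(lengths(sets) == 0)) stop_spec("gene sets must be non-empty")
  structure(list(
    cell_types = lapply(cell_types, as.character),
    pathways = lapply(pathways, as.character),
    housekeeping = as.character(housekeeping)
  ), class = "gene_set_catalog")
}

#' @rdname gene_set_catalog
#' @param path JSON catalog path.
#' @export
read_catalog_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_set_catalog(js$cell_types, js$pathways %||% list(), js$housekeeping)
}

#' @rdname gene_set_catalog
#' @param catalog a `gene_set_catalog`.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(unclass(catalog), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname gene_set_catalog
#' @export
default_gene_catalog <- function() {
  read_catalog_json(system.file("extdata", "synthetic_immune_catalog.json",
                                package = "tmectx", mustWork = TRUE))
}

#' Housekeeping geometric-mean normalization
#'
#' Each sample is rescaled so its housekeeping geometric mean matches the
#' grand geometric mean of housekeeping counts across all samples
#' (`scale = grand_geomean / sample_geomean`), then values are put on the
#' log2 scale as `log2(scaled count + 1)`. Housekeeping genes with a zero
#' count in any sample are dropped from the factor with a warning (the
#' geometric mean would collapse); if all are dropped, normalization
#' fails.
#'
#' @param expr raw-count [expression_matrix()].
#' @param housekeeping housekeeping gene ids (all present in `expr`).
#' @return A log2-scale [expression_matrix()] with attribute
#'   `scale_factors`.
#' @export
normalize_expression <- function(expr, housekeeping) {
  if (is_log2(expr)) {
    warning("matrix already log2-normalized; returning unchanged")
    return(expr)
  }
  if (any(expr < 0)) stop_spec("raw counts must be non-negative")
  missing_hk <- setdiff(housekeeping, rownames(expr))
  if (length(missing_hk)) {
    stop_spec("housekeeping gene(s) absent from matrix: ",
              paste(missing_hk, collapse = ", "))
  }
  hk <- expr[housekeeping, , drop = FALSE]
  zero <- rowSums(hk == 0) > 0
  if (any(zero)) {
    warning(sum(zero), " housekeeping gene(s) with zero counts dropped ",
            "from the scale factor: ",
            paste(housekeeping[zero], collapse = ", "))
    hk <- hk[!zero, , drop = FALSE]
  }
  if (nrow(hk) == 0) stop_data("no usable housekeeping genes (all have zeros)")
  sample_geo <- exp(colMeans(log(hk)))
  grand_geo <- exp(mean(log(hk)))
  sf <- grand_geo / sample_geo
  out <- log2(sweep(unclass(expr), 2, sf, `*`) + 1)
  res <- expression_matrix(out, log2_scale = TRUE)
  attr(res, "scale_factors") <- sf
  res
}

# Mean log2 expression of each set's member genes, per sample.
score_sets <- function(expr, sets) {
  if (!is_log2(expr)) stop_spec("scores require a log2-normalized matrix")
  out <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  for (nm in names(sets)) {
    present <- intersect(sets[[nm]], rownames(expr))
    missing <- setdiff(sets[[nm]], rownames(expr))
    if (length(missing)) {
      warning("set '", nm, "': ", length(missing), " gene(s) not in matrix")
    }
    if (length(present) == 0) next # score stays missing
    out[, nm] <- colMeans(expr[present, , drop = FALSE])
  }
  out
}

#' Cell-type scores from marker sets
#'
#' The score of a set in a sample is the mean log2 expression of its
#' member genes; a single-gene set's score is that gene's value. Missing
#' genes are excluded with a warning; a set with no present genes scores
#' `NA`.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param catalog a [gene_set_catalog()].
#' @return Samples x sets numeric matrix of scores.
#' @export
score_cell_types <- function(expr, catalog) {
  score_sets(expr, catalog$cell_types)
}

#' @rdname score_cell_types
#' @export
pathway_scores <- function(expr, catalog) {
  score_sets(expr, catalog$pathways)
}

#' Relative score of two sets
#'
#' On the log2 scale the difference of two mean-marker scores corresponds
#' to the (log) ratio of the underlying abundances, e.g. B cells relative
#' to total TILs. Antisymmetric under swapping the sets.
#'
#' @param scores samples x sets score matrix.
#' @param set_a,set_b set names.
#' @return Numeric vector `scores[, set_a] - scores[, set_b]`.
#' @export
relative_score <- function(scores, set_a, set_b) {
  if (!all(c(set_a, set_b) %in% colnames(scores))) {
    stop_spec("both sets must be present in the score matrix")
  }
  scores[, set_a] - scores[, set_b]
}

#' Cluster samples into immune phenotypes
#'
#' Scores are z-scored across samples, samples clustered by agglomerative
#' hierarchical clustering (Ward linkage on Euclidean distance) and the
#' tree cut at `k`. For `k = 3`, clusters are named from their centroid
#' profiles: the cluster with the highest mean anti-tumour score
#' (CD8/T/B/NK/Th1 sets) is `inflamed`; of the rest, the one with the
#' higher myeloid/Treg score (macrophage/neutrophil/Treg sets) is
#' `myeloid_treg`; the remainder is `desert`. For other `k`, clusters are
#' labelled `cluster1..k` in dendrogram order. Fully deterministic.
#'
#' @param scores samples x sets score matrix (missing values mean-imputed
#'   with a warning).
#' @param k number of clusters.
#' @return A list with `labels` (named character vector), `hclust` (the
#'   dendrogram), `centroids` (clusters x sets mean z-scores, so users can
#'   audit or rename), and `k`.
#' @export
cluster_immune_phenotypes <- function(scores, k = 3) {
  if (k < 1 || k > nrow(scores)) stop_spec("k must be in [1, n samples]")
  if (anyNA(scores)) {
    warning("missing scores mean-imputed before clustering")
    for (j in seq_len(ncol(scores))) {
      miss <- is.na(scores[, j])
      scores[miss, j] <- mean(scores[, j], na.rm = TRUE)
    }
  }
  z <- scale(scores)
  z[, attr(z, "scaled:scale") == 0] <- 0 # constant columns carry no signal
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cut <- stats::cutree(hc, k = k)
  centroids <- t(vapply(seq_len(k), function(cl) {
    colMeans(z[cut == cl, , drop = FALSE])
  }, numeric(ncol(z))))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  labels <- paste0("cluster", cut)
  if (k == 3) {
    anti <- c("CD8_T", "T_cells", "B_cells", "NK", "Th1")
    myeloid <- c("macrophages", "neutrophils", "Treg")
    anti_score <- rowMeans(centroids[, intersect(anti, colnames(centroids)),
                                     drop = FALSE])
    myel_score <- rowMeans(centroids[, intersect(myeloid, colnames(centroids)),
                                     drop = FALSE])
    inflamed <- which.max(anti_score)
    rest <- setdiff(1:3, inflamed)
    myeloid_treg <- rest[which.max(myel_score[rest])]
    desert <- setdiff(rest, myeloid_treg)
    name_map <- character(3)
    name_map[c(inflamed, myeloid_treg, desert)] <-
      c("inflamed", "myeloid_treg", "desert")
    labels <- name_map[cut]
    rownames(centroids) <- name_map
  }
  names(labels) <- rownames(scores)
  list(labels = labels, hclust = hc, centroids = centroids, k = k)
}

#' Differential expression between two sample groups
#'
#' Per gene: Welch's two-sample t-test on log2 values, log2 fold change as
#' the difference of group means (A minus B), Benjamini-Hochberg
#' adjustment across all tested genes. A gene is significant when
#' `|log2FC| > lfc_cutoff` and adjusted p < `alpha`.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param group_a,group_b sample ids of the two groups (each >= 2).
#' @param lfc_cutoff absolute log2 fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return A `data.frame` with `gene, log2fc, t, df, p, p_adj,
#'   significant`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    lfc_cutoff = 1.5, alpha = 0.05) {
  if (!is_log2(expr)) stop_spec("differential expression requires log2 values")
  bad <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(bad)) stop_spec("unknown sample(s): ", paste(bad, collapse = ", "))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_spec("each group needs at least 2 samples")
  }
  a <- unclass(expr)[, group_a, drop = FALSE]
  b <- unclass(expr)[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1 # constant gene in both groups: no evidence
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene = rownames(expr),
    log2fc = ma - mb,
    t = tstat, df = df, p = p, p_adj = p_adj,
    significant = abs(ma - mb) > lfc_cutoff & p_adj < alpha,
    row.names = NULL
  )
}

#' @rdname read_cells_csv
#' @param expr an [expression_matrix()].
#' @param log2_scale scale flag recorded in the header comment.
#' @export
write_expression_csv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), unclass(expr), check.names = FALSE)
  con <- file(path, "w")
  writeLines(paste0("# scale=", if (is_log2(expr)) "log2" else "counts"), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname read_cells_csv
#' @export
read_expression_csv <- function(path) {
  first <- readLines(path, n = 1)
  log2_scale <- grepl("scale=log2", first, fixed = TRUE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, log2_scale = log2_scale)
}
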