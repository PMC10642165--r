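# Shared fixtures: small geometric masks, brute-force oracles, and a
# compact catalog for expression tests.

# A disc of tumour (label 1) in stroma (label 2).
disc_mask <- function(n_px = 60, radius_px = 20, um_per_pixel = 10,
                      centre = c(n_px / 2, n_px / 2)) {
  d2 <- outer((seq_len(n_px) - centre[1])^2, (seq_len(n_px) - centre[2])^2, `+`)
  lab <- matrix(2L, n_px, n_px)
  lab[d2 <= radius_px^2] <- 1L
  region_mask(lab, um_per_pixel)
}

# Exhaustive nearest-border-point oracle: distance (um) from each cell's
# coordinates to the closest border pixel centre.
brute_force_depth <- function(cells, border) {
  vapply(seq_len(nrow(cells)), function(i) {
    sqrt(min((cells$x_um[i] - border$x_um)^2 + (cells$y_um[i] - border$y_um)^2))
  }, 0)
}

# Exhaustive maxstat scan: standardize the score sum at every admissible
# cutpoint one at a time, independent of the vectorized implementation.
brute_force_maxstat <- function(time, event, x, minprop = 0.1, maxprop = 0.9) {
  a <- logrank_scores(time, event)
  n <- length(x)
  abar <- mean(a)
  ssq <- sum((a - abar)^2)
  vals <- sort(unique(x))
  best <- -Inf
  best_cut <- NA_real_
  for (i in seq_len(length(vals) - 1)) {
    cut <- (vals[i] + vals[i + 1]) / 2
    m <- sum(x <= cut)
    if (m / n < minprop || m / n > maxprop) next
    s <- sum(a[x <= cut])
    z <- abs((s - m * abar) / sqrt(m * (n - m) / (n * (n - 1)) * ssq))
    if (z > best + 1e-12) {
      best <- z
      best_cut <- cut
    }
  }
  list(statistic = best, cutpoint = best_cut)
}

# Tiny two-set catalog used where the full panel is overkill.
mini_catalog <- function() {
  gene_set_catalog(
    cell_types = list(A = c("a1", "a2", "a3"), B = c("b1", "b2")),
    pathways = list(P = c("p1", "p2")),
    housekeeping = c("hk1", "hk2", "hk3")
  )
}

rand_counts <- function(genes, samples, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(length(genes) * length(samples), 200),
              length(genes), length(samples),
              dimnames = list(genes, samples))
  expression_matrix(m, log2_scale = FALSE)
}

# Clinical table with exact margins for cohort-summary checks.
clinical_with_margins <- function(n, n_ncrt, n_mpr, n_n0, n_post,
                                  n_post_ncrt = NULL) {
  arm <- rep("nCT", n)
  has_post <- c(rep(1L, n_post), rep(0L, n - n_post))
  if (is.null(n_post_ncrt)) {
    arm[seq_len(n_ncrt)] <- "nCRT"
  } else {
    # place the requested number of nCRT patients inside the post subset
    arm[seq_len(n_post_ncrt)] <- "nCRT"
    arm[n_post + seq_len(n_ncrt - n_post_ncrt)] <- "nCRT"
  }
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    arm = arm,
    archetype = "inflamed",
    mpr = c(rep(1L, n_mpr), rep(0L, n - n_mpr)),
    n_stage = c(rep("N0", n_n0), rep("N+", n - n_n0)),
    has_post_sample = has_post,
    stringsAsFactors = FALSE
  )
}
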