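#' Kaplan-Meier product-limit estimate
#'
#' @param time event/censoring times in months (> 0).
#' @param event 1 = event, 0 = censored.
#' @return A `data.frame` with one row per distinct observed time:
#'   `time, n_risk, n_event, n_censor, surv`; `surv` starts from
#'   `S(0) = 1` and is non-increasing and right-continuous.
#' @export
km_estimate <- function(time, event) {
  check_survival_args(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
}

#' Median survival from a Kaplan-Meier fit
#'
#' Smallest observed time at which the survival curve reaches 0.5 or
#' below; `NA` when the curve never does.
#'
#' @inheritParams km_estimate
#' @return Median survival time (months).
#' @export
km_median <- function(time, event) {
  km <- km_estimate(time, event)
  hit <- which(km$surv <= 0.5)
  if (length(hit) == 0) NA_real_ else km$time[hit[1]]
}

#' Log-rank test across groups
#'
#' Standard (O-E)^2/V chi-square statistic with `groups - 1` degrees of
#' freedom; for two groups it is the square of the standardized log-rank
#' Z.
#'
#' @inheritParams km_estimate
#' @param group group membership (>= 2 non-empty groups).
#' @return A `tme_test` list: `statistic, df, p, method, n`.
#' @export
logrank_test <- function(time, event, group) {
  check_survival_args(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop_data("log-rank needs >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  tme_test(sd$chisq, df, stats::pchisq(sd$chisq, df, lower.tail = FALSE),
           "log-rank", length(time))
}

tme_test <- function(statistic, df, p, method, n) {
  structure(list(statistic = unname(statistic), df = df, p = unname(p),
                 method = method, n = n),
            class = "tme_test")
}

#' @export
print.tme_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %d)\n",
              x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p, x$n))
  invisible(x)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling (Newton-Raphson,
#' tolerance 1e-9, at most 50 iterations). Monotone likelihood (perfect
#' separation) is flagged as non-converged together with the sign of the
#' drift.
#'
#' @inheritParams km_estimate
#' @param covariate numeric (or two-level) covariate; must vary.
#' @return A `cox_fit` list: `beta, se, hr, ci_low, ci_high, p,
#'   converged, n, n_event`.
#' @export
cox_univariate <- function(time, event, covariate) {
  check_survival_args(time, event)
  if (is.character(covariate) || is.factor(covariate)) {
    covariate <- as.factor(covariate)
    if (nlevels(droplevels(covariate)) != 2) {
      stop_spec("categorical covariates must have exactly 2 levels")
    }
    covariate <- as.numeric(covariate) - 1
  }
  if (length(unique(covariate[!is.na(covariate)])) < 2) {
    stop_data("covariate is constant")
  }
  if (sum(event) < 1) stop_data("no events")
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  v <- fit$var[1, 1]
  se <- if (is.finite(v) && v >= 0) unname(sqrt(v)) else NA_real_
  converged <- !warned && is.finite(beta) && abs(beta) < 15
  structure(list(
    beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged,
    drift = if (!converged) sign(beta) else 0,
    n = fit$n, n_event = fit$nevent
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d (%d events)%s\n",
              x$hr, x$ci_low, x$ci_high, x$p, x$n, x$n_event,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Log-rank (Savage) scores
#'
#' Per-subject scores `a_i = event_i - NelsonAalen(t_i)`; the two-group
#' log-rank statistic is a linear rank statistic in these scores, which
#' is what the maximally selected rank statistic scans over.
#'
#' @inheritParams km_estimate
#' @return Numeric vector of scores, one per subject.
#' @export
logrank_scores <- function(time, event) {
  check_survival_args(time, event)
  ord <- order(time)
  t_sorted <- time[ord]
  e_sorted <- event[ord]
  n <- length(time)
  dist_t <- unique(t_sorted[e_sorted == 1])
  cumhaz_at <- function(t) {
    h <- 0
    for (dt in dist_t) {
      if (dt > t) break
      h <- h + sum(t_sorted == dt & e_sorted == 1) / sum(t_sorted >= dt)
    }
    h
  }
  event - vapply(time, cumhaz_at, 0)
}

#' Dichotomize a covariate by maximally selected rank statistics
#'
#' Candidate cutpoints are the midpoints between consecutive distinct
#' covariate values whose split keeps both groups within
#' `[minprop, maxprop]` of the sample. At each candidate the standardized
#' two-group log-rank statistic `|Z|` is computed from the log-rank
#' scores; the selected cutpoint maximizes `|Z|` (smallest cutpoint on
#' ties). The p-value for the maximum is computed either by permutation
#' of the covariate (default, 9999 permutations, exact exchangeability
#' null) or by the Brownian-bridge crossing approximation of
#' Miller-Siegmund/Lausen-Schumacher type (`"approx"`, fast, slightly
#' conservative near the proportion bounds); the method used is recorded.
#'
#' @inheritParams km_estimate
#' @param covariate numeric covariate to split (>= 10 non-missing values).
#' @param minprop,maxprop admissible range for the low-group proportion.
#' @param p_method `"permutation"`, `"approx"`, or `"none"`.
#' @param n_perm permutations for `p_method = "permutation"`.
#' @return A `tme_dichotomy` list: `covariate` (deparsed name),
#'   `cutpoint`, `statistic` (max |Z|), `p`, `p_method`, `labels`
#'   (`high` above the cutpoint / `low` at or below), `minprop`,
#'   `maxprop`, `n`, and the scanned `candidates` table.
#' @export
maxstat_dichotomize <- function(time, event, covariate,
                                minprop = 0.1, maxprop = 0.9,
                                p_method = c("permutation", "approx", "none"),
                                n_perm = 9999) {
  p_method <- match.arg(p_method)
  keep <- !is.na(covariate)
  if (sum(keep) < 10) stop_data("need >= 10 non-missing covariate values")
  time <- time[keep]; event <- event[keep]
  x <- covariate[keep]
  check_survival_args(time, event)
  if (sum(event) < 1) stop_data("no events")

  a <- logrank_scores(time, event)
  scan <- maxstat_scan(x, a, minprop, maxprop)
  if (nrow(scan$candidates) == 0) stop_data("degenerate covariate: no admissible cutpoint")
  best <- which.max(scan$candidates$abs_z)
  # ties: smallest maximizing cutpoint
  best <- which(scan$candidates$abs_z == scan$candidates$abs_z[best])[1]
  m_stat <- scan$candidates$abs_z[best]
  cut <- scan$candidates$cutpoint[best]

  p <- switch(p_method,
    none = NA_real_,
    approx = maxstat_p_approx(m_stat, scan$candidates$prop_low),
    permutation = {
      n <- length(a)
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        mb <- maxstat_scan_stat(sample(a), scan)
        if (mb >= m_stat) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    }
  )
  labels <- rep(NA_character_, length(keep))
  labels[keep] <- ifelse(x > cut, "high", "low")
  structure(list(
    covariate = deparse(substitute(covariate)),
    cutpoint = cut, statistic = m_stat, p = p, p_method = p_method,
    labels = labels, minprop = minprop, maxprop = maxprop,
    n = length(x), candidates = scan$candidates
  ), class = "tme_dichotomy")
}

# Precompute the scan layout: sort order, admissible split positions and
# cutpoints, and the standardized statistic for the observed scores.
maxstat_scan <- function(x, a, minprop, maxprop) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  m <- seq_len(n - 1)
  admissible <- (xs[m] != xs[m + 1]) & (m / n >= minprop) & (m / n <= maxprop)
  pos <- m[admissible]
  abar <- mean(a)
  ssq <- sum((a - abar)^2)
  var_m <- pos * (n - pos) / (n * (n - 1)) * ssq
  csum <- cumsum(a[ord])
  z <- (csum[pos] - pos * abar) / sqrt(var_m)
  list(
    ord = ord, pos = pos, abar = abar, n = n,
    sd_m = sqrt(var_m),
    candidates = data.frame(
      cutpoint = (xs[pos] + xs[pos + 1]) / 2,
      prop_low = pos / n, z = z, abs_z = abs(z)
    )
  )
}

# Max |Z| for a permuted score vector on a precomputed scan layout.
maxstat_scan_stat <- function(a_perm, scan) {
  csum <- cumsum(a_perm)
  max(abs((csum[scan$pos] - scan$pos * mean(a_perm)) / scan$sd_m))
}

# Brownian-bridge crossing approximation for P(max |Z| > b) over the
# proportion window [t0, t1] (Miller & Siegmund 1982 form).
maxstat_p_approx <- function(b, props) {
  t0 <- min(props); t1 <- max(props)
  p <- stats::dnorm(b) * (b - 1 / b) *
    log((t1 * (1 - t0)) / (t0 * (1 - t1))) + 4 * stats::dnorm(b) / b
  # the single-cutpoint two-sided tail is a lower bound; cap at 1
  min(1, max(p, 2 * stats::pnorm(-b)))
}

#' @export
print.tme_dichotomy <- function(x, ...) {
  cat(sprintf(
    "Maximally selected rank statistic: cutpoint = %.4g, max |Z| = %.3f, p = %.4g (%s)\n",
    x$cutpoint, x$statistic, x$p, x$p_method))
  cat(sprintf("  n = %d; low-group proportion window [%.2f, %.2f]\n",
              x$n, x$minprop, x$maxprop))
  invisible(x)
}

#' Combine two dichotomies into a four-level co-infiltration group
#'
#' @param labels_a,labels_b per-sample `"high"`/`"low"` labels over the
#'   same samples (same length; same names when named).
#' @return Character vector in
#'   `{high/high, high/low, low/high, low/low}` (`NA` where either input
#'   is missing).
#' @export
combine_dichotomies <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_spec("label vectors must cover the same samples")
  }
  if (!is.null(names(labels_a)) && !is.null(names(labels_b)) &&
      !identical(names(labels_a), names(labels_b))) {
    stop_spec("label vectors are named over different samples")
  }
  ok_a <- is.na(labels_a) | labels_a %in% c("high", "low")
  ok_b <- is.na(labels_b) | labels_b %in% c("high", "low")
  if (!all(ok_a) || !all(ok_b)) stop_spec("labels must be 'high'/'low'/NA")
  ifelse(is.na(labels_a) | is.na(labels_b), NA_character_,
         paste(labels_a, labels_b, sep = "/"))
}

#' Rank and contingency tests
#'
#' Thin, vocabulary-preserving wrappers over the standard tests used for
#' group comparisons: Wilcoxon rank-sum for two independent groups (exact
#' for small untied samples), Wilcoxon signed-rank for paired pre/post
#' comparisons, Kruskal-Wallis for three or more groups, and the
#' chi-square test of independence without continuity correction.
#'
#' @param x,y numeric samples.
#' @param paired `TRUE` selects the signed-rank test on pairs.
#' @return A `tme_test` list.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  n_used <- length(x) + if (paired) 0L else length(y)
  if (paired && all(x == y)) {
    return(tme_test(0, NA, 1, "Wilcoxon signed-rank", n_used))
  }
  if (!paired && length(unique(c(x, y))) == 1) {
    return(tme_test(0, NA, 1, "Wilcoxon rank-sum", n_used))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  tme_test(wt$statistic, NA, wt$p.value,
           if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
           length(x) + if (paired) 0L else length(y))
}

#' @rdname wilcoxon_test
#' @param values numeric values.
#' @param group group labels.
#' @export
kruskal_wallis <- function(values, group) {
  group <- as.factor(group)
  if (length(unique(values)) == 1) {
    return(tme_test(0, nlevels(droplevels(group)) - 1, 1,
                    "Kruskal-Wallis", length(values)))
  }
  kt <- stats::kruskal.test(values, group)
  tme_test(kt$statistic, unname(kt$parameter), kt$p.value,
           "Kruskal-Wallis", length(values))
}

#' @rdname wilcoxon_test
#' @param contingency a two-way table/matrix of counts.
#' @export
chi_square <- function(contingency) {
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  tme_test(ct$statistic, unname(ct$parameter), ct$p.value,
           "chi-square", sum(contingency))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_spec("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Mock subtraction of cytokine positivity
#'
#' Background cytokine positivity measured in the unstimulated (mock)
#' condition is subtracted from the stimulated condition, floored at
#' zero.
#'
#' @param stimulated,mock percentages in `[0, 100]`.
#' @return `pmax(stimulated - mock, 0)`.
#' @export
mock_subtract <- function(stimulated, mock) {
  if (any(stimulated < 0 | stimulated > 100) || any(mock < 0 | mock > 100)) {
    stop_spec("percentages must lie in [0, 100]")
  }
  pmax(stimulated - mock, 0)
}

#' Long-/short-term survivor classification
#'
#' Survival of at least `cutoff` months counts as long-term. Patients
#' censored before the cutoff have unknown status and are excluded
#' (`NA`), avoiding immortal-time artefacts; the caller should report the
#' excluded count.
#'
#' @inheritParams km_estimate
#' @param cutoff months defining long-term survival (default 24).
#' @return Character vector in `{long, short, NA}`.
#' @export
long_term_survivor <- function(time, event, cutoff = 24) {
  check_survival_args(time, event)
  ifelse(time >= cutoff, "long",
         ifelse(event == 1, "short", NA_character_))
}

check_survival_args <- function(time, event) {
  if (length(time) < 1) stop_data("empty survival data")
  if (length(time) != length(event)) stop_spec("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_spec("times must be positive and finite")
  }
  if (!all(event %in% c(0, 1))) stop_spec("event must be 0/1")
  invisible(TRUE)
}
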