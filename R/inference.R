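# Group-level statistics: sign-permutation cluster inference, bootstrap
# latency confidence intervals, FDR maps, latency-difference, peak-mismatch
# and behavior-MEG correlation tests.

#' Inference configuration
#'
#' @param n_perm sign permutations for pointwise/cluster inference.
#' @param cluster_def_p one-sided cluster-definition threshold.
#' @param cluster_quantile quantile of the maximal-cluster-size null a
#'   cluster must exceed to be significant.
#' @param n_boot_latency bootstrap resamples for latency CIs.
#' @param n_boot_behavior bootstrap resamples for behavior-MEG correlations.
#' @param fdr_q FDR level for map-wise tests (0.01 sensorwise, 0.05
#'   temporal generalization).
#' @param chance chance accuracy level in percent.
#' @return object of class `test_config`.
#' @export
test_config <- function(n_perm = 1000, cluster_def_p = 0.05,
                        cluster_quantile = 0.95, n_boot_latency = 1000,
                        n_boot_behavior = 10000, fdr_q = 0.05, chance = 50) {
  stopifnot(n_perm >= 1, n_boot_latency >= 1, n_boot_behavior >= 1,
            cluster_def_p > 0, cluster_def_p < 1,
            cluster_quantile > 0, cluster_quantile < 1)
  structure(list(n_perm = as.integer(n_perm), cluster_def_p = cluster_def_p,
                 cluster_quantile = cluster_quantile,
                 n_boot_latency = as.integer(n_boot_latency),
                 n_boot_behavior = as.integer(n_boot_behavior),
                 fdr_q = fdr_q, chance = chance), class = "test_config")
}

#' Sign-permutation pointwise p-values
#'
#' Tests the group-mean accuracy against chance at every time point.  Each
#' permutation draws one random sign per participant (shared across time
#' points, preserving temporal autocorrelation) and multiplies that
#' participant's chance-centered time course by it.  One-sided p-values use
#' the exact-test convention p = (1 + #\{null >= obs\}) / (1 + n_perm), so
#' the smallest attainable p is 1/(n_perm + 1).
#'
#' @param subject_courses subjects x time matrix of accuracies (%).
#' @param cfg a [test_config()].
#' @param seed integer seed for the sign flips.
#' @return list with `p` (pointwise p per time point), `obs_mean`
#'   (chance-centered group mean), `null_means` (n_perm x T matrix of
#'   permuted group means) and `cfg`.
#' @export
sign_permutation_pvalues <- function(subject_courses, cfg = test_config(),
                                     seed = 1) {
  S <- as.matrix(subject_courses) - cfg$chance
  if (nrow(S) < 2) stopf("need >= 2 subjects")
  if (anyNA(S)) stopf("NaN/NA in subject time courses")
  obs <- colMeans(S)
  flips <- with_seed(child_seed(seed, 601L),
                     matrix(sample(c(-1, 1), cfg$n_perm * nrow(S),
                                   replace = TRUE), cfg$n_perm, nrow(S)))
  null_means <- flips %*% S / nrow(S) # n_perm x T
  ge <- colSums(null_means >= rep(obs, each = cfg$n_perm))
  p <- (1 + ge) / (1 + cfg$n_perm)
  list(p = p, obs_mean = obs, null_means = null_means, cfg = cfg)
}

# maximal runs of TRUE; returns data.frame(start, end, size) in indices
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep], size = r$lengths[keep])
}

#' Cluster-size correction
#'
#' Clusters are maximal contiguous runs of time points with pointwise
#' p below the cluster-definition threshold; the cluster statistic is the
#' run length in time points.  The null distribution is the maximal cluster
#' size of each sign permutation (each permutation's pointwise p-values are
#' computed against the same permutation ensemble); observed clusters
#' exceeding the `cluster_quantile` of that null are significant.
#'
#' @param perm result of [sign_permutation_pvalues()].
#' @param time_ms time axis matching the courses.
#' @param cfg a [test_config()] (defaults to the one stored in `perm`).
#' @param peak_window restrict the peak search to this window, ms.
#' @return object of class `cluster_inference`: list with `pointwise_p`,
#'   `clusters` (data.frame: start_ms, end_ms, size, significant),
#'   `sig_mask`, `onset_ms` (first significant time point, NA if none),
#'   `peak_ms` (argmax of the group mean within `peak_window`),
#'   `cluster_null` and `size_threshold`.
#' @export
cluster_correct <- function(perm, time_ms, cfg = NULL,
                            peak_window = c(0, Inf)) {
  cfg <- cfg %||% perm$cfg
  n_perm <- nrow(perm$null_means)
  Tn <- length(perm$p)
  stopifnot(length(time_ms) == Tn)

  obs_clusters <- runs_of(perm$p < cfg$cluster_def_p)

  # per-permutation p maps from column ranks within the permutation ensemble
  null_max <- numeric(n_perm)
  R <- apply(perm$null_means, 2, function(col) {
    (1 + n_perm - rank(col, ties.method = "min")) / n_perm
  }) # n_perm x T: proportion of permutations >= this one (inclusive)
  thr_mask <- R < cfg$cluster_def_p
  for (b in seq_len(n_perm)) {
    cl <- runs_of(thr_mask[b, ])
    null_max[b] <- if (nrow(cl)) max(cl$size) else 0
  }
  size_thr <- stats::quantile(null_max, cfg$cluster_quantile, names = FALSE,
                              type = 1)
  sig <- obs_clusters$size > size_thr
  mask <- logical(Tn)
  for (i in which(sig)) mask[obs_clusters$start[i]:obs_clusters$end[i]] <- TRUE

  win <- which(time_ms >= peak_window[1] & time_ms <= peak_window[2])
  peak_ms <- if (length(win)) time_ms[win[which.max(perm$obs_mean[win])]] else NA_real_
  onset_ms <- if (any(mask)) time_ms[which(mask)[1]] else NA_real_

  structure(list(
    pointwise_p = perm$p,
    clusters = data.frame(start_ms = time_ms[obs_clusters$start],
                          end_ms = time_ms[obs_clusters$end],
                          size = obs_clusters$size, significant = sig),
    sig_mask = mask, onset_ms = onset_ms, peak_ms = peak_ms,
    cluster_null = null_max, size_threshold = size_thr, cfg = cfg),
    class = "cluster_inference")
}

#' Bootstrap confidence intervals for onset and peak latency
#'
#' Resamples participants with replacement `n_boot_latency` times; for each
#' resample recomputes the group mean, the sign-permutation pointwise
#' p-values and the cluster correction (with a fixed sign-flip ensemble
#' shared across resamples), and records the onset (first significant time
#' point) and the peak (argmax of the resampled group mean within
#' `peak_window`).  CIs are the 2.5/97.5 percentiles of the recorded values.
#' Resamples with no significant cluster contribute no onset; if more than
#' half lack one, the onset CI is reported as undefined (NA).
#'
#' @param subject_courses subjects x time accuracy matrix (%).
#' @param time_ms time axis.
#' @param cfg a [test_config()].
#' @param seed integer seed.
#' @param peak_window peak search window, ms (experiment-2 style analyses
#'   restrict it to the stimulus-on interval, e.g. c(0, 2000)).
#' @return list with `onset_ms`, `onset_ci`, `peak_ms`, `peak_ci`,
#'   `boot_onsets`, `boot_peaks`, `prop_onset_defined` and the full-sample
#'   `inference`.
#' @export
bootstrap_latency_ci <- function(subject_courses, time_ms,
                                 cfg = test_config(), seed = 1,
                                 peak_window = c(0, Inf)) {
  S <- as.matrix(subject_courses)
  N <- nrow(S)
  if (N < 2) stopf("need >= 2 subjects")
  perm <- sign_permutation_pvalues(S, cfg, seed = seed)
  full <- cluster_correct(perm, time_ms, cfg, peak_window)

  flips <- with_seed(child_seed(seed, 601L),
                     matrix(sample(c(-1, 1), cfg$n_perm * N, replace = TRUE),
                            cfg$n_perm, N))
  win <- which(time_ms >= peak_window[1] & time_ms <= peak_window[2])
  boot_onsets <- rep(NA_real_, cfg$n_boot_latency)
  boot_peaks <- rep(NA_real_, cfg$n_boot_latency)
  with_seed(child_seed(seed, 613L), {
    for (b in seq_len(cfg$n_boot_latency)) {
      idx <- sample.int(N, N, replace = TRUE)
      Sb <- S[idx, , drop = FALSE] - cfg$chance
      obs <- colMeans(Sb)
      null_means <- flips %*% Sb / N
      ge <- colSums(null_means >= rep(obs, each = cfg$n_perm))
      p <- (1 + ge) / (1 + cfg$n_perm)
      pb <- list(p = p, obs_mean = obs, null_means = null_means, cfg = cfg)
      ci <- cluster_correct(pb, time_ms, cfg, peak_window)
      boot_onsets[b] <- ci$onset_ms
      boot_peaks[b] <- time_ms[win[which.max(obs[win])]]
    }
  })
  prop_def <- mean(!is.na(boot_onsets))
  onset_ci <- if (prop_def > 0.5)
    stats::quantile(boot_onsets, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  else c(NA_real_, NA_real_)
  list(onset_ms = full$onset_ms, onset_ci = onset_ci,
       peak_ms = full$peak_ms,
       peak_ci = stats::quantile(boot_peaks, c(0.025, 0.975), names = FALSE),
       boot_onsets = boot_onsets, boot_peaks = boot_peaks,
       prop_onset_defined = prop_def, inference = full)
}

#' One-sided latency-difference test
#'
#' Compares a bootstrap distribution of latencies for condition A against a
#' scalar reference latency for condition B, under the hypothesis that A is
#' later: p is the proportion of A's bootstrap values at or below the
#' reference (exact-test corrected).  Undefined (NA) bootstrap values are
#' excluded and counted.
#'
#' @param boot_a bootstrap latency distribution for A (ms).
#' @param reference_b scalar latency estimate for B (ms).
#' @return list with `p`, `n_used`, `n_undefined`.
#' @export
latency_difference_test <- function(boot_a, reference_b) {
  keep <- !is.na(boot_a)
  x <- boot_a[keep]
  if (!length(x)) stopf("no defined bootstrap latencies")
  list(p = (1 + sum(x <= reference_b)) / (1 + length(x)),
       n_used = length(x), n_undefined = sum(!keep))
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control at level `q`.
#'
#' @param pvals finite p-values.
#' @param q FDR level.
#' @return logical vector: which hypotheses are rejected.
#' @export
fdr_bh <- function(pvals, q) {
  if (any(!is.finite(pvals))) stopf("p-values must be finite")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Temporal-generalization significance map
#'
#' One-sample t-test of accuracy against chance across participants at every
#' (train, test) coordinate, one-sided (above chance), BH-FDR corrected over
#' all coordinates.  Zero-variance coordinates get p = 0 if their mean
#' exceeds chance and p = 1 otherwise (documented degenerate convention).
#'
#' @param tg_list list of T x T accuracy matrices, one per subject (>= 2).
#' @param cfg a [test_config()] (`fdr_q` is the map-wise level).
#' @return list with `mean` (group-mean matrix), `t`, `p` and `sig_mask`
#'   (all T x T).
#' @export
tg_significance <- function(tg_list, cfg = test_config(fdr_q = 0.05)) {
  if (length(tg_list) < 2) stopf("need >= 2 subjects")
  N <- length(tg_list)
  dm <- dim(tg_list[[1]])
  arr <- array(unlist(tg_list), dim = c(dm, N))
  mu <- apply(arr, c(1, 2), mean) - cfg$chance
  sdv <- apply(arr, c(1, 2), stats::sd)
  tstat <- mu / (sdv / sqrt(N))
  p <- stats::pt(tstat, df = N - 1, lower.tail = FALSE)
  zero <- sdv < 1e-12
  p[zero] <- ifelse(mu[zero] > 0, 0, 1)
  sig <- matrix(fdr_bh(as.vector(p), cfg$fdr_q), dm[1], dm[2])
  list(mean = mu + cfg$chance, t = tstat, p = p, sig_mask = sig)
}

#' Peak-mismatch test
#'
#' Two-sided test of whether a stimulus-derived peak latency is consistent
#' with the bootstrap distribution of MEG decoding peak latencies: twice the
#' smaller tail proportion (exact-test corrected, capped at 1).
#'
#' @param meg_boot_peaks bootstrap MEG peak latencies (ms), e.g. 10000
#'   resamples.
#' @param stimulus_peak_ms stimulus dissimilarity peak (ms).
#' @return p-value.
#' @export
peak_mismatch_test <- function(meg_boot_peaks, stimulus_peak_ms) {
  x <- meg_boot_peaks[!is.na(meg_boot_peaks)]
  n <- length(x)
  lo <- (1 + sum(x <= stimulus_peak_ms)) / (1 + n)
  hi <- (1 + sum(x >= stimulus_peak_ms)) / (1 + n)
  min(1, 2 * min(lo, hi))
}

#' Behavior-MEG correlation with joint bootstrap
#'
#' Spearman correlation across the 6 matched comparison categories (3 source
#' pairs, 3 space pairs) between a behavioral summary (mean RT or accuracy)
#' and an MEG decoding summary (peak latency or peak accuracy).  Point
#' estimate uses the across-subject category means; significance and CI come
#' from jointly resampling both participant pools with replacement
#' `n_boot_behavior` times and recomputing the category means and rho.  The
#' p-value is one-sided for a positive correlation (proportion of bootstrap
#' rho at or below zero, exact-test corrected).
#'
#' @param behavior_summary data.frame: `subject`, `category`, and the value
#'   column named by `behavior_var`.
#' @param meg_summary data.frame: `subject`, `category`, and the value
#'   column named by `meg_var`.
#' @param behavior_var,meg_var column names to correlate.
#' @param cfg a [test_config()].
#' @param seed integer seed.
#' @return list with `rho`, `p`, `ci`, `boot_rho`, `categories`.
#' @export
behavior_meg_correlation <- function(behavior_summary, meg_summary,
                                     behavior_var = "rt_ms",
                                     meg_var = "peak_ms",
                                     cfg = test_config(), seed = 1) {
  cats <- sort(unique(behavior_summary$category))
  if (!setequal(cats, unique(meg_summary$category)))
    stopf("behavioral and MEG category sets differ")
  cat_means <- function(df, var, subj) {
    df <- df[df$subject %in% subj, ]
    # average within subject first, then across the (possibly repeated) pool
    agg <- tapply(df[[var]], list(df$subject, df$category), mean)
    out <- numeric(length(cats))
    for (i in seq_along(cats))
      out[i] <- mean(agg[match(subj, rownames(agg)), cats[i]])
    out
  }
  bs <- unique(behavior_summary$subject)
  ms <- unique(meg_summary$subject)
  bx <- cat_means(behavior_summary, behavior_var, bs)
  my <- cat_means(meg_summary, meg_var, ms)
  if (stats::sd(bx) < 1e-12 || stats::sd(my) < 1e-12)
    stopf("constant summaries: Spearman correlation undefined")
  rho <- stats::cor(bx, my, method = "spearman")
  boot_rho <- with_seed(child_seed(seed, 701L), {
    vapply(seq_len(cfg$n_boot_behavior), function(b) {
      rb <- sample(bs, length(bs), replace = TRUE)
      rm_ <- sample(ms, length(ms), replace = TRUE)
      xb <- cat_means(behavior_summary, behavior_var, rb)
      yb <- cat_means(meg_summary, meg_var, rm_)
      if (stats::sd(xb) < 1e-12 || stats::sd(yb) < 1e-12) return(NA_real_)
      stats::cor(xb, yb, method = "spearman")
    }, numeric(1))
  })
  ok <- boot_rho[!is.na(boot_rho)]
  list(rho = rho,
       p = (1 + sum(ok <= 0)) / (1 + length(ok)),
       ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
       boot_rho = boot_rho, categories = cats)
}
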